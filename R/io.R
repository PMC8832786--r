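#' Read and write FASTA
#'
#' Biostrings-backed FASTA I/O returning/consuming tidy tibbles so sequence
#' sets flow through the same pipes as every other table.
#'
#' @param path FASTA file.
#' @param id_col,seq_col column names used for identifiers and sequences.
#' @return `read_fasta()` returns a tibble with the id and sequence columns.
#' @export
read_fasta <- function(path, id_col = "contig_id", seq_col = "sequence") {
  set <- Biostrings::readBStringSet(path)
  out <- tibble::tibble(
    id = stringr::str_extract(names(set), "^\\S+"),
    seq = as.character(set)
  )
  stats::setNames(out, c(id_col, seq_col))
}

#' @param x named character vector of sequences, or a tibble with id and
#'   sequence columns.
#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, id_col = "contig_id", seq_col = "sequence") {
  if (is.data.frame(x)) x <- stats::setNames(x[[seq_col]], x[[id_col]])
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), path, width = 70L)
  invisible(path)
}

#' Write annotated NLR loci as GFF3
#'
#' One `NLR_locus` feature per locus, 1-based inclusive coordinates, with
#' `ID`, `completeness` and `motif_chain` attributes.
#'
#' @param loci locus tibble (see [chain_loci()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  lines <- c("##gff-version 3")
  if (nrow(loci) > 0L) {
    chain <- vapply(loci$motif_chain, paste, character(1), collapse = ",")
    completeness <- loci$completeness %||% rep(".", nrow(loci))
    lines <- c(lines, paste(
      loci$contig_id, "nlrkit", "NLR_locus",
      loci$start + 1L, loci$end, ".", loci$strand, ".",
      paste0("ID=", loci$locus_id,
             ";completeness=", completeness,
             ";motif_chain=", chain),
      sep = "\t"
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
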