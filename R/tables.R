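# Readers for the published-style worked-example tables shipped under
# inst/extdata (transcribed from a published SMRT-RenSeq survey of the
# H. villosa NLR complement) and for user-supplied tables of the same shape.

#' Path to a bundled example table
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path, or a character vector of file names.
#' @export
nlrkit_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "nlrkit")))
  }
  path <- system.file("extdata", file, package = "nlrkit")
  if (!nzchar(path)) stop("no bundled file '", file, "'", call. = FALSE)
  path
}

#' Read a chromosomal-location table
#'
#' One row per physically mapped NLR marker: in-silico best-hit chromosome in
#' each reference genome plus the physical chromosome arm from
#' translocation-line PCR. Duplicate rows (a marker mapped under two arms)
#' are kept; [congruence_report()] surfaces them.
#'
#' @param path TSV with columns `nlr_gene`, `status`, one chromosome column
#'   per genome, `physical_arm`.
#' @return tibble.
#' @export
read_location_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read an R-gene orthologue screen table
#'
#' One row per catalog NLR matched to a cloned R gene, with percent identity
#' and coverage against the query, the in-silico location, and (for anchored
#' loci such as Mla) the subject locus position in Mb.
#'
#' @param path TSV with columns `r_gene`, `r_gene_group`, `locus_mb`,
#'   `nlr_gene`, `in_silico_location`, `nlr_type`, `protein_length`,
#'   `identity`, `coverage`.
#' @return tibble with an added integer `nlr_group` column parsed from
#'   `in_silico_location`.
#' @export
read_orthologue_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  tbl$nlr_group <- chrom_number(tbl$in_silico_location)
  tbl
}

#' Read an integrated-domain membership table
#'
#' One row per integrated domain with the set of genomes it was detected in.
#'
#' @param path TSV with columns `id_name`, `description`, `genomes`
#'   (comma-separated genome labels).
#' @return `IdMembershipTable` tibble; `genomes` becomes a list-column.
#' @export
read_id_membership <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  tbl$genomes <- strsplit(tbl$genomes, ",\\s*")
  tbl
}
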