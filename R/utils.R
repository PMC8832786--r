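# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed summary tables here follow the
#' usual half-up convention (80.05 -> 80.1 at one decimal).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Translate a DNA string (character) in frame 0; ambiguous codons become X.
#' @noRd
translate_dna <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(substr(x, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

# codons per amino acid, stops excluded (used for reverse translation)
.codon_table <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# Reverse-translate an amino-acid string with uniformly sampled synonymous
# codons. Uses the current RNG stream.
#' @noRd
reverse_translate <- function(aa) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  codons <- vapply(chars, function(a) {
    opts <- .codon_table[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue '", a, "'")
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

# Random DNA background at a given GC content. Uses the current RNG stream.
#' @noRd
random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Random amino-acid string over the 20 standard residues (no stops).
#' @noRd
random_aa <- function(n) {
  paste(sample(setdiff(names(.codon_table), "*"), n, replace = TRUE),
        collapse = "")
}

# Unique k-mer set of a sequence (uppercased).
#' @noRd
kmer_set <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  unique(substring(seq, seq_len(n), seq_len(n) + k - 1L))
}

# Containment of the smaller k-mer set in the larger one, in [0, 1].
#' @noRd
kmer_containment <- function(set_a, set_b) {
  if (length(set_a) == 0L || length(set_b) == 0L) return(0)
  length(intersect(set_a, set_b)) / min(length(set_a), length(set_b))
}

#' @noRd
assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' @noRd
assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    stop(name, " must be an integer >= ", min, call. = FALSE)
  }
  invisible(as.integer(x))
}

# Leading chromosome number of labels like "1A", "7D"; NA for "Un"/unparsable.
#' @noRd
chrom_number <- function(chrom) {
  num <- suppressWarnings(as.integer(stringr::str_extract(chrom, "^[0-9]+")))
  num[chrom %in% c("Un", "un", "UN", "", NA_character_)] <- NA_integer_
  num
}
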