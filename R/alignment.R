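# Thin wrappers around Biostrings::pairwiseAlignment used by several stages.
# Identity is always computed over alignment columns excluding terminal gaps
# (semi-global / "overlap" alignments), matching cd-hit-like behaviour for
# capture contigs that differ mainly by end truncation.

.dna_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2, baseOnly = FALSE)
}

# Semi-global DNA alignment; returns identity and coverage (percent).
# coverage = aligned fraction of the shorter sequence.
#' @noRd
align_overlap_dna <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "overlap", substitutionMatrix = .dna_submat(),
    gapOpening = 5, gapExtension = 2
  )
  .overlap_metrics(pa, nchar(a), nchar(b))
}

# Semi-global protein alignment (BLOSUM62).
#' @noRd
align_overlap_protein <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "overlap", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  .overlap_metrics(pa, nchar(a), nchar(b))
}

#' @noRd
.overlap_metrics <- function(pa, len_a, len_b) {
  ni <- Biostrings::nindel(pa)
  ncols <- Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
    sum(Biostrings::insertion(ni)[, "WidthSum"]) +
    sum(Biostrings::deletion(ni)[, "WidthSum"]) # cols excl. terminal gaps
  identity <- if (ncols > 0) 100 * Biostrings::nmatch(pa) / ncols else 0
  w_a <- Biostrings::width(Biostrings::pattern(pa))
  w_b <- Biostrings::width(Biostrings::subject(pa))
  shorter <- if (len_a <= len_b) w_a / len_a else w_b / len_b
  list(
    identity = identity,
    coverage = 100 * shorter,
    coverage_pattern = 100 * w_a / len_a,
    coverage_subject = 100 * w_b / len_b
  )
}

# Global alignment p-distance: mismatches / columns where both sequences are
# non-gap. High gap penalties so equal-length substitution-only pairs align
# without gaps.
#' @noRd
align_pdistance <- function(a, b, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "protein") {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 12, gapExtension = 2
    )
  } else {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
      type = "global", substitutionMatrix = .dna_submat(),
      gapOpening = 8, gapExtension = 3
    )
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- p != "-" & s != "-"
  if (!any(keep)) return(1)
  mean(p[keep] != s[keep])
}

# Indels of a global alignment of query vs subject, reported in query
# coordinates. type "del" = bases missing from the query relative to the
# subject (gap in query), "ins" = extra bases in the query (gap in subject).
#' @noRd
align_indels <- function(query, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(query)), Biostrings::DNAString(toupper(subject)),
    type = "global", substitutionMatrix = .dna_submat(),
    gapOpening = 8, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- cumsum(p != "-") # query coordinate at each column
  runs <- function(gap_in) {
    r <- rle(gap_in)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tibble::tibble(col_start = starts[r$values], col_end = ends[r$values])
  }
  del <- runs(p == "-")
  ins <- runs(s == "-")
  out <- dplyr::bind_rows(
    dplyr::mutate(del, type = "del"),
    dplyr::mutate(ins, type = "ins")
  )
  if (nrow(out) == 0L) {
    return(tibble::tibble(position = integer(0), length = integer(0),
                          type = character(0)))
  }
  out$position <- qpos[out$col_start] # last query base before/at event start
  out$length <- out$col_end - out$col_start + 1L
  dplyr::arrange(out[, c("position", "length", "type")], .data$position)
}
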