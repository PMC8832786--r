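# Contig post-processing: redundancy removal at a percent-identity cutoff,
# rescue rules for removed contigs, and low-complexity soft-masking.

#' Pairwise percent identity and coverage of two sequences
#'
#' Semi-global (end-gap-free) alignment identity: matches over alignment
#' columns excluding terminal-gap columns, as a percentage. Coverage is the
#' aligned fraction of the shorter sequence. Symmetric in its arguments.
#'
#' @param a,b DNA sequences (character scalars).
#' @return named numeric vector `c(identity = , coverage = )`.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGAACGT") # 87.5, 100
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  m <- align_overlap_dna(a, b)
  c(identity = m$identity, coverage = m$coverage)
}

#' Remove redundant contigs at an identity threshold
#'
#' Greedy longest-first clustering in the cd-hit style: contigs are sorted by
#' length (descending, ties by id) and each is compared against the retained
#' representatives; a contig whose identity to a representative exceeds
#' `threshold` is removed and linked to it. A k-mer containment prefilter
#' avoids aligning unrelated pairs.
#'
#' @param contigs tibble (`contig_id`, `sequence`).
#' @param threshold percent identity in (50, 100]; default 95 (contigs
#'   sharing more than 95% identity are removed).
#' @param prefilter_k,prefilter_min k-mer size and minimum containment for a
#'   pair to be aligned at all.
#' @return a `ClusterDecision` tibble: `contig_id`, `status`
#'   (`retained`/`removed`), `matched_id`, `identity`, `reason`.
#' @export
remove_redundant <- function(contigs, threshold = 95,
                             prefilter_k = 12L, prefilter_min = 0.3) {
  if (threshold <= 50 || threshold > 100) {
    stop("threshold must be in (50, 100]", call. = FALSE)
  }
  if (anyDuplicated(contigs$contig_id)) stop("duplicate contig ids", call. = FALSE)
  ord <- order(-nchar(contigs$sequence), contigs$contig_id)
  contigs <- contigs[ord, ]
  ksets <- lapply(contigs$sequence, kmer_set, k = prefilter_k)
  n <- nrow(contigs)
  status <- rep("retained", n)
  matched <- rep(NA_character_, n)
  identity <- rep(NA_real_, n)
  reason <- rep("unique", n)
  reps <- integer(0)
  for (i in seq_len(n)) {
    for (r in reps) {
      if (kmer_containment(ksets[[i]], ksets[[r]]) < prefilter_min) next
      m <- align_overlap_dna(contigs$sequence[i], contigs$sequence[r])
      if (m$identity > threshold) {
        status[i] <- "removed"
        matched[i] <- contigs$contig_id[r]
        identity[i] <- m$identity
        reason[i] <- "duplicate_gt_threshold"
        break
      }
    }
    if (status[i] == "retained") reps <- c(reps, i)
  }
  tibble::tibble(contig_id = contigs$contig_id, status = status,
                 matched_id = matched, identity = identity, reason = reason)
}

#' Re-annotate removed contigs and apply the rescue rules
#'
#' Contigs discarded as redundant can still carry genuine loci (recent
#' duplications, residual heterozygosity). Each removed contig is
#' re-annotated; a contig with no complete NLR is dropped; one whose complete
#' NLR is more than 99% identical to an already-annotated NLR is dropped as a
#' true duplicate; complete NLRs at 95-99% identity are rescued and join the
#' catalog.
#'
#' @param decisions `ClusterDecision` tibble from [remove_redundant()].
#' @param contigs the full contig tibble the decisions refer to.
#' @param catalog_loci annotated locus tibble for the retained set (must carry
#'   `locus_id`, `contig_id`, `start`, `end`, `completeness`).
#' @param annotate_fn function(contigs_tibble) -> locus tibble, used to
#'   re-annotate removed contigs (typically a partial of [annotate_contigs()]).
#' @return `decisions` with removed rows updated to `rescued`/`removed` and
#'   reasons `rescue_complete_95_99`, `drop_complete_gt99` or
#'   `drop_no_or_partial_nlr`; rescued loci are attached as the
#'   `"rescued_loci"` attribute.
#' @export
rescue_removed <- function(decisions, contigs, catalog_loci, annotate_fn) {
  removed_ids <- decisions$contig_id[decisions$status == "removed"]
  if (length(removed_ids) == 0L) {
    attr(decisions, "rescued_loci") <- catalog_loci[0, ]
    return(decisions)
  }
  catalog_seq <- locus_sequences(catalog_loci[catalog_loci$completeness ==
                                                "complete", , drop = FALSE], contigs)
  rescued <- list()
  for (cid in removed_ids) {
    sub <- contigs[contigs$contig_id == cid, ]
    loci <- annotate_fn(sub)
    complete <- loci[loci$completeness == "complete", , drop = FALSE]
    row <- which(decisions$contig_id == cid)
    if (nrow(complete) == 0L) {
      decisions$reason[row] <- "drop_no_or_partial_nlr"
      next
    }
    seqs <- locus_sequences(complete, sub)
    best <- vapply(seqs, function(s) {
      if (length(catalog_seq) == 0L) return(0)
      max(vapply(catalog_seq, function(cs) align_overlap_dna(s, cs)$identity,
                 numeric(1)))
    }, numeric(1))
    if (all(best > 99)) {
      decisions$reason[row] <- "drop_complete_gt99"
    } else {
      decisions$status[row] <- "rescued"
      decisions$reason[row] <- "rescue_complete_95_99"
      decisions$identity[row] <- max(best)
      rescued[[cid]] <- complete[best <= 99, , drop = FALSE]
    }
  }
  attr(decisions, "rescued_loci") <- dplyr::bind_rows(rescued)
  decisions
}

# forward-strand genomic sequence of each locus, named by locus_id
#' @noRd
locus_sequences <- function(loci, contigs) {
  if (nrow(loci) == 0L) return(character(0))
  seqs <- vapply(seq_len(nrow(loci)), function(i) {
    ctg <- contigs$sequence[contigs$contig_id == loci$contig_id[i]]
    substr(ctg, loci$start[i] + 1L, loci$end[i])
  }, character(1))
  stats::setNames(seqs, loci$locus_id)
}

#' Soft-mask low-complexity sequence
#'
#' DUST-style triplet-entropy masking: windows whose triplet composition is
#' dominated by few triplets are lowercased. Length-preserving, idempotent,
#' and ignored by the case-insensitive motif scanner only where masking is
#' requested.
#'
#' @param seq DNA character scalar (or vector, masked element-wise).
#' @param window window size in bp (>= 3).
#' @param threshold DUST score above which a window is masked; the score of a
#'   window is `sum(c_t * (c_t - 1) / 2) / (n_triplets - 1)` over triplet
#'   counts `c_t`. Random sequence scores ~0.5; homopolymers score ~w/2.
#' @return the sequence with masked stretches in lowercase.
#' @export
mask_low_complexity <- function(seq, window = 64L, threshold = 2) {
  if (length(seq) > 1L) {
    return(vapply(seq, mask_low_complexity, character(1),
                  window = window, threshold = threshold, USE.NAMES = FALSE))
  }
  if (window < 3L) stop("window must be >= 3", call. = FALSE)
  up <- toupper(seq)
  n <- nchar(up)
  if (n < window) return(seq)
  base_code <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  chars <- strsplit(up, "")[[1]]
  code <- unname(base_code[chars])
  code[is.na(code)] <- 0L
  tri <- code[1:(n - 2L)] * 16L + code[2:(n - 1L)] * 4L + code[3:n] + 1L
  starts <- seq(1L, n - window + 1L, by = max(1L, window %/% 2L))
  if (utils::tail(starts, 1L) != n - window + 1L) starts <- c(starts, n - window + 1L)
  mask <- logical(n)
  k <- window - 2L # triplets per window
  for (s in starts) {
    cnt <- tabulate(tri[s:(s + k - 1L)], nbins = 64L)
    score <- sum(cnt * (cnt - 1L) / 2) / (k - 1L)
    if (score > threshold) mask[s:(s + window - 1L)] <- TRUE
  }
  if (any(mask)) chars[mask] <- tolower(chars[mask])
  # preserve prior soft-masking (idempotence over already-masked input)
  prior <- strsplit(seq, "")[[1]] %in% c("a", "c", "g", "t", "n")
  chars[prior] <- tolower(chars[prior])
  paste(chars, collapse = "")
}
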