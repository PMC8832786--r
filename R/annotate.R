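# Motif scanning and locus chaining: contigs are scanned in all six reading
# frames for library motifs; same-strand hits are chained into NLR loci, with
# a border split before a fresh P-loop once a chain already carries LRR hits,
# so adjacent NLRs on long contigs are separated.

# Six-frame translations of a contig set; returns a list keyed "<strand><frame>"
# of AAStringSets (one entry per contig), uppercased (scanning ignores case).
#' @noRd
six_frame_translations <- function(contigs) {
  dna <- Biostrings::DNAStringSet(toupper(contigs$sequence))
  names(dna) <- contigs$contig_id
  rc <- Biostrings::reverseComplement(dna)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else rc
    for (f in 0:2) {
      L <- Biostrings::width(s)
      w <- pmax(0L, ((L - f) %/% 3L) * 3L)
      sub <- Biostrings::subseq(s, start = pmin(f + 1L, L + 1L), width = w)
      out[[paste0(strand, f)]] <- suppressWarnings(
        Biostrings::translate(sub, if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
  }
  out
}

#' Scan contigs for library motifs in all six reading frames
#'
#' Every translation window whose identity to a motif consensus reaches the
#' motif's score threshold is reported with forward-strand, 0-based half-open
#' nucleotide coordinates. Scanning is case-insensitive (soft-masked input is
#' scanned unchanged) and strand-symmetric.
#'
#' @param contigs tibble (`contig_id`, `sequence`); sequences over ACGTN,
#'   case ignored.
#' @param library a motif library ([generate_motif_library()]).
#' @return `MotifHit` tibble: `contig_id`, `motif_id`, `category`, `frame`,
#'   `strand`, `start`, `end`, `aa_start`, `score`, sorted by contig and
#'   start. Contigs shorter than the shortest motif yield no rows.
#' @export
scan_motifs <- function(contigs, library) {
  library <- validate_motif_library(library)
  if (nrow(contigs) == 0L) return(.empty_hits())
  frames <- six_frame_translations(contigs)
  frame_chars <- lapply(frames, as.character)
  L <- stats::setNames(nchar(contigs$sequence), contigs$contig_id)
  res <- list()
  for (key in names(frames)) {
    strand <- substr(key, 1L, 1L)
    f <- as.integer(substr(key, 2L, 2L))
    set <- frames[[key]]
    chars <- frame_chars[[key]]
    for (m in seq_len(nrow(library))) {
      cons <- library$consensus[m]
      w <- nchar(cons)
      mm_allowed <- floor(w * (1 - library$score_threshold[m]))
      hits <- Biostrings::vmatchPattern(Biostrings::AAString(cons), set,
                                        max.mismatch = mm_allowed)
      counts <- S4Vectors::elementNROWS(hits)
      if (sum(counts) == 0L) next
      idx <- which(counts > 0L)
      for (i in idx) {
        starts <- BiocGenerics::start(hits[[i]])
        cid <- names(set)[i]
        for (p in starts) {
          window <- substr(chars[i], p, p + w - 1L)
          score <- mean(strsplit(window, "")[[1]] == strsplit(cons, "")[[1]])
          if (score < library$score_threshold[m]) next
          if (strand == "+") {
            s0 <- f + 3L * (p - 1L)
            e0 <- s0 + 3L * w
          } else {
            rc_s0 <- f + 3L * (p - 1L)
            rc_e0 <- rc_s0 + 3L * w
            s0 <- L[[cid]] - rc_e0
            e0 <- L[[cid]] - rc_s0
          }
          res[[length(res) + 1L]] <- tibble::tibble(
            contig_id = cid, motif_id = library$motif_id[m],
            category = library$category[m], frame = f, strand = strand,
            start = s0, end = e0, aa_start = p, score = score
          )
        }
      }
    }
  }
  if (length(res) == 0L) return(.empty_hits())
  dplyr::arrange(dplyr::bind_rows(res), .data$contig_id, .data$start, .data$end)
}

#' @noRd
.empty_hits <- function() {
  tibble::tibble(contig_id = character(0), motif_id = character(0),
                 category = character(0), frame = integer(0),
                 strand = character(0), start = integer(0), end = integer(0),
                 aa_start = integer(0), score = numeric(0))
}

#' Chain motif hits into NLR loci
#'
#' Same-strand hits within `max_gap_bp` of each other (walked 5' to 3' on
#' their own strand) form one chain; a chain is split before a fresh P-loop
#' hit once it already contains at least one LRR-category hit, which is what
#' separates tandem NLRs that sit closer than the chaining gap. Each chain
#' becomes a locus spanning its outermost hits; locus ids follow the
#' `<contig>_nlr_<k>` convention with `k` increasing along the forward
#' strand. Chaining is invariant to hit input order.
#'
#' @param hits `MotifHit` tibble from [scan_motifs()] (any number of contigs).
#' @param library the motif library used for the scan.
#' @param max_gap_bp maximum within-locus gap between consecutive hits.
#' @return `NlrLocus` tibble: `locus_id`, `contig_id`, `start`, `end`,
#'   `strand`, `motif_chain` (list of motif ids, 5' to 3'), `locus_hits`
#'   (nested hit tibble).
#' @export
chain_loci <- function(hits, library, max_gap_bp = 3000) {
  library <- validate_motif_library(library)
  p_loop_id <- library$motif_id[library$p_loop]
  out <- list()
  for (cid in unique(hits$contig_id)) {
    chains <- list()
    for (strand in c("+", "-")) {
      h <- hits[hits$contig_id == cid & hits$strand == strand, ]
      if (nrow(h) == 0L) next
      h <- if (strand == "+") h[order(h$start, h$end), ] else h[order(-h$start, -h$end), ]
      cur <- integer(0); has_lrr <- FALSE
      flush <- function(rows) if (length(rows)) chains[[length(chains) + 1L]] <<- h[rows, ]
      for (i in seq_len(nrow(h))) {
        gap <- if (length(cur) == 0L) 0 else {
          prev <- h[cur[length(cur)], ]
          if (strand == "+") h$start[i] - prev$end else prev$start - h$end[i]
        }
        new_chain <- length(cur) == 0L || gap > max_gap_bp ||
          (h$motif_id[i] == p_loop_id && has_lrr)
        if (new_chain && length(cur)) {
          flush(cur); cur <- integer(0); has_lrr <- FALSE
        }
        cur <- c(cur, i)
        if (h$category[i] == "LRR") has_lrr <- TRUE
      }
      flush(cur)
    }
    if (length(chains) == 0L) next
    loci <- purrr::map_dfr(chains, function(ch) {
      tibble::tibble(
        contig_id = cid,
        start = min(ch$start), end = max(ch$end),
        strand = ch$strand[1],
        motif_chain = list(ch$motif_id),
        locus_hits = list(ch)
      )
    })
    loci <- loci[order(loci$start, loci$end), ]
    loci$locus_id <- paste0(cid, "_nlr_", seq_len(nrow(loci)))
    out[[cid]] <- loci
  }
  if (length(out) == 0L) {
    return(tibble::tibble(locus_id = character(0), contig_id = character(0),
                          start = integer(0), end = integer(0),
                          strand = character(0), motif_chain = list(),
                          locus_hits = list()))
  }
  dplyr::bind_rows(out)[, c("locus_id", "contig_id", "start", "end", "strand",
                            "motif_chain", "locus_hits")]
}

#' Classify locus completeness and pseudogene status
#'
#' A locus is complete iff its motif chain contains the P-loop motif, the
#' NB-ARC start motif and at least one LRR-category motif; otherwise partial.
#' Independently, a locus is flagged `*_pseudogene` when its chain span shows
#' an in-frame stop codon (in the modal reading frame of its hits) or a frame
#' inconsistency between same-strand hits.
#'
#' @param loci locus tibble from [chain_loci()].
#' @param contigs contig tibble providing the sequence under each locus.
#' @param library the motif library.
#' @return `loci` with a `completeness` column (`complete`,
#'   `complete_pseudogene`, `partial`, `partial_pseudogene`).
#' @export
classify_completeness <- function(loci, contigs, library) {
  library <- validate_motif_library(library)
  p_loop_id <- library$motif_id[library$p_loop]
  nb_start_id <- library$motif_id[library$nb_start]
  seqs <- stats::setNames(toupper(contigs$sequence), contigs$contig_id)
  loci$completeness <- vapply(seq_len(nrow(loci)), function(i) {
    chain <- loci$motif_chain[[i]]
    h <- loci$locus_hits[[i]]
    cats <- library$category[match(chain, library$motif_id)]
    complete <- p_loop_id %in% chain && nb_start_id %in% chain && "LRR" %in% cats
    pseudo <- length(unique(h$frame)) > 1L
    if (!pseudo) {
      ctg <- seqs[[loci$contig_id[i]]]
      f <- h$frame[1]
      if (loci$strand[i] == "+") {
        span <- substr(ctg, loci$start[i] + 1L, loci$end[i])
        off <- (f - loci$start[i]) %% 3L
      } else {
        L <- nchar(ctg)
        rc <- revcomp(ctg)
        span <- substr(rc, L - loci$end[i] + 1L, L - loci$start[i])
        off <- (f - (L - loci$end[i])) %% 3L
      }
      aa <- translate_dna(substr(span, off + 1L, nchar(span)))
      pseudo <- grepl("*", aa, fixed = TRUE)
    }
    paste0(if (complete) "complete" else "partial",
           if (pseudo) "_pseudogene" else "")
  }, character(1))
  loci
}

#' Annotate a contig set end to end
#'
#' Convenience wrapper: [scan_motifs()], [chain_loci()],
#' [classify_completeness()].
#'
#' @inheritParams scan_motifs
#' @inheritParams chain_loci
#' @return classified locus tibble.
#' @export
annotate_contigs <- function(contigs, library, max_gap_bp = 3000) {
  hits <- scan_motifs(contigs, library)
  loci <- chain_loci(hits, library, max_gap_bp = max_gap_bp)
  classify_completeness(loci, contigs, library)
}

#' Compare annotated loci against planted truth
#'
#' A predicted locus recovers a truth locus when both sit on the same contig
#' and strand and their spans overlap at least half of the truth span;
#' matching is one-to-one. Classes are compared on the motif-chain grammar
#' (see [classify_motif_chain()]).
#'
#' @param loci classified locus tibble ([annotate_contigs()]).
#' @param truth planted truth ([generate_contig_set()]).
#' @param library the motif library.
#' @return one-row tibble: `n_truth`, `n_predicted`, `n_matched`,
#'   `precision`, `recall`, `completeness_agreement`, `class_agreement`.
#' @export
evaluate_recovery <- function(loci, truth, library) {
  matched_truth <- rep(NA_integer_, nrow(loci))
  used <- logical(nrow(truth))
  for (i in seq_len(nrow(loci))) {
    cand <- which(!used & truth$contig_id == loci$contig_id[i] &
                    truth$strand == loci$strand[i])
    for (j in cand) {
      ov <- min(loci$end[i], truth$end[j]) - max(loci$start[i], truth$start[j])
      if (ov >= 0.5 * (truth$end[j] - truth$start[j])) {
        matched_truth[i] <- j; used[j] <- TRUE; break
      }
    }
  }
  ok <- !is.na(matched_truth)
  n_matched <- sum(ok)
  comp_agree <- class_agree <- NA_real_
  if (n_matched > 0L) {
    tm <- truth[matched_truth[ok], ]
    comp_agree <- mean(loci$completeness[ok] == tm$true_completeness)
    pred_class <- vapply(loci$motif_chain[ok], classify_motif_chain, character(1),
                         library = library)
    class_agree <- mean(pred_class == tm$true_class)
  }
  tibble::tibble(
    n_truth = nrow(truth), n_predicted = nrow(loci), n_matched = n_matched,
    precision = if (nrow(loci)) n_matched / nrow(loci) else NA_real_,
    recall = if (nrow(truth)) n_matched / nrow(truth) else NA_real_,
    completeness_agreement = comp_agree,
    class_agreement = class_agree
  )
}
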