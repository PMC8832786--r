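# Homology-guided protein prediction: each locus is extended by a flank on
# both sides, open reading frames overlapping the locus are collected, the
# best homolog picks the reading and the start codon, and a single optional
# GT..AG intron is recovered where the homolog alignment shows a contiguous
# inserted block.

#' Predict coding sequences and proteins for annotated loci
#'
#' The locus interval is extended by `flank` bp on both sides (clipped to the
#' contig); ORFs on the locus strand overlapping the locus are translated and
#' screened against the homolog database; the homolog with the highest
#' identity (ties by longer coverage) guides start-codon choice and intron
#' recovery. Loci whose best homolog identity falls below `min_identity` are
#' flagged unpredicted rather than failing.
#'
#' @param loci locus tibble ([annotate_contigs()]); typically filtered to
#'   complete loci.
#' @param contigs contig tibble.
#' @param homolog_db tibble (`protein_id`, `protein`); must be non-empty.
#' @param flank extension in bp on each side (default 3000).
#' @param min_identity floor percent identity for accepting a homolog.
#' @return `PredictedProtein` tibble: `locus_id`, `predicted`, `cds`
#'   (spliced), `protein`, `homolog_id`, `homolog_identity`,
#'   `homolog_coverage`, `intron_offset`, `intron_length` (0-based nt within
#'   the unspliced gene), `genomic_span` (unspliced gene sequence, 5'->3').
#' @export
predict_protein <- function(loci, contigs, homolog_db, flank = 3000,
                            min_identity = 40) {
  if (nrow(homolog_db) == 0L) stop("homolog_db is empty", call. = FALSE)
  hom_kmers <- lapply(homolog_db$protein, kmer_set, k = 5L)
  seqs <- stats::setNames(toupper(contigs$sequence), contigs$contig_id)
  purrr::map_dfr(seq_len(nrow(loci)), function(i) {
    locus <- loci[i, ]
    ctg <- seqs[[locus$contig_id]]
    win_start <- max(0L, locus$start - flank)
    win_end <- min(nchar(ctg), locus$end + flank)
    window <- substr(ctg, win_start + 1L, win_end)
    if (locus$strand == "-") {
      window <- revcomp(window)
      span <- c(win_end - locus$end, win_end - locus$start)
    } else {
      span <- c(locus$start - win_start, locus$end - win_start)
    }
    best <- .best_orf_homolog(window, span, homolog_db, hom_kmers)
    if (is.null(best) || best$identity < min_identity) {
      return(tibble::tibble(
        locus_id = locus$locus_id, predicted = FALSE, cds = NA_character_,
        protein = NA_character_, homolog_id = NA_character_,
        homolog_identity = NA_real_, homolog_coverage = NA_real_,
        intron_offset = NA_integer_, intron_length = NA_integer_,
        genomic_span = NA_character_))
    }
    fit <- .fit_gene(window, best, homolog_db$protein[best$hom])
    m <- align_overlap_protein(fit$protein, homolog_db$protein[best$hom])
    tibble::tibble(
      locus_id = locus$locus_id, predicted = TRUE,
      cds = fit$cds, protein = fit$protein,
      homolog_id = homolog_db$protein_id[best$hom],
      homolog_identity = m$identity, homolog_coverage = m$coverage_subject,
      intron_offset = fit$intron_offset, intron_length = fit$intron_length,
      genomic_span = fit$genomic_span)
  })
}

# Pick the ORF segment + homolog combination with the best protein identity.
#' @noRd
.best_orf_homolog <- function(window, span, homolog_db, hom_kmers) {
  best <- NULL
  for (f in 0:2) {
    aa <- translate_dna(substr(window, f + 1L, nchar(window)))
    if (!nzchar(aa)) next
    pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
    offset <- 0L # aa offset of piece start within the frame translation
    for (seg in pieces) {
      seg_off <- offset
      offset <- offset + nchar(seg) + 1L
      if (nchar(seg) < 100L) next
      nt0 <- f + 3L * seg_off
      nt1 <- f + 3L * (seg_off + nchar(seg))
      if (nt1 <= span[1] || nt0 >= span[2]) next # must overlap the locus
      if (!grepl("M", seg, fixed = TRUE)) next
      cand <- order(vapply(hom_kmers, kmer_containment,
                           numeric(1), set_a = kmer_set(seg, 5L)),
                    decreasing = TRUE)[seq_len(min(3L, nrow(homolog_db)))]
      for (h in cand) {
        m <- align_overlap_protein(seg, homolog_db$protein[h])
        if (is.null(best) || m$identity > best$identity ||
            (m$identity == best$identity &&
             m$coverage_subject > best$coverage)) {
          best <- list(frame = f, seg = seg, seg_off = seg_off, hom = h,
                       identity = m$identity, coverage = m$coverage_subject)
        }
      }
    }
  }
  best
}

# Choose the start codon nearest the homolog's aligned start, then attempt
# single-intron recovery against the homolog.
#' @noRd
.fit_gene <- function(window, best, homolog) {
  seg <- best$seg
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seg), Biostrings::AAString(homolog),
    type = "overlap", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  aln_start <- BiocGenerics::start(Biostrings::pattern(pa))
  m_pos <- stringr::str_locate_all(seg, "M")[[1]][, 1]
  start_aa <- m_pos[which.min(abs(m_pos - aln_start))]
  protein <- substr(seg, start_aa, nchar(seg))
  # unspliced gene: chosen ATG through the stop codon, window coordinates
  g0 <- best$frame + 3L * (best$seg_off + start_aa - 1L) # 0-based
  g1 <- best$frame + 3L * (best$seg_off + nchar(seg)) + 3L
  genomic <- substr(window, g0 + 1L, min(g1, nchar(window)))
  fit <- list(cds = genomic, protein = protein, genomic_span = genomic,
              intron_offset = NA_integer_, intron_length = NA_integer_)
  refined <- .refine_intron(genomic, protein, homolog)
  if (!is.null(refined)) fit[names(refined)] <- refined
  fit
}

# Single-intron refinement: a contiguous run of residues inserted relative to
# the homolog marks a translated intron; GT donors / AG acceptors near the
# run boundaries are tried and the splice maximising identity is kept.
#' @noRd
.refine_intron <- function(genomic, protein, homolog) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein), Biostrings::AAString(homolog),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 12, gapExtension = 0.5)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ins <- s == "-"
  if (!any(ins)) return(NULL)
  r <- rle(ins)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= 10L)
  if (length(runs) == 0L) return(NULL)
  run <- runs[which.max(r$lengths[runs])]
  qpos <- cumsum(p != "-")
  a1 <- qpos[starts[run]]; a2 <- qpos[ends[run]] # inserted aa range
  base_id <- align_overlap_protein(protein, homolog)$identity
  donor_lo <- max(0L, 3L * (a1 - 6L)); donor_hi <- 3L * (a1 + 5L)
  acc_lo <- 3L * (a2 - 5L); acc_hi <- min(nchar(genomic), 3L * (a2 + 6L))
  chars <- strsplit(genomic, "")[[1]]
  donors <- which(chars == "G" & dplyr::lead(chars) == "T") - 1L # 0-based
  donors <- donors[donors >= donor_lo & donors <= donor_hi]
  accept <- which(chars == "A" & dplyr::lead(chars) == "G") + 1L # 0-based end
  accept <- accept[accept >= acc_lo & accept <= acc_hi]
  best <- NULL
  for (d in donors) {
    for (a in accept) {
      len <- a - d
      if (len < 30L || len %% 3L != 0L) next
      spliced <- paste0(substr(genomic, 1L, d), substr(genomic, a + 1L, nchar(genomic)))
      aa <- translate_dna(spliced)
      aa <- sub("\\*.*$", "", aa)
      if (grepl("*", aa, fixed = TRUE) || nchar(aa) < 50L) next
      idt <- align_overlap_protein(aa, homolog)$identity
      if (idt > base_id + 1 && (is.null(best) || idt > best$identity)) {
        best <- list(identity = idt, cds = spliced, protein = aa,
                     intron_offset = d, intron_length = len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$identity <- NULL
  best
}
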