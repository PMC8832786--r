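# Chromosomal location and comparative screens: homoeologous-group
# assignment from best hits, congruence with physical translocation-line
# placements, orthologue and expression screens, private indel discovery and
# cross-species integrated-domain bookkeeping.

#' Assign homoeologous groups from reference best hits
#'
#' Per query and genome the best hit is kept (highest bitscore, ties by
#' identity then lexicographically smallest chromosome); the group is the
#' majority chromosome number across genomes, with `"Un"` chromosomes
#' excluded from the vote and ties left unassigned (`NA`).
#'
#' @param hits `HitRecord` tibble: `query_id`, `genome`, `chromosome`, and
#'   optionally `identity` and `bitscore` (already-best tables work too).
#' @return `GroupAssignment` tibble: `query_id`, one `chr_<genome>` column
#'   per genome, `group` (integer or `NA`).
#' @export
assign_homoeologous_group <- function(hits) {
  if (!"bitscore" %in% names(hits)) hits$bitscore <- 0
  if (!"identity" %in% names(hits)) hits$identity <- 0
  best <- dplyr::slice_head(
    dplyr::arrange(
      dplyr::group_by(hits, .data$query_id, .data$genome),
      dplyr::desc(.data$bitscore), dplyr::desc(.data$identity), .data$chromosome),
    n = 1L)
  best <- dplyr::ungroup(best)
  wide <- tidyr::pivot_wider(best[, c("query_id", "genome", "chromosome")],
                             names_from = "genome", values_from = "chromosome",
                             names_prefix = "chr_")
  wide$group <- vapply(seq_len(nrow(wide)), function(i) {
    nums <- chrom_number(unlist(wide[i, -1], use.names = FALSE))
    nums <- nums[!is.na(nums)]
    if (length(nums) == 0L) return(NA_integer_)
    tab <- table(nums)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L) NA_integer_ else as.integer(names(top))
  }, integer(1))
  wide
}

#' Group assignment from a per-genome chromosome table
#'
#' Convenience for ingested location tables that already carry one (best-hit)
#' chromosome column per genome.
#'
#' @param tbl tibble with an id column and the chromosome columns.
#' @param id_col name of the identifier column.
#' @param genome_cols names of the chromosome columns; default: every column
#'   except the id, a `status` and a `physical_arm` column.
#' @return tibble (`query_id`, `group`).
#' @export
assign_group_from_chromosomes <- function(tbl, id_col = "nlr_gene",
                                          genome_cols = NULL) {
  if (is.null(genome_cols)) {
    genome_cols <- setdiff(names(tbl), c(id_col, "status", "physical_arm"))
  }
  group <- vapply(seq_len(nrow(tbl)), function(i) {
    nums <- chrom_number(unlist(tbl[i, genome_cols], use.names = FALSE))
    nums <- nums[!is.na(nums)]
    if (length(nums) == 0L) return(NA_integer_)
    tab <- table(nums)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L) NA_integer_ else as.integer(names(top))
  }, integer(1))
  tibble::tibble(query_id = tbl[[id_col]], group = group)
}

#' Congruence of in-silico groups with physical arm placements
#'
#' For each physical chromosome arm, tabulates the in-silico group
#' distribution of its markers and flags arms whose modal in-silico group
#' differs from the arm's own chromosome number (the signature of ancestral
#' translocations such as 4L/7S).
#'
#' @param assignments tibble (`query_id`, `group`).
#' @param markers `MarkerRecord` tibble: `marker_id`, `status`
#'   (`"Complete NLR"` / `"Partial or pseudogene"`), `physical_arm`
#'   (e.g. `"4VL"`).
#' @return a list of class `congruence_report`: `by_arm` tibble (`physical_arm`,
#'   `n_markers`, `n_complete`, `n_partial`, `modal_group`, `arm_number`,
#'   `discordant`), `status_counts`, `unknown_ids` (marker ids absent from
#'   the assignments, listed but not fatal) and `duplicate_markers` (markers
#'   recorded under more than one arm, kept in both).
#' @export
congruence_report <- function(assignments, markers) {
  if (!all(grepl("^[1-7]V[SL]$", markers$physical_arm))) {
    stop("physical_arm must match [1-7]V[SL]", call. = FALSE)
  }
  duplicate_markers <- unique(markers$marker_id[duplicated(markers$marker_id)])
  joined <- dplyr::left_join(markers, dplyr::distinct(assignments),
                             by = c(marker_id = "query_id"))
  unknown <- joined$marker_id[!joined$marker_id %in% assignments$query_id]
  by_arm <- dplyr::summarise(
    dplyr::group_by(joined, .data$physical_arm),
    n_markers = dplyr::n(),
    n_complete = sum(.data$status == "Complete NLR"),
    n_partial = sum(.data$status != "Complete NLR"),
    modal_group = {
      g <- .data$group[!is.na(.data$group)]
      if (length(g) == 0L) NA_integer_ else {
        tab <- table(g)
        as.integer(names(tab)[which.max(tab)])
      }
    },
    .groups = "drop")
  by_arm$arm_number <- as.integer(substr(by_arm$physical_arm, 1L, 1L))
  by_arm$discordant <- !is.na(by_arm$modal_group) &
    by_arm$modal_group != by_arm$arm_number
  status_counts <- dplyr::count(markers, .data$status, name = "n")
  structure(list(by_arm = by_arm, status_counts = status_counts,
                 unknown_ids = unique(unknown),
                 duplicate_markers = duplicate_markers),
            class = "congruence_report")
}

#' Default screen thresholds
#'
#' Orthologue screen: > 80% identity and > 60% coverage against a cloned R
#' gene. Expression screen: > 95% identity and > 90% coverage against a
#' transcript. All comparisons are strict.
#'
#' @param ortho_identity,ortho_coverage,expr_identity,expr_coverage percents
#'   in (0, 100].
#' @return named list of thresholds.
#' @export
screen_thresholds <- function(ortho_identity = 80, ortho_coverage = 60,
                              expr_identity = 95, expr_coverage = 90) {
  vals <- c(ortho_identity, ortho_coverage, expr_identity, expr_coverage)
  if (any(vals <= 0 | vals > 100)) stop("thresholds must be in (0, 100]", call. = FALSE)
  list(ortho_identity = ortho_identity, ortho_coverage = ortho_coverage,
       expr_identity = expr_identity, expr_coverage = expr_coverage)
}

#' Screen catalog NLRs for orthologues of cloned R genes
#'
#' Candidates must exceed both identity and coverage thresholds against the
#' query R gene and, when group columns are present, sit on the same
#' homoeologous group as the query.
#'
#' @param r_gene_hits tibble with `identity`, `coverage`, and optionally
#'   `nlr_group` and `r_gene_group` columns.
#' @param thresholds list from [screen_thresholds()].
#' @return the passing rows.
#' @export
screen_orthologues <- function(r_gene_hits, thresholds = screen_thresholds()) {
  keep <- r_gene_hits$identity > thresholds$ortho_identity &
    r_gene_hits$coverage > thresholds$ortho_coverage
  if (all(c("nlr_group", "r_gene_group") %in% names(r_gene_hits))) {
    keep <- keep & !is.na(r_gene_hits$nlr_group) &
      r_gene_hits$nlr_group == r_gene_hits$r_gene_group
  }
  r_gene_hits[keep & !is.na(keep), , drop = FALSE]
}

#' Match predicted NLRs against transcripts (expression screen)
#'
#' An NLR is expressed when some transcript aligns to its predicted CDS with
#' identity and CDS coverage above the thresholds. For expressed NLRs the
#' splice pattern is compared: introns implied by aligning the transcript to
#' the unspliced gene (gaps >= `min_intron`) are matched against the
#' predicted intron chain; `splice` is `"match"` or `"mismatch at junction
#' <k>"`.
#'
#' @param predictions `PredictedProtein` tibble ([predict_protein()]).
#' @param transcripts tibble (`transcript_id`, `sequence`).
#' @param thresholds list from [screen_thresholds()].
#' @param min_intron minimum alignment gap treated as an intron.
#' @param junction_tol tolerance (nt) when comparing junction positions.
#' @return tibble (`locus_id`, `transcript_id`, `identity`, `coverage`,
#'   `expressed`, `splice`), one row per prediction with its best transcript.
#' @export
match_expression <- function(predictions, transcripts,
                             thresholds = screen_thresholds(),
                             min_intron = 30L, junction_tol = 3L) {
  preds <- predictions[predictions$predicted %in% TRUE, , drop = FALSE]
  tx_kmers <- lapply(transcripts$sequence, kmer_set, k = 12L)
  purrr::map_dfr(seq_len(nrow(preds)), function(i) {
    cds <- preds$cds[i]
    ck <- kmer_set(cds, 12L)
    sim <- vapply(tx_kmers, kmer_containment, numeric(1), set_a = ck)
    out <- tibble::tibble(locus_id = preds$locus_id[i],
                          transcript_id = NA_character_, identity = NA_real_,
                          coverage = NA_real_, expressed = FALSE,
                          splice = NA_character_)
    if (length(sim) == 0L || max(sim) < 0.2) return(out)
    cand <- order(sim, decreasing = TRUE)[seq_len(min(3L, length(sim)))]
    best <- NULL
    for (k in cand) {
      m <- align_overlap_dna(cds, transcripts$sequence[k])
      score <- m$identity * m$coverage_pattern # identity of a trivial overlap must not win
      if (is.null(best) || score > best$score) {
        best <- list(k = k, identity = m$identity,
                     coverage = m$coverage_pattern, score = score)
      }
    }
    out$transcript_id <- transcripts$transcript_id[best$k]
    out$identity <- best$identity
    out$coverage <- best$coverage
    out$expressed <- best$identity > thresholds$expr_identity &
      best$coverage > thresholds$expr_coverage
    if (out$expressed) {
      out$splice <- .compare_splice(
        preds$genomic_span[i], transcripts$sequence[best$k],
        preds$intron_offset[i], preds$intron_length[i],
        min_intron = min_intron, tol = junction_tol)
    }
    out
  })
}

# Compare the transcript-implied intron chain with the predicted one.
#' @noRd
.compare_splice <- function(genomic, transcript, intron_offset, intron_length,
                            min_intron = 30L, tol = 3L) {
  ind <- align_indels(transcript, genomic)
  observed <- ind[ind$type == "del" & ind$length >= min_intron, , drop = FALSE]
  # observed$position is the transcript coordinate of the junction, which is
  # the genomic offset of the donor once upstream introns are accounted for
  pred <- if (is.na(intron_offset)) integer(0) else intron_offset
  obs <- integer(0)
  removed <- 0L
  for (r in seq_len(nrow(observed))) {
    obs <- c(obs, observed$position[r] + removed)
    removed <- removed + observed$length[r]
  }
  if (length(pred) != length(obs)) {
    k <- min(length(pred), length(obs)) + 1L
    return(paste("mismatch at junction", k))
  }
  if (length(pred) == 0L) return("match")
  bad <- which(abs(obs - pred) > tol)
  if (length(bad)) paste("mismatch at junction", bad[1]) else "match"
}

#' Find indels private to a query relative to an orthologue set
#'
#' Pairwise global alignments of the query against every orthologue; an indel
#' is reported when an event of the same type overlaps the same query
#' position against every orthologue (the basis for designing
#' presence/absence PCR markers).
#'
#' @param query DNA character scalar.
#' @param orthologues named character vector (>= 1).
#' @param min_len minimum indel length (default 3 bp).
#' @return tibble (`position`, `length`, `type`) in query coordinates.
#' @export
find_private_indels <- function(query, orthologues, min_len = 3L) {
  if (length(orthologues) < 1L) stop("need at least one orthologue", call. = FALSE)
  per_orth <- lapply(orthologues, function(o) {
    ind <- align_indels(query, o)
    ind[ind$length >= min_len, , drop = FALSE]
  })
  base <- per_orth[[1]]
  if (nrow(base) == 0L) return(base)
  keep <- vapply(seq_len(nrow(base)), function(i) {
    all(vapply(per_orth[-1], function(other) {
      if (nrow(other) == 0L) return(FALSE)
      any(other$type == base$type[i] &
            abs(other$position - base$position[i]) <= base$length[i] &
            other$length == base$length[i])
    }, logical(1)))
  }, logical(1))
  base[keep, , drop = FALSE]
}

#' Shared and unique integrated domains per species
#'
#' For each species: total = rows listing it, unique = rows listing only it,
#' shared = total - unique; the grand total is the number of distinct
#' integrated domains in the table.
#'
#' @param table `IdMembershipTable` tibble: `id_name`, optional
#'   `description`, `genomes` (list-column of labels, or a comma/space
#'   separated string column).
#' @return list with `per_species` tibble (`species`, `total`, `shared`,
#'   `unique`) and `grand_total`.
#' @export
shared_unique_ids <- function(table) {
  if (nrow(table) == 0L) {
    return(list(per_species = tibble::tibble(species = character(0),
                                             total = integer(0),
                                             shared = integer(0),
                                             unique = integer(0)),
                grand_total = 0L))
  }
  if (anyDuplicated(table$id_name)) stop("duplicate id_name rows", call. = FALSE)
  sets <- table$genomes
  if (!is.list(sets)) sets <- strsplit(as.character(sets), "[,;]\\s*|\\s+")
  if (any(lengths(sets) == 0L)) stop("empty genome set", call. = FALSE)
  species <- sort(unique(unlist(sets)))
  per <- purrr::map_dfr(species, function(s) {
    has <- vapply(sets, function(g) s %in% g, logical(1))
    only <- vapply(sets, function(g) identical(g, s) ||
                     (length(g) == 1L && g[[1]] == s), logical(1))
    tibble::tibble(species = s, total = sum(has), unique = sum(only),
                   shared = sum(has) - sum(only))
  })
  list(per_species = per[, c("species", "total", "shared", "unique")],
       grand_total = nrow(table))
}

#' Count catalog NLRs whose best hit falls at an anchor locus
#'
#' Used to gauge enrichment of known clusters (e.g. the barley Mla locus):
#' counts queries whose best-hit subject position lies within a window of the
#' anchor.
#'
#' @param hits tibble with a subject position column in Mb.
#' @param anchor_mb anchor position in Mb.
#' @param window_mb half-width of the anchor window (default 1 Mb).
#' @param position_col name of the position column.
#' @return integer count.
#' @export
locus_paralogue_count <- function(hits, anchor_mb, window_mb = 1,
                                  position_col = "locus_mb") {
  pos <- hits[[position_col]]
  sum(!is.na(pos) & abs(pos - anchor_mb) <= window_mb)
}

#' Marker polymorphism rate
#'
#' Percentage of primer pairs yielding a polymorphism, rounded half-up to the
#' nearest integer (the convention used for printed marker statistics).
#'
#' @param n_polymorphic,n_total counts.
#' @return integer percent.
#' @export
polymorphism_rate <- function(n_polymorphic, n_total) {
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  as.integer(round_half_up(100 * n_polymorphic / n_total, 0))
}
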