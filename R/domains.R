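# Domain-composition analysis: merging of two annotation sources, the NB-ARC
# gate, Type I-V classification (CNL / NL / CN / N / NLR-ID), integrated
# domain terminal assignment and linked-pair detection.

# canonical NLR domains; everything else counts as atypical / integrated
.CANONICAL_DOMAINS <- c("CC", "NB-ARC", "LRR")

#' Classify a motif chain by its category grammar
#'
#' Chain-level twin of [classify_nlr()], used for planted-truth bookkeeping
#' and recovery scoring: NB motifs gate NLR status, an ID motif makes the
#' locus an NLR-ID, otherwise the CC/LRR combination selects CNL, NL, CN or N.
#'
#' @param chain character vector of motif ids.
#' @param library the motif library.
#' @return one of `"CNL"`, `"NL"`, `"CN"`, `"N"`, `"NLR-ID"`, `"not_nlr"`.
#' @export
classify_motif_chain <- function(chain, library) {
  cats <- library$category[match(chain, library$motif_id)]
  if (!"NB" %in% cats) return("not_nlr")
  if ("ID" %in% cats) return("NLR-ID")
  has_cc <- "CC" %in% cats
  has_lrr <- "LRR" %in% cats
  if (has_cc && has_lrr) "CNL" else if (has_lrr) "NL" else if (has_cc) "CN" else "N"
}

#' Derive coarse domain annotations from motif content
#'
#' For synthetic runs (and as a fallback where no external domain scan is
#' available) the motif scanner doubles as a coarse domain caller: the span of
#' CC motif matches on a protein becomes its CC domain, NB motifs its NB-ARC,
#' LRR motifs its LRR, and each ID motif an atypical domain under its own
#' name. Coordinates are 1-based amino-acid positions.
#'
#' @param proteins tibble (`protein_id`, `protein`).
#' @param library the motif library.
#' @return `DomainAnnotation` tibble: `protein_id`, `domain_name`, `start`,
#'   `end`, `source = "builtin"`, `evalue = 0`.
#' @export
domains_from_motifs <- function(proteins, library) {
  library <- validate_motif_library(library)
  rows <- purrr::map_dfr(seq_len(nrow(proteins)), function(i) {
    aa <- Biostrings::AAString(proteins$protein[i])
    hits <- purrr::map_dfr(seq_len(nrow(library)), function(m) {
      w <- nchar(library$consensus[m])
      mm <- floor(w * (1 - library$score_threshold[m]))
      found <- Biostrings::matchPattern(Biostrings::AAString(library$consensus[m]),
                                        aa, max.mismatch = mm)
      if (length(found) == 0L) return(NULL)
      tibble::tibble(category = library$category[m],
                     motif_id = library$motif_id[m],
                     start = BiocGenerics::start(found),
                     end = BiocGenerics::end(found))
    })
    if (nrow(hits) == 0L) return(NULL)
    canonical <- hits[hits$category != "ID", ]
    dom <- dplyr::summarise(
      dplyr::group_by(canonical, .data$category),
      start = min(.data$start), end = max(.data$end), .groups = "drop")
    dom$domain_name <- unname(c(CC = "CC", NB = "NB-ARC", LRR = "LRR")[dom$category])
    dom <- dom[, c("domain_name", "start", "end")]
    idh <- hits[hits$category == "ID", ]
    if (nrow(idh) > 0L) {
      dom <- dplyr::bind_rows(dom, tibble::tibble(
        domain_name = idh$motif_id, start = idh$start, end = idh$end))
    }
    dplyr::mutate(dom, protein_id = proteins$protein_id[i], .before = 1)
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(protein_id = character(0), domain_name = character(0),
                          start = integer(0), end = integer(0),
                          source = character(0), evalue = numeric(0)))
  }
  dplyr::mutate(dplyr::arrange(rows, .data$protein_id, .data$start),
                source = "builtin", evalue = 0)
}

#' Merge two domain-annotation sources
#'
#' Integrates annotation tables from two scanners (e.g. an R-gene domain
#' pipeline providing CC/NB-ARC/ID calls and a superfamily scan providing LRR
#' calls): rows above the e-value ceiling are dropped, same-name overlapping
#' intervals on one protein are merged to their union, disjoint rows are kept
#' side by side.
#'
#' @param a,b `DomainAnnotation` tibbles (`protein_id`, `domain_name`,
#'   `start`, `end`, `source`, `evalue`; optional `protein_length`).
#' @param evalue_max e-value ceiling (default 1e-3).
#' @return merged, sorted annotation tibble.
#' @export
merge_domain_sources <- function(a, b, evalue_max = 1e-3) {
  both <- dplyr::bind_rows(a, b)
  if ("protein_length" %in% names(both)) {
    bad <- dplyr::summarise(dplyr::group_by(both, .data$protein_id),
                            n = dplyr::n_distinct(stats::na.omit(.data$protein_length)))
    if (any(bad$n > 1L)) {
      stop("inconsistent protein lengths across sources for: ",
           paste(bad$protein_id[bad$n > 1L], collapse = ", "), call. = FALSE)
    }
  }
  both <- both[is.na(both$evalue) | both$evalue <= evalue_max, ]
  if (nrow(both) == 0L) return(both)
  merged <- dplyr::group_modify(
    dplyr::group_by(both, .data$protein_id, .data$domain_name),
    function(g, key) {
      g <- g[order(g$start, g$end), ]
      out <- g[1, ]
      for (i in seq_len(nrow(g))[-1]) {
        last <- nrow(out)
        if (g$start[i] <= out$end[last]) { # 1-based inclusive overlap
          out$end[last] <- max(out$end[last], g$end[i])
          out$evalue[last] <- min(out$evalue[last], g$evalue[i])
          out$source[last] <- paste(unique(c(out$source[last], g$source[i])),
                                    collapse = "+")
        } else {
          out <- dplyr::bind_rows(out, g[i, ])
        }
      }
      out
    })
  dplyr::arrange(dplyr::ungroup(merged), .data$protein_id, .data$start)
}

#' Classify proteins into NLR types from merged domains
#'
#' The NB-ARC domain gates NLR status: proteins without one are rejected. Any
#' atypical domain (not CC, NB-ARC or LRR after alias mapping) makes the
#' protein an NLR-ID (Type V); otherwise CC+LRR gives CNL (Type I), LRR only
#' NL (Type II), CC only CN (Type III) and neither N (Type IV). Invariant to
#' annotation order and duplicated rows.
#'
#' @param domains merged `DomainAnnotation` tibble.
#' @param aliases named character vector mapping source-specific names onto
#'   canonical ones (e.g. `c(Rx_N = "CC", "LRR superfamily" = "LRR")`).
#' @return tibble (`protein_id`, `nlr_class`) with `nlr_class` in
#'   CNL/NL/CN/N/NLR-ID or `"rejected"` (no NB-ARC).
#' @export
classify_nlr <- function(domains, aliases = NULL) {
  canon <- function(x) {
    if (!is.null(aliases)) {
      hit <- match(x, names(aliases))
      x[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
    }
    x
  }
  dplyr::summarise(
    dplyr::group_by(domains, .data$protein_id),
    nlr_class = {
      nm <- canon(.data$domain_name)
      if (!"NB-ARC" %in% nm) "rejected"
      else if (any(!nm %in% .CANONICAL_DOMAINS)) "NLR-ID"
      else if ("CC" %in% nm && "LRR" %in% nm) "CNL"
      else if ("LRR" %in% nm) "NL"
      else if ("CC" %in% nm) "CN"
      else "N"
    },
    .groups = "drop"
  )
}

#' Assign integrated domains to a protein terminal
#'
#' An integrated domain wholly before the NB-ARC start sits at the N
#' (CC-side) terminal, wholly after the NB-ARC end at the C (LRR-side)
#' terminal, and overlapping the NB-ARC span is ambiguous.
#'
#' @param domains merged `DomainAnnotation` tibble; each protein with an
#'   atypical domain must carry an NB-ARC row.
#' @param aliases alias map as in [classify_nlr()].
#' @return tibble (`protein_id`, `domain_name`, `terminal`) with `terminal`
#'   in N/C/ambiguous, one row per integrated domain occurrence.
#' @export
assign_id_terminal <- function(domains, aliases = NULL) {
  canon <- domains$domain_name
  if (!is.null(aliases)) {
    hit <- match(canon, names(aliases))
    canon[!is.na(hit)] <- aliases[hit[!is.na(hit)]]
  }
  atypical <- domains[!canon %in% .CANONICAL_DOMAINS, ]
  if (nrow(atypical) == 0L) {
    return(tibble::tibble(protein_id = character(0), domain_name = character(0),
                          terminal = character(0)))
  }
  nbarc <- domains[canon == "NB-ARC", c("protein_id", "start", "end")]
  missing <- setdiff(atypical$protein_id, nbarc$protein_id)
  if (length(missing)) {
    stop("no NB-ARC span for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  nb <- dplyr::summarise(dplyr::group_by(nbarc, .data$protein_id),
                         nb_start = min(.data$start), nb_end = max(.data$end),
                         .groups = "drop")
  joined <- dplyr::left_join(atypical, nb, by = "protein_id")
  tibble::tibble(
    protein_id = joined$protein_id,
    domain_name = joined$domain_name,
    terminal = dplyr::case_when(
      joined$end < joined$nb_start ~ "N",
      joined$start > joined$nb_end ~ "C",
      TRUE ~ "ambiguous"
    )
  )
}

#' Find physically linked NLR pairs on a contig
#'
#' Adjacent loci on one contig within `max_separation_bp` of each other are
#' reported with their relative orientation: same strand is a tandem pair;
#' opposite strands are head-to-head when the 5' ends face each other
#' (upstream locus on the minus strand) and tail-to-tail otherwise.
#'
#' @param loci locus tibble (`locus_id`, `contig_id`, `start`, `end`,
#'   `strand`).
#' @param max_separation_bp maximum gap between the paired loci.
#' @return tibble (`contig_id`, `locus_a`, `locus_b`, `gap_bp`,
#'   `orientation`).
#' @export
find_paired_nlrs <- function(loci, max_separation_bp = 10000) {
  purrr::map_dfr(split(loci, loci$contig_id), function(g) {
    if (nrow(g) < 2L) return(NULL)
    g <- g[order(g$start, g$end), ]
    i <- seq_len(nrow(g) - 1L)
    gap <- g$start[i + 1L] - g$end[i]
    keep <- gap <= max_separation_bp
    if (!any(keep)) return(NULL)
    tibble::tibble(
      contig_id = g$contig_id[1],
      locus_a = g$locus_id[i][keep],
      locus_b = g$locus_id[i + 1L][keep],
      gap_bp = gap[keep],
      orientation = dplyr::case_when(
        g$strand[i][keep] == g$strand[i + 1L][keep] ~ "tandem",
        g$strand[i][keep] == "-" ~ "head_to_head",
        TRUE ~ "tail_to_tail"
      )
    )
  })
}

#' Summarise NLR classes
#'
#' Counts and one-decimal percentages per class (half-up rounding, matching
#' the usual printed-table convention), with a total row. Rejected records
#' (no NB-ARC) are excluded from the denominator.
#'
#' @param records tibble with an `nlr_class` column.
#' @return tibble (`nlr_class`, `n`, `pct`) of class `nlr_class_summary`.
#' @export
summarize_classes <- function(records) {
  classes <- c("CNL", "NL", "CN", "N", "NLR-ID")
  kept <- records[records$nlr_class %in% classes, , drop = FALSE]
  n <- vapply(classes, function(cl) sum(kept$nlr_class == cl), integer(1))
  total <- sum(n)
  counts <- unname(c(n, total))
  pct <- if (total > 0) round_half_up(100 * counts / total, 1) else rep(0, 6)
  out <- tibble::tibble(nlr_class = c(classes, "Total"), n = counts, pct = pct)
  tibble::new_tibble(out, class = "nlr_class_summary")
}
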