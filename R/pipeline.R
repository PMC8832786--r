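# End-to-end orchestration: dedup -> annotate -> rescue -> predict ->
# classify -> tree -> locate -> screens, with a per-stage manifest and
# deterministic report writing.

#' Pipeline configuration
#'
#' One flat list with one entry per stage parameter; the defaults are the
#' published settings (95% dedup identity, 1e-3 e-value ceiling, 3000 bp
#' flank and chaining gap, 80/60 orthologue screen, 95/90 expression screen,
#' 1000 bootstrap replicates), so the default configuration is the published
#' run. `synthetic` carries the generator config used when no input files are
#' supplied.
#'
#' @param seed master seed.
#' @param dedup_identity,evalue_max,flank,max_gap_bp,bootstrap,
#'   ortho_identity,ortho_coverage,expr_identity,expr_coverage stage
#'   parameters (see the stage functions).
#' @param synthetic a [synthetic_config()] for simulated inputs.
#' @param out_dir optional output directory; when set, all reports are
#'   written there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 42, dedup_identity = 95, evalue_max = 1e-3,
                            flank = 3000, max_gap_bp = 3000, bootstrap = 1000,
                            ortho_identity = 80, ortho_coverage = 60,
                            expr_identity = 95, expr_coverage = 90,
                            synthetic = NULL, out_dir = NULL) {
  if (is.null(synthetic)) synthetic <- synthetic_config(seed = seed)
  if (dedup_identity <= 50 || dedup_identity > 100) {
    stop("dedup_identity must be in (50, 100]", call. = FALSE)
  }
  structure(list(
    seed = assert_count(seed, "seed", min = 0L),
    dedup_identity = dedup_identity, evalue_max = evalue_max,
    flank = flank, max_gap_bp = max_gap_bp,
    bootstrap = assert_count(bootstrap, "bootstrap"),
    thresholds = screen_thresholds(ortho_identity, ortho_coverage,
                                   expr_identity, expr_coverage),
    synthetic = synthetic, out_dir = out_dir
  ), class = "pipeline_config")
}

#' Run the NLR annotation pipeline end to end
#'
#' Stages run in order: contig de-redundancy, motif annotation of the
#' retained contigs, rescue of removed contigs, protein prediction for
#' complete loci, domain classification, NB-ARC bootstrap tree,
#' homoeologous-group assignment with physical congruence, and the
#' expression screen. With `inputs = NULL` every input is simulated from
#' `config$synthetic`; otherwise `inputs` supplies the tables/sequence sets
#' directly (elements `contigs`, `homologs`, `reference_hits`, `markers`,
#' `transcripts`, `library`). Re-running with the same config and inputs
#' reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param inputs optional list of in-memory inputs (see Details).
#' @return list of class `nlr_run` with per-stage results and a `manifest`
#'   tibble of input/output counts.
#' @export
run_nlr_pipeline <- function(config = pipeline_config(), inputs = NULL) {
  manifest <- list()
  note <- function(stage, n_in, n_out, detail = "") {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, detail = detail)
  }

  if (is.null(inputs)) {
    sim <- simulate_renseq(config$synthetic)
    inputs <- list(contigs = sim$contigs, homologs = sim$homologs,
                   reference_hits = sim$hits, markers = sim$markers,
                   transcripts = sim$transcripts, library = sim$library,
                   truth = sim$truth)
    note("simulate", config$synthetic$n_loci, nrow(sim$contigs),
         paste0("seed=", config$synthetic$seed))
  }
  contigs <- inputs$contigs
  library <- inputs$library %||%
    generate_motif_library(config$seed, n_cc = 3, n_nb = 8, n_lrr = 4)

  decisions <- remove_redundant(contigs, threshold = config$dedup_identity)
  retained <- contigs[contigs$contig_id %in%
                        decisions$contig_id[decisions$status == "retained"], ]
  note("dedup", nrow(contigs), nrow(retained),
       paste0("identity=", config$dedup_identity))

  loci <- annotate_contigs(retained, library, max_gap_bp = config$max_gap_bp)
  note("annotate", nrow(retained), nrow(loci),
       paste0("max_gap_bp=", config$max_gap_bp))

  annotate_fn <- function(ctgs) annotate_contigs(ctgs, library,
                                                 max_gap_bp = config$max_gap_bp)
  decisions <- rescue_removed(decisions, contigs, loci, annotate_fn)
  rescued_loci <- attr(decisions, "rescued_loci")
  catalog <- dplyr::bind_rows(loci, rescued_loci)
  note("rescue", sum(decisions$status != "retained"), nrow(rescued_loci))

  complete <- catalog[catalog$completeness == "complete", , drop = FALSE]
  predictions <- if (nrow(complete) > 0L && nrow(inputs$homologs %||% tibble::tibble()) > 0L) {
    predict_protein(complete, contigs, inputs$homologs, flank = config$flank)
  } else {
    tibble::tibble(locus_id = character(0), predicted = logical(0),
                   cds = character(0), protein = character(0))
  }
  note("predict", nrow(complete), sum(predictions$predicted %in% TRUE),
       paste0("flank=", config$flank))

  proteins <- predictions[predictions$predicted %in% TRUE,
                          c("locus_id", "protein")]
  names(proteins) <- c("protein_id", "protein")
  domains <- domains_from_motifs(proteins, library)
  records <- classify_nlr(domains)
  id_terminals <- assign_id_terminal(domains)
  pairs <- find_paired_nlrs(catalog)
  class_summary <- summarize_classes(records)
  completeness_summary <- summarize_completeness(catalog)
  note("classify", nrow(proteins), sum(records$nlr_class != "rejected"))

  tree <- NULL; motif_profiles <- NULL
  accepted <- records$protein_id[records$nlr_class != "rejected"]
  tree_prots <- proteins[proteins$protein_id %in% accepted, , drop = FALSE]
  if (nrow(tree_prots) >= 4L) {
    nbarc <- extract_nbarc(tree_prots, domains)
    tree <- bootstrap_support(nbarc, n_replicates = config$bootstrap,
                              seed = config$seed)
    motif_profiles <- attach_motif_profiles(tree, catalog)
  }
  note("tree", nrow(tree_prots), if (is.null(tree)) 0L else length(tree$tip.label),
       paste0("bootstrap=", config$bootstrap))

  assignments <- NULL; congruence <- NULL
  if (!is.null(inputs$reference_hits) && nrow(inputs$reference_hits) > 0L) {
    assignments <- assign_homoeologous_group(inputs$reference_hits)
    if (!is.null(inputs$markers) && nrow(inputs$markers) > 0L) {
      congruence <- congruence_report(assignments, inputs$markers)
    }
  }
  note("locate", length(unique(inputs$reference_hits$query_id %||% character(0))),
       if (is.null(assignments)) 0L else sum(!is.na(assignments$group)))

  expression <- NULL
  if (!is.null(inputs$transcripts) && nrow(inputs$transcripts) > 0L &&
      nrow(predictions) > 0L) {
    expression <- match_expression(predictions, inputs$transcripts,
                                   thresholds = config$thresholds)
  }
  note("expression",
       if (is.null(inputs$transcripts)) 0L else nrow(inputs$transcripts),
       if (is.null(expression)) 0L else sum(expression$expressed))

  run <- structure(list(
    config = config, library = library, contigs = contigs,
    decisions = decisions, loci = catalog, predictions = predictions,
    domains = domains, records = records, id_terminals = id_terminals,
    pairs = pairs, class_summary = class_summary,
    completeness_summary = completeness_summary, tree = tree,
    motif_profiles = motif_profiles, assignments = assignments,
    congruence = congruence, expression = expression,
    truth = inputs$truth,
    manifest = dplyr::bind_rows(manifest)
  ), class = "nlr_run")
  if (!is.null(config$out_dir)) render_reports(run, config$out_dir)
  run
}

#' Summarise locus completeness categories
#'
#' Counts of complete, complete-pseudogene, partial and partial-pseudogene
#' loci with a total row.
#'
#' @param loci classified locus tibble.
#' @return tibble (`completeness`, `n`).
#' @export
summarize_completeness <- function(loci) {
  cats <- c("complete", "complete_pseudogene", "partial", "partial_pseudogene")
  n <- vapply(cats, function(x) sum(loci$completeness == x), integer(1))
  tibble::tibble(completeness = c(cats, "Total"), n = unname(c(n, sum(n))))
}

#' Write the run's report files
#'
#' Class summary, completeness summary, cluster decisions, locus GFF3,
#' predicted proteins, group assignments, congruence-by-arm, expression
#' table, Newick tree with motif-profile sidecar and the manifest — all as
#' plain text, byte-stable across reruns.
#'
#' @param run an `nlr_run` ([run_nlr_pipeline()]).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
render_reports <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) readr::write_tsv(x, file.path(out_dir, name))
  w(run$class_summary, "class_summary.tsv")
  w(run$completeness_summary, "completeness_summary.tsv")
  w(run$decisions, "cluster_decisions.tsv")
  w(run$manifest, "manifest.tsv")
  write_loci_gff3(run$loci, file.path(out_dir, "nlr_loci.gff3"))
  preds <- run$predictions[run$predictions$predicted %in% TRUE, , drop = FALSE]
  if (nrow(preds) > 0L) {
    write_fasta(stats::setNames(preds$protein, preds$locus_id),
                file.path(out_dir, "nlr_proteins.fasta"))
    write_fasta(stats::setNames(preds$cds, preds$locus_id),
                file.path(out_dir, "nlr_cds.fasta"))
  }
  if (!is.null(run$assignments)) w(run$assignments, "group_assignments.tsv")
  if (!is.null(run$congruence)) w(run$congruence$by_arm, "congruence_by_arm.tsv")
  if (!is.null(run$expression)) w(run$expression, "expression.tsv")
  if (!is.null(run$tree)) {
    ape::write.tree(run$tree, file.path(out_dir, "nbarc_tree.nwk"))
    w(run$motif_profiles, "motif_profiles.tsv")
  }
  invisible(out_dir)
}

#' @export
print.nlr_run <- function(x, ...) {
  cat("<nlr_run>\n")
  print(x$manifest)
  invisible(x)
}
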