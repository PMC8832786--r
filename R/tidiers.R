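# broom-style tidiers and ggplot2 helpers for run objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an NLR pipeline run into one row per locus
#'
#' @param x an `nlr_run`.
#' @param ... unused.
#' @return tibble with locus coordinates, completeness, predicted-protein
#'   metrics and NLR class.
#' @export
tidy.nlr_run <- function(x, ...) {
  out <- x$loci[, c("locus_id", "contig_id", "start", "end", "strand",
                    "completeness")]
  if (nrow(x$predictions) > 0L) {
    out <- dplyr::left_join(
      out,
      x$predictions[, c("locus_id", "predicted", "homolog_id",
                        "homolog_identity", "homolog_coverage")],
      by = "locus_id")
  }
  out <- dplyr::left_join(out, x$records,
                          by = c(locus_id = "protein_id"))
  if (!is.null(x$expression)) {
    out <- dplyr::left_join(
      out, x$expression[, c("locus_id", "expressed", "splice")],
      by = "locus_id")
  }
  out
}

#' One-row summary of an NLR pipeline run
#'
#' @param x an `nlr_run`.
#' @param ... unused.
#' @return one-row tibble of headline counts.
#' @export
glance.nlr_run <- function(x, ...) {
  tibble::tibble(
    n_contigs = nrow(x$contigs),
    n_retained = sum(x$decisions$status == "retained"),
    n_rescued = sum(x$decisions$status == "rescued"),
    n_loci = nrow(x$loci),
    n_complete = sum(x$loci$completeness == "complete"),
    n_nlr = sum(x$records$nlr_class != "rejected"),
    n_nlr_id = sum(x$records$nlr_class == "NLR-ID"),
    n_expressed = if (is.null(x$expression)) NA_integer_
                  else sum(x$expression$expressed)
  )
}

#' Bar chart of NLR class composition
#'
#' @param object an `nlr_class_summary` ([summarize_classes()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.nlr_class_summary <- function(object, ...) {
  df <- object[object$nlr_class != "Total", ]
  df$nlr_class <- factor(df$nlr_class, levels = df$nlr_class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nlr_class, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$pct, "%")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "NLRs",
                  title = "NLR class composition (Types I-V)") +
    ggplot2::theme_minimal()
}

#' Tile plot of physical arm vs modal in-silico group
#'
#' Discordant arms (modal group differing from the arm's own chromosome
#' number) are outlined.
#'
#' @param object a `congruence_report` ([congruence_report()]).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.congruence_report <- function(object, ...) {
  df <- object$by_arm
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$modal_group),
                                   y = .data$physical_arm)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$discordant),
                       colour = "white") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                               name = "discordant") +
    ggplot2::labs(x = "modal in-silico homoeologous group",
                  y = "physical arm") +
    ggplot2::theme_minimal()
}
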