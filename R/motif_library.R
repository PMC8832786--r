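#' Generate a synthetic NLR motif library
#'
#' Builds an ordered library of amino-acid consensus motifs tagged by domain
#' category (CC, NB, LRR, plus optional integrated-domain motifs), playing the
#' role that curated NLR motif sets (e.g. the 20 Jupe motifs used by
#' NLR-Annotator) play on real data. Exactly one NB motif is flagged as the
#' Walker-A P-loop and exactly one as the NB-ARC start; the completeness rule
#' for annotated loci keys on these flags. Real motif definitions in the same
#' tabular format can be supplied anywhere a library is accepted.
#'
#' @param seed integer seed; the same seed reproduces the same library.
#' @param n_cc,n_nb,n_lrr number of motifs per category (each >= 1).
#' @param n_id number of integrated-domain motifs, named after common
#'   integrated-decoy domains (WRKY, Kelch, zf-BED, ...).
#' @param score_threshold minimum fraction of identical residues for a scan
#'   window to count as a motif hit (per motif, in (0, 1]).
#' @return A tibble of class `motif_library` with columns `motif_id`,
#'   `category`, `consensus`, `score_threshold`, `p_loop`, `nb_start`.
#' @examples
#' lib <- generate_motif_library(1, n_cc = 3, n_nb = 8, n_lrr = 4)
#' sum(lib$p_loop)
#' @export
generate_motif_library <- function(seed, n_cc, n_nb, n_lrr, n_id = 3,
                                   score_threshold = 0.8) {
  n_cc <- assert_count(n_cc, "n_cc")
  n_nb <- assert_count(n_nb, "n_nb")
  n_lrr <- assert_count(n_lrr, "n_lrr")
  n_id <- assert_count(n_id, "n_id", min = 0L)
  if (score_threshold <= 0 || score_threshold > 1) {
    stop("score_threshold must be in (0, 1]", call. = FALSE)
  }
  id_names <- c("WRKY", "Kelch_1", "zf-BED", "Pkinase", "B3", "PP2C",
                "Thioredoxin", "DDE_Tnp_4")
  if (n_id > length(id_names)) stop("at most ", length(id_names), " ID motifs")
  # scramble the seed so a motif library and a contig set built from the same
  # user seed do not replay one RNG stream (a linker must never reproduce a
  # consensus verbatim)
  stream <- as.integer((as.double(seed) * 2654435761) %% 2147483647)
  withr::with_seed(stream, {
    make <- function(n, prefix) {
      tibble::tibble(
        motif_id = paste0(prefix, "_", seq_len(n)),
        consensus = vapply(seq_len(n), function(i) random_aa(sample(10:25, 1L)),
                           character(1))
      )
    }
    lib <- dplyr::bind_rows(
      dplyr::mutate(make(n_cc, "cc"), category = "CC"),
      dplyr::mutate(make(n_nb, "nb"), category = "NB"),
      dplyr::mutate(make(n_lrr, "lrr"), category = "LRR"),
      if (n_id > 0L) {
        tibble::tibble(
          motif_id = id_names[seq_len(n_id)],
          consensus = vapply(seq_len(n_id), function(i) random_aa(sample(12:25, 1L)),
                             character(1)),
          category = "ID"
        )
      }
    )
  })
  lib$score_threshold <- score_threshold
  lib$p_loop <- lib$motif_id == "nb_1"
  lib$nb_start <- lib$motif_id == "nb_2"
  if (n_nb < 2L) lib$nb_start <- lib$p_loop # degenerate single-NB library
  lib <- lib[, c("motif_id", "category", "consensus", "score_threshold",
                 "p_loop", "nb_start")]
  validate_motif_library(tibble::new_tibble(lib, class = "motif_library"))
}

#' Validate a motif library
#'
#' Checks the invariants every downstream stage relies on: unique motif ids,
#' known categories, exactly one P-loop flag and exactly one NB-ARC-start flag
#' (possibly the same motif), finite thresholds.
#'
#' @param library a `motif_library` tibble (see [generate_motif_library()]).
#' @return the validated library, invisibly usable in pipes.
#' @export
validate_motif_library <- function(library) {
  req <- c("motif_id", "category", "consensus", "score_threshold",
           "p_loop", "nb_start")
  missing <- setdiff(req, names(library))
  if (length(missing)) stop("motif library lacks columns: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(library$motif_id)) stop("duplicate motif ids", call. = FALSE)
  if (!all(library$category %in% c("CC", "NB", "LRR", "ID"))) {
    stop("motif categories must be CC, NB, LRR or ID", call. = FALSE)
  }
  if (sum(library$p_loop) != 1L) stop("exactly one motif must be flagged p_loop",
                                      call. = FALSE)
  if (sum(library$nb_start) != 1L) stop("exactly one motif must be flagged nb_start",
                                        call. = FALSE)
  if (library$category[library$p_loop] != "NB" ||
      library$category[library$nb_start] != "NB") {
    stop("p_loop and nb_start flags must sit on NB motifs", call. = FALSE)
  }
  if (!all(is.finite(library$score_threshold))) stop("non-finite score threshold",
                                                     call. = FALSE)
  if (!inherits(library, "motif_library")) {
    library <- tibble::new_tibble(library, class = "motif_library")
  }
  library
}

#' Read or write a motif library as TSV
#'
#' Plain tab-separated representation (one motif per row) so externally
#' curated motif sets can be dropped in.
#'
#' @param path file path.
#' @param library a `motif_library` tibble.
#' @return `read_motif_library()` returns a validated `motif_library`;
#'   `write_motif_library()` returns `path` invisibly.
#' @export
read_motif_library <- function(path) {
  lib <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           motif_id = "c", category = "c", consensus = "c",
                           score_threshold = "d", p_loop = "l", nb_start = "l"
                         ))
  validate_motif_library(lib)
}

#' @rdname read_motif_library
#' @export
write_motif_library <- function(library, path) {
  validate_motif_library(library)
  readr::write_tsv(library, path)
  invisible(path)
}
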