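# NB-ARC phylogeny: domain extraction, alignment p-distances, an explicit
# Saitou-Nei neighbor-joining implementation (deterministic tie-breaking,
# exact on additive matrices) and column-resampling bootstrap support.

#' Extract the NB-ARC domain from each protein
#'
#' @param proteins tibble (`protein_id`, `protein`).
#' @param domains merged `DomainAnnotation` tibble; every protein must carry
#'   exactly one merged NB-ARC span within its length.
#' @return named character vector of NB-ARC subsequences.
#' @export
extract_nbarc <- function(proteins, domains) {
  nb <- domains[domains$domain_name == "NB-ARC", ]
  out <- character(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    rows <- nb[nb$protein_id == proteins$protein_id[i], ]
    if (nrow(rows) != 1L) {
      stop(nrow(rows), " NB-ARC spans for ", proteins$protein_id[i], call. = FALSE)
    }
    if (rows$end > nchar(proteins$protein[i]) || rows$start < 1L) {
      stop("NB-ARC span out of bounds for ", proteins$protein_id[i], call. = FALSE)
    }
    out[i] <- substr(proteins$protein[i], rows$start, rows$end)
  }
  stats::setNames(out, proteins$protein_id)
}

#' Pairwise p-distance matrix from global alignments
#'
#' `d(i, j)` = mismatches over aligned non-gap columns of a global pairwise
#' alignment of sequences i and j.
#'
#' @param seqs named character vector (>= 3 sequences) or a two-column
#'   tibble (id, sequence).
#' @param alphabet `"protein"` or `"dna"`.
#' @return symmetric numeric matrix with zero diagonal, labelled by names.
#' @export
pairwise_distance <- function(seqs, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs[[2]], seqs[[1]])
  n <- length(seqs)
  if (n < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- align_pdistance(seqs[[i]], seqs[[j]], alphabet)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei agglomeration: at each step the pair minimising the
#' Q-criterion is joined, with exact ties broken by the lexicographically
#' smallest pair of subtree labels (the smallest leaf label each side), so
#' the result is fully deterministic. Negative branch-length estimates are
#' clamped to zero and flagged via the `"clamped"` attribute. For an additive
#' matrix the tree reproduces the input distances exactly.
#'
#' @param d symmetric numeric distance matrix (zero diagonal, labelled).
#' @return an unrooted `ape::phylo` tree; attribute `"clamped"` is `TRUE`
#'   when any branch was clamped.
#' @export
neighbor_joining <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("matrix must be symmetric", call. = FALSE)
  if (any(!is.finite(d))) stop("non-finite distances", call. = FALSE)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa", call. = FALSE)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  sub <- labels        # newick fragment per active node
  rep_label <- labels  # smallest leaf label per active node (tie-breaking)
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) clamped <<- TRUE
    format(max(0, x), digits = 17, scientific = FALSE, trim = TRUE)
  }
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(rep_label[cand[k, 1]], rep_label[cand[k, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    new_sub <- paste0("(", sub[i], ":", bl(bi), ",", sub[j], ":", bl(bj), ")")
    new_rep <- min(rep_label[i], rep_label[j])
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    sub <- c(sub[keep], new_sub)
    rep_label <- c(rep_label[keep], new_rep)
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- paste0("(", sub[1], ":", bl(b1), ",", sub[2], ":", bl(b2),
                   ",", sub[3], ":", bl(b3), ");")
  tree <- ape::read.tree(text = newick)
  attr(tree, "clamped") <- clamped
  tree
}

# Character profile of sequences: equal-length sequences are stacked
# directly; otherwise each sequence is projected onto the columns of the
# longest sequence via global pairwise alignment (insertions relative to the
# anchor are dropped).
#' @noRd
sequence_profile <- function(seqs, alphabet = "protein") {
  lens <- nchar(seqs)
  if (length(unique(lens)) == 1L) {
    return(do.call(rbind, strsplit(seqs, "")))
  }
  ref_i <- which.max(lens)
  ref <- seqs[[ref_i]]
  L <- nchar(ref)
  mat <- matrix("-", length(seqs), L, dimnames = list(names(seqs), NULL))
  for (i in seq_along(seqs)) {
    if (i == ref_i) { mat[i, ] <- strsplit(ref, "")[[1]]; next }
    if (alphabet == "protein") {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(ref),
        type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 12, gapExtension = 2)
    } else {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[i]]), Biostrings::DNAString(ref),
        type = "global", substitutionMatrix = .dna_submat(),
        gapOpening = 8, gapExtension = 3)
    }
    p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
    s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
    mat[i, ] <- p[s != "-"]
  }
  mat
}

# p-distances over a (possibly column-weighted) character profile.
#' @noRd
profile_pdist <- function(mat, w = NULL) {
  if (is.null(w)) w <- rep(1, ncol(mat))
  letters_used <- setdiff(unique(as.vector(mat)), "-")
  valid <- (mat != "-") * 1
  matches <- 0
  for (a in letters_used) {
    xa <- (mat == a) * 1
    matches <- matches + tcrossprod(sweep(xa, 2, w, "*"), xa)
  }
  pairs <- tcrossprod(sweep(valid, 2, w, "*"), valid)
  d <- 1 - matches / pmax(pairs, 1)
  d[pairs == 0] <- 1
  diag(d) <- 0
  dimnames(d) <- list(rownames(mat), rownames(mat))
  d
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the profile implied by pairwise alignment to the longest sequence,
#' computes the NJ tree from its p-distances, and resamples profile columns
#' with replacement `n_replicates` times; the support of each internal edge
#' is the percentage of replicate trees containing its bipartition.
#' Deterministic for a fixed seed and invariant to leaf order.
#'
#' @param seqs named character vector (or two-column tibble) of sequences.
#' @param n_replicates number of bootstrap replicates (>= 1; 1000 matches the
#'   usual published setting).
#' @param seed integer seed.
#' @param alphabet `"protein"` or `"dna"`.
#' @return an `ape::phylo` tree whose `node.label` holds supports in
#'   `[0, 100]` (root label empty).
#' @export
bootstrap_support <- function(seqs, n_replicates = 1000, seed = 1,
                              alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs[[2]], seqs[[1]])
  assert_count(n_replicates, "n_replicates")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- seqs[order(names(seqs))] # leaf-order invariance
  mat <- sequence_profile(seqs, alphabet)
  L <- ncol(mat)
  main <- neighbor_joining(profile_pdist(mat))
  reps <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(k) {
      w <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      neighbor_joining(profile_pdist(mat, w))
    })
  })
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round_half_up(100 * counts / n_replicates, 1))
  if (length(main$node.label)) main$node.label[1] <- ""
  main
}

#' Attach per-leaf motif profiles to a tree
#'
#' Emits the ordered motif-id string of each leaf's locus, the sidecar used
#' to display conserved motifs alongside an NB-ARC tree.
#'
#' @param tree an `ape::phylo` tree whose tips are locus ids.
#' @param loci locus tibble with `locus_id` and `motif_chain`.
#' @return tibble (`label`, `motif_profile`), one row per leaf.
#' @export
attach_motif_profiles <- function(tree, loci) {
  idx <- match(tree$tip.label, loci$locus_id)
  if (anyNA(idx)) {
    stop("tree leaves without a locus: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    label = tree$tip.label,
    motif_profile = vapply(loci$motif_chain[idx], paste, character(1),
                           collapse = ",")
  )
}
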