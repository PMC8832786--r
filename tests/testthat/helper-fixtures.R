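# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

fixture_library <- function() cached("lib", generate_motif_library(1, 3, 8, 4))

# mid-sized synthetic set with introns, duplicates and fusions
fixture_sim <- function() cached("sim", {
  generate_contig_set(
    synthetic_config(seed = 7, n_loci = 30, n_contigs = 40, intron_rate = 0.5),
    fixture_library())
})

fixture_originals <- function() {
  sim <- fixture_sim()
  sim$contigs[!sim$contigs$contig_id %in% sim$duplicates$contig_id, ]
}

fixture_loci <- function() cached("loci", {
  annotate_contigs(fixture_originals(), fixture_library())
})

fixture_predictions <- function() cached("pred", {
  loci <- fixture_loci()
  predict_protein(loci[loci$completeness == "complete", ],
                  fixture_sim()$contigs, fixture_sim()$homologs)
})

# one clean planted locus sequence for hand-built contigs
build_test_locus <- function(lib, motif_ids, stop_in_linker = FALSE, seed = 99) {
  withr::with_seed(seed, {
    aa <- "M"
    for (id in motif_ids) {
      aa <- paste0(aa, nlrkit:::random_aa(12),
                   lib$consensus[lib$motif_id == id])
    }
    aa <- paste0(aa, nlrkit:::random_aa(12))
    dna <- paste0(nlrkit:::reverse_translate(aa), "TGA")
    if (stop_in_linker) {
      # overwrite the codon just after the second motif with TAA
      idx <- 1L + 12L + nchar(lib$consensus[lib$motif_id == motif_ids[1]]) +
        12L + nchar(lib$consensus[lib$motif_id == motif_ids[2]]) + 2L
      nt <- (idx - 1L) * 3L + 1L
      substr(dna, nt, nt + 2L) <- "TAA"
    }
    dna
  })
}

random_background <- function(n, seed) {
  withr::with_seed(seed, nlrkit:::random_dna(n))
}

# Independent textbook neighbor-joining oracle: plain loops, no shared code
# with the package implementation; returns an ape tree.
nj_oracle <- function(d) {
  labels <- rownames(d)
  nodes <- as.list(labels)
  active <- seq_along(labels)
  dm <- d
  while (length(active) > 3) {
    r <- length(active)
    best_q <- Inf; bi <- NA; bj <- NA
    for (x in seq_len(r - 1)) {
      for (y in (x + 1):r) {
        i <- active[x]; j <- active[y]
        qv <- (r - 2) * dm[i, j] -
          sum(dm[i, active]) - sum(dm[j, active])
        if (qv < best_q - 1e-12) { best_q <- qv; bi <- i; bj <- j }
      }
    }
    ri <- sum(dm[bi, active]); rj <- sum(dm[bj, active])
    li <- dm[bi, bj] / 2 + (ri - rj) / (2 * (r - 2))
    lj <- dm[bi, bj] - li
    new_id <- nrow(dm) + 1
    dm <- rbind(cbind(dm, 0), 0)
    for (k in active) {
      dm[new_id, k] <- dm[k, new_id] <- (dm[bi, k] + dm[bj, k] - dm[bi, bj]) / 2
    }
    nodes[[new_id]] <- paste0("(", nodes[[bi]], ":", max(0, li),
                              ",", nodes[[bj]], ":", max(0, lj), ")")
    active <- c(setdiff(active, c(bi, bj)), new_id)
  }
  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (dm[a, b] + dm[a, c3] - dm[b, c3]) / 2
  lb <- (dm[a, b] + dm[b, c3] - dm[a, c3]) / 2
  lc <- (dm[a, c3] + dm[b, c3] - dm[a, b]) / 2
  ape::read.tree(text = paste0("(", nodes[[a]], ":", max(0, la), ",",
                               nodes[[b]], ":", max(0, lb), ",",
                               nodes[[c3]], ":", max(0, lc), ");"))
}

random_distance_matrix <- function(n) {
  m <- matrix(stats::runif(n * n, 0.1, 2), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  rownames(m) <- colnames(m) <- paste0("t", seq_len(n))
  m
}
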