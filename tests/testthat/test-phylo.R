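test_that("NB-ARC extraction returns the exact span and errors on bad input", {
  prot <- tibble::tibble(protein_id = "p", protein = strrep("A", 900))
  dom <- tibble::tibble(protein_id = "p", domain_name = "NB-ARC",
                        start = 150, end = 450, source = "s", evalue = 0)
  nb <- extract_nbarc(prot, dom)
  expect_equal(nchar(nb[["p"]]), 301)
  expect_error(extract_nbarc(prot, dom[0, ]), "0 NB-ARC")
  expect_error(extract_nbarc(prot, dplyr::bind_rows(dom, dom)), "2 NB-ARC")
  out_of_bounds <- dplyr::mutate(dom, end = 1200)
  expect_error(extract_nbarc(prot, out_of_bounds), "out of bounds")
})

test_that("p-distances match direct column counting", {
  a <- withr::with_seed(61, nlrkit:::random_aa(100))
  chars <- strsplit(a, "")[[1]]
  pos <- withr::with_seed(62, sample(100, 50))
  chars[pos] <- vapply(chars[pos], function(x) {
    setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], x)[1]
  }, character(1))
  b <- paste(chars, collapse = "")
  c3 <- withr::with_seed(63, nlrkit:::random_aa(100))
  d <- pairwise_distance(c(x = a, y = b, z = c3))
  expect_equal(d["x", "x"], 0)
  expect_equal(d["x", "y"], 0.5)
  expect_equal(d, t(d))
  expect_error(pairwise_distance(c(x = a, y = b)), "at least 3")
})

test_that("3-taxon branch lengths equal the closed form", {
  d <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], (2 + 3 - 5) / 2)
  expect_equal(bl[["b"]], (2 + 5 - 3) / 2)
  expect_equal(bl[["c"]], (3 + 5 - 2) / 2)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|taxa")
})

test_that("additive matrices are reproduced exactly", {
  withr::with_seed(64, {
    for (n in c(4, 6, 12)) {
      tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
      d <- stats::cophenetic(tr)
      my <- neighbor_joining(d)
      expect_lt(max(abs(stats::cophenetic(my)[rownames(d), colnames(d)] - d)),
                1e-9)
      expect_equal(ape::dist.topo(ape::unroot(tr), my), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("NJ matches an independently coded textbook oracle", {
  withr::with_seed(65, {
    for (k in 1:100) {
      d <- random_distance_matrix(6)
      expect_equal(ape::dist.topo(neighbor_joining(d), nj_oracle(d)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("NJ agrees with the reference implementation in ape", {
  withr::with_seed(66, {
    for (k in 1:20) {
      d <- random_distance_matrix(8)
      expect_equal(ape::dist.topo(neighbor_joining(d), ape::nj(d)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("negative branch estimates are clamped and flagged", {
  d <- matrix(c(0, 1, 1, 4,
                1, 0, 1, 4,
                1, 1, 0, 1,
                4, 4, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(d)
  expect_true(all(tr$edge.length >= 0))
  expect_true(isTRUE(attr(tr, "clamped")))
})

test_that("bootstrap gives full support to a clean split and is reproducible", {
  seqs <- c(a1 = "MKLVAQWERTYIPASDFGHKL", a2 = "MKLVAQWERTYIPASDFGHKL",
            a3 = "MKLVAQWERTYIPASDFGHKL", b1 = "WWWWAQAARTYIPASDAAHAA",
            b2 = "WWWWAQAARTYIPASDAAHAA", b3 = "WWWWAQAARTYIPASDAAHAA")
  tr <- bootstrap_support(seqs, n_replicates = 200, seed = 5)
  supports <- as.numeric(tr$node.label[tr$node.label != ""])
  expect_true(all(supports == 100))
  tr2 <- bootstrap_support(seqs, n_replicates = 200, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  # invariant to leaf order
  tr3 <- bootstrap_support(seqs[c(4, 2, 6, 1, 3, 5)], n_replicates = 200, seed = 5)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr3))
  expect_error(bootstrap_support(seqs, n_replicates = 0), "n_replicates")
})

test_that("support frequencies are stable between 100 and 1000 replicates", {
  seqs <- withr::with_seed(67, {
    base <- nlrkit:::random_aa(60)
    mutate_n <- function(s, n) {
      chars <- strsplit(s, "")[[1]]
      pos <- sample(length(chars), n)
      chars[pos] <- strsplit(nlrkit:::random_aa(n), "")[[1]]
      paste(chars, collapse = "")
    }
    c(a = base, b = mutate_n(base, 4), c = mutate_n(base, 25),
      d = mutate_n(base, 28), e = mutate_n(base, 30))
  })
  s100 <- bootstrap_support(seqs, n_replicates = 100, seed = 9)
  s1000 <- bootstrap_support(seqs, n_replicates = 1000, seed = 10)
  expect_equal(ape::dist.topo(s100, s1000), 0, ignore_attr = TRUE)
  p100 <- as.numeric(s100$node.label[-1]) / 100
  p1000 <- as.numeric(s1000$node.label[-1]) / 100
  # 3-sigma binomial bound on the difference of the two estimates
  tol <- 3 * sqrt(pmax(p1000 * (1 - p1000), 0.25 / 1000) * (1 / 100 + 1 / 1000))
  expect_true(all(abs(p100 - p1000) <= pmax(tol, 0.03)))
})

test_that("motif profiles align with tree leaves", {
  loci <- tibble::tibble(locus_id = c("l1", "l2", "l3"),
                         motif_chain = list(c("cc_1", "nb_1"), "nb_1",
                                            c("nb_1", "lrr_1")))
  d <- random_distance_matrix(3)
  rownames(d) <- colnames(d) <- loci$locus_id
  tr <- neighbor_joining(d)
  prof <- attach_motif_profiles(tr, loci)
  expect_equal(nrow(prof), 3)
  expect_equal(prof$motif_profile[prof$label == "l1"], "cc_1,nb_1")
  expect_error(attach_motif_profiles(tr, loci[-1, ]), "without a locus")
})
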