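test_that("a planted motif is located at its exact forward coordinates", {
  lib <- fixture_library()
  ploop <- lib$consensus[lib$p_loop]
  dna <- withr::with_seed(31, nlrkit:::reverse_translate(ploop))
  contig <- paste0(random_background(300, 32), dna, random_background(300, 33))
  hits <- scan_motifs(tibble::tibble(contig_id = "c", sequence = contig), lib)
  hit <- hits[hits$motif_id == lib$motif_id[lib$p_loop] & hits$strand == "+", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 300)
  expect_equal(hit$end, 300 + 3 * nchar(ploop))
  expect_equal(hit$frame, 0)
  expect_gte(hit$score, 0.8)
})

test_that("scanning is strand-symmetric and case-insensitive", {
  lib <- fixture_library()
  ploop <- lib$consensus[lib$p_loop]
  dna <- withr::with_seed(31, nlrkit:::reverse_translate(ploop))
  fwd <- paste0(random_background(240, 34), dna, random_background(150, 35))
  rev <- nlrkit:::revcomp(fwd)
  h_fwd <- scan_motifs(tibble::tibble(contig_id = "c", sequence = fwd), lib)
  h_rev <- scan_motifs(tibble::tibble(contig_id = "c", sequence = rev), lib)
  pf <- h_fwd[h_fwd$motif_id == lib$motif_id[lib$p_loop], ]
  pr <- h_rev[h_rev$motif_id == lib$motif_id[lib$p_loop], ]
  expect_equal(pr$strand, "-")
  expect_equal(pr$start, nchar(fwd) - pf$end)  # mirrored interval
  expect_equal(pr$end, nchar(fwd) - pf$start)
  h_low <- scan_motifs(tibble::tibble(contig_id = "c", sequence = tolower(fwd)), lib)
  expect_equal(h_low, h_fwd)
  # short and empty-ish input
  expect_equal(nrow(scan_motifs(tibble::tibble(contig_id = "s", sequence = "ACGTACG"),
                                lib)), 0)
})

test_that("chaining respects the gap and splits at a fresh P-loop after LRR", {
  lib <- fixture_library()
  mk_hit <- function(motif_id, start) {
    w <- nchar(lib$consensus[lib$motif_id == motif_id])
    tibble::tibble(contig_id = "c", motif_id = motif_id,
                   category = lib$category[lib$motif_id == motif_id],
                   frame = 0L, strand = "+", start = start,
                   end = start + 3L * w, aa_start = start %/% 3L + 1L,
                   score = 1)
  }
  canonical <- dplyr::bind_rows(mk_hit("cc_1", 0), mk_hit("nb_1", 300),
                                mk_hit("nb_2", 600), mk_hit("lrr_1", 900))
  expect_equal(nrow(chain_loci(canonical, lib)), 1)
  # two chains 10 kb apart with a 3 kb gap limit
  two <- dplyr::bind_rows(canonical,
                          dplyr::mutate(canonical, start = start + 11000,
                                        end = end + 11000))
  loci2 <- chain_loci(two, lib, max_gap_bp = 3000)
  expect_equal(nrow(loci2), 2)
  expect_equal(loci2$locus_id, c("c_nlr_1", "c_nlr_2"))
  # contiguous CC,P-loop,LRR,LRR,P-loop,LRR splits before the second P-loop
  border <- dplyr::bind_rows(
    mk_hit("cc_1", 0), mk_hit("nb_1", 200), mk_hit("lrr_1", 400),
    mk_hit("lrr_2", 600), mk_hit("nb_1", 800), mk_hit("lrr_1", 1000))
  loci3 <- chain_loci(border, lib)
  expect_equal(nrow(loci3), 2)
  expect_equal(loci3$motif_chain[[1]], c("cc_1", "nb_1", "lrr_1", "lrr_2"))
  expect_equal(loci3$motif_chain[[2]], c("nb_1", "lrr_1"))
  # invariant to hit input order
  shuffled <- border[withr::with_seed(1, sample(nrow(border))), ]
  expect_equal(chain_loci(shuffled, lib)$motif_chain,
               loci3$motif_chain)
})

test_that("completeness follows the P-loop/NB-start/LRR rule with pseudogene flags", {
  lib <- fixture_library()
  complete <- build_test_locus(lib, c("cc_1", "nb_1", "nb_2", "lrr_1"), seed = 41)
  no_lrr <- build_test_locus(lib, c("cc_1", "nb_1", "nb_2"), seed = 42)
  with_stop <- build_test_locus(lib, c("cc_1", "nb_1", "nb_2", "lrr_1"),
                                stop_in_linker = TRUE, seed = 43)
  contigs <- tibble::tibble(
    contig_id = c("a", "b", "d"),
    sequence = vapply(list(complete, no_lrr, with_stop), function(s) {
      paste0(random_background(400, 44), s, random_background(400, 45))
    }, character(1)))
  loci <- annotate_contigs(contigs, lib)
  got <- setNames(loci$completeness, loci$contig_id)
  expect_equal(unname(got[c("a", "b", "d")]),
               c("complete", "partial", "complete_pseudogene"))
})

test_that("a frameshift inside the chain is called a pseudogene", {
  lib <- fixture_library()
  locus <- build_test_locus(lib, c("cc_1", "nb_1", "nb_2", "lrr_1"), seed = 46)
  # delete one base in the linker after the second motif
  cut <- 3L * (1L + 12L + nchar(lib$consensus[lib$motif_id == "cc_1"]) +
                 12L + nchar(lib$consensus[lib$motif_id == "nb_1"]) + 5L)
  shifted <- paste0(substr(locus, 1, cut), substr(locus, cut + 2, nchar(locus)))
  contig <- tibble::tibble(contig_id = "fs",
                           sequence = paste0(random_background(400, 47), shifted,
                                             random_background(400, 48)))
  loci <- annotate_contigs(contig, lib)
  expect_equal(loci$completeness, "complete_pseudogene")
})

test_that("clean synthetic data is recovered perfectly", {
  sim <- fixture_sim()
  loci <- fixture_loci()
  r <- evaluate_recovery(loci, sim$truth, fixture_library())
  expect_equal(r$precision, 1)
  expect_equal(r$recall, 1)
  expect_equal(r$completeness_agreement, 1)
  expect_equal(r$class_agreement, 1)
  # locus naming: <contig>_nlr_<k>, k increasing 5'->3' on the forward strand
  expect_true(all(grepl("^Contig_\\d+_nlr_\\d+$", loci$locus_id)))
  per_contig <- split(loci, loci$contig_id)
  for (g in per_contig) {
    expect_equal(g$locus_id[order(g$start)],
                 paste0(g$contig_id[1], "_nlr_", seq_len(nrow(g))))
  }
})

test_that("loci on one contig do not overlap after chaining", {
  loci <- fixture_loci()
  for (g in split(loci, loci$contig_id)) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})
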