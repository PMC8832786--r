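test_that("pairwise identity matches hand-counted examples", {
  seq100 <- random_background(100, seed = 1)
  expect_equal(unname(pairwise_identity(seq100, seq100)), c(100, 100))
  expect_equal(unname(pairwise_identity("ACGTACGT", "ACGAACGT")), c(87.5, 100))
  expect_error(pairwise_identity("", "ACGT"), "empty")
  # symmetric
  a <- random_background(300, seed = 2)
  b <- random_background(300, seed = 3)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
})

test_that("50 substitutions in a 1 kb sequence give ~95% identity", {
  base <- random_background(1000, seed = 4)
  chars <- strsplit(base, "")[[1]]
  pos <- withr::with_seed(5, sample(1000, 50))
  chars[pos] <- vapply(chars[pos],
                       function(x) setdiff(c("A", "C", "G", "T"), x)[1],
                       character(1))
  mut <- paste(chars, collapse = "")
  expect_equal(unname(pairwise_identity(base, mut)["identity"]), 95,
               tolerance = 0.1 / 95)
})

test_that("greedy dedup removes planted near-duplicates and only those", {
  sim <- fixture_sim()
  dec <- remove_redundant(sim$contigs, threshold = 95)
  expect_equal(nrow(dec), nrow(sim$contigs))               # conservation
  expect_setequal(dec$contig_id[dec$status == "removed"],
                  sim$duplicates$contig_id)
  removed <- dec[dec$status == "removed", ]
  expect_equal(removed$matched_id,
               sim$duplicates$source_contig_id[
                 match(removed$contig_id, sim$duplicates$contig_id)])
  expect_true(all(dec$reason[dec$status == "retained"] == "unique"))
  # 97% duplicates survive a 98% threshold: monotone in the threshold
  dec98 <- remove_redundant(sim$contigs, threshold = 98)
  expect_equal(sum(dec98$status == "removed"), 0)
  expect_gte(sum(dec98$status == "retained"), sum(dec$status == "retained"))
})

test_that("identical contigs collapse; threshold 100 keeps near-identicals", {
  two <- tibble::tibble(contig_id = c("a", "b"),
                        sequence = rep(random_background(500, 6), 2))
  dec <- remove_redundant(two, 95)
  expect_equal(sort(dec$status), c("removed", "retained"))
  dec100 <- remove_redundant(two, 100)
  expect_equal(sum(dec100$status == "removed"), 0) # identity must EXCEED 100
  expect_error(remove_redundant(tibble::tibble(contig_id = c("a", "a"),
                                               sequence = c("ACGT", "ACGT"))),
               "duplicate")
})

test_that("rescue rules keep 95-99% complete NLRs and drop the rest", {
  lib <- fixture_library()
  locus <- build_test_locus(lib, c("cc_1", "nb_1", "nb_2", "lrr_1"), seed = 21)
  contig <- paste0(random_background(1200, 22), locus, random_background(1200, 23))
  # copy with substitutions confined to the flanks: complete NLR > 99% identical
  flank_mut <- function(seq, n_mut, seed) {
    withr::with_seed(seed, {
      chars <- strsplit(seq, "")[[1]]
      pos <- sample(c(1:1200, (nchar(seq) - 1199):nchar(seq)), n_mut)
      chars[pos] <- vapply(chars[pos],
                           function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                           character(1))
      paste(chars, collapse = "")
    })
  }
  # copy whose locus carries benign substitutions (~3%), keeping it complete
  locus_mut <- function(seq, seed) {
    withr::with_seed(seed, {
      chars <- strsplit(seq, "")[[1]]
      idx <- 1200 + seq(30, nchar(locus) - 30, by = 35) # sparse, in-locus
      for (p in idx) {
        for (cand in setdiff(c("A", "C", "G", "T"), chars[p])) {
          old <- chars[p]; chars[p] <- cand
          codon_start <- 1200 + (((p - 1200 - 1) %/% 3) * 3) + 1
          codon <- paste(chars[codon_start:(codon_start + 2)], collapse = "")
          if (!codon %in% c("TAA", "TAG", "TGA")) break
          chars[p] <- old
        }
      }
      paste(chars, collapse = "")
    })
  }
  # near-identical copy whose locus is pseudogenised by an in-frame stop
  pseudo_copy <- flank_mut(contig, 30, 26)
  stop_at <- 1200 + 181 # codon boundary inside the chain span
  substr(pseudo_copy, stop_at, stop_at + 2) <- "TAA"
  contigs <- tibble::tibble(
    contig_id = c("a_orig", "dup_hi", "dup_mid", "dup_partial"),
    sequence = c(contig,
                 flank_mut(contig, 60, 24),       # >99% over the locus
                 locus_mut(contig, 25),           # 95-99% over the locus
                 pseudo_copy))
  dec <- remove_redundant(contigs, 95)
  expect_equal(dec$status[dec$contig_id == "a_orig"], "retained")
  annotate_fn <- function(ctgs) annotate_contigs(ctgs, lib)
  catalog <- annotate_fn(contigs[contigs$contig_id == "a_orig", ])
  dec <- rescue_removed(dec, contigs, catalog, annotate_fn)
  reason_of <- function(id) dec$reason[dec$contig_id == id]
  if ("dup_hi" %in% dec$contig_id[dec$status != "retained"]) {
    expect_equal(reason_of("dup_hi"), "drop_complete_gt99")
  }
  expect_equal(reason_of("dup_mid"), "rescue_complete_95_99")
  expect_equal(dec$status[dec$contig_id == "dup_mid"], "rescued")
  expect_equal(reason_of("dup_partial"), "drop_no_or_partial_nlr")
  rescued <- attr(dec, "rescued_loci")
  expect_equal(unique(rescued$contig_id), "dup_mid")
  expect_true(all(rescued$completeness == "complete"))
})

test_that("low-complexity masking is soft, targeted and idempotent", {
  poly <- strrep("A", 200)
  expect_equal(mask_low_complexity(poly), tolower(poly))
  rand <- random_background(200, seed = 9)
  expect_identical(mask_low_complexity(rand), rand)
  mixed <- paste0(rand, strrep("AT", 60), random_background(150, 10))
  masked <- mask_low_complexity(mixed)
  expect_equal(nchar(masked), nchar(mixed))
  expect_identical(toupper(masked), toupper(mixed))     # length + content kept
  expect_identical(mask_low_complexity(masked), masked) # idempotent
  expect_true(grepl("atatat", masked, fixed = TRUE))
  expect_error(mask_low_complexity("ACGT", window = 2), "window")
})

test_that("masked contigs annotate identically (scanner ignores case)", {
  sim <- fixture_sim()
  lib <- fixture_library()
  one <- fixture_originals()[1, ]
  masked <- dplyr::mutate(one, sequence = mask_low_complexity(sequence))
  expect_equal(scan_motifs(masked, lib), scan_motifs(one, lib))
})
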