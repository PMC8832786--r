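test_that("group assignment takes the per-genome best hit and majority vote", {
  hits <- tibble::tibble(
    query_id = "q1",
    genome = c("AABBDD", "AABBDD", "HH", "DD"),
    chromosome = c("1A", "3B", "1H", "1D"),
    identity = c(95, 90, 92, 93),
    bitscore = c(2000, 1500, 1800, 1700))
  a <- assign_homoeologous_group(hits)
  expect_equal(a$group, 1L)             # best AABBDD hit is 1A by bitscore
  # majority with one off-genome vote
  h2 <- tibble::tibble(query_id = "q2", genome = c("AABBDD", "HH", "DD"),
                       chromosome = c("7D", "5H", "7D"))
  expect_equal(assign_homoeologous_group(h2)$group, 7L)
  # three-way tie is unassigned
  h3 <- tibble::tibble(query_id = "q3", genome = c("AABBDD", "HH", "DD"),
                       chromosome = c("1A", "2H", "3D"))
  expect_true(is.na(assign_homoeologous_group(h3)$group))
  # Un chromosomes are excluded from the vote
  h4 <- tibble::tibble(query_id = "q4", genome = c("AABBDD", "HH", "DD"),
                       chromosome = c("Un", "4H", "4D"))
  expect_equal(assign_homoeologous_group(h4)$group, 4L)
})

test_that("a fully concordant marker set raises no flags", {
  asg <- tibble::tibble(query_id = paste0("m", 1:14),
                        group = rep(1:7, each = 2))
  mk <- tibble::tibble(marker_id = paste0("m", 1:14),
                       status = "Complete NLR",
                       physical_arm = paste0(rep(1:7, each = 2), "V",
                                             rep(c("S", "L"), 7)))
  cr <- congruence_report(asg, mk)
  expect_false(any(cr$by_arm$discordant))
  expect_equal(sum(cr$by_arm$n_markers), 14)
  expect_error(congruence_report(asg, dplyr::mutate(mk, physical_arm = "8VL")),
               "physical_arm")
  unknown <- congruence_report(asg[-1, ], mk)
  expect_equal(unknown$unknown_ids, "m1")
})

test_that("synthetic 4VL discordance converges to the configured fraction", {
  lib <- fixture_library()
  sim <- generate_contig_set(synthetic_config(seed = 13, n_loci = 220,
                                              n_contigs = 260), lib)
  f <- 0.5
  hits <- generate_reference_hits(sim$truth, discordant_group_fraction = f,
                                  seed = 14)
  asg <- assign_homoeologous_group(hits)
  j <- dplyr::inner_join(asg, sim$truth[, c("locus_id", "physical_arm")],
                         by = c(query_id = "locus_id"))
  v4 <- j[j$physical_arm == "4VL", ]
  observed <- mean(v4$group == 7, na.rm = TRUE)
  expect_lt(abs(observed - f), 3 * sqrt(f * (1 - f) / nrow(v4)))
  # determinism of the discordant draw
  hits2 <- generate_reference_hits(sim$truth, discordant_group_fraction = f,
                                   seed = 14)
  expect_identical(hits, hits2)
})

test_that("orthologue screen applies strict thresholds and group matching", {
  rows <- tibble::tibble(
    nlr_gene = c("a", "b", "c", "d"),
    identity = c(91.5, 79.9, 85.0, 85.0),
    coverage = c(93.4, 95.0, 59.0, 80.0),
    nlr_group = c(1, 1, 1, 2), r_gene_group = 1)
  passed <- screen_orthologues(rows)
  expect_equal(passed$nlr_gene, "a") # b fails identity, c coverage, d group
  # threshold monotonicity: raising either threshold never enlarges the set
  loose <- screen_orthologues(rows, screen_thresholds(ortho_identity = 70,
                                                      ortho_coverage = 50))
  expect_true(all(passed$nlr_gene %in% loose$nlr_gene))
  tight <- screen_orthologues(rows, screen_thresholds(ortho_identity = 92))
  expect_true(all(tight$nlr_gene %in% passed$nlr_gene))
})

test_that("expression screen honours identity/coverage and splice comparison", {
  sim <- fixture_sim()
  pred <- fixture_predictions()
  tx <- generate_transcripts(sim$truth, sim$contigs, transcript_rate = 1,
                             transcript_error_rate = 0.002, seed = 3)
  expr <- match_expression(pred, tx)
  expect_true(all(expr$expressed))
  expect_true(all(expr$splice == "match"))
  # transcripts at ~94% identity fail the screen
  noisy <- generate_transcripts(sim$truth, sim$contigs, transcript_rate = 1,
                                transcript_error_rate = 0.06, seed = 3)
  expr_noisy <- match_expression(pred, noisy)
  expect_false(any(expr_noisy$expressed))
  # a shifted donor site is reported as a junction mismatch
  shifted <- generate_transcripts(sim$truth, sim$contigs, transcript_rate = 1,
                                  transcript_error_rate = 0, seed = 3,
                                  junction_shift_bp = 9)
  expr_shift <- match_expression(pred, shifted)
  intronic <- pred$locus_id[!is.na(pred$intron_offset)]
  got <- expr_shift[expr_shift$locus_id %in% intronic & expr_shift$expressed, ]
  expect_gt(nrow(got), 0)
  expect_true(all(got$splice == "mismatch at junction 1"))
  plain <- expr_shift[!expr_shift$locus_id %in% intronic & expr_shift$expressed, ]
  expect_true(all(plain$splice == "match"))
})

test_that("private indels require absence from every orthologue", {
  base <- random_background(600, seed = 71)
  query <- paste0(substr(base, 1, 300), substr(base, 307, 600)) # 6 bp deletion
  orths <- c(o1 = base, o2 = base, o3 = base)
  found <- find_private_indels(query, orths)
  expect_equal(nrow(found), 1)
  expect_equal(found$type, "del")
  expect_equal(found$length, 6)
  expect_equal(found$position, 300, tolerance = 3 / 300)
  # shared with one orthologue: excluded
  expect_equal(nrow(find_private_indels(query, c(o1 = base, o2 = query))), 0)
  expect_equal(nrow(find_private_indels(base, c(o1 = base))), 0)
  # short indels below min_len are ignored
  q2 <- paste0(substr(base, 1, 300), substr(base, 303, 600))
  expect_equal(nrow(find_private_indels(q2, orths, min_len = 3)), 0)
  expect_error(find_private_indels(base, character(0)), "orthologue")
})

test_that("shared/unique partitions hold for membership tables", {
  tbl <- tibble::tibble(
    id_name = c("X", "Y", "Z"),
    genomes = list(c("VV"), c("VV", "AA"), c("AA", "HH")))
  su <- shared_unique_ids(tbl)
  expect_equal(su$grand_total, 3)
  vv <- su$per_species[su$per_species$species == "VV", ]
  expect_equal(c(vv$total, vv$shared, vv$unique), c(2, 1, 1))
  expect_true(all(su$per_species$shared + su$per_species$unique ==
                    su$per_species$total))
  single <- shared_unique_ids(tibble::tibble(id_name = "X",
                                             genomes = list("VV")))
  expect_equal(single$per_species$unique, 1)
  empty <- shared_unique_ids(tbl[0, ])
  expect_equal(empty$grand_total, 0)
})

test_that("anchor windows count paralogues; empty anchors count zero", {
  hits <- tibble::tibble(locus_mb = c(29.9, 30.5, 8.4, NA))
  expect_equal(locus_paralogue_count(hits, 30.2), 2)
  expect_equal(locus_paralogue_count(hits, 8.6), 1)
  expect_equal(locus_paralogue_count(hits, 500), 0)
})

test_that("polymorphism rate rounds half-up to integer percent", {
  expect_equal(polymorphism_rate(105, 757), 14L)
  expect_equal(polymorphism_rate(1, 8), 13L)   # 12.5 rounds up
  expect_error(polymorphism_rate(1, 0), "positive")
})
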