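test_that("simulated genomes hit the target GC and are seed-deterministic", {
  g <- simulate_genome(10000, gc_content = 0.38, seed = 1)
  freq <- Biostrings::letterFrequency(g[[1]], c("C", "G"))
  expect_lt(abs(sum(freq) / 10000 - 0.38), 0.03)
  g2 <- simulate_genome(10000, gc_content = 0.38, seed = 1)
  expect_identical(as.character(g), as.character(g2))
  expect_error(simulate_genome(10000, gc_content = 0), "between 0 and 1")
  expect_error(simulate_genome(500), ">= 1000")
})

test_that("planted cohorts have the requested background/private structure", {
  truth <- make_test_cohort(seed = 11, n_background = 10, n_private = c(3, 2, 1, 0, 2, 2))
  expect_equal(nrow(truth$background), 10L)
  expect_equal(nrow(truth$private), 10L)
  expect_equal(unname(table(factor(truth$private$strain,
                                   levels = truth$strains))), c(3L, 2L, 1L, 0L, 2L, 2L),
               ignore_attr = TRUE)
  # background variants are ALT in every strain (MAF = 1), privates in exactly one
  maf <- compute_maf(truth$calls)
  bg_keys <- paste(truth$background$chrom, truth$background$pos)
  expect_true(all(maf$maf[paste(maf$chrom, maf$pos) %in% bg_keys] == 1))
  pv_keys <- paste(truth$private$chrom, truth$private$pos)
  expect_true(all(maf$n_alt[paste(maf$chrom, maf$pos) %in% pv_keys] == 1L))
  # spacing: no background/private variant within 50 bp of a guide site
  for (i in seq_len(nrow(truth$guides))) {
    gd <- truth$guides[i, ]
    near <- truth$background$chrom == gd$chrom &
      abs(truth$background$pos - gd$pos) <= 50
    expect_false(any(near))
  }
})

test_that("duplicate guide loci and impossible placements are rejected", {
  g <- simulate_genome(5000, seed = 2)
  guides <- tibble::tibble(
    strain = c("a", "b"), protospacer = strrep("A", 20), pam = "AGG",
    chrom = names(g)[1], pos = c(1000L, 1000L), strand = "+")
  edits <- tibble::tibble(strain = c("a", "b"), chrom = names(g)[1],
                          pos = c(1016L, 1016L), ref = "A", alt = "C")
  expect_error(plant_cohort(g, guides, edits, n_background = 1,
                            n_private_per_strain = 0),
               "same locus")
  guides$pos <- c(1000L, 2000L); edits$pos <- c(1016L, 2016L)
  expect_error(plant_cohort(g, guides, edits, n_background = 5000,
                            n_private_per_strain = 0),
               "larger genome")
})

test_that("off-target planting realizes the intended distance, brute-force verified", {
  g <- simulate_genome(30000, seed = 21)
  dg <- design_guides(g, "s1", seed = 22)
  for (d in c(0L, 3L)) {
    res <- plant_offtarget_site(g, dg$guides, d, seed = 30 + d)
    expect_equal(res$realized_distance, d)
    # independent check of the mutated genome with the adist-based oracle
    cs <- as.character(res$genome[[res$variant$chrom]])
    win <- substr(cs, res$variant$pos - 30, res$variant$pos + 30)
    expect_equal(min(bf_infix(dg$guides$target23, win),
                     bf_infix(dg$guides$target23, bf_revcomp(win))), d)
    # and the package scan recovers it
    sc <- scan_offtargets(dplyr::mutate(res$variant, strain = "s1"),
                          dg$guides, res$genome)
    expect_equal(sc$best_distance, d)
  }
  expect_error(plant_offtarget_site(g, dg$guides, 11), "0..10")
})

test_that("simulated coverage matches its model: mean, dropout, zero, determinism", {
  g <- simulate_genome(100000, seed = 31)
  tr <- simulate_coverage(g, coverage_model(mean_depth = 30), seed = 32)
  expect_lt(abs(mean(tr$depth) / 30 - 1), 0.01)

  drop <- tibble::tibble(chrom = names(g)[1], start = 10000L, end = 20000L,
                         factor = 0.2)
  trd <- simulate_coverage(g, coverage_model(mean_depth = 30, dropout = drop),
                           seed = 33)
  inside <- trd$depth[trd$pos > 10000 & trd$pos <= 20000]
  outside <- trd$depth[trd$pos <= 10000 | trd$pos > 20000]
  expect_lt(abs(mean(inside) / mean(outside) / 0.2 - 1), 0.1)

  tr0 <- simulate_coverage(g, coverage_model(mean_depth = 0), seed = 34)
  expect_true(all(tr0$depth == 0L))

  expect_identical(simulate_coverage(g, coverage_model(5, overdispersion = 0.3), seed = 35),
                   simulate_coverage(g, coverage_model(5, overdispersion = 0.3), seed = 35))
})

test_that("GC slope induces the right sign of coverage-GC correlation", {
  g <- simulate_genome(100000, seed = 41)
  gc <- gc_profile(g)
  pos_runs <- vapply(1:5, function(s) {
    tr <- simulate_coverage(g, coverage_model(20, gc_slope = 8), seed = 100 + s)
    correlate_coverage_covariate(tr, gc, method = "spearman", seed = s)$estimate
  }, numeric(1))
  expect_true(all(pos_runs > 0))
  tr0 <- simulate_coverage(g, coverage_model(20, gc_slope = 0), seed = 42)
  est0 <- correlate_coverage_covariate(tr0, gc, method = "spearman", seed = 43)$estimate
  expect_lt(abs(est0), 0.05)
})

test_that("simulated call sets behave binomially and respect edge cases", {
  g <- simulate_genome(50000, seed = 51)
  truth <- tibble::tibble(chrom = names(g)[1], pos = seq(100L, by = 9L,
                                                         length.out = 5000L),
                          ref = "A", alt = "C")
  expect_identical(simulate_calls(truth, tpr = 1, fpr_count = 0, g, seed = 52),
                   truth[, c("chrom", "pos", "ref", "alt")])
  kept <- simulate_calls(truth, tpr = 0.9, fpr_count = 0, g, seed = 53)
  expect_lt(abs(nrow(kept) - 0.9 * 5000), 3 * sqrt(5000 * 0.9 * 0.1))
  none <- simulate_calls(truth, tpr = 0, fpr_count = 5, g, seed = 54)
  expect_equal(nrow(none), 5L)
  expect_false(any(paste(none$chrom, none$pos) %in% paste(truth$chrom, truth$pos)))
})

test_that("simulated on/off-target pairs sit at exactly the requested distances", {
  target <- paste0(random_dna(20), "TGG")
  withr::with_seed(61, {
    pairs <- simulate_target_pairs(target, rep(0:6, each = 2), seed = 62)
    pd <- pair_distances(pairs)
    expect_equal(pd$distance, rep(0:6, each = 2))
    # cross-check against adist, the independent implementation
    expect_equal(pd$distance, as.integer(utils::adist(target, pairs$off_seq)))
  })
})
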