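test_that("hard filters use strict inequalities and label violated clauses", {
  rec <- tibble::tibble(chrom = "c1", pos = 1:5,
                        QD = c(1.9, NA, 2.0, 25, 1.0),
                        FS = c(NA, NA, 60.0, 61.0, 70.0),
                        MQ = 60, SOR = 1)
  out <- apply_hard_filters(rec)
  expect_equal(out$pass, c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$filter_reasons[1], "QD<2")          # QD = 1.9 fails
  expect_true(is.na(out$filter_reasons[2]))            # absent annotations pass
  expect_true(out$pass[3])                             # FS = 60.0 exactly passes
  expect_equal(out$filter_reasons[4], "FS>60")
  expect_equal(out$filter_reasons[5], "QD<2;FS>60")    # all violations reported
  # partition is exhaustive
  expect_true(all(out$pass | !is.na(out$filter_reasons)))

  bad <- dplyr::mutate(rec, QD = as.character(QD))
  expect_error(apply_hard_filters(bad), "not numeric")

  loose <- apply_hard_filters(rec, hard_filter_thresholds(QD_min = 0.5))
  expect_true(loose$pass[1])
})

test_that("cohort filters mask low-depth genotypes then drop high-missingness records", {
  strains <- paste0("s", 1:16)
  calls <- tidyr::crossing(
    tibble::tibble(chrom = "c1", pos = c(10L, 20L, 30L), ref = "A", alt = "T"),
    sample = factor(strains, levels = strains)) |>
    dplyr::mutate(gt = "ALT", dp = 20L)
  # pos 10: one genotype at DP 2 (< 0.1 x 30 = 3) -> masked, record kept
  calls$dp[calls$pos == 10 & calls$sample == "s1"] <- 2L
  # pos 20: two genotypes at DP 2 -> masked twice -> record excluded
  calls$dp[calls$pos == 20 & calls$sample %in% c("s1", "s2")] <- 2L
  # pos 30: DP 2 but unknown-average exemption does not apply; NA dp is exempt
  calls$dp[calls$pos == 30 & calls$sample == "s3"] <- NA
  cov <- tibble::tibble(sample = strains, mean_depth = 30)
  out <- suppressMessages(apply_cohort_filters(calls, cov))
  expect_equal(attr(out, "n_masked"), 3L)
  expect_equal(attr(out, "n_excluded_records"), 1L)
  expect_false(any(out$pos == 20))
  expect_equal(sum(out$gt[out$pos == 10] == "MISSING"), 1L)
  expect_true(all(out$gt[out$pos == 30] == "ALT"))   # unknown depth untouched

  expect_error(apply_cohort_filters(calls, tibble::tibble(sample = strains,
                                                          mean_depth = 0)),
               "positive mean_depth")
})

test_that("MAF counts non-reference alleles after excluding missing genotypes", {
  mk <- function(gts) {
    tibble::tibble(chrom = "c1", pos = 1L, ref = "A", alt = "T",
                   sample = factor(paste0("s", seq_along(gts))), gt = gts,
                   dp = NA_integer_)
  }
  expect_equal(compute_maf(mk(rep("ALT", 16)))$maf, 1)
  expect_equal(compute_maf(mk(c("ALT", rep("REF", 14), "MISSING")))$maf, 1 / 15)
  expect_error(compute_maf(mk(rep("MISSING", 16))), "MAF undefined")
  # invariant to sample order
  gts <- c("ALT", "ALT", "REF", "MISSING", "REF")
  expect_equal(compute_maf(mk(gts))$maf, compute_maf(mk(rev(gts)))$maf)
})

test_that("classification partitions variants and issues per-strain verdicts", {
  truth <- make_test_cohort(seed = 61, n_background = 8, n_private = rep(2, 6))
  cl <- classify_variants(truth$calls, truth$edits)
  g <- glance(cl)
  expect_equal(g$n_background, 8L)
  expect_equal(g$n_private, 12L)
  expect_equal(g$n_on_target, 6L)
  expect_equal(g$n_shared, 0L)
  expect_equal(g$n_strains_edited, 5L)     # one strain left wild-type
  expect_equal(g$n_strains_wildtype, 1L)
  # partition is exhaustive and mutually exclusive
  expect_equal(sum(cl$counts$n), nrow(cl$variants))
  expect_true(all(cl$variants$class %in% c("ON_TARGET", "BACKGROUND",
                                           "PRIVATE", "SHARED")))
  # private variants carry their strain
  pv <- cl$variants[cl$variants$class == "PRIVATE", ]
  expect_true(all(!is.na(pv$strain)))

  # a variant ALT in 3 of 6 strains is SHARED
  strains <- truth$strains
  shared <- tidyr::crossing(
    tibble::tibble(chrom = "c1", pos = 999L, ref = "A", alt = "T"),
    sample = factor(strains, levels = strains)) |>
    dplyr::mutate(gt = ifelse(sample %in% strains[1:3], "ALT", "REF"),
                  dp = NA_integer_)
  cl2 <- classify_variants(dplyr::bind_rows(truth$calls[, names(shared)], shared),
                           truth$edits)
  expect_equal(cl2$variants$class[cl2$variants$pos == 999], "SHARED")

  # verdict "no call" when the designed record is absent from the calls
  drop_edit <- truth$edits[1, ]
  pruned <- dplyr::anti_join(truth$calls, drop_edit,
                             by = c("chrom", "pos", "ref", "alt"))
  cl3 <- classify_variants(pruned, truth$edits)
  expect_equal(cl3$verdicts$verdict[cl3$verdicts$strain == drop_edit$strain],
               "no call")
})

test_that("wild-type strains are reported from a REF genotype at the designed edit", {
  truth <- make_test_cohort(seed = 62)
  wt <- truth$edits$strain[!truth$edits$edited]
  cl <- classify_variants(truth$calls, truth$edits)
  expect_equal(sort(cl$verdicts$strain[cl$verdicts$verdict == "wild-type at target"]),
               sort(wt))
})

test_that("SNP calling rates implement the set-based TPR/FPR definitions", {
  truth <- tibble::tibble(chrom = "c1", pos = 1:100, ref = "A", alt = "T")
  expect_equal(snp_calling_rates(truth, truth)$tpr, 1)
  expect_equal(snp_calling_rates(truth, truth)$fpr, 0)

  called <- dplyr::bind_rows(truth[1:90, ],
                             tibble::tibble(chrom = "c2", pos = 1:10,
                                            ref = "G", alt = "C"))
  r <- snp_calling_rates(called, truth)
  expect_equal(r$tpr, 0.9)
  expect_equal(r$fpr, 0.1)
  # identity: tpr * |truth| + |truth \ called| = |truth|
  expect_equal(r$tpr * r$n_truth + (r$n_truth - r$n_true_called), r$n_truth)

  # indels are ignored in rate computations
  with_indel <- dplyr::bind_rows(called, tibble::tibble(
    chrom = "c1", pos = 500L, ref = "A", alt = "ATT"))
  expect_equal(snp_calling_rates(with_indel, truth), r)

  expect_error(snp_calling_rates(called, truth[0, ]), "empty")
  expect_warning(z <- snp_calling_rates(truth[0, ], truth), "FPR reported as 0")
  expect_equal(z$fpr, 0)
  expect_equal(z$tpr, 0)
})
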