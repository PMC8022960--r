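test_that("levenshtein matches classic instances and the reference implementation", {
  expect_equal(levenshtein("GATTACA", "GATTACA"), 0L)
  expect_equal(levenshtein("AC", ""), 2L)
  expect_equal(levenshtein("", "ACGT"), 4L)
  expect_equal(levenshtein("kitten", "sitting"), 3L)
  withr::with_seed(1, {
    a <- replicate(100, random_dna(sample(0:15, 1)))
    b <- replicate(100, random_dna(sample(0:15, 1)))
    expect_equal(levenshtein(a, b),
                 as.integer(diag(utils::adist(a, b))))
  })
})

test_that("levenshtein is a metric: identity, symmetry, triangle inequality", {
  withr::with_seed(2, {
    for (i in 1:30) {
      x <- random_dna(sample(1:12, 1)); y <- random_dna(sample(1:12, 1))
      z <- random_dna(sample(1:12, 1))
      expect_equal(levenshtein(x, x), 0L)
      expect_equal(levenshtein(x, y), levenshtein(y, x))
      expect_lte(levenshtein(x, z), levenshtein(x, y) + levenshtein(y, z))
    }
  })
})

test_that("infix best match equals the brute-force substring minimum", {
  expect_equal(infix_best_match("ACG", "TTACGTT")$distance, 0L)
  expect_equal(infix_best_match("ACG", "")$distance, 3L)
  expect_error(infix_best_match("", "ACGT"), "non-empty")
  withr::with_seed(3, {
    for (i in 1:200) {
      pattern <- random_dna(sample(1:8, 1))
      text <- random_dna(sample(0:30, 1))
      expect_equal(infix_best_match(pattern, text)$distance,
                   as.integer(bf_infix(pattern, text)))
    }
  })
})

test_that("infix match end positions identify substrings achieving the minimum", {
  hit <- infix_best_match("ACG", "ACGTACG")
  expect_equal(hit$distance, 0L)
  expect_equal(hit$ends, c(3L, 7L))   # both exact occurrences
})

test_that("scan windows span 30 bp flanks around the reference footprint", {
  g <- c(c1 = random_dna(500))
  snp <- tibble::tibble(chrom = "c1", pos = 101L, ref = "A", alt = "T")
  w <- extract_window(g, snp)
  expect_equal(c(w$window_start, w$window_end), c(70L, 131L))   # 0-based [70,131)
  expect_equal(nchar(w$window_seq), 61L)
  expect_false(w$truncated)

  del <- tibble::tibble(chrom = "c1", pos = 101L, ref = "AAA", alt = "A")
  wd <- extract_window(g, del)
  expect_equal(nchar(wd$window_seq), 63L)    # 60 + X with X = 3

  edge <- tibble::tibble(chrom = "c1", pos = 11L, ref = "A", alt = "T")
  we <- extract_window(g, edge)
  expect_equal(nchar(we$window_seq), 41L)
  expect_true(we$truncated)
  expect_equal(we$window_start, 0L)

  expect_error(extract_window(g, tibble::tibble(chrom = "c1", pos = 900L,
                                                ref = "A", alt = "T")),
               "outside chromosome bounds")
})

test_that("scanning finds reverse-strand targets and reports the matched span", {
  withr::with_seed(4, {
    target <- paste0(random_dna(20), "TGG")
    left <- random_dna(200)
    right <- random_dna(200)
    # place the reverse complement of the target so only the minus strand hits
    g <- c(c1 = paste0(left, bf_revcomp(target), right))
    snp_pos <- 200L + 12L   # inside the planted 23-mer
    v <- tibble::tibble(chrom = "c1", pos = snp_pos,
                        ref = substr(g[["c1"]], snp_pos, snp_pos), alt = "A",
                        strain = "s1")
    guides <- tibble::tibble(strain = "s1", protospacer = substr(target, 1, 20),
                             pam = substr(target, 21, 23), chrom = "c1",
                             pos = 201L, strand = "-")
    res <- scan_offtargets(v, guides, g)
    expect_equal(res$best_distance, 0L)
    expect_equal(res$strand, "-")
    expect_equal(res$match_seq, target)
    # the reported genomic span is the planted 23-mer
    expect_equal(c(res$match_start, res$match_end), c(200L, 223L))
  })
})

test_that("scanning is strand-symmetric under genome reverse complementation", {
  withr::with_seed(5, {
    g <- c(c1 = random_dna(400))
    grc <- c(c1 = bf_revcomp(g[["c1"]]))
    guides <- tibble::tibble(strain = "s1", protospacer = random_dna(20),
                             pam = paste0(random_dna(1), "GG"), chrom = "c1",
                             pos = 1L, strand = "+")
    for (p in c(60L, 200L, 333L)) {
      v <- tibble::tibble(chrom = "c1", pos = p, ref = "A", alt = "T", strain = "s1")
      vrc <- dplyr::mutate(v, pos = 400L - p + 1L)
      expect_equal(scan_offtargets(v, guides, g)$best_distance,
                   scan_offtargets(vrc, guides, grc)$best_distance)
    }
  })
})

test_that("extending the scan window can only decrease the best distance", {
  withr::with_seed(6, {
    g <- c(c1 = random_dna(2000))
    guides <- tibble::tibble(strain = "s1", protospacer = random_dna(20),
                             pam = paste0(random_dna(1), "GG"), chrom = "c1",
                             pos = 1L, strand = "+")
    v <- tibble::tibble(chrom = "c1", pos = c(300L, 900L, 1500L),
                        ref = "A", alt = "T", strain = "s1")
    d30 <- scan_offtargets(v, guides, g, flank = 30L)$best_distance
    d60 <- scan_offtargets(v, guides, g, flank = 60L)$best_distance
    expect_true(all(d60 <= d30))
  })
})

test_that("pair distances and the cleaning option behave as documented", {
  on <- paste0(strrep("ACGT", 5), "TGG")
  expect_equal(pair_distances(tibble::tibble(on_seq = on, off_seq = on))$distance, 0L)
  off2 <- paste0("TT", substr(on, 3, 23))   # two substitutions
  expect_equal(pair_distances(tibble::tibble(on_seq = on, off_seq = off2))$distance, 2L)
  gapped <- tibble::tibble(on_seq = on, off_seq = paste0("-", on))
  expect_equal(pair_distances(gapped, clean = TRUE)$distance, 0L)
  expect_equal(pair_distances(gapped, clean = FALSE)$distance, 1L)
})

test_that("distance comparison counts overlap with the reference regime", {
  cmp <- compare_distance_distributions(c(7, 8, 9), 0:6)
  expect_equal(glance(cmp)$n_observed_le_max_reference, 0L)
  expect_equal(glance(cmp)$min_observed, 7)
  cmp2 <- compare_distance_distributions(c(3), 0:6)
  expect_equal(glance(cmp2)$n_observed_le_max_reference, 1L)
  h <- cmp$histogram
  expect_equal(sum(h$n_observed), 3L)
  expect_equal(sum(h$n_reference), 7L)
  long <- tidy(cmp)
  expect_equal(nrow(long), 2 * nrow(h))
})

test_that("planted off-targets are flagged among spontaneous private variants", {
  g <- simulate_genome(60000, seed = 81)
  dg <- design_guides(g, paste0("s", 1:4), seed = 82)
  truth <- plant_cohort(g, dg$guides, dg$edits, n_background = 5,
                        n_private_per_strain = rep(6, 4), n_wildtype = 0,
                        seed = 83,
                        offtarget_plan = tibble::tibble(strain = c("s1", "s2"),
                                                        distance = c(1L, 4L)))
  cl <- classify_variants(truth$calls, truth$edits)
  priv <- dplyr::filter(tidy(cl), class == "PRIVATE")
  expect_equal(nrow(priv), 26L)   # 24 spontaneous + 2 planted
  res <- scan_offtargets(priv, truth$guides, truth$genome)
  planted <- truth$planted_offtargets
  got <- res$best_distance[match(paste(planted$chrom, planted$pos),
                                 paste(res$chrom, res$pos))]
  expect_equal(got, planted$realized_distance)
  expect_equal(got, c(1L, 4L))
})
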