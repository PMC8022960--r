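# Independent oracles and small fixture builders used across tests.
# Oracles deliberately avoid the package's own DP / window code paths:
# edit distances come from utils::adist, window enumeration is re-derived
# from first principles.

# brute-force minimum Levenshtein distance between `pattern` and any
# substring of `text` (including the empty substring), via utils::adist
bf_infix <- function(pattern, text) {
  n <- nchar(text)
  subs <- ""
  if (n > 0L) {
    subs <- c(subs, unlist(lapply(seq_len(n), function(s) substring(text, s, s:n))))
  }
  min(utils::adist(pattern, subs))
}

bf_revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1L]]), collapse = ""))
}

# brute-force per-base GC covariate: independently enumerate the windows
# covering each base under the stated rules and average their GC fractions
bf_gc_per_base <- function(seq, window = 500L, step = 250L) {
  L <- nchar(seq)
  starts <- seq(0L, max(L - 1L, 0L), by = step)
  ends <- pmin(starts + window, L)
  keep <- (ends - starts) == window | (ends - starts) >= step
  if (!any(keep)) { starts <- 0L; ends <- L } else {
    starts <- starts[keep]; ends <- ends[keep]
  }
  win_gc <- vapply(seq_along(starts), function(k) {
    s <- substring(seq, starts[k] + 1L, ends[k])
    ch <- strsplit(s, "")[[1L]]
    denom <- sum(ch %in% c("A", "C", "G", "T"))
    if (denom == 0L) NA_real_ else sum(ch %in% c("C", "G")) / denom
  }, numeric(1))
  vapply(seq_len(L), function(b) {
    covering <- which(starts + 1L <= b & b <= ends & !is.na(win_gc))
    if (length(covering) == 0L) NA_real_ else mean(win_gc[covering])
  }, numeric(1))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small ready-made cohort for filter/classification tests
make_test_cohort <- function(seed = 42, n_strains = 6, glen = 40000,
                             n_background = 10, n_private = rep(2, 6), ...) {
  genome <- simulate_genome(glen, seed = seed)
  dg <- design_guides(genome, paste0("s", seq_len(n_strains)), seed = seed + 1)
  truth <- plant_cohort(genome, dg$guides, dg$edits,
                        n_background = n_background,
                        n_private_per_strain = n_private,
                        n_wildtype = 1, seed = seed + 2, ...)
  truth
}

uniform_track <- function(len = 100, depth = 30, chrom = "c1") {
  tibble::tibble(chrom = chrom, pos = seq_len(len), depth = as.integer(depth))
}
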