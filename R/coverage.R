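#' Per-base coverage-bias profile
#'
#' Coverage bias at a base is the ratio of its depth to the genome-wide
#' average depth: the closer to 1, the more evenly the base is covered
#' relative to the rest of the genome. The mean ratio over all bases is 1
#' by construction.
#'
#' @param track Dense depth tibble (`chrom`, `pos`, `depth`) covering the
#'   whole genome (as from [read_depth_tsv()] or [simulate_coverage()]).
#' @param probs Quantile probabilities for the summary (default
#'   1, 5, 25, 50, 75, 95, 99 percent).
#' @return An object of class `bias_profile`: a list with `ratios` (tibble
#'   `chrom`, `pos`, `ratio`), `quantiles` (tibble `prob`, `ratio`),
#'   `mean_depth` and `n_bases`. Has `tidy()`, `glance()` and `autoplot()`
#'   methods.
#' @export
bias_profile <- function(track, probs = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(track)))
  if (nrow(track) == 0L) stop("empty coverage track", call. = FALSE)
  avg <- mean(track$depth)
  if (avg == 0) stop("average coverage is zero", call. = FALSE)
  ratios <- tibble::tibble(chrom = track$chrom, pos = track$pos,
                           ratio = track$depth / avg)
  q <- quantile(ratios$ratio, probs = probs, names = FALSE)
  structure(list(ratios = ratios,
                 quantiles = tibble::tibble(prob = probs, ratio = q),
                 mean_depth = avg,
                 n_bases = nrow(track)),
            class = "bias_profile")
}

#' @export
#' @method print bias_profile
print.bias_profile <- function(x, ...) {
  cat(sprintf("Coverage-bias profile over %d bases (mean depth %.2f)\n",
              x$n_bases, x$mean_depth))
  print(x$quantiles)
  invisible(x)
}

#' Breadth of coverage at a depth threshold
#'
#' Fraction of genome positions covered at least `min_depth`-fold — e.g.
#' breadth at 8x, a common variant-calling coverage filter. Vectorised over
#' `min_depth`.
#'
#' @param track Dense depth tibble.
#' @param min_depth Non-negative depth threshold(s).
#' @return Numeric vector of fractions in `[0, 1]`, one per threshold.
#' @export
breadth_at_depth <- function(track, min_depth = 8L) {
  stopifnot(all(min_depth >= 0), nrow(track) > 0L)
  vapply(min_depth, function(m) mean(track$depth >= m), numeric(1))
}

#' Thin a coverage track to a fraction of its depth
#'
#' Emulates down-sampling a library to fewer reads at the depth level: each
#' base's depth is replaced by a binomial draw with size = depth and
#' success probability `fraction`, preserving the shape of metric-versus-
#' depth curves.
#'
#' @param track Dense depth tibble.
#' @param fraction Retention probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The thinned track (same shape).
#' @export
thin_coverage <- function(track, fraction, seed = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  with_seed_if(seed, {
    dplyr::mutate(tibble::as_tibble(track),
                  depth = rbinom(dplyr::n(), .data$depth, fraction))
  })
}

#' Per-base GC-content covariate from sliding windows
#'
#' GC content is computed in sliding windows (default 500 bp stepped by
#' 250 bp, starting at the chromosome start); each base's covariate is the
#' mean GC fraction of the windows covering it. A trailing window shorter
#' than the full width is kept iff its length is at least `step`; a
#' chromosome shorter than `step` becomes a single whole-chromosome window.
#' `N` bases are excluded from window denominators; windows with no
#' non-`N` base, and bases covered by no window, yield `NA`.
#'
#' @param genome Genome (`DNAStringSet` or named character vector).
#' @param window Window width in bp (default 500).
#' @param step Step between window starts in bp (default 250); must satisfy
#'   `window >= step >= 1`.
#' @return A tibble with columns `chrom`, `pos` (1-based), `gc`
#'   (in `[0, 1]` or `NA`).
#' @export
gc_profile <- function(genome, window = 500L, step = 250L) {
  genome <- validate_genome(genome)
  stopifnot(window >= step, step >= 1)
  purrr::map_dfr(names(genome), function(cn) {
    L <- Biostrings::width(genome[names(genome) == cn])
    starts <- seq(0L, max(L - 1L, 0L), by = step)
    ends <- pmin(starts + window, L)
    keep <- (ends - starts) == window | (ends - starts) >= step
    if (!any(keep)) { starts <- 0L; ends <- L } else { starts <- starts[keep]; ends <- ends[keep] }
    v <- Biostrings::Views(genome[[cn]], start = starts + 1L, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
    denom <- rowSums(freq)
    wgc <- ifelse(denom > 0, (freq[, "C"] + freq[, "G"]) / denom, NA_real_)
    acc <- numeric(L); cnt <- numeric(L)
    for (k in seq_along(starts)) {
      if (is.na(wgc[k])) next
      idx <- (starts[k] + 1L):ends[k]
      acc[idx] <- acc[idx] + wgc[k]
      cnt[idx] <- cnt[idx] + 1
    }
    tibble::tibble(chrom = cn, pos = seq_len(L),
                   gc = ifelse(cnt > 0, acc / cnt, NA_real_))
  })
}

#' Correlate coverage with a per-base covariate
#'
#' Joins a depth track with a per-base covariate (e.g. the GC profile or a
#' nucleosome-occupancy track), subsamples positions uniformly without
#' replacement (default 100,000, to bound computation on large genomes) and
#' returns the rank (Spearman, default) or Pearson correlation.
#'
#' @param track Dense depth tibble.
#' @param covariate Tibble with `chrom`, `pos` and one value column.
#' @param n_subsample Maximum number of positions used (default 100000).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param seed Optional integer seed for the subsample.
#' @return A one-row tibble with `method`, `estimate`, `n_used`.
#' @export
correlate_coverage_covariate <- function(track, covariate, n_subsample = 100000L,
                                         method = c("spearman", "pearson"),
                                         seed = NULL) {
  method <- match.arg(method)
  val_col <- setdiff(names(covariate), c("chrom", "pos"))[1L]
  if (is.na(val_col)) stop("covariate needs a value column", call. = FALSE)
  d <- dplyr::inner_join(track, covariate, by = c("chrom", "pos"))
  d <- d[!is.na(d[[val_col]]) & !is.na(d$depth), ]
  if (nrow(d) < 10L) stop("fewer than 10 usable positions", call. = FALSE)
  d <- with_seed_if(seed, {
    if (nrow(d) > n_subsample) d[sample.int(nrow(d), n_subsample), ] else d
  })
  if (sd(d$depth) == 0 || sd(d[[val_col]]) == 0) {
    stop("degenerate input: correlation undefined (constant depth or covariate)",
         call. = FALSE)
  }
  tibble::tibble(method = method,
                 estimate = cor(d$depth, d[[val_col]], method = method),
                 n_used = nrow(d))
}

#' Coverage bias stratified by annotation category
#'
#' Summarises the per-base bias ratio (depth / genome-wide average depth)
#' within annotation categories (e.g. the four rDNA sub-regions: 35S rRNA
#' genes, external/internal transcribed spacers, non-transcribed spacers).
#' Categories may overlap: a base contributes to every category containing
#' it. Bases in no category are summarised as `"unannotated"`.
#'
#' @param track Dense depth tibble.
#' @param annotations Tibble with columns `category`, `chrom`, `start`,
#'   `end` (0-based half-open, BED-style).
#' @return A tibble with one row per category (plus `"unannotated"`):
#'   `category`, `n_bases`, `mean_ratio` and bias-ratio quantiles `q05`,
#'   `q25`, `q50`, `q75`, `q95`. Empty categories get `n_bases = 0` and
#'   `NA` summaries.
#' @export
stratified_coverage <- function(track, annotations) {
  stopifnot(all(c("category", "chrom", "start", "end") %in% names(annotations)))
  if (any(annotations$end <= annotations$start)) {
    stop("annotation intervals must have end > start", call. = FALSE)
  }
  avg <- mean(track$depth)
  if (avg == 0) stop("average coverage is zero", call. = FALSE)
  depth_by_chrom <- track_vectors(track)
  bad <- !annotations$chrom %in% names(depth_by_chrom) |
    annotations$end > vapply(annotations$chrom, function(cn) {
      length(depth_by_chrom[[cn]] %||% integer(0))
    }, numeric(1))
  if (any(bad)) stop("annotation interval out of genome bounds", call. = FALSE)

  cat_positions <- function(sub) {
    unique(unlist(purrr::map2(sub$start, sub$end, function(s, e) s + seq_len(e - s)),
                  use.names = FALSE))
  }
  summarise_ratio <- function(category, ratios) {
    if (length(ratios) == 0L) {
      return(tibble::tibble(category = category, n_bases = 0L,
                            mean_ratio = NA_real_, q05 = NA_real_, q25 = NA_real_,
                            q50 = NA_real_, q75 = NA_real_, q95 = NA_real_))
    }
    q <- quantile(ratios, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    tibble::tibble(category = category, n_bases = length(ratios),
                   mean_ratio = mean(ratios),
                   q05 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q95 = q[5])
  }

  used <- lapply(depth_by_chrom, function(v) logical(length(v)))
  per_cat <- purrr::map_dfr(unique(annotations$category), function(cat) {
    ratios <- unlist(lapply(names(depth_by_chrom), function(cn) {
      sub <- annotations[annotations$category == cat & annotations$chrom == cn, ]
      if (nrow(sub) == 0L) return(numeric(0))
      p <- cat_positions(sub)
      used[[cn]][p] <<- TRUE
      depth_by_chrom[[cn]][p] / avg
    }), use.names = FALSE)
    summarise_ratio(cat, ratios)
  })
  unann <- unlist(lapply(names(depth_by_chrom), function(cn) {
    depth_by_chrom[[cn]][!used[[cn]]] / avg
  }), use.names = FALSE)
  dplyr::bind_rows(per_cat, summarise_ratio("unannotated", unann))
}

#' Median and mode of an insert-size histogram
#'
#' The median is the smallest insert length at which the cumulative count
#' reaches at least half of the total; the mode is the length with the
#' maximal count (smallest such length on ties). These are the two library
#' fragment-size summaries conventionally reported for tagmentation
#' libraries.
#'
#' @param histogram Tibble with columns `insert_length`, `count`.
#' @return A one-row tibble with `median`, `mode`, `total_count`.
#' @export
insert_size_summary <- function(histogram) {
  stopifnot(all(c("insert_length", "count") %in% names(histogram)))
  h <- histogram[histogram$count > 0, ]
  if (nrow(h) == 0L) stop("empty insert-size histogram", call. = FALSE)
  h <- h[order(h$insert_length), ]
  total <- sum(h$count)
  med <- h$insert_length[which(cumsum(h$count) >= total / 2)[1L]]
  mode <- h$insert_length[which.max(h$count)]
  tibble::tibble(median = med, mode = mode, total_count = total)
}
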