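# broom-style tidiers for the package's result objects

#' @describeIn bias_profile `tidy()`: the quantile summary as a tibble.
#' @param x A `bias_profile` object.
#' @param ... Unused.
#' @export
tidy.bias_profile <- function(x, ...) x$quantiles

#' @describeIn bias_profile `glance()`: one-row summary (mean depth,
#'   number of bases, mean ratio — 1 by construction).
#' @export
glance.bias_profile <- function(x, ...) {
  tibble::tibble(mean_depth = x$mean_depth, n_bases = x$n_bases,
                 mean_ratio = mean(x$ratios$ratio))
}

#' @describeIn classify_variants `tidy()`: the per-variant classification
#'   table.
#' @param x A `classified_cohort` object.
#' @param ... Unused.
#' @export
tidy.classified_cohort <- function(x, ...) x$variants

#' @describeIn classify_variants `glance()`: one row with per-class counts
#'   and the number of edited / wild-type / no-call strains.
#' @export
glance.classified_cohort <- function(x, ...) {
  counts <- stats::setNames(x$counts$n, paste0("n_", tolower(x$counts$class)))
  v <- x$verdicts$verdict
  dplyr::bind_cols(tibble::as_tibble(as.list(counts)),
                   tibble::tibble(n_variants = nrow(x$variants),
                                  n_strains_edited = sum(v == "edited"),
                                  n_strains_wildtype = sum(v == "wild-type at target"),
                                  n_strains_no_call = sum(v == "no call")))
}

#' @describeIn compare_distance_distributions `tidy()`: the long histogram
#'   (one row per distance and collection).
#' @param x A `distance_comparison` object.
#' @param ... Unused.
#' @export
tidy.distance_comparison <- function(x, ...) {
  tidyr::pivot_longer(x$histogram, c("n_observed", "n_reference"),
                      names_to = "collection", names_prefix = "n_",
                      values_to = "n")
}

#' @describeIn compare_distance_distributions `glance()`: the separation
#'   summary.
#' @export
glance.distance_comparison <- function(x, ...) x$separation

#' @describeIn plant_cohort `tidy()`: planted truth counts per class.
#' @param x A `cohort_truth` object.
#' @param ... Unused.
#' @export
tidy.cohort_truth <- function(x, ...) {
  tibble::tibble(
    class = c("background", "private", "designed", "planted_offtarget"),
    n = c(nrow(x$background), nrow(x$private), nrow(x$edits),
          nrow(x$planted_offtargets)))
}
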