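# ggplot2 displays for the main result types

#' @describeIn bias_profile `autoplot()`: density of the per-base bias
#'   ratio on a log axis, the conventional coverage-bias display.
#' @param object A `bias_profile` object.
#' @export
autoplot.bias_profile <- function(object, ...) {
  d <- object$ratios[object$ratios$ratio > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_density() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "per-base coverage / average coverage",
                  y = "density", title = "Coverage bias distribution") +
    ggplot2::theme_minimal()
}

#' @describeIn compare_distance_distributions `autoplot()`: side-by-side
#'   histogram of observed scan distances and reference pair distances.
#' @param object A `distance_comparison` object.
#' @export
autoplot.distance_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$n,
                                  fill = .data$collection)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Levenshtein edit distance to guide target", y = "count",
                  title = "Observed private variants vs reference off-target pairs") +
    ggplot2::theme_minimal()
}

#' Breadth-of-coverage curve across down-sampled depths
#'
#' Thins a track to a grid of retention fractions ([thin_coverage()]) and
#' plots breadth at `min_depth` against the realised mean depth — the
#' standard "fraction covered at least k-fold vs sequencing depth" curve.
#'
#' @param track Dense depth tibble.
#' @param min_depth Depth threshold (default 8).
#' @param fractions Retention fractions (default `seq(0.1, 1, 0.1)`).
#' @param seed Optional integer seed.
#' @return A ggplot; the underlying tibble (`fraction`, `mean_depth`,
#'   `breadth`) is in the plot's `data`.
#' @export
plot_breadth_curve <- function(track, min_depth = 8L,
                               fractions = seq(0.1, 1, by = 0.1), seed = NULL) {
  d <- with_seed_if(seed, purrr::map_dfr(fractions, function(f) {
    th <- thin_coverage(track, f)
    tibble::tibble(fraction = f, mean_depth = mean(th$depth),
                   breadth = breadth_at_depth(th, min_depth))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_depth, y = .data$breadth)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "mean depth after down-sampling",
                  y = paste0("fraction of genome covered >= ", min_depth, "x")) +
    ggplot2::theme_minimal()
}

#' Cohort mutation overview plot
#'
#' Tile plot of genotypes per strain and variant, coloured by variant
#' class, with the designed on-target edits highlighted — an overview of
#' identified mutations per edited strain.
#'
#' @param classified A `classified_cohort` ([classify_variants()]).
#' @param calls The long cohort tibble the classification was computed
#'   from.
#' @return A ggplot.
#' @export
plot_cohort_overview <- function(classified, calls) {
  sites <- classified$variants
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt, sep = ":")
  d <- calls |>
    dplyr::mutate(key = site_key(calls)) |>
    dplyr::left_join(sites |>
                       dplyr::mutate(key = key) |>
                       dplyr::select("key", "class"), by = "key") |>
    dplyr::filter(.data$gt == "ALT")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$key, y = .data$sample,
                                  fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "variant", y = "strain") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
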