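#' Hard-filter thresholds for site annotations
#'
#' The GATK-style hard-filter expression for short variants: a record fails
#' when at least one *present* annotation violates its threshold
#' (`QD < 2.0 || FS > 60.0 || MQ < 40.0 || SOR > 3.0 || MQRankSum < -12.5 ||
#' ReadPosRankSum < -8.0`). All inequalities are strict, exactly as printed:
#' `FS = 60.0` passes. Absent annotations never trigger a filter.
#'
#' @param QD_min,FS_max,MQ_min,SOR_max,MQRankSum_min,ReadPosRankSum_min
#'   Numeric thresholds (defaults as above).
#' @return A named list of thresholds for [apply_hard_filters()].
#' @export
hard_filter_thresholds <- function(QD_min = 2.0, FS_max = 60.0, MQ_min = 40.0,
                                   SOR_max = 3.0, MQRankSum_min = -12.5,
                                   ReadPosRankSum_min = -8.0) {
  list(QD_min = QD_min, FS_max = FS_max, MQ_min = MQ_min, SOR_max = SOR_max,
       MQRankSum_min = MQRankSum_min, ReadPosRankSum_min = ReadPosRankSum_min)
}

#' Apply hard filters to variant annotations
#'
#' Evaluates the hard-filter expression (see [hard_filter_thresholds()]) on
#' each record's annotation columns and labels failing records with the
#' specific violated clauses (e.g. `"QD<2;SOR>3"`). The pass/fail partition
#' is exhaustive: every record is either passing (`pass = TRUE`,
#' `filter_reasons = NA`) or failing with at least one reason.
#'
#' @param records Tibble with (any subset of) numeric annotation columns
#'   `QD`, `FS`, `MQ`, `SOR`, `MQRankSum`, `ReadPosRankSum`; `NA` = absent.
#' @param thresholds Output of [hard_filter_thresholds()].
#' @return `records` with added logical `pass` and character
#'   `filter_reasons` columns.
#' @export
apply_hard_filters <- function(records, thresholds = hard_filter_thresholds()) {
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  get_ann <- function(key) {
    if (!key %in% names(records)) return(rep(NA_real_, n))
    v <- records[[key]]
    if (!is.numeric(v)) {
      stop("annotation ", key, " is not numeric; first offending record: ",
           if (all(c("chrom", "pos") %in% names(records))) {
             paste0(records$chrom[1L], ":", records$pos[1L])
           } else "row 1",
           call. = FALSE)
    }
    v
  }
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.4f", x))
  clauses <- list(
    list(key = "QD", fail = function(v) v < thresholds$QD_min,
         label = paste0("QD<", fmt(thresholds$QD_min))),
    list(key = "FS", fail = function(v) v > thresholds$FS_max,
         label = paste0("FS>", fmt(thresholds$FS_max))),
    list(key = "MQ", fail = function(v) v < thresholds$MQ_min,
         label = paste0("MQ<", fmt(thresholds$MQ_min))),
    list(key = "SOR", fail = function(v) v > thresholds$SOR_max,
         label = paste0("SOR>", fmt(thresholds$SOR_max))),
    list(key = "MQRankSum", fail = function(v) v < thresholds$MQRankSum_min,
         label = paste0("MQRankSum<", fmt(thresholds$MQRankSum_min))),
    list(key = "ReadPosRankSum", fail = function(v) v < thresholds$ReadPosRankSum_min,
         label = paste0("ReadPosRankSum<", fmt(thresholds$ReadPosRankSum_min))))
  reasons <- rep("", n)
  for (cl in clauses) {
    v <- get_ann(cl$key)
    hit <- !is.na(v) & cl$fail(v)
    reasons[hit] <- paste(reasons[hit],
                          rep(cl$label, sum(hit)), sep = ";")
  }
  reasons <- sub("^;", "", reasons)
  records$pass <- reasons == ""
  records$filter_reasons <- ifelse(records$pass, NA_character_, reasons)
  records
}

#' Apply cohort-level depth and missingness filters
#'
#' Two sequential filters on a haploid cohort genotype table:
#'
#' 1. **Depth masking** — a genotype whose per-sample depth is below
#'    `depth_factor` times that sample's average genome-wide coverage is set
#'    to `MISSING` (depth is too low to trust the call). Genotypes with
#'    unknown depth (`dp = NA`) are exempt.
#' 2. **Missingness exclusion** — records with `MISSING` genotypes in at
#'    least `max_missing` samples (after masking) are excluded.
#'
#' Masking precedes the missingness count (the stricter ordering); both
#' steps report counts via `message()`.
#'
#' @param calls Long cohort tibble (see [read_vcf_cohort()]).
#' @param sample_coverage Tibble with columns `sample` and `mean_depth`
#'   (each sample's genome-wide average base coverage); must be positive
#'   for every sample that has any known depth.
#' @param depth_factor Masking factor (default 0.1: mask when
#'   `dp < 0.1 * mean_depth`).
#' @param max_missing Exclusion threshold on the per-record count of missing
#'   genotypes (default 2: exclude when missing in >= 2 samples).
#' @return The kept records (same long shape, genotypes masked), with
#'   attributes `n_masked` and `n_excluded_records`.
#' @export
apply_cohort_filters <- function(calls, sample_coverage, depth_factor = 0.1,
                                 max_missing = 2L) {
  stopifnot(depth_factor > 0, max_missing >= 1)
  stopifnot(all(c("sample", "mean_depth") %in% names(sample_coverage)))
  cov <- sample_coverage$mean_depth[match(as.character(calls$sample),
                                          as.character(sample_coverage$sample))]
  has_dp <- !is.na(calls$dp)
  if (any(has_dp & (is.na(cov) | cov <= 0))) {
    stop("positive mean_depth required for every sample with known DP",
         call. = FALSE)
  }
  mask <- has_dp & !is.na(cov) & calls$dp < depth_factor * cov &
    calls$gt != "MISSING"
  out <- dplyr::mutate(tibble::as_tibble(calls),
                       gt = ifelse(mask, "MISSING", .data$gt))
  message(sum(mask), " genotype(s) masked at depth < ", depth_factor,
          " x sample average coverage")
  out <- out |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::mutate(.n_missing = sum(.data$gt == "MISSING")) |>
    dplyr::ungroup()
  n_records_before <- nrow(dplyr::distinct(out, .data$chrom, .data$pos,
                                           .data$ref, .data$alt))
  kept <- dplyr::filter(out, .data$.n_missing < max_missing)
  n_records_after <- nrow(dplyr::distinct(kept, .data$chrom, .data$pos,
                                          .data$ref, .data$alt))
  message(n_records_before - n_records_after, " record(s) excluded with >= ",
          max_missing, " missing genotype(s)")
  kept <- dplyr::select(kept, -".n_missing")
  attr(kept, "n_masked") <- sum(mask)
  attr(kept, "n_excluded_records") <- n_records_before - n_records_after
  kept
}

#' Mutant allele frequency per site
#'
#' MAF is the fraction of non-reference alleles among non-missing haploid
#' genotypes: `#ALT / (#ALT + #REF)`. A site where every genotype is
#' missing has no defined MAF and is a hard error.
#'
#' @param calls Long cohort tibble.
#' @return A site-level tibble (one row per variant) with the site columns,
#'   annotation columns, `n_alt`, `n_ref`, `n_missing`, `maf` and, when
#'   `n_alt == 1`, `alt_strain` (the single carrier).
#' @export
compute_maf <- function(calls) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample", "gt") %in% names(calls)))
  keep_cols <- intersect(c("type", annotation_keys()), names(calls))
  sites <- calls |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(keep_cols), dplyr::first),
      n_alt = sum(.data$gt == "ALT"),
      n_ref = sum(.data$gt == "REF"),
      n_missing = sum(.data$gt == "MISSING"),
      alt_strain = if (sum(.data$gt == "ALT") == 1L) {
        as.character(.data$sample[.data$gt == "ALT"])
      } else NA_character_,
      .groups = "drop")
  if (any(sites$n_alt + sites$n_ref == 0L)) {
    bad <- sites[sites$n_alt + sites$n_ref == 0L, ][1L, ]
    stop("all genotypes missing at ", bad$chrom, ":", bad$pos,
         " - MAF undefined", call. = FALSE)
  }
  dplyr::mutate(sites, maf = .data$n_alt / (.data$n_alt + .data$n_ref))
}

#' Classify cohort variants by MAF and sharing pattern
#'
#' Classifies each variant of a (filtered) haploid cohort:
#'
#' * `ON_TARGET` — chrom/pos/ref/alt match a declared designed edit
#'   (overrides everything else);
#' * `BACKGROUND` — MAF exactly 1 (present in every non-missing strain;
#'   the base-strain differences from the reference);
#' * `PRIVATE` — ALT in exactly one strain (candidate spontaneous or
#'   off-target mutation);
#' * `SHARED` — anything else.
#'
#' Also produces a per-strain on-target verdict: `"edited"` when the
#' strain's genotype at its designed edit is ALT, `"wild-type at target"`
#' when REF, and `"no call"` when the record is absent from the calls or
#' the genotype is missing.
#'
#' @param calls Long cohort tibble (ideally after [apply_hard_filters()] /
#'   [apply_cohort_filters()]).
#' @param edits Designed-edit table: tibble with columns `strain`, `chrom`,
#'   `pos`, `ref`, `alt` (one row per strain).
#' @return An object of class `classified_cohort`: a list with `variants`
#'   (site tibble with `maf`, `class`, `strain` — carrier for PRIVATE,
#'   edited strain for ON_TARGET), `verdicts` (per-strain tibble) and
#'   `counts` (class counts). Has `tidy()` and `glance()` methods.
#' @export
classify_variants <- function(calls, edits = NULL) {
  sites <- compute_maf(calls)
  if (!is.null(edits)) {
    stopifnot(all(c("strain", "chrom", "pos", "ref", "alt") %in% names(edits)))
    edit_key <- paste(edits$chrom, edits$pos, edits$ref, edits$alt, sep = ":")
    if (anyDuplicated(edit_key)) {
      stop("duplicate designed-edit locus", call. = FALSE)
    }
  } else {
    edits <- tibble::tibble(strain = character(), chrom = character(),
                            pos = integer(), ref = character(), alt = character())
    edit_key <- character()
  }
  skey <- site_key(sites)
  on_idx <- match(skey, edit_key)
  sites$class <- dplyr::case_when(
    !is.na(on_idx) ~ "ON_TARGET",
    sites$maf == 1 ~ "BACKGROUND",
    sites$n_alt == 1L ~ "PRIVATE",
    TRUE ~ "SHARED")
  sites$strain <- dplyr::case_when(
    sites$class == "ON_TARGET" ~ edits$strain[on_idx],
    sites$class == "PRIVATE" ~ sites$alt_strain,
    TRUE ~ NA_character_)

  gt_lookup <- stats::setNames(calls$gt, paste(site_key(calls), calls$sample, sep = "@"))
  verdicts <- dplyr::mutate(tibble::as_tibble(edits), verdict = {
    key <- paste(.data$chrom, .data$pos, .data$ref, .data$alt, sep = ":")
    gt <- gt_lookup[paste(key, .data$strain, sep = "@")]
    dplyr::case_when(is.na(gt) ~ "no call",
                     gt == "ALT" ~ "edited",
                     gt == "REF" ~ "wild-type at target",
                     TRUE ~ "no call")
  })
  counts <- sites |>
    dplyr::count(.data$class, name = "n") |>
    tidyr::complete(class = c("ON_TARGET", "BACKGROUND", "PRIVATE", "SHARED"),
                    fill = list(n = 0L))
  structure(list(variants = dplyr::select(sites, -"alt_strain"),
                 verdicts = verdicts, counts = counts),
            class = "classified_cohort")
}

#' @export
#' @method print classified_cohort
print.classified_cohort <- function(x, ...) {
  cat("Classified cohort:", nrow(x$variants), "variants\n")
  print(x$counts)
  if (nrow(x$verdicts)) {
    cat("Strain verdicts:\n")
    print(dplyr::count(x$verdicts, .data$verdict))
  }
  invisible(x)
}

#' SNP-calling true and false positive rates
#'
#' Scores a called SNP set against a gold-standard truth set. SNPs are
#' identified by (chrom, pos, ref, alt); indel records in either set are
#' ignored. The true positive rate is the fraction of truth SNPs that were
#' called (`|called intersect truth| / |truth|`); the false-positive rate is
#' the fraction of called SNPs that are not in the truth set
#' (`|called \ truth| / |called|`). With zero called SNPs the FPR is
#' reported as 0 with a warning.
#'
#' @param called,truth Site tibbles with columns `chrom`, `pos`, `ref`,
#'   `alt`; `truth` must contain at least one SNP.
#' @return A one-row tibble: `tpr`, `fpr`, `n_truth`, `n_called`,
#'   `n_true_called`, `n_miscalled`.
#' @export
snp_calling_rates <- function(called, truth) {
  only_snps <- function(d) {
    d <- tibble::as_tibble(d)
    d[variant_type(d$ref, d$alt) == "SNP", c("chrom", "pos", "ref", "alt")] |>
      dplyr::distinct()
  }
  truth <- only_snps(truth)
  if (nrow(truth) == 0L) stop("truth SNP set is empty", call. = FALSE)
  called <- only_snps(called)
  tk <- site_key(truth); ck <- site_key(called)
  n_true_called <- sum(ck %in% tk)
  n_miscalled <- sum(!ck %in% tk)
  fpr <- if (nrow(called) == 0L) {
    warning("no called SNPs; FPR reported as 0", call. = FALSE)
    0
  } else n_miscalled / nrow(called)
  tibble::tibble(tpr = n_true_called / nrow(truth), fpr = fpr,
                 n_truth = nrow(truth), n_called = nrow(called),
                 n_true_called = n_true_called, n_miscalled = n_miscalled)
}
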