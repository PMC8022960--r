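#' Read a multi-sample haploid VCF into a long cohort table
#'
#' Parses a VCF v4.2 (via \pkg{vcfR}) into a tidy long tibble with one row
#' per (variant, sample). Genotypes are interpreted for a haploid cohort:
#'
#' * haploid GT `"0"` -> `"REF"`, a non-zero allele index -> `"ALT"` (for the
#'   record carrying that alternate allele), `"."` -> `"MISSING"`;
#' * homozygous diploid GTs collapse to the corresponding haploid call
#'   (`"0/0"` -> REF, `"1/1"` -> ALT); heterozygous or `"./."` genotypes map
#'   to `"MISSING"` with a warning (stray diploid records are tolerated, not
#'   fatal, since the intended input is haploid calling);
#' * multi-allelic sites are split into one biallelic record per alternate
#'   allele, duplicating site annotations; in the child record for alternate
#'   *k*, allele *k* is `"ALT"`, allele 0 is `"REF"` and any other non-zero
#'   allele is `"MISSING"` (the sample carries neither this alternate nor
#'   the reference).
#'
#' Per-sample `DP` is parsed when present; an absent DP is `NA` ("depth
#' unknown") and is exempt from depth-based masking in
#' [apply_cohort_filters()]. The INFO annotations `QD`, `FS`, `MQ`, `SOR`,
#' `MQRankSum`, `ReadPosRankSum` are parsed as numeric columns (`NA` when
#' absent); a non-numeric value is a hard error naming the record.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF with a GT FORMAT
#'   field and at least one sample column.
#' @return A tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `type` (`"SNP"`/`"INDEL"`), the six annotation columns, `sample` (factor
#'   in VCF column order), `gt` (`"REF"`/`"ALT"`/`"MISSING"`) and `dp`
#'   (integer, `NA` = unknown).
#' @export
read_vcf_cohort <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0L) stop("VCF has no variant records: ", path, call. = FALSE)
  if (ncol(vcf@gt) < 2L) stop("VCF has no sample columns: ", path, call. = FALSE)
  samples <- colnames(vcf@gt)[-1L]

  fix <- vcf@fix
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  dp_raw <- suppressWarnings(vcfR::extract.gt(vcf, element = "DP"))
  if (is.null(dp_raw)) dp_raw <- matrix(NA_character_, nrow(fix), length(samples))

  info <- fix[, "INFO"]
  ann <- lapply(annotation_keys(), function(key) {
    m <- regmatches(info, regexpr(paste0("(?:^|;)", key, "=([^;]*)"), info, perl = TRUE))
    val <- rep(NA_character_, length(info))
    hit <- grepl(paste0("(?:^|;)", key, "="), info, perl = TRUE)
    val[hit] <- sub(paste0("^.*?", key, "="), "", m)
    num <- suppressWarnings(as.numeric(ifelse(val == ".", NA, val)))
    bad <- hit & val != "." & is.na(num)
    if (any(bad)) {
      stop("non-numeric ", key, " annotation at ",
           fix[which(bad)[1L], "CHROM"], ":", fix[which(bad)[1L], "POS"],
           call. = FALSE)
    }
    num
  })
  names(ann) <- annotation_keys()

  gt_ok <- "^(\\.|[0-9]+)([/|](\\.|[0-9]+))?$"
  n_het <- 0L
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    gts <- gt_raw[i, ]
    gts[is.na(gts)] <- "."
    bad <- !grepl(gt_ok, gts)
    if (any(bad)) {
      stop("malformed GT '", gts[which(bad)[1L]], "' at record ", i,
           " (", fix[i, "CHROM"], ":", fix[i, "POS"], ")", call. = FALSE)
    }
    # collapse to a single haploid allele index per sample ("." = missing)
    allele <- vapply(strsplit(gts, "[/|]"), function(a) {
      if (length(a) == 1L) return(a)
      if (any(a == ".") || a[1L] != a[2L]) {
        n_het <<- n_het + 1L
        return(".")
      }
      a[1L]
    }, character(1))
    dp <- suppressWarnings(as.integer(ifelse(dp_raw[i, ] %in% c(".", ""), NA, dp_raw[i, ])))
    for (k in seq_along(alts)) {
      gt <- ifelse(allele == "0", "REF",
                   ifelse(allele == as.character(k), "ALT", "MISSING"))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"],
        alt = alts[k],
        QD = ann$QD[i], FS = ann$FS[i], MQ = ann$MQ[i], SOR = ann$SOR[i],
        MQRankSum = ann$MQRankSum[i], ReadPosRankSum = ann$ReadPosRankSum[i],
        sample = samples,
        gt = unname(gt),
        dp = unname(dp)
      )
    }
  }
  if (n_het > 0L) {
    warning(n_het, " heterozygous or partially missing diploid genotype(s) ",
            "set to MISSING (haploid cohort expected)", call. = FALSE)
  }
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  out$type <- variant_type(out$ref, out$alt)
  out$sample <- factor(out$sample, levels = samples)
  dplyr::relocate(out, "type", .after = "alt")
}

#' Write a long cohort table to VCF v4.2
#'
#' Inverse of [read_vcf_cohort()] for haploid cohorts: genotypes are written
#' as haploid GT (`0`, `1`, `.`), per-sample DP as an integer or `.`, and the
#' non-`NA` site annotations into INFO. Records already split per alternate
#' allele are written as separate biallelic lines (re-reading is idempotent).
#'
#' @param calls Long cohort tibble as returned by [read_vcf_cohort()] or
#'   [plant_cohort()].
#' @param path Output path.
#' @param genome Optional genome (`DNAStringSet`) used to emit contig header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_vcf_cohort <- function(calls, path, genome = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "sample", "gt") %in% names(calls)))
  samples <- if (is.factor(calls$sample)) levels(calls$sample) else unique(calls$sample)
  sites <- calls |>
    dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt,
                    .keep_all = TRUE) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$alt)

  fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))
  info_of <- function(row) {
    keys <- annotation_keys()
    vals <- unlist(row[keys])
    keep <- !is.na(vals)
    if (!any(keep)) return(".")
    paste(paste0(keys[keep], "=", fmt_num(vals[keep])), collapse = ";")
  }

  gt_wide <- calls |>
    dplyr::mutate(key = site_key(calls),
                  gt_code = dplyr::case_match(.data$gt, "REF" ~ "0",
                                              "ALT" ~ "1", "MISSING" ~ "."),
                  dp_code = ifelse(is.na(.data$dp), ".", as.character(.data$dp)),
                  cell = paste0(.data$gt_code, ":", .data$dp_code))
  cell_map <- split(gt_wide, gt_wide$key)

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=editscan",
    if (!is.null(genome)) {
      lens <- chrom_lengths(genome)
      sprintf("##contig=<ID=%s,length=%d>", names(lens), lens)
    },
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            annotation_keys(), annotation_keys()),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  body <- vapply(seq_len(nrow(sites)), function(i) {
    row <- sites[i, ]
    cells <- cell_map[[site_key(row)]]
    cells <- cells[match(samples, as.character(cells$sample)), ]
    paste(c(row$chrom, row$pos, ".", row$ref, row$alt, ".", ".",
            info_of(row), "GT:DP", cells$cell), collapse = "\t")
  }, character(1))

  writeLines(c(header, body), path)
  invisible(path)
}
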