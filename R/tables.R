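#' Read a per-base depth track
#'
#' Reads a headerless three-column TSV (`chrom`, `pos`, `depth`; 1-based
#' positions, as produced by `samtools depth`) and densifies it against a
#' genome: every base of every chromosome gets a row, with unlisted
#' positions at depth 0. Positions beyond the chromosome length or negative
#' depths are hard errors; an empty file yields all-zero tracks with a
#' warning.
#'
#' @param path Path to the TSV.
#' @param genome Genome the track is aligned to (`DNAStringSet` or named
#'   character vector); defines chromosome set and lengths.
#' @return A tibble with columns `chrom`, `pos` (1-based), `depth`, dense
#'   over the whole genome.
#' @export
read_depth_tsv <- function(path, genome) {
  genome <- validate_genome(genome)
  if (!file.exists(path)) stop("depth TSV not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_names = c("chrom", "pos", "depth"),
                         col_types = readr::cols(chrom = "c", pos = "i", depth = "i"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty depth file; returning all-zero tracks", call. = FALSE)
  } else {
    if (any(is.na(raw$pos)) || any(is.na(raw$depth))) {
      stop("malformed depth row in ", path, call. = FALSE)
    }
    if (any(raw$depth < 0L)) stop("negative depth in ", path, call. = FALSE)
    unknown <- setdiff(unique(raw$chrom), names(genome))
    if (length(unknown)) {
      stop("depth rows on chromosome(s) absent from genome: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    lens <- chrom_lengths(genome)
    bad <- raw$pos < 1L | raw$pos > lens[raw$chrom]
    if (any(bad)) {
      stop("depth position out of chromosome bounds: ",
           raw$chrom[which(bad)[1L]], ":", raw$pos[which(bad)[1L]],
           call. = FALSE)
    }
  }
  lens <- chrom_lengths(genome)
  purrr::map_dfr(names(lens), function(cn) {
    v <- integer(lens[[cn]])
    sub <- raw[raw$chrom == cn, ]
    v[sub$pos] <- sub$depth
    tibble::tibble(chrom = cn, pos = seq_len(lens[[cn]]), depth = v)
  })
}

#' Write a depth track as a sparse TSV
#'
#' Writes non-zero depths as a headerless `chrom`, `pos`, `depth` TSV
#' (the dialect [read_depth_tsv()] reads); round-tripping preserves every
#' non-zero depth.
#'
#' @param track Dense depth tibble (`chrom`, `pos`, `depth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_tsv <- function(track, path) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(track)))
  readr::write_tsv(track[track$depth > 0L, c("chrom", "pos", "depth")],
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a guide-target table
#'
#' Reads a TSV with header columns `strain`, `protospacer` (20 nt),
#' `pam` (3 nt), `chrom`, `pos` (1-based start of the 23-bp target site on
#' the plus strand), `strand` (`+`/`-`), and adds `target23` =
#' protospacer + PAM as written on the guide strand.
#'
#' @param path Path to the TSV.
#' @return A tibble of guide targets.
#' @export
read_guide_table <- function(path) {
  if (!file.exists(path)) stop("guide table not found: ", path, call. = FALSE)
  g <- readr::read_tsv(path, col_types = readr::cols(
    strain = "c", protospacer = "c", pam = "c",
    chrom = "c", pos = "i", strand = "c"), progress = FALSE)
  g$protospacer <- toupper(g$protospacer)
  g$pam <- toupper(g$pam)
  validate_guides(g)
}

validate_guides <- function(g) {
  need <- c("strain", "protospacer", "pam", "chrom", "pos", "strand")
  if (!all(need %in% names(g))) {
    stop("guide table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(nchar(g$protospacer) != 20L)) stop("protospacer must be 20 nt", call. = FALSE)
  if (any(nchar(g$pam) != 3L)) stop("PAM must be 3 nt", call. = FALSE)
  if (any(grepl("[^ACGT]", paste0(g$protospacer, g$pam)))) {
    stop("guide sequences must be over {A,C,G,T}", call. = FALSE)
  }
  if (!all(g$strand %in% c("+", "-"))) stop("guide strand must be + or -", call. = FALSE)
  g$target23 <- paste0(g$protospacer, g$pam)
  tibble::as_tibble(g)
}

#' Write a guide-target table
#'
#' @param guides Guide tibble (see [read_guide_table()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guide_table <- function(guides, path) {
  readr::write_tsv(guides[, c("strain", "protospacer", "pam", "chrom",
                              "pos", "strand")], path, progress = FALSE)
  invisible(path)
}

#' Read an insert-size histogram
#'
#' Reads a TSV with header columns `insert_length` and `count`.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `insert_length`, `count`.
#' @export
read_insert_histogram <- function(path) {
  if (!file.exists(path)) stop("histogram not found: ", path, call. = FALSE)
  h <- readr::read_tsv(path, col_types = readr::cols(insert_length = "i", count = "i"),
                       progress = FALSE)
  if (any(h$insert_length <= 0L) || any(h$count < 0L)) {
    stop("insert lengths must be positive and counts non-negative", call. = FALSE)
  }
  h
}

#' Read an on/off-target sequence-pair table
#'
#' Reads a TSV with header columns `on_seq`, `off_seq` and optionally
#' `read_count` (e.g. CIRCLE-seq cleavage read support).
#'
#' @param path Path to the TSV.
#' @return A tibble of sequence pairs.
#' @export
read_target_pairs <- function(path) {
  if (!file.exists(path)) stop("pair table not found: ", path, call. = FALSE)
  p <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (!all(c("on_seq", "off_seq") %in% names(p))) {
    stop("pair table must have columns on_seq and off_seq", call. = FALSE)
  }
  if (any(is.na(p$on_seq) | nchar(p$on_seq) == 0L) ||
      any(is.na(p$off_seq) | nchar(p$off_seq) == 0L)) {
    stop("pair sequences must be non-empty", call. = FALSE)
  }
  p$on_seq <- toupper(p$on_seq)
  p$off_seq <- toupper(p$off_seq)
  if ("read_count" %in% names(p)) p$read_count <- as.numeric(p$read_count)
  p
}
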