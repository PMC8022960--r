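#' Levenshtein edit distance
#'
#' Minimum number of single-character substitutions, insertions and
#' deletions transforming `a` into `b`, by the standard dynamic program.
#' Vectorised over pairs (arguments are recycled).
#'
#' @param a,b Character vectors of sequences (any alphabet).
#' @return Integer vector of distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")  # 3
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) lev1(a[i], b[i]), integer(1))
}

lev1 <- function(a, b) {
  s <- strsplit(a, "", fixed = TRUE)[[1L]]
  t <- strsplit(b, "", fixed = TRUE)[[1L]]
  m <- length(s); n <- length(t)
  if (m == 0L) return(n)
  if (n == 0L) return(m)
  prev <- 0:n
  cur <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (s[i] != t[j]), prev[j + 1L] + 1L, cur[j] + 1L)
    }
    tmp <- prev; prev <- cur; cur <- tmp
  }
  as.integer(prev[n + 1L])
}

#' Best infix (semi-global) match of a pattern in a text
#'
#' Minimum Levenshtein distance between `pattern` and *any substring* of
#' `text`, computed with a semi-global dynamic program whose first row is
#' all zeros (a match may start anywhere in the text for free). This equals
#' the brute-force minimum over all \eqn{O(n^2)} substrings, including the
#' empty substring, so the distance never exceeds `nchar(pattern)`.
#'
#' @param pattern Non-empty pattern sequence.
#' @param text Text sequence; may be empty, in which case the distance is
#'   `nchar(pattern)` and the match is the empty substring.
#' @return A list with `distance` (integer) and `ends` (integer vector of
#'   all 0-based end offsets in `text` achieving the minimum; an end offset
#'   `e` means the match is a substring ending at text position `e`,
#'   with `e = 0` denoting the empty substring at the start).
#' @export
infix_best_match <- function(pattern, text) {
  p <- strsplit(as.character(pattern), "", fixed = TRUE)[[1L]]
  t <- strsplit(as.character(text), "", fixed = TRUE)[[1L]]
  m <- length(p); n <- length(t)
  if (m == 0L) stop("pattern must be non-empty", call. = FALSE)
  if (n == 0L) return(list(distance = m, ends = 0L))
  prev <- integer(n + 1L)          # row i = 0: free start everywhere
  cur <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur[1L] <- i
    for (j in seq_len(n)) {
      cur[j + 1L] <- min(prev[j] + (p[i] != t[j]), prev[j + 1L] + 1L, cur[j] + 1L)
    }
    tmp <- prev; prev <- cur; cur <- tmp
  }
  d <- min(prev)
  list(distance = as.integer(d), ends = which(prev == d) - 1L)
}

#' Reverse complement of a DNA sequence
#'
#' `N` maps to `N`; other IUPAC codes are handled by \pkg{Biostrings}.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  vapply(as.character(x), dna_revcomp, character(1), USE.NAMES = FALSE)
}

#' Extract the (60 + X) bp scan window around a variant
#'
#' X is the variant length, `max(nchar(ref), nchar(alt))`, so the window
#' covers the full reference footprint of a deletion and scales for an
#' insertion. The window spans the X reference bases starting at the variant
#' position plus 30 bases of flank on each side (a SNP gives a symmetric
#' 30 + 1 + 30 = 61 bp window) and is truncated at chromosome ends with
#' `truncated = TRUE`.
#'
#' @param genome Genome (`DNAStringSet` or named character vector).
#' @param variants Tibble with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt` (one row per variant).
#' @param flank Flank width in bp on each side (default 30, giving the
#'   60 + X window).
#' @return The input with added columns `window_start`, `window_end`
#'   (0-based half-open genomic span), `window_seq` and `truncated`.
#' @export
extract_window <- function(genome, variants, flank = 30L) {
  genome <- validate_genome(genome)
  lens <- chrom_lengths(genome)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  if (any(!variants$chrom %in% names(lens))) {
    stop("variant chromosome absent from genome", call. = FALSE)
  }
  x_len <- pmax(nchar(variants$ref), nchar(variants$alt))
  pos0 <- variants$pos - 1L
  if (any(pos0 < 0L | pos0 >= lens[variants$chrom])) {
    stop("variant position outside chromosome bounds", call. = FALSE)
  }
  start <- pmax(pos0 - flank, 0L)
  end <- pmin(pos0 + x_len + flank, lens[variants$chrom])
  seqs <- vapply(seq_len(nrow(variants)), function(i) {
    substr(chrom_seq(genome, variants$chrom[i]), start[i] + 1L, end[i])
  }, character(1))
  dplyr::mutate(tibble::as_tibble(variants),
                window_start = as.integer(start),
                window_end = as.integer(end),
                window_seq = seqs,
                truncated = (end - start) < (2L * flank + x_len))
}

# distance + leftmost achieving span for one strand of one window
scan_one_strand <- function(target23, text) {
  hit <- infix_best_match(target23, text)
  j <- min(hit$ends)                       # leftmost end
  # reconstruct an achieving substring: leftmost start whose substring
  # ending at j attains the best distance
  lo <- max(0L, j - nchar(target23) - hit$distance)
  starts <- lo:j                           # 0-based start offsets (start == j -> empty)
  subs <- substring(text, starts + 1L, j)
  d_sub <- levenshtein(rep(target23, length(subs)), subs)
  s <- starts[which(d_sub == hit$distance)[1L]]
  list(distance = hit$distance, start = s, end = j)
}

#' Scan private variants for guide-like sequences
#'
#' For each variant, extracts the (60 + X) bp reference window centered on
#' it ([extract_window()]) and computes the best infix Levenshtein match of
#' the strain's 23-bp target (20-nt protospacer + 3-nt PAM) against the
#' window on both strands. A low best distance marks the variant as lying in
#' a guide-like sequence context, consistent with a Cas9 off-target edit;
#' unrelated windows typically score 7 or higher against a 23-bp target.
#'
#' Ties between strands break toward `+`; ties among match end positions
#' break toward the leftmost. Windows shorter than 23 bp after truncation
#' are still scanned (the infix DP handles them); windows containing `N`
#' are scanned as-is (`N` matches nothing).
#'
#' @param variants Tibble of variants with columns `chrom`, `pos`, `ref`,
#'   `alt` and `strain` (e.g. the private variants from
#'   [classify_variants()]).
#' @param guides Guide table (see [read_guide_table()]); each variant's
#'   strain must have exactly one guide.
#' @param genome Reference genome.
#' @param flank Flank width (default 30).
#' @return The variants with window columns plus `best_distance`, `strand`,
#'   `match_start`, `match_end` (0-based half-open genomic span of the
#'   matched substring, in plus-strand coordinates) and `match_seq` (the
#'   matched substring as scanned, i.e. reverse-complemented for `-`).
#' @export
scan_offtargets <- function(variants, guides, genome, flank = 30L) {
  stopifnot("strain" %in% names(variants))
  guides <- validate_guides(guides)
  missing_guide <- setdiff(unique(variants$strain), guides$strain)
  if (length(missing_guide)) {
    stop("no guide for strain(s): ", paste(missing_guide, collapse = ", "),
         call. = FALSE)
  }
  win <- extract_window(genome, variants, flank = flank)
  res <- purrr::map_dfr(seq_len(nrow(win)), function(i) {
    target <- guides$target23[match(win$strain[i], guides$strain)]
    fwd <- scan_one_strand(target, win$window_seq[i])
    rcseq <- dna_revcomp(win$window_seq[i])
    rev <- scan_one_strand(target, rcseq)
    L <- nchar(win$window_seq[i])
    if (fwd$distance <= rev$distance) {
      tibble::tibble(
        best_distance = fwd$distance, strand = "+",
        match_start = win$window_start[i] + fwd$start,
        match_end = win$window_start[i] + fwd$end,
        match_seq = substring(win$window_seq[i], fwd$start + 1L, fwd$end))
    } else {
      tibble::tibble(
        best_distance = rev$distance, strand = "-",
        match_start = win$window_start[i] + L - rev$end,
        match_end = win$window_start[i] + L - rev$start,
        match_seq = substring(rcseq, rev$start + 1L, rev$end))
    }
  })
  dplyr::bind_cols(win, res)
}

#' Edit distances of on/off-target sequence pairs
#'
#' Computes the Levenshtein distance between each on-target sequence and its
#' paired (e.g. CIRCLE-seq-captured) off-target sequence. Distances of
#' empirically cleaved pairs form the reference distribution against which
#' private-variant scan distances are compared: genuine Cas9 off-target
#' sites sit at low edit distance from their target.
#'
#' @param pairs Tibble with columns `on_seq`, `off_seq` and optionally
#'   `read_count`.
#' @param clean If `TRUE`, strip non-ACGT characters (e.g. bulge notation)
#'   from both sequences before computing distances. Default `FALSE`:
#'   distances are computed on the sequences as provided.
#' @return The input tibble with an added integer `distance` column.
#' @export
pair_distances <- function(pairs, clean = FALSE) {
  stopifnot(all(c("on_seq", "off_seq") %in% names(pairs)))
  on <- toupper(pairs$on_seq); off <- toupper(pairs$off_seq)
  if (any(nchar(on) == 0L) || any(nchar(off) == 0L)) {
    stop("pair sequences must be non-empty", call. = FALSE)
  }
  if (clean) {
    on <- gsub("[^ACGT]", "", on)
    off <- gsub("[^ACGT]", "", off)
  }
  dplyr::mutate(tibble::as_tibble(pairs), distance = levenshtein(on, off))
}

#' Cleavage activity stratified by pair edit distance
#'
#' Summarises `read_count` (cleavage read support) by edit distance for a
#' pair table with distances, for activity-versus-distance comparisons.
#'
#' @param pairs Output of [pair_distances()] with a `read_count` column.
#' @return A tibble with `distance`, `n`, `mean_read_count`,
#'   `median_read_count`.
#' @export
activity_by_distance <- function(pairs) {
  stopifnot(all(c("distance", "read_count") %in% names(pairs)))
  pairs |>
    dplyr::group_by(.data$distance) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_read_count = mean(.data$read_count, na.rm = TRUE),
                     median_read_count = median(.data$read_count, na.rm = TRUE),
                     .groups = "drop")
}

#' Compare observed scan distances with a reference distance distribution
#'
#' Tabulates counts per integer edit distance for the observed scan results
#' (private variants vs their strain's guide) and for a reference set
#' (e.g. empirical on/off-target pair distances), and summarises their
#' separation. An observed variant at or below the reference maximum is a
#' candidate off-target edit; a clear gap exonerates the cohort's private
#' variants.
#'
#' @param observed Numeric vector of distances, or a tibble with a
#'   `best_distance` column ([scan_offtargets()] output).
#' @param reference Numeric vector of distances, or a tibble with a
#'   `distance` column ([pair_distances()] output).
#' @return An object of class `distance_comparison`: a list with
#'   `histogram` (tibble `distance`, `n_observed`, `n_reference`) and
#'   `separation` (tibble `min_observed`, `max_reference`,
#'   `n_observed_le_max_reference`). Has `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
compare_distance_distributions <- function(observed, reference) {
  obs <- if (is.data.frame(observed)) observed$best_distance else observed
  ref <- if (is.data.frame(reference)) reference$distance else reference
  if (length(obs) == 0L || length(ref) == 0L) {
    stop("both distance collections must be non-empty", call. = FALSE)
  }
  dmax <- max(obs, ref)
  hist <- tibble::tibble(
    distance = 0:dmax,
    n_observed = vapply(0:dmax, function(d) sum(obs == d), integer(1)),
    n_reference = vapply(0:dmax, function(d) sum(ref == d), integer(1)))
  sep <- tibble::tibble(
    min_observed = min(obs),
    max_reference = max(ref),
    n_observed_le_max_reference = sum(obs <= max(ref)))
  structure(list(histogram = hist, separation = sep),
            class = "distance_comparison")
}

#' @export
#' @method print distance_comparison
print.distance_comparison <- function(x, ...) {
  cat("Edit-distance comparison (observed scan vs reference pairs)\n")
  print(x$histogram)
  cat(sprintf("min observed %d; max reference %d; observed <= reference max: %d\n",
              x$separation$min_observed, x$separation$max_reference,
              x$separation$n_observed_le_max_reference))
  invisible(x)
}
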