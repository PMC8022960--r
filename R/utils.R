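# internal helpers shared across modules

# Coerce a genome to an uppercase DNAStringSet with unique, non-empty
# chromosomes. Accepts a DNAStringSet or a named character vector.
validate_genome <- function(genome) {
  if (is.character(genome)) {
    if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == "")) {
      stop("a character genome must have chromosome names", call. = FALSE)
    }
    genome <- Biostrings::DNAStringSet(toupper(genome))
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("`genome` must be a DNAStringSet or named character vector", call. = FALSE)
  }
  if (length(genome) == 0L) stop("genome has no chromosomes", call. = FALSE)
  if (anyDuplicated(names(genome))) {
    stop("duplicate chromosome name: ",
         paste(unique(names(genome)[duplicated(names(genome))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(Biostrings::width(genome) == 0L)) {
    stop("empty sequence for chromosome: ",
         paste(names(genome)[Biostrings::width(genome) == 0L], collapse = ", "),
         call. = FALSE)
  }
  genome
}

chrom_lengths <- function(genome) {
  genome <- validate_genome(genome)
  stats::setNames(Biostrings::width(genome), names(genome))
}

# chromosome sequence as a plain character scalar
chrom_seq <- function(genome, chrom) {
  if (!chrom %in% names(genome)) {
    stop("chromosome not in genome: ", chrom, call. = FALSE)
  }
  as.character(genome[[chrom]])
}

# run `expr` under a fixed seed if one is given, otherwise in the current
# RNG stream (so nested generator calls advance one reproducible stream)
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

site_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

# SNP iff both alleles are single, distinct bases
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L & ref != alt, "SNP", "INDEL")
}

annotation_keys <- function() {
  c("QD", "FS", "MQ", "SOR", "MQRankSum", "ReadPosRankSum")
}

# dense per-chromosome depth vectors from a (chrom, pos, depth) tibble
track_vectors <- function(track) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(track)))
  split(track, track$chrom) |>
    lapply(function(d) {
      v <- integer(max(d$pos))
      v[d$pos] <- d$depth
      v
    })
}

dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
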