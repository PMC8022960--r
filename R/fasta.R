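#' Read a reference genome from FASTA
#'
#' Loads a FASTA file into a [Biostrings::DNAStringSet]. Sequences are
#' uppercased; any character outside `{A,C,G,T,N}` (IUPAC ambiguity codes,
#' stray letters) is replaced by `N` with a warning. Chromosome names are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A named `DNAStringSet`, one element per chromosome.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("invalid FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(raw) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(raw))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for chromosome: ",
         paste(nm[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }
  n_bad <- sum(vapply(seqs, function(s) nchar(gsub("[ACGTN]", "", s)), numeric(1)))
  if (n_bad > 0) {
    warning(n_bad, " character(s) outside {A,C,G,T,N} replaced by N",
            call. = FALSE)
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nm
  out
}

#' Write a genome to FASTA
#'
#' @param genome A `DNAStringSet` or named character vector of chromosomes.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- validate_genome(genome)
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}
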