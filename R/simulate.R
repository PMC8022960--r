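#' Simulate a random reference genome
#'
#' Bases are drawn i.i.d. with `P(G) + P(C) = gc_content`, split equally
#' between G and C (and between A and T). Deterministic under `seed`.
#'
#' @param lengths Integer vector of chromosome lengths (each >= 1000).
#' @param gc_content Target GC fraction, strictly between 0 and 1
#'   (default 0.38, yeast-like).
#' @param seed Optional integer seed.
#' @param chrom_names Optional chromosome names (default `chrI`, `chrII`,
#'   ... roman-numeral style).
#' @return A named `DNAStringSet`.
#' @export
simulate_genome <- function(lengths, gc_content = 0.38, seed = NULL,
                            chrom_names = NULL) {
  if (gc_content <= 0 || gc_content >= 1) {
    stop("gc_content must be strictly between 0 and 1", call. = FALSE)
  }
  if (any(lengths < 1000)) stop("chromosome lengths must be >= 1000", call. = FALSE)
  if (is.null(chrom_names)) {
    chrom_names <- paste0("chr", as.character(utils::as.roman(seq_along(lengths))))
  }
  stopifnot(length(chrom_names) == length(lengths))
  p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
         G = gc_content / 2, T = (1 - gc_content) / 2)
  with_seed_if(seed, {
    seqs <- vapply(lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
    names(seqs) <- chrom_names
    Biostrings::DNAStringSet(seqs)
  })
}

#' Design one guide target per strain on a genome
#'
#' Picks, for each strain, a random 23-bp target site (20-nt protospacer +
#' 3-nt PAM read off the genome on a random strand) such that target sites
#' are mutually separated and away from chromosome ends, and derives the
#' designed edit: a SNP at the protospacer's position 17 (adjacent to the
#' Cas9 cut site).
#'
#' @param genome Genome (`DNAStringSet`).
#' @param strains Character vector of strain names.
#' @param seed Optional integer seed.
#' @param min_separation Minimum bp between target sites (default 300).
#' @return A list with `guides` (tibble `strain`, `protospacer`, `pam`,
#'   `chrom`, `pos` (1-based plus-strand start of the 23-bp site), `strand`,
#'   `target23`) and `edits` (tibble `strain`, `chrom`, `pos`, `ref`,
#'   `alt`).
#' @export
design_guides <- function(genome, strains, seed = NULL, min_separation = 300L) {
  genome <- validate_genome(genome)
  lens <- chrom_lengths(genome)
  with_seed_if(seed, {
    placed <- tibble::tibble(chrom = character(), pos = integer())
    rows <- purrr::map_dfr(strains, function(st) {
      for (try in 1:200) {
        cn <- sample(names(lens), 1L, prob = lens)
        p <- sample.int(lens[[cn]] - 22L - 100L, 1L) + 50L
        ok <- !any(placed$chrom == cn & abs(placed$pos - p) < min_separation)
        if (ok) {
          placed <<- dplyr::bind_rows(placed, tibble::tibble(chrom = cn, pos = p))
          strand <- sample(c("+", "-"), 1L)
          site <- substr(chrom_seq(genome, cn), p, p + 22L)
          t23 <- if (strand == "+") site else dna_revcomp(site)
          return(tibble::tibble(strain = st, protospacer = substr(t23, 1, 20),
                                pam = substr(t23, 21, 23), chrom = cn,
                                pos = p, strand = strand, target23 = t23))
        }
      }
      stop("could not place guide for strain ", st,
           "; use a larger genome or smaller min_separation", call. = FALSE)
    })
    # designed edit: SNP at protospacer position 17 (just 5' of the cut site)
    edit_pos <- ifelse(rows$strand == "+", rows$pos + 16L, rows$pos + 23L - 17L)
    ref <- vapply(seq_len(nrow(rows)), function(i) {
      substr(chrom_seq(genome, rows$chrom[i]), edit_pos[i], edit_pos[i])
    }, character(1))
    alt <- vapply(ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1L)
    }, character(1), USE.NAMES = FALSE)
    list(guides = rows,
         edits = tibble::tibble(strain = rows$strain, chrom = rows$chrom,
                                pos = as.integer(edit_pos), ref = ref, alt = alt))
  })
}

# apply `d` random single-character edits (substitution / insertion /
# deletion) to a sequence; redundant edits may cancel, which is why callers
# verify the realized distance by brute force
mutate_sequence <- function(s, d) {
  bases <- c("A", "C", "G", "T")
  v <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (i in seq_len(d)) {
    op <- sample(c("sub", "ins", "del"), 1L)
    if (op == "del" && length(v) > 1L) {
      v <- v[-sample.int(length(v), 1L)]
    } else if (op == "ins") {
      at <- sample.int(length(v) + 1L, 1L)
      v <- append(v, sample(bases, 1L), after = at - 1L)
    } else {
      at <- sample.int(length(v), 1L)
      v[at] <- sample(setdiff(bases, v[at]), 1L)
    }
  }
  paste(v, collapse = "")
}

# brute-force best-match distance of `pattern` against any substring of
# `text`, on both strands, via utils::adist (independent of the package's
# semi-global DP) — the generator's ground-truth oracle
bf_window_distance <- function(pattern, text) {
  one <- function(tx) {
    n <- nchar(tx)
    if (n == 0L) return(nchar(pattern))
    subs <- c("", unlist(lapply(seq_len(n), function(s) substring(tx, s, s:n))))
    min(adist(pattern, subs))
  }
  min(one(text), one(dna_revcomp(text)))
}

#' Plant an off-target-like site in a genome
#'
#' Writes, at a random location far from the guide's true target, a
#' sequence derived from the guide's 23-bp target by `intended_distance`
#' random single-character edits, and places a private SNP at its center
#' (the putative off-target edit a scan should flag). Because random edits
#' can cancel, and flanking sequence can contain closer spurious matches,
#' the construction is verified by brute force: the best-match Levenshtein
#' distance of the target within the variant's 61-bp scan window (both
#' strands, all substrings, via `utils::adist`) must equal the intended
#' distance, redrawing up to `max_tries` times otherwise. The planted
#' distance is therefore a ground truth, not an intention.
#'
#' @param genome Genome (`DNAStringSet`).
#' @param guide One-row guide tibble (see [read_guide_table()]).
#' @param intended_distance Integer in 0..10.
#' @param seed Optional integer seed.
#' @param min_dist_from_guide Minimum bp from the true target site
#'   (default 200).
#' @param max_tries Redraw budget (default 100).
#' @return A list with `genome` (mutated), `variant` (one-row tibble
#'   `chrom`, `pos`, `ref`, `alt`, `type`) and `realized_distance`
#'   (== `intended_distance`, brute-force verified).
#' @export
plant_offtarget_site <- function(genome, guide, intended_distance, seed = NULL,
                                 min_dist_from_guide = 200L, max_tries = 100L) {
  genome <- validate_genome(genome)
  if (intended_distance < 0 || intended_distance > 10) {
    stop("intended_distance must be in 0..10", call. = FALSE)
  }
  guide <- validate_guides(tibble::as_tibble(guide))
  lens <- chrom_lengths(genome)
  margin <- 40L
  with_seed_if(seed, {
    for (try in seq_len(max_tries)) {
      planted <- mutate_sequence(guide$target23, intended_distance)
      len <- nchar(planted)
      cn <- sample(names(lens), 1L, prob = lens)
      if (lens[[cn]] < len + 2L * margin) next
      p1 <- sample.int(lens[[cn]] - len - 2L * margin, 1L) + margin
      if (cn == guide$chrom && abs(p1 - guide$pos) < min_dist_from_guide) next
      cs <- chrom_seq(genome, cn)
      cs2 <- paste0(substr(cs, 1L, p1 - 1L), planted, substr(cs, p1 + len, nchar(cs)))
      snp_pos <- p1 + (len + 1L) %/% 2L - 1L
      ref <- substr(cs2, snp_pos, snp_pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      window <- substr(cs2, snp_pos - 30L, snp_pos + 30L)
      realized <- bf_window_distance(guide$target23, window)
      if (realized == intended_distance) {
        genome2 <- genome
        genome2[[cn]] <- Biostrings::DNAString(cs2)
        return(list(genome = genome2,
                    variant = tibble::tibble(chrom = cn, pos = as.integer(snp_pos),
                                             ref = ref, alt = alt, type = "SNP"),
                    realized_distance = as.integer(realized)))
      }
    }
    stop("could not realize intended distance ", intended_distance, " in ",
         max_tries, " tries (genome too small or distance too large)",
         call. = FALSE)
  })
}

#' Plant a synthetic edited-strain cohort
#'
#' Builds the ground truth and the call set of a haploid cohort with the
#' structure the classification stage assumes: shared background variants
#' (ALT in every strain, MAF = 1), one designed on-target edit per strain
#' (ALT only in that strain; a configurable number of strains remain
#' wild-type), strain-private spontaneous variants (ALT in exactly one
#' strain), and optional planted off-target-like variants at brute-force-
#' verified edit distance from the strain's guide ([plant_offtarget_site()]).
#' Background/private positions are sampled without replacement with a
#' minimum spacing from each other, from guide target sites and from
#' planted off-target sites. SNP alternate alleles are drawn uniformly from
#' the three non-reference bases; a configurable fraction of sites are
#' 1–3 bp indels.
#'
#' @param genome Genome (`DNAStringSet`).
#' @param guides Guide table with one guide per strain ([design_guides()]
#'   or [read_guide_table()]); duplicate loci are an error.
#' @param edits Designed-edit table (`strain`, `chrom`, `pos`, `ref`,
#'   `alt`), e.g. from [design_guides()].
#' @param n_background Number of background variants (default 121).
#' @param n_private_per_strain Integer vector (recycled / or one per strain)
#'   of private-variant counts; default distributes 107 across the strains.
#' @param n_wildtype Number of strains left unedited at their target
#'   (default 2); chosen at random under the seed.
#' @param indel_fraction Fraction of background/private sites planted as
#'   1–3 bp indels (default 0.15).
#' @param depth_mean Mean of the per-genotype Poisson read depth (default
#'   20; `NULL` for unknown depths).
#' @param annotations Named list of constant site-annotation values attached
#'   to every record (default clean values passing the hard filters), or
#'   `NULL` for absent annotations.
#' @param offtarget_plan Optional tibble (`strain`, `distance`): plants one
#'   off-target-like private variant per row.
#' @param min_spacing Minimum bp between planted variants (default 50).
#' @param seed Optional integer seed.
#' @return An object of class `cohort_truth`: a list with `genome`
#'   (mutated when off-targets are planted), `strains`, `guides`, `edits`
#'   (with `edited` flag), `background`, `private` (with `strain` and
#'   `planted` flag), `planted_offtargets` (with intended and realized
#'   distance), and `calls` (long cohort tibble ready for
#'   [classify_variants()] or [write_vcf_cohort()]).
#' @export
plant_cohort <- function(genome, guides, edits,
                         n_background = 121L, n_private_per_strain = NULL,
                         n_wildtype = 2L, indel_fraction = 0.15,
                         depth_mean = 20, annotations = list(QD = 25, FS = 2, MQ = 60, SOR = 1),
                         offtarget_plan = NULL, min_spacing = 50L, seed = NULL) {
  genome <- validate_genome(genome)
  guides <- validate_guides(tibble::as_tibble(guides))
  strains <- guides$strain
  if (anyDuplicated(strains)) stop("one guide per strain required", call. = FALSE)
  if (anyDuplicated(paste(guides$chrom, guides$pos))) {
    stop("two guides at the same locus", call. = FALSE)
  }
  stopifnot(n_wildtype >= 0, n_wildtype <= length(strains))
  n_strains <- length(strains)
  if (is.null(n_private_per_strain)) {
    base <- 107L %/% n_strains
    n_private_per_strain <- rep(base, n_strains) +
      c(rep(1L, 107L %% n_strains), rep(0L, n_strains - 107L %% n_strains))
  } else {
    n_private_per_strain <- rep_len(as.integer(n_private_per_strain), n_strains)
  }

  with_seed_if(seed, {
    # 1. plant off-target-like sites first (they mutate the genome)
    planted <- tibble::tibble(strain = character(), chrom = character(),
                              pos = integer(), ref = character(), alt = character(),
                              intended_distance = integer(),
                              realized_distance = integer())
    if (!is.null(offtarget_plan) && nrow(offtarget_plan) > 0L) {
      stopifnot(all(c("strain", "distance") %in% names(offtarget_plan)),
                all(offtarget_plan$strain %in% strains))
      for (i in seq_len(nrow(offtarget_plan))) {
        g <- guides[guides$strain == offtarget_plan$strain[i], ]
        res <- plant_offtarget_site(genome, g, offtarget_plan$distance[i])
        genome <- res$genome
        planted <- dplyr::bind_rows(planted, dplyr::mutate(
          res$variant[, c("chrom", "pos", "ref", "alt")],
          strain = offtarget_plan$strain[i],
          intended_distance = as.integer(offtarget_plan$distance[i]),
          realized_distance = res$realized_distance,
          .before = 1L))
      }
    }

    # 2. sample spontaneous variant positions with spacing constraints
    lens <- chrom_lengths(genome)
    n_needed <- n_background + sum(n_private_per_strain)
    accepted <- stats::setNames(vector("list", length(lens)), names(lens))
    conflict <- function(cn, p) {
      any(guides$chrom == cn & p >= guides$pos - min_spacing &
            p <= guides$pos + 22L + min_spacing) ||
        any(planted$chrom == cn & abs(planted$pos - p) < min_spacing + 12L) ||
        any(abs(accepted[[cn]] - p) < min_spacing)
    }
    got <- 0L; tries <- 0L
    chroms <- character(n_needed); positions <- integer(n_needed)
    while (got < n_needed) {
      tries <- tries + 1L
      if (tries > 100L * n_needed) {
        stop("could not place ", n_needed, " variants without collisions; ",
             "use a larger genome or smaller min_spacing", call. = FALSE)
      }
      cn <- sample(names(lens), 1L, prob = lens)
      p <- sample.int(lens[[cn]] - 4L, 1L) + 1L
      if (conflict(cn, p)) next
      got <- got + 1L
      chroms[got] <- cn; positions[got] <- p
      accepted[[cn]] <- c(accepted[[cn]], p)
    }

    # 3. draw alleles (SNPs, plus a fraction of 1-3 bp indels)
    draw_allele <- function(cn, p) {
      cs <- chrom_seq(genome, cn)
      refb <- substr(cs, p, p)
      if (stats::runif(1) < indel_fraction) {
        k <- sample.int(3L, 1L)
        if (stats::runif(1) < 0.5 && p + k <= nchar(cs)) {  # deletion
          list(ref = substr(cs, p, p + k), alt = refb)
        } else {                                            # insertion
          list(ref = refb,
               alt = paste0(refb, paste(sample(c("A", "C", "G", "T"), k,
                                               replace = TRUE), collapse = "")))
        }
      } else {
        list(ref = refb, alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1L))
      }
    }
    alleles <- purrr::map2(chroms, positions, draw_allele)
    sites <- tibble::tibble(
      chrom = chroms, pos = positions,
      ref = vapply(alleles, `[[`, character(1), "ref"),
      alt = vapply(alleles, `[[`, character(1), "alt"))

    bg <- sites[seq_len(n_background), ]
    pv <- if (n_background > 0L) sites[-seq_len(n_background), ] else sites
    pv$strain <- rep(strains, times = n_private_per_strain)

    # 4. designed edits: which strains actually got edited
    wildtype <- if (n_wildtype > 0L) sample(strains, n_wildtype) else character(0)
    edits <- dplyr::mutate(tibble::as_tibble(edits),
                           edited = !.data$strain %in% wildtype)

    # 5. assemble the long call table
    pv_all <- dplyr::bind_rows(
      dplyr::mutate(pv, planted = FALSE),
      dplyr::mutate(planted[, c("chrom", "pos", "ref", "alt", "strain")],
                    planted = TRUE))
    site_tbl <- dplyr::bind_rows(
      dplyr::mutate(bg, truth_class = "background", strain = NA_character_),
      dplyr::mutate(pv_all[, c("chrom", "pos", "ref", "alt", "strain")],
                    truth_class = "private"),
      dplyr::mutate(edits[, c("chrom", "pos", "ref", "alt", "strain")],
                    truth_class = "designed"))
    site_tbl$type <- variant_type(site_tbl$ref, site_tbl$alt)
    for (key in annotation_keys()) {
      site_tbl[[key]] <- if (!is.null(annotations) && !is.null(annotations[[key]])) {
        as.numeric(annotations[[key]])
      } else NA_real_
    }
    calls <- tidyr::crossing(site_tbl, sample = factor(strains, levels = strains))
    edited_of <- stats::setNames(edits$edited, edits$strain)
    calls$gt <- dplyr::case_when(
      calls$truth_class == "background" ~ "ALT",
      calls$truth_class == "private" &
        as.character(calls$sample) == calls$strain ~ "ALT",
      calls$truth_class == "designed" &
        as.character(calls$sample) == calls$strain ~
        ifelse(edited_of[calls$strain], "ALT", "REF"),
      TRUE ~ "REF")
    calls$dp <- if (is.null(depth_mean)) NA_integer_ else rpois(nrow(calls), depth_mean)
    calls <- dplyr::select(calls, "chrom", "pos", "ref", "alt", "type",
                           dplyr::all_of(annotation_keys()), "sample", "gt", "dp",
                           "truth_class", "strain_truth" = "strain")

    structure(list(genome = genome, strains = strains, guides = guides,
                   edits = edits, background = bg, private = pv_all,
                   planted_offtargets = planted, calls = calls),
              class = "cohort_truth")
  })
}

#' @export
#' @method print cohort_truth
print.cohort_truth <- function(x, ...) {
  cat("Synthetic cohort:", length(x$strains), "strains;",
      nrow(x$background), "background,", nrow(x$private), "private variants;",
      sum(x$edits$edited), "strains edited,",
      sum(!x$edits$edited), "wild-type;",
      nrow(x$planted_offtargets), "planted off-target site(s)\n")
  invisible(x)
}

#' Coverage simulation model
#'
#' Parameters for [simulate_coverage()]: per-base depth is drawn from a
#' negative binomial (Poisson in the `overdispersion = 0` limit) with mean
#' `mean_depth * exp(gc_slope * (gc_b - genome_gc)) * dropout_factor(b)`,
#' where `gc_b` is the per-base sliding-window GC covariate
#' ([gc_profile()]) and `genome_gc` the genome-wide GC fraction. Dropout
#' intervals emulate systematically under-covered regions (e.g. the
#' condensed fraction of an rDNA array).
#'
#' @param mean_depth Mean depth (>= 0).
#' @param gc_slope Log-linear GC effect on expected depth (default 0).
#' @param overdispersion Negative-binomial dispersion `phi` with
#'   `var = mu + phi * mu^2`; 0 gives Poisson (default 0).
#' @param dropout Optional tibble (`chrom`, `start`, `end`, `factor`)
#'   of 0-based half-open intervals with multiplicative depth factor in
#'   `[0, 1]`.
#' @param gc_window,gc_step GC covariate window/step (defaults 500/250).
#' @param seed Optional integer seed used by [simulate_coverage()].
#' @return A list of class `coverage_model`.
#' @export
coverage_model <- function(mean_depth, gc_slope = 0, overdispersion = 0,
                           dropout = NULL, gc_window = 500L, gc_step = 250L,
                           seed = NULL) {
  stopifnot(mean_depth >= 0, overdispersion >= 0)
  if (!is.null(dropout)) {
    stopifnot(all(c("chrom", "start", "end", "factor") %in% names(dropout)),
              all(dropout$factor >= 0 & dropout$factor <= 1),
              all(dropout$end > dropout$start))
  }
  structure(list(mean_depth = mean_depth, gc_slope = gc_slope,
                 overdispersion = overdispersion, dropout = dropout,
                 gc_window = gc_window, gc_step = gc_step, seed = seed),
            class = "coverage_model")
}

#' Simulate a per-base coverage track
#'
#' Draws a dense depth track from a [coverage_model()]: negative-binomial
#' (or Poisson) per-base depths with a log-linear GC effect and optional
#' multiplicative dropout intervals. Deterministic under the model's (or
#' the argument's) seed.
#'
#' @param genome Genome (`DNAStringSet`).
#' @param model A [coverage_model()].
#' @param seed Optional integer seed (overrides `model$seed`).
#' @return A dense depth tibble (`chrom`, `pos`, `depth`).
#' @export
simulate_coverage <- function(genome, model, seed = NULL) {
  genome <- validate_genome(genome)
  stopifnot(inherits(model, "coverage_model"))
  seed <- seed %||% model$seed
  gcprof <- gc_profile(genome, window = model$gc_window, step = model$gc_step)
  freq <- Biostrings::letterFrequency(genome, letters = c("A", "C", "G", "T"))
  tot <- colSums(freq)
  genome_gc <- (tot[["C"]] + tot[["G"]]) / sum(tot)
  lens <- chrom_lengths(genome)
  with_seed_if(seed, {
    purrr::map_dfr(names(lens), function(cn) {
      L <- lens[[cn]]
      gcb <- gcprof$gc[gcprof$chrom == cn]
      gcb[is.na(gcb)] <- genome_gc
      mu <- model$mean_depth * exp(model$gc_slope * (gcb - genome_gc))
      fac <- rep(1, L)
      if (!is.null(model$dropout)) {
        sub <- model$dropout[model$dropout$chrom == cn, ]
        for (i in seq_len(nrow(sub))) {
          if (sub$end[i] > L) stop("dropout interval out of bounds", call. = FALSE)
          idx <- (sub$start[i] + 1L):sub$end[i]
          fac[idx] <- fac[idx] * sub$factor[i]
        }
      }
      mu <- mu * fac
      depth <- if (model$overdispersion == 0) {
        rpois(L, mu)
      } else {
        rnbinom(L, mu = mu, size = 1 / model$overdispersion)
      }
      tibble::tibble(chrom = cn, pos = seq_len(L), depth = as.integer(depth))
    })
  })
}

#' Simulate a called SNP set from a truth set
#'
#' Test harness for [snp_calling_rates()]: each true SNP is retained
#' independently with probability `tpr`, and `fpr_count` novel miscalled
#' SNPs are added at positions absent from the truth set.
#'
#' @param truth_snps Site tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param tpr Retention probability in `[0, 1]`.
#' @param fpr_count Number of novel miscalls (>= 0).
#' @param genome Genome, used to draw novel positions and reference alleles.
#' @param seed Optional integer seed.
#' @return A called site tibble.
#' @export
simulate_calls <- function(truth_snps, tpr, fpr_count, genome, seed = NULL) {
  stopifnot(tpr >= 0, tpr <= 1, fpr_count >= 0)
  genome <- validate_genome(genome)
  lens <- chrom_lengths(genome)
  with_seed_if(seed, {
    kept <- truth_snps[stats::runif(nrow(truth_snps)) < tpr,
                       c("chrom", "pos", "ref", "alt")]
    truth_pos <- paste(truth_snps$chrom, truth_snps$pos)
    novel <- tibble::tibble(chrom = character(), pos = integer(),
                            ref = character(), alt = character())
    while (nrow(novel) < fpr_count) {
      cn <- sample(names(lens), 1L, prob = lens)
      p <- sample.int(lens[[cn]], 1L)
      if (paste(cn, p) %in% c(truth_pos, paste(novel$chrom, novel$pos))) next
      refb <- substr(chrom_seq(genome, cn), p, p)
      if (refb == "N") next
      novel <- dplyr::bind_rows(novel, tibble::tibble(
        chrom = cn, pos = p, ref = refb,
        alt = sample(setdiff(c("A", "C", "G", "T"), refb), 1L)))
    }
    dplyr::bind_rows(kept, novel)
  })
}

#' Simulate on/off-target sequence pairs at controlled edit distances
#'
#' Generates a synthetic stand-in for an empirical on/off-target pair set
#' (e.g. CIRCLE-seq captured sites): each off-target sequence is derived
#' from the on-target by random edits and verified (via `utils::adist`) to
#' sit at exactly the requested Levenshtein distance, redrawing otherwise.
#' Optionally attaches read counts that decay with distance, emulating
#' lower cleavage activity at higher distances.
#'
#' @param target23 On-target sequence (protospacer + PAM).
#' @param distances Integer vector of desired pair distances (one pair per
#'   element, e.g. `rep(0:6, each = 5)`).
#' @param read_counts If `TRUE` (default), attach a `read_count` column
#'   drawn with mean decaying in distance.
#' @param seed Optional integer seed.
#' @return A pair tibble (`on_seq`, `off_seq`, optionally `read_count`).
#' @export
simulate_target_pairs <- function(target23, distances, read_counts = TRUE,
                                  seed = NULL) {
  stopifnot(all(distances >= 0), nchar(target23) > 0)
  with_seed_if(seed, {
    off <- vapply(distances, function(d) {
      for (try in 1:100) {
        cand <- mutate_sequence(target23, d)
        if (adist(target23, cand) == d) return(cand)
      }
      stop("could not realize pair distance ", d, call. = FALSE)
    }, character(1))
    out <- tibble::tibble(on_seq = target23, off_seq = off)
    if (read_counts) {
      out$read_count <- rpois(nrow(out), lambda = 200 * exp(-0.8 * distances)) + 1L
    }
    out
  })
}

#' Per-sample mean coverage table from depth tracks
#'
#' Convenience for [apply_cohort_filters()]: computes each sample's
#' genome-wide mean depth from a named list of dense depth tracks.
#'
#' @param tracks Named list (by sample) of dense depth tibbles.
#' @return A tibble with columns `sample`, `mean_depth`.
#' @export
sample_coverage_table <- function(tracks) {
  purrr::imap_dfr(tracks, function(tr, nm) {
    tibble::tibble(sample = nm, mean_depth = mean(tr$depth))
  })
}
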