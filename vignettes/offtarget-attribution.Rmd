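---
title: "Coverage QC and off-target attribution for haploid strain cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage QC and off-target attribution for haploid strain cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-genome sequencing of engineered haploid strains (the motivating
system is CRISPR/Cas9-edited *Saccharomyces cerevisiae*) is used for two
linked purposes: to judge the quality of the sequencing library itself, and
to verify the genotype — did each strain receive its designed edit, and are
any of the other variants it carries plausibly caused by Cas9 cutting at an
off-target site? `editscan` implements the downstream analysis: it consumes
a reference genome (FASTA), per-base depth tracks (TSV), and multi-sample
haploid variant calls (VCF), and produces library QC metrics, a cohort
variant classification, and a per-variant off-target verdict. Read
trimming, alignment, duplicate marking and variant calling are upstream
tools' jobs; this package starts from their outputs.

Because the interesting guarantees are cohort-level (counts recovered
exactly, planted signals detected), the package ships a first-class
synthetic-data module that generates genomes, strain cohorts, coverage
tracks and call sets with the statistical structure the analysis assumes.
Every pipeline stage is therefore testable end to end with no external
data.

## Cohort model and classification

Genotypes are haploid: each sample is `REF`, `ALT` or `MISSING` at each
site. Two filters precede interpretation:

* **Hard filters** on site annotations, with the standard short-variant
  expression `QD < 2.0 || FS > 60.0 || MQ < 40.0 || SOR > 3.0 ||
  MQRankSum < -12.5 || ReadPosRankSum < -8.0`. Inequalities are strict
  exactly as written (`FS = 60.0` passes), and an absent annotation never
  triggers a clause — a deliberately conservative reading, since failing
  records on missing evidence would discard structurally simple sites
  (e.g. those without heterozygous reads to rank-sum over).
* **Cohort filters**: a genotype is masked to `MISSING` when its depth is
  below `0.1 x` that sample's average genome-wide coverage, and records
  missing in `>= 2` samples are then excluded. Masking precedes the
  missingness count; the two filters are not explicitly ordered by the
  analysis they reproduce, and masking-first is the stricter composition.
  Both steps log their counts so the composition is auditable. A genotype
  whose depth is unknown (no `DP`) is exempt from masking — the
  alternative, treating unknown as zero, would silently erase whole
  samples from annotation-poor VCFs.

The mutant allele frequency (MAF) of a site is the fraction of
non-reference alleles among non-missing genotypes. Classification is then:

| class | rule |
|---|---|
| `ON_TARGET` | site matches a declared designed edit (overrides all else) |
| `BACKGROUND` | MAF = 1 — the shared base-strain differences from the reference |
| `PRIVATE` | ALT in exactly one strain — candidate spontaneous or off-target mutation |
| `SHARED` | anything else |

The partition is exhaustive and mutually exclusive. Per strain, the
genotype at its own designed edit yields the verdict `edited`,
`wild-type at target`, or `no call` (record absent or genotype missing).
Note one corner the MAF rule implies: a record that is ALT in one strain
and missing in all others has MAF 1 and classifies as `BACKGROUND`; the
cohort missingness filter removes such records before classification in
any realistic configuration.

Multi-allelic records are split into one biallelic record per alternate
allele, duplicating site annotations to each child (a documented
limitation — the annotations were computed for the joint site). In the
child record for alternate *k*, allele *k* maps to `ALT`, allele 0 to
`REF`, and any *other* non-zero allele to `MISSING`: the sample carries
neither this alternate nor the reference, and counting it as `ALT` would
corrupt the private-variant definition. Heterozygous diploid genotypes in
a nominally haploid cohort map to `MISSING` with a warning rather than
erroring — tolerating stray records is safer than aborting an analysis.

## Off-target attribution by windowed Levenshtein scan

A Cas9 off-target edit must sit in sequence context similar to the guide's
target. For each private variant the package extracts a `(60 + X)` bp
window — `X = max(|ref|, |alt|)` is the variant length — spanning the X
reference bases at the variant position plus 30 bp of flank on each side,
and computes the best match of the strain's 23-bp target (20-nt
protospacer + 3-nt PAM) against the window on both strands:

* "Best match" is formalized as the minimum Levenshtein distance between
  the target and *any substring* of the window (semi-global / infix
  alignment: the DP's first row is zero, the answer is the minimum of the
  final row). Enumerating only fixed-length 23-mers would misprice matches
  containing insertions or deletions; the infix formulation prices all
  substring lengths correctly and is verified in the tests against a
  brute-force minimum over all substrings.
* `X = max(|ref|, |alt|)` guarantees the window covers a deletion's full
  reference footprint and scales for insertions. The analysis this
  reproduces specifies only "variant length"; the max is our documented
  convention, as is anchoring the flanks around the reference footprint
  (for even-length indels "centered" is otherwise ambiguous).
* The window is taken from the reference sequence, not an alt-edited
  haplotype: the guide was designed against the reference, and the edit
  itself (the variant) should not be allowed to lower its own distance.
* The PAM is included in the distance and no PAM-anchoring constraint is
  imposed — pure edit distance over the 23-mer.
* Ties between strands break toward `+`; among end positions, toward the
  leftmost. Windows truncated at chromosome ends are flagged and scanned
  as-is; `N` bases match nothing.

The observed distances are compared against a reference distribution of
edit distances between empirically cleaved on/off-target pairs (e.g.
CIRCLE-seq captured sites, read from a pair TSV). Empirical off-target
sites sit at distances 0–6 from their target; unrelated 61-bp windows
against a random 23-mer typically score 7 or more. The separation summary
(minimum observed, maximum reference, overlap count) makes the verdict
explicit: private variants inside the reference regime are candidate
off-target edits, the rest are exonerated as spontaneous mutations.

## Coverage QC

* **Bias profile** — per-base depth divided by the genome-wide average
  depth; mean exactly 1 by construction (asserted to `1e-9` in tests), with
  quantiles at 1/5/25/50/75/95/99%.
* **Breadth at depth k** — fraction of positions covered at least k-fold
  (default 8, a common variant-calling filter); non-increasing in k.
* **Depth thinning** — binomial thinning `Binomial(depth, f)` per base
  emulates read down-sampling at the depth level for metric-versus-depth
  curves. Thinning by `f1` then `f2` is distributionally identical to
  thinning by `f1 f2`.
* **GC covariate** — GC fraction in 500-bp windows stepped by 250 bp, with
  each base assigned the mean over windows covering it. Chromosome ends
  are our choice: a trailing partial window is kept iff at least one step
  long, and a chromosome shorter than the step becomes one whole-chromosome
  window. `N` bases are excluded from window denominators; bases whose
  covering windows are all-`N` (or that no kept window covers) get `NA`
  rather than a fabricated value and are dropped from correlations.
* **Coverage–covariate correlation** — Spearman by default (robust to the
  heavy right tail of depth distributions; Pearson available), on up to
  100,000 positions subsampled uniformly without replacement in a single
  seed-controlled draw.
* **Stratified coverage** — bias-ratio summaries within annotation
  categories (the motivating case: the four rDNA sub-regions — 35S genes,
  external/internal transcribed spacers, non-transcribed spacers — which
  drop in coverage in extraction-free libraries). Overlapping categories
  each count their bases; uncovered bases are summarised as `unannotated`.
* **Insert sizes** — median (smallest length where the cumulative count
  reaches half the total) and mode (smallest length with maximal count)
  of a fragment-length histogram.

## What the generator emulates — and what it does not

The synthetic cohort defaults mirror the motivating study's shape: 16
strains, 121 background variants (MAF = 1), 107 private variants spread
across strains, one designed edit per strain with 2 strains left
wild-type, ~20x coverage. Those numbers are the fixed study conditions,
not tuning knobs. Other generator choices, where the emulated analysis is
silent, are:

* variant positions uniform over the genome with ≥ 50 bp spacing from each
  other and from guide sites (real spontaneous mutation spectra are not
  uniform; nothing downstream depends on the spectrum);
* alternate alleles uniform over the three non-reference bases; 15% of
  planted sites are 1–3 bp indels (capped so scan windows stay small);
* coverage negative-binomial with mean
  `mean_depth * exp(gc_slope * (gc_b - genome_gc)) * dropout(b)`;
  dispersion 0 is the Poisson limit. The log-linear GC term and
  multiplicative dropout are a deliberately simple bias model — enough to
  give the QC stages a signed signal to detect, not a fitted model of
  transposase chemistry;
* annotation values are user-supplied constants (clean defaults); the
  generator does not imitate a caller's annotation distributions, so hard-
  filter behaviour is tested by construction, not by realism.

Planted off-target sites are the one place the generator is paranoid:
after writing a mutated copy of the target into the genome and centering a
private SNP on it, it *verifies by brute force* (all substrings, both
strands, `utils::adist`) that the window's true best-match distance equals
the intended distance, redrawing otherwise — random edits can cancel, and
flanks can spawn closer spurious matches. The planted distance is thus a
ground truth. Consequently, passing tests demonstrate correct recovery of
the implanted structure; they do not certify performance on real libraries
with alignment artefacts, repeat-mediated miscalls, or annotation-driven
filtering, none of which the generator imitates.

One empirical property of the null is worth knowing: against a random
23-mer target, a spontaneous private variant's 61-bp window scores 6 or
less in roughly 1–2% of cases (observed across seeds in the acceptance
runs), so in a cohort of ~100 private variants one or two spurious
low-distance hits are expected alongside any true off-target. The
separation summary reports the overlap count rather than a binary verdict
for exactly this reason.

## Numerical and design notes

* Point positions are 1-based (VCF / `samtools depth` convention);
  intervals (BED annotations, scan windows, match spans) are 0-based
  half-open. Each function documents which applies.
* Levenshtein and the infix DP are integer dynamic programs — no
  tolerances anywhere in the scan path; ties are broken deterministically
  (strand `+`, leftmost end, leftmost start).
* All generators are deterministic functions of (parameters, seed); seeded
  functions leave the caller's RNG state untouched.
* Problem sizes in tests and the acceptance script (2 x 150 kb genomes,
  100 kb QC tracks, 5,000-SNP rate experiments, 20 seeds x 7 distances for
  planting recovery) were chosen as the smallest sizes at which the
  binomial/Poisson concentration bounds used by the assertions are sharp;
  all scale linearly if increased.
* `breadth_at_depth`, `thin_coverage` and the classification counts are
  exact set/count operations; the only stochastic assertions are
  concentration checks at 3 standard deviations or explicit tolerance
  bands stated in the tests.

## Known limitations

* No mappability or duplicate-level modelling: depth tracks are taken at
  face value.
* Multi-allelic annotation duplication (above).
* The scan is reference-based; an off-target edit inside a structural
  rearrangement absent from the reference would be mispriced.
* No activity scoring (CFD/MIT-style) — pure edit distance, as in the
  analysis this package reproduces; `pair_distances()` + read counts give
  an activity-versus-distance summary but no per-site cleavage prediction.

## A worked run

```r
library(editscan)
library(dplyr)

genome <- simulate_genome(c(150000, 150000), gc_content = 0.38, seed = 1)
dg     <- design_guides(genome, paste0("strain", 1:16), seed = 2)
truth  <- plant_cohort(genome, dg$guides, dg$edits, seed = 3,
                       offtarget_plan = tibble::tibble(strain = "strain1",
                                                       distance = 2))

cl <- classify_variants(truth$calls, truth$edits)
glance(cl)                      # 121 background, 107 + 1 private, 14 edited

priv <- filter(tidy(cl), class == "PRIVATE")
scan <- scan_offtargets(priv, truth$guides, truth$genome)
pairs <- pair_distances(simulate_target_pairs(dg$guides$target23[1],
                                              rep(0:6, each = 5), seed = 4))
compare_distance_distributions(scan, pairs)   # the planted d=2 site stands out

track <- simulate_coverage(truth$genome, coverage_model(20), seed = 5)
glance(bias_profile(track))     # mean ratio 1
breadth_at_depth(track, 8)      # ~0.997 at 20x Poisson coverage
```
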