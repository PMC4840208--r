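---
title: "Methods: differential methylation and its integration with expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and its integration with expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symmeth)
```

# The model

A bacterial methylome, as seen by SMRT sequencing, is a set of
strand-specific base-modification calls: one record per called base with a
Phred-like quality (modQV), read coverage and an IPD (inter-pulse duration)
ratio. The package treats the methylome as a map from *motif sites* to
binary states. A motif site is the methylatable base of one occurrence of a
degenerate recognition motif on one strand — site identity is the
`(position, strand)` pair, because the two strands of a duplex are
methylated independently and, for bipartite Type I motifs such as
GAGA(N)₆RTG / CAY(N)₆TCTC, different offsets are methylated on each strand.

A site is **methylated** in a condition iff a QC-passing call exists at
exactly its position, strand and modification type; the absence of a call
is unmethylated. This matches how per-motif "% methylated" tables are
tabulated from kinetics pipelines, which emit records only for detected
modifications. A **methylation change** between two conditions is a state
flip (gain or loss); no effect-size or QV delta is used, because the
quantity of interest is the count of changed sites. A **candidate gene**
has at least one state change in its coding or upstream region and a
significant expression change.

## Coordinates and regions

All coordinates are 1-based with inclusive ends (GFF convention). Two
region measures are exposed: `region_length_bp` (end − start + 1) and
`region_span_bp` (end − start). The span is used when reproducing numbers
quoted from flanking coordinates — the *B. diazoefficiens* symbiosis
island, 1,000,419–1,681,419, is the "681-kb" span; its inclusive length is
681,001 bp. The island's genome fraction is reported as computed
(681,000 / 9,106,064 = 7.5% at one decimal), slightly above the commonly
quoted 7.4%; the package does not force the rounder figure.

The upstream (5′-UTR) region of a gene is the intergenic interval
immediately 5′ of its start on its own strand, capped at
`upstream_max_len` (default 500 bp — intergenic gaps in this genome are
short, and a cap prevents a long gap from attributing distal sites to a
gene) and truncated at the nearest annotated gene body on either strand. A
site in the shared gap upstream of two divergent genes counts toward both:
the grouping is by region membership with no exclusivity rule, so
regulatory sites between divergent promoters are credited to each.
Sites in no coding or upstream region enter genome-level tallies only.

## Scanning degenerate motifs

Sites are enumerated by matching the IUPAC pattern and its reverse
complement against the forward strand (Biostrings pattern matching with
IUPAC interpretation on the pattern only). For minus-strand matches the
methylated-base coordinate counts from the 3′ end of the match on the
forward coordinate system. Circular genomes are scanned across the origin
junction by virtually appending the first (motif length − 1) bases;
coordinates wrap. Every overlapping occurrence is reported. Ambiguity
bases in the reference (N etc.) never host or support a site: a motif
letter, including the spacer N, matches only A/C/G/T, so windows
containing ambiguity codes are discarded — this prevents phantom sites on
uncertain reference positions.

Both counting conventions are available: `per_strand` (distinct
(position, strand) pairs — the natural unit for strand-specific calls, and
the pipeline default) and `per_duplex` (distinct match loci, collapsing the
palindromic double count of motifs like GANTC).

## Quality control

Calls are filtered at coverage ≥ 25 and modQV ≥ 30, both boundaries
inclusive, the protocol's recommended minimums; both thresholds are
configurable. m4C calls (the weak CRAGGAT position-1 signal) are parsed
and summarised but excluded from differential analysis by default, since
cytosine-modification kinetics at this depth do not reliably clear the
quality threshold; a switch re-enables them. Sites whose coverage is below
threshold are folded into "unmethylated" rather than treated as
undecidable; their supporting records are simply absent after QC, and the
off-motif record count is logged separately.

## Differential expression

Expression input is a per-array log₂ intensity matrix with optional spot
replicates per gene. Processing: (1) optional recentring of each array's
median to the across-array mean median (a rank-preserving within-array
step approximating two-channel "reduce"-style normalization; it does not
affect between-array contrasts once quantile normalization is applied);
(2) quantile normalization across arrays (sorted-column row means, ties
averaged); (3) spot averaging per gene; (4) a two-sample t per gene with
pooled variance. By default each gene's variance is shrunk toward the
across-gene mean variance with prior weight d₀ = 4, adding d₀ degrees of
freedom — a light-weight analogue of microarray variance moderation. With
three arrays per condition the plain pooled t has only 4 degrees of
freedom and its heavy tails make even log₂FC ≈ 3–5 effects unstable at
adjusted p < 0.001, whereas the original analyses of such arrays used
moderated statistics; moderation is therefore the default and the plain t
(`shrink = FALSE`) the option. The full empirical-Bayes machinery
(estimating d₀ from the data) is deliberately not reproduced — the
package's contribution is the integration, and the significance convention
(BH-adjusted p < 0.001, log₂FC = free-living − bacteroid, positive =
higher in culture) is preserved exactly.

# The synthetic study

The generator produces a complete desk-scale study with known truth. Its
defaults are the study conditions, chosen once:

* **Genome**: 100 kb, circular, i.i.d. bases at GC 0.64 outside and 0.59
  inside a 15-kb island (positions 20,001–35,000) — the GC contrast that
  lets a windowed profile locate the island. Each of the four distinct
  forward motif patterns is planted 60 times at uniform positions
  (degenerate letters resolved randomly) so the rarer motifs reach
  workable site counts; GANTC occurs abundantly by composition alone.
  Cross-motif base coincidences (one adenine claimed by two motifs) are
  removed by flipping a constrained base of the commoner motif's
  occurrence, so each site's state is its own Bernoulli draw.
* **Genes**: 900 bp with 300-bp gaps on alternating strands — fixed sizes
  keep per-kb tallies analytically checkable.
* **Methylation rates**: the published per-motif percentages, free-living
  → bacteroid: GANTC 0.9977 → 0.9746; CRAGGAT m6A 0.9995 → 0.8749;
  GAGA(N)₆RTG 1.0 → 0.8260; CAY(N)₆TCTC 0.9995 → 0.8606; CCTTGAG 0 →
  0.8006 (the condition-exclusive motif); CRAGGAT m4C 0.1531 → 0.
* **Call noise**: methylated sites emit one record with coverage ~
  round(Normal(130 or 64, 20% CV)) truncated at 1 (the published mean
  coverages per condition) and modQV ~ Normal(136 or 65, sd 8). A
  configurable fraction of methylated sites receives a sub-threshold modQV
  to exercise the QC filter (default 0 — the QC exercise is a test
  scenario, not part of the baseline study).
* **Expression**: three arrays per condition, two spots per gene, array
  noise σ = 0.25, baselines ~ Normal(8, 1.5). The array measures a
  transcriptome-scale set: the annotated genes plus 1900 null background
  genes, mirroring the ~8k-gene complement of real arrays. This matters:
  quantile normalization is only valid when differential genes are a small
  share of the distribution, and with only the 82 annotated genes on the
  array it visibly distorts both null and planted fold changes. 20% of
  the annotated genes receive planted log₂ effects recycling the nine
  published candidate-gene magnitudes (3.06, 5.49, 4.60, 5.06, 4.55,
  1.23, 0.89, 5.73, 0.78), directed toward the bacteroid with probability
  0.88 (the direction split observed among island candidates).

## Ground truth and how recovery is judged

Truth records each site's planted state and QC fate, and each gene's
planted effect. Two candidate sets are derived:

* `planted_candidates` — genes with ≥ 1 QC-passing methylation state
  change and *any* planted effect. The pipeline's **false discovery rate**
  is measured against this set: a gene with a small planted effect that
  the test does detect is a true positive, not an error.
* `expected_candidates` — genes with a change and a *detectable* effect.
  Detectability is computed in closed form from the noncentral-t power of
  the moderated test at the BH-effective threshold (a first pass at the
  raw α estimates the number of comfortable detections R, a second pass
  at α·R/m classifies each effect; an effect is detectable if its power is
  ≥ 0.99). **Sensitivity** is measured against this set: the three small
  published magnitudes (1.23, 0.89, 0.78) are below the power threshold at
  n = 3 and σ = 0.25, and missing them is the correct behaviour of a
  calibrated test, not a pipeline defect. Their measured detection rates
  are simply reported.

This two-set design avoids judging the pipeline against effects that no
test of this size could find, while still penalising genuine false
positives.

## What the simulation does and does not emulate

It emulates the features the pipeline's correctness depends on: motif
degeneracy and bipartite spacers, strand-specific states, per-motif rate
contrasts including condition exclusivity, QC-relevant noise in coverage
and modQV, island/background GC contrast, compartment structure, spot
replication and realistic per-gene effect sizes. It does not emulate:
kinetic detection itself (IPD values are decorative noise), sequence
composition beyond i.i.d. bases (no codon structure, no repeats),
methyltransferase genetics, host-read contamination, dye effects or
spatial artefacts on arrays, or correlated expression noise. Passing
recovery therefore validates the pipeline's arithmetic and logic, not the
upstream kinetics calling, and says nothing about biological effect sizes
in real data.

# Numerical choices

* Reported percentages round half away from zero: per-motif tables at two
  decimals, headline fractions at one — matching the precision of the
  published tables (base R's round-half-even would turn 99.765 into
  99.76).
* Sliding windows are 1 kb with a 100-bp step by default ("overlapping
  1-kb windows" requires a step below 1 kb; 100 bp gives ten-fold
  overlap). Windows with no motif site yield a missing value, not 0% — a
  0/0 proportion is undefined and plotting it as zero would fabricate
  hypomethylation in motif-free regions. Circular genomes wrap; bedGraph
  export clips the wrapping window at the genome end.
* The DnaA-box rotation uses the first forward-strand occurrence at the
  lowest coordinate; reverse-strand occurrences are ignored (one box
  string, no orientation rule — a deterministic tie-break is needed).
  Rotation is length-preserving and leaves the circular k-mer multiset
  invariant.
* Genes straddling the island boundary are in-island iff their start
  coordinate is. Any single unambiguous rule serves; the start coordinate
  is the one every annotation format agrees on.
* Duplicate modification records at one (position, strand, type) are an
  error, not a silent overwrite: they indicate a malformed input file.
* Degenerate inputs: zero-site motifs report missing percentages;
  zero-length upstream regions are valid (overlapping/abutting genes);
  a condition with fewer than two arrays is an error.

# Problem sizes

The default simulation is 100 kb / ~82 genes / ~1,100 motif sites with a
~2,000-gene expression matrix — large enough for three-binomial-SE rate
recovery and candidate scoring, small enough that the full study
(generation, pipeline, scoring) runs in seconds. Oracle-equivalence
checks run the scanner against a brute-force window matcher on a hundred
random 10–50-kb sequences, and BH against an independent step-up on a
thousand random p-vectors.

# Known limitations

* Upstream regions do not wrap across the origin; a gene abutting
  position 1 gets a clipped upstream interval.
* The moderated test fixes d₀ rather than estimating it; with very few
  genes the across-gene mean variance is itself noisy.
* Off-motif calls are counted but not otherwise analysed (no de novo
  motif discovery).
* The per-duplex counting mode collapses by match locus, which for
  non-palindromic motifs equals per-strand counting unless both strands
  happen to host occurrences at the same locus.
* Quantile normalization assumes differential genes are a small fraction
  of the array; the generator respects this, but applying the pipeline to
  arrays dominated by differential signal would distort fold changes.
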