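---
title: "Calling recurrent copy-number alterations and genomic circuits in tumor cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling recurrent copy-number alterations and genomic circuits in tumor cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnacircuits)
library(dplyr)
```

## The analysis in one paragraph

Urothelial carcinoma, like most solid tumors, accumulates recurrent DNA
copy-number alterations — short high-level focal amplifications (FGA),
homozygous deletions (HD), broader minimal regions of deletion (MRD), and
whole-arm gains and losses — alongside point mutations in a handful of
driver genes. `cnacircuits` takes already-segmented array-CGH profiles on
a shared probe grid and (1) discretizes them into per-probe states with
sample-adaptive thresholds, (2) discovers recurrent regions with a
peak-and-extend algorithm, (3) quantifies each tumor's genomic complexity
(nFGA, fBAC, a CIN expression score), (4) clusters expression profiles
into molecular subtypes, (5) tests every pair of alterations for
co-occurrence or mutual exclusivity with exact hypergeometric tests under
Bonferroni control and assembles the significant associations into
networks — the "genomic circuits" — and (6) reads the groupings out
against disease-specific survival. A synthetic-cohort generator with
recorded ground truth makes every stage testable end to end.

## Copy-number state model

Input profiles are segmented log2 ratios aligned to an ordered probe map
(0-based, half-open coordinates throughout; BED files are read and
written natively). Five states are assigned per probe and sample:

* **GAIN / LOSS** where the 250-kb-smoothed value exceeds the sample's
  adaptive threshold (SAT) in absolute value. Smoothing takes the mean of
  non-missing segmented values whose probe midpoints lie within ±125 kb
  on the same chromosome.
* **AMP / HD** where the *unsmoothed* segmented value is at or beyond
  ±0.8 over a run of at least 4 consecutive probes ("longer than three").
  Shorter extreme runs stay GAIN/LOSS. Extreme states dominate where both
  rules fire.

The SAT is `multiplier × 1.4826 × median(|d − median(d)|)` with `d` the
within-chromosome first differences of the segmented values divided by
√2 — a per-sample robust noise scale — floored at 0.05 and with default
multiplier 2.5. On perfectly piecewise-constant segmented data most first
differences are exactly zero, the robust scale degenerates, and the floor
is the operative threshold; the estimator becomes genuinely adaptive only
when residual probe-level scatter survives segmentation. This SAT
definition is this package's own construction, and both multiplier and
floor are configurable in `cna_config()`.

FGAs less than 1 Mbp apart are merged into a single amplicon before
counting (`merge_amplicons()`), which defines nFGA. fBAC is the fraction
of a sample's probes in any non-neutral state; probes with missing input
count in the denominator as unaltered, a conservative choice that keeps
denominators fixed across samples.

Arm-level events need strictly more than 50% of an arm's probes beyond
the SAT in the same direction; if both directions pass, the larger
fraction wins and ties give no call.

## Recurrent-region discovery (peak and extend)

For each kind, per-probe support counts (number of altered samples) are
scanned per chromosome (FGA/HD) or per arm (MRD):

1. every maximal plateau of locally maximal support at or above the
   kind's minimum — FGA 3, HD 2, MRD 15 samples — becomes a **core**
   region. A flat local maximum yields one core spanning the plateau, and
   chromosome/arm ends count as lower neighbours;
2. each core is widened to the surrounding contiguous run with support at
   least `peak − 2` (`peak − 1` for HD), absorbing boundary uncertainty
   from technical noise;
3. MRDs whose extended interval covers more than half their arm are
   dropped — such events are represented by the arm-level call instead
   (deletions of whole arms otherwise produce meaningless "minimal"
   regions);
4. where an MRD's extended interval intersects an HD's, the HD-defined
   region is used;
5. regions whose extended interval is covered more than 50% by known
   germline CNV intervals are removed when a CNV mask is supplied. "High
   overlap" is not otherwise quantified anywhere, so the 50% cutoff is
   this package's documented choice.

MRD support counts deletions of any depth (states LOSS or HD). Extension
never crosses a chromosome boundary, and for MRDs not an arm boundary.
Ambiguities in the procedure were resolved as follows:
each of several nearby local maxima yields its own region (duplicated
extended intervals are deduplicated keeping distinct cores), and the
15-case MRD minimum applies to the peak maximum.

The binary alteration matrix has one column per recurrent region
(carriage = any of the sample's events intersecting the extended
interval), per recurrent arm event (carried by >10% of samples), and per
mutated gene. FGA/HD features rarer than 5% are flagged and excluded
from MDS and pairwise association, but kept for all other analyses.

## Association networks

Every feature pair is tested with the exact hypergeometric tail in both
directions — `P(X ≥ k)` for co-occurrence, `P(X ≤ k)` for exclusivity —
accumulated in log space so that very small p-values remain exact (the
test suite checks equality with exhaustive enumeration to 1e-12).
Both tails of all pairs are Bonferroni-adjusted jointly (`m = 2 ×`
number of pairs; `m` is recorded on the edge table, since the right
`m` is an analysis choice worth auditing). One-sided tails, rather than two-sided
Fisher tests, match the directional positive/negative association
language. Nodes incident to at least one significant edge form the
network; connected components are the circuits. Feature-level maps use
classical (Torgerson) multidimensional scaling on Jaccard distances
between carrier sets — points are aberrations, not samples.

## Expression pipeline

Raw bead-array-style intensities are normalized in this fixed order: per-probe scaling of each non-reference labeling batch to the
reference batch's geometric mean, background subtraction (default
constant 0, since the original background method is unspecified),
capping of negatives to zero, addition of an intensity constant of 30,
quantile normalization (via `limma::normalizeQuantiles`), log2, and a
variance filter keeping genes with SD > 0.25. The sorted values of every
sample are identical after quantile normalization; the SD filter then
removes per-gene rows, which is why the alignment invariant is stated at
the normalization stage.

Subtyping clusters samples on `1 − Pearson` distances with Ward linkage
(`ward.D2`); the tree is cut at `k = 5` (a configured default conventional for
this tumor type, not an internally selected number) and at `k = 2` for the two top-level molecular subtypes. Cluster
labels are ordered by decreasing mean FGFR3 expression when that gene is
present — a labeling convention.
Ward variants differ across implementations, so the variant is fixed and
documented here. Rank-based gene categorization (low/intermediate/high)
takes thresholds as config inputs rather than fixing cutoffs; ties go to the lower category.

Differential expression is a deliberately plain Welch-t + Bonferroni
screen. Moderated-statistic pipelines are the usual alternative and are
deliberately out of scope here; the gene-level output table (statistic,
p, adjusted p, direction) keeps the same shape so a moderated variant
could drop in. The TP53/MDM2 composite status calls a sample altered on
TP53 mutation, an FGA over the MDM2 locus, or a high MDM2 expression
category (default: top decile, configurable). IHC tumor-cell protein scores multiply staining
intensity (0–3) by the positive-nucleus fraction (10% grid), scaled
0–300, averaging a sample's two cores.

Survival uses Kaplan–Meier estimation with disease-specific survival as
endpoint (death of disease is the event; everything else censors,
including at event/censoring ties, where events are processed first) and
log-rank comparisons, both through the `survival` package. No follow-up
truncation is applied.

## What the synthetic cohort emulates

`generate_cohort()` produces a 146-sample cohort on a 3000-probe grid
(four chromosomes, p/q arms, 100-kb spacing, a 3-Mb centromeric probe
gap). Samples split into four groups (40/25/12/23%):

* **circuit A** — FGFR3-mutant-like: 9q-like whole-arm loss (75% of the
  group), CDKN2A-like HD nested *inside* the arm-loss carriers (40%),
  FGFR3 mutations (80%), high FGFR3/CCND1 expression;
* **circuit B** — 6p22-like focal amplification (75%), RB1-like HD
  (60%), 5p-like arm gain (65%), a PTEN-like MRD (60%), low FGFR3/PTEN
  and high CDKN2A expression;
* **keratinized-like** — a keratin expression program, CCND1-like
  amplifications, the worst survival hazard;
* **background** — noise and passengers only.

The nesting of the CDKN2A-like deletion inside circuit A's arm-loss
carriers emulates deletions that arise late in that route's progression.
Noise is one Gaussian draw per segment — the input is already segmented,
so probe-level noise would misrepresent the data model — with SD 0.08
for a minimal 4-probe segment, scaled by `sqrt(4/L)` for longer
segments, because a segment mean averages probe-level noise. Carrier
boundaries jitter by ±1 probe. Random passenger events (Poisson rate 0.3
per sample, 4–12 probes, |log2| 1.0–1.6) are drawn away from the planted
loci so the planted truth stays exactly recoverable; coincidentally
overlapping passengers still produce genuine low-support recurrent HDs,
which is intended. Expression is generated on the raw log-normal
intensity scale with a ×1.3 multiplicative second-batch factor so the
normalization pipeline has real work to do; planted programs are a
200-gene subtype signature (1.0 log2), small group-specific marker sets,
and a 40-gene CIN program whose shift scales with the number of planted
events a sample carries (0.3 log2 per event). Survival is exponential
with per-month hazards 0.002/0.010/0.020/0.004 for
A/B/keratinized/background and 30% independent censoring, calibrated so
the censoring probability is exact per group.

What it does **not** emulate: clonal heterogeneity, segmentation
artifacts, probe-specific biases, correlated passenger structure, and
realistic segment-length distributions (not described in the source
analyses; the defaults here are this package's own and configurable).
Passing the planted-truth tests therefore demonstrates algorithmic
correctness under this generative model, not performance on real arrays.

## Numerical choices and degenerate inputs

* SAT floor 0.05; ties at ±0.8 are inclusive.
* Strict inequalities at every fraction cutoff (arm 50%, arm
  recurrence 10%, CNV overlap 50%, MRD arm coverage 50%).
* All-missing smoothing windows stay missing; missing probes are
  NEUTRAL.
* A probe map's order is the single source of truth; every aligned
  vector is checked against it.
* Quantile normalization ties take limma's mean-of-quantiles treatment.
* Hypergeometric tails via log-sum-exp over `dhyper(log = TRUE)`.
* Classical MDS pads coordinates with zeros when the geometry is
  degenerate (e.g. duplicated features).
* Jaccard distance between two empty carrier sets is undefined; empty
  features are removed with a warning before embedding.

## Problem sizes used by the tests

The simulation-based checks run 20 replicate default cohorts (146
samples × 3000 probes, 2000 genes) shared across test blocks, 50
randomized small fixtures (≤100 probes, ≤10 samples) against the
exhaustive recurrence oracle, the complete hypergeometric configuration
space up to N = 12 against carrier enumeration, 200 null survival
replicates, and 100 null/100 shifted differential-expression replicates.
These sizes keep the whole suite in the low minutes on one CPU while
leaving the statistical assertions well-powered.

## A short worked example

```{r example}
co <- generate_cohort(simulation_config(), seed = 1)
res <- analyze_cohort(co)
glance(res)
res$recurrence$regions |>
  select(kind, chrom, core_from, core_to, max_support)
```

The planted 6p22-like amplification, the two planted homozygous
deletions, the PTEN-like MRD, and both planted arm events are recovered;
the network splits into the two planted positive-association circuits
(`assemble_network()` on the positive edges), connected to each other
only by negative (exclusivity) edges.

## Known limitations

* The SAT is a declared stand-in noise estimator and collapses to its floor on noiseless segmented input.
* Bonferroni `m` and test sidedness for the association networks are
  this package's documented choices.
* Real 32K-probe genome-wide cohorts yield far richer region catalogs
  than the reduced synthetic grid used here; the tests demonstrate
  recovery of planted truth, not genome-scale performance.
* No GISTIC-style significance model (G-scores/q-values) and no Cox
  regression — both out of scope.
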