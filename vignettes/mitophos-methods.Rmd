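---
title: "Phosphoproteome dynamics during mitotic exit: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphoproteome dynamics during mitotic exit: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitophos)
```

# The experimental design

`mitophos` analyses a two-condition (control / phosphatase mutant)
TMT10plex time course across mitotic exit. Ten samples per condition are
taken at 0, 5, 10, 15, 20, 25, 30, 40, 60 and 90 minutes after release
from a metaphase arrest. Labelling interleaves the series: one 10plex
carries both conditions at {0, 10, 20, 30, 60} min (plex group A), the
other at {5, 15, 25, 40, 90} min (group B). A consequence the whole
pipeline is built around is the missingness structure: a phosphopeptide
detected in only one of the two runs is missing *exactly its five
alternating time points* in both conditions, and those gaps are always
flanked by measured neighbours.

The central container, `PhosphoSet`, extends `SummarizedExperiment`:
assay `log2intensity` holds the values, assay `status` the per-cell
provenance (`measured`, `imputed`, `smoothed`), `rowData` the site
identity (protein, 1-based position, acceptor residue, localization
probability, peptide multiplicity, 13-mer sequence window), and
`metadata()$scale_tag` the processing stage, which can only advance
through `raw_log2 -> median_normalized -> t0_normalized`. The tag is what
enforces the fixed stage order filter → normalize → impute → smooth →
anchor.

# Preprocessing model

**Filtering.** Retained sites are singly phosphorylated
(`multiplicity == 1`), have localization probability strictly greater
than 0.75, and are quantified in all 10 channels of at least one plex
group. The boundary is read strictly — 0.75 exactly is rejected — because
the criterion is "greater than"; a site exactly at the cutoff carries no
more evidence than one just below it.

**Normalization.** Two median subtractions on the log2 scale: per channel
(centres away labelling and loading differences between reporter
channels) and then per site across all of a site's channels (removes
site-specific abundance so only the temporal shape remains). The row
median is taken over all 20 channels of both conditions: the two
conditions share each physical 10plex by design, so their channels are
normalized as one pool. A per-condition variant would decouple the
conditions and is deliberately not the default. After the second step
every site's median over its present values is 0 by construction, which
the tests assert to 1e-9.

**Imputation.** A missing interior time point becomes the arithmetic mean
of the values at the two adjacent *grid positions* (not minutes-weighted
interpolation — the grid is treated as ordinal, matching how the
alternating design guarantees measured flanks). A missing 0-minute value
copies the 5-minute value; a missing 90-minute value copies the 60-minute
value. Gaps whose neighbours are also missing ("irregular" gaps, which
the plex design never produces) are filled from the nearest measured time
point and reported with a warning; their status stays `imputed` so the
three-level status vocabulary remains a partition.

**Smoothing.** Each value is replaced by the mean of its two neighbours'
*pre-smoothing* values; endpoints copy their single neighbour. The update
is simultaneous, not sweep-in-place: a sequential update would make the
result depend on traversal order, which no sensible reading of the
procedure can intend. The wording that motivates this operator is
ambiguous about whether only imputed/technical-replicate values or all
values are replaced; both readings are implemented as modes. The default
(`"paper"`) replaces every value; `"centered3"` (mean of self and both
neighbours, which leaves index-linear profiles unchanged on the interior)
is a milder alternative for sensitivity checks, as is `smooth = FALSE`.

**Anchoring.** Per site and condition the *t* = 0 value is subtracted, so
profiles start at exactly 0 and categories below are statements about
change relative to metaphase.

# Dynamics classification

With θ = log2(1.5) ≈ 0.585:

* a **down-run** is ≥ `min_run` (default 2) consecutive points with
  xₜ ≤ −θ; an **up-run** uses ≥ +θ. Comparisons are inclusive so that
  "at least a 1.5-fold change" and "less than a 1.5-fold change"
  (stable) partition the space exactly;
* a qualifying run later followed by ≥ `return_run` (default 2)
  consecutive points **strictly inside** (−θ, +θ) makes the site
  *transient*; the band, not a return to baseline, defines the return,
  because one threshold governs the whole rule set. A single inside
  point at the end of the series does not rescue transience;
* no qualifying run in either direction → *stable*;
* **timing** is the grid time of the first point of the first qualifying
  run. A config switch (`timing = "first_crossing"` semantics via
  `min_run = 1`) gives the literal first-crossing alternative;
* if both directions qualify, the temporally earlier run decides and the
  other direction is kept in `secondary_flag` — profiles like this are
  rare and the choice is documented rather than silent.

Because the anchored value at *t* = 0 is 0, the earliest possible timing
is 5 min. The classifier is validated against an independently written
brute-force run scanner on *all* 3⁹ anchored profiles over {−1, 0, +1}
(19,683 cases, category and timing both), not on sampled cases.

Divergent-site selection compares the per-condition calls:
`stable_ctrl_dephos_mut` takes sites stable *or phosphorylated* in
control but dephosphorylated in the mutant; `dephos_ctrl_stable_mut` the
reverse contrast. The "most affected" ranking needs a score the source
analyses never specify; the package's explicit stand-in is the mean of
(mutant − control) anchored values over the last three time points
(40/60/90 min), sign-adjusted per mode, with ties broken by site key so
rankings are deterministic.

# Sequence-level analyses

Motif classes are exact positional matches on the 13-mer window (offset 0
= acceptor): Cdk full (S/T)Px(K/R); Cdk minimal +1 P; Plk (D/E/N) at −2;
Aurora (R/K) at −2; NDR HxRxxS (H at −5, R at −3) and RxxS. `'_'` padding
never matches. All flags are always reported; the single `primary_class`
uses precedence cdk_full > plk > aurora > ndr > cdk_minimal > other so
mutually exclusive motif groups can be formed — the overlap-resolution
order is not given by the source analyses, so the full flag set is kept
alongside. Tyrosine acceptors get `other` and are excluded from the S/T
preference test.

The LxxIxE docking pattern is implemented exactly as printed in the
literature — `[LCVMIF][ST]P[ILVM]xE` — although the character classes at
positions 2–3 contradict the "x" letters of the motif's name. Whether
that is a typesetting artefact cannot be decided from the text, so the
printed form is the default and a `canonical` variant (`L..I.E`) is one
argument away. Overlapping matches are all reported.

The iceLogo-style enrichment computes, per offset and residue, the
percentage difference (foreground − background frequency, in points) and
a two-sided exact binomial test of the foreground count against the
background frequency. p = 0.01 is applied per cell as the detection
threshold, with no multiple-testing correction — that mirrors how the
logo tool this emulates thresholds cells, and the p-value is a detection
gate rather than an inferential claim. Padding mass is excluded from the
denominators.

The acceptor-preference comparison summarizes each site by the median of
its 10 time-point values and applies a classic pooled-variance unpaired
t test between the serine and threonine site populations (Welch is
available via `var.equal = FALSE`). Group sizes below 2 skip the test
with a warning.

Template matching uses root-mean-square Euclidean distance over the
concatenated condition profiles the template defines; dividing by the
dimension count keeps 10- and 20-dimensional templates comparable. The
number of reported hits (default k = 29) is a free parameter — the
historical analysis this mirrors reported 29 selected sites without
stating its cutoff. Hierarchical clustering is complete-linkage on plain
Euclidean distances of the anchored profiles — unscaled, to preserve
differences in absolute phosphorylation change — cut into 12 subtrees by
default; labels are relabelled by each cluster's median time-of-extreme
so cluster 1 is always the earliest-responding one.

# The synthetic-data generator

`generateDataset()` emulates the study conditions so the pipeline can be
validated without any deposited data:

* category mix: 12% lasting decreases, 12% lasting increases (the middle
  of the 10–14% band such experiments report), 3% + 3% transient;
* lasting trajectories are logistic in time. The midpoint sits halfway
  between the intended crossing time and the preceding grid point, with
  slope 4/gap, so the crossing point sits at ~88% of the amplitude and
  the preceding point at ~12%: the intended first-crossing time is hit
  with a wide margin and survives smoothing. Amplitudes are drawn
  N(1.5, 0.2) on the log2 scale (mean effect 1.5, clamped to [1.3, 3]);
  crossing times are drawn from {10, …, 60} min;
* transient trajectories are Gaussian bumps (width 10 min, centre 20 or
  25 min) that exceed θ for ≥ 2 grid points and return well inside the
  band by 60 min;
* the mutant phenotype is an additive delay (default 15 min) plus a
  multiplicative attenuation: the mutant log2 effect is
  (1 − `mutant_attenuation`) × the control effect, so 0 reproduces the
  control and 1 abolishes the response (used to plant divergent sites);
* intensities are 2^(baseline + trajectory + ε), baseline ~ N(23, 2) log2
  units (lognormal reporter intensities), ε ~ N(0, 0.15) — the noise SD
  is a free parameter since no magnitude is stated anywhere; 0.15 gives
  per-point uncertainty comfortably below the 0.585 threshold, which is
  what a usable TMT experiment must achieve;
* 40% of sites lose one whole plex group (both conditions), so ~20% of
  all values end up imputed — matching the reported imputation load —
  and the withheld cells are always an exact alternating group;
* windows are coupled to categories (dephosphorylated sites enriched for
  Cdk-full and Plk windows, phosphorylated for Aurora/NDR, transient
  increases for NxT), with the planted motif recorded in the truth
  table.

Ground-truth categories and timings are obtained by applying the
classification rule to the noiseless anchored control trajectory, which
makes the zero-noise recovery contract exact by construction and keeps
noisy-recovery statements meaningful.

What the generator does **not** model: TMT ratio compression and
co-isolation interference, peptide-level effects (shared peptides,
multiply phosphorylated forms beyond the multiplicity filter), protein
abundance changes, correlated noise across channels, and biological
heterogeneity of trajectory shapes. Passing recovery tests therefore
demonstrates that the pipeline's rules behave as specified under the
design's missingness and noise geometry — not that real data meet these
assumptions.

# Numerical conventions and degenerate inputs

* Site keys are `(protein_id, 1-based position, residue)`; all joins and
  tie-breaks use them, so every ranking and cluster labelling is
  deterministic and independent of row order.
* Result TSVs are written with fixed 6-decimal formatting and key-sorted
  rows; re-running a pipeline config reproduces the bundle byte for
  byte.
* Channels with no measured values abort normalization by name; empty
  foregrounds, empty groups, `k ≤ 0`, fewer sites than subtrees, and
  unknown modes all raise immediate errors rather than propagating NAs.
* Imputed-value accounting survives smoothing (which reflags cells it
  changes) via `metadata()$imputed_fraction`, recorded at imputation
  time.

# Problem sizes

The test suite validates the classifier on all 19,683 bounded profiles,
runs recovery on ten 5,000-site seed-swept datasets (the scale of one
experimental dataset), Monte-Carlo checks on 10–20 seeds for the
enrichment, timing-order and template analyses, and 200-replicate
calibration of the acceptor test. These sizes are chosen to match the
scale of the experiments the package targets while keeping a full check
run in minutes on one core.

# Limitations

The dynamics categories are threshold rules, not statistical tests — no
per-site error control is attempted, by design. The iceLogo cell test is
a detection gate without multiplicity correction. The divergence score
and the template cutoff k are explicit conventions for quantities the
mirrored analyses left unspecified; both are parameters. The pipeline's
interface is R functions plus `runPipeline()`; there is no shell
executable, since the intended users drive analyses from R or Rmd.
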