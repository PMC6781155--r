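---
title: "Measuring synaptonemal complexes and crossover patterning from pachytene spreads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring synaptonemal complexes and crossover patterning from pachytene spreads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioscope)
```

## The measurement problem

At pachytene, each pair of homologous chromosomes is joined along its length
by the synaptonemal complex (SC). In immunofluorescence spreads of
spermatocytes, three channels carry the relevant structure: SYCP3 (red)
stains the SC axis, MLH1 (green) marks mature class I crossovers as discrete
foci, and CREST serum (blue) marks the centromere. Three quantities per
bivalent summarize crossover patterning: the SC length (the axis length of
the straightened SC, a proxy for axis packing), the number and arc-length
positions of MLH1 foci, and the centromere position, which anchors an
orientation so positions are comparable across bivalents.

Manually tracing bivalents is accurate but slow (tens of minutes per cell).
`meioscope` automates the measurement, accepts that a fraction of automated
observations will be wrong in diagnosable ways, and makes the subsequent
*curation* step rule-based and reproducible rather than interactive. The
downstream statistics — count summaries, focus-class tables, position
distributions, gamma interference strength, the intra-chromosomal
genetic-shuffling measure, and permutation tests of variance — operate on
the curated tables.

## Pipeline overview

1. **Preprocess** (`preprocess`): per channel, the smooth background is a
   plane fitted to block-minimum samples (16 px blocks); it is subtracted,
   negative values are clamped, and the channel is rescaled to a maximum of
   1. Block minima are used rather than quantiles because after one pass
   the background is exactly zero almost everywhere, making the operation
   idempotent; a plane captures constant offsets and linear illumination
   gradients, the dominant large-scale artifacts.
2. **Segment** (`detect_objects`): Otsu threshold on the red channel (plus
   a configurable offset), morphological closing with a radius-1 disc to
   bridge 1-px staining gaps, hole filling, connected-component labeling.
   Objects are enumerated row-major by bounding-box origin so indices are
   stable across runs.
3. **Classify** (`classify_bivalent`): range heuristics making "elongated
   single bivalent" explicit — area 150–6000 px², pruned-skeleton length
   30–400 px, no branch points after spur pruning, moment eccentricity
   ≥ 0.85, solidity ≥ 0.25, and a 3-px border margin. Checks run in a
   documented order and the first violation is reported; branching is
   checked before the shape criteria so merged bivalents are reported as
   merged. All bounds are configuration entries, since a real instrument
   or species will shift them.
4. **Midline and SC length** (`extract_midline`): Zhang–Suen thinning to a
   1-px skeleton; side branches shorter than 5 px are pruned; the midline
   is the longest geodesic path between skeleton endpoints (edge weights
   are Euclidean step lengths, with lexicographic tie-breaks); a smoothing
   spline is fitted with its stiffness relaxed until it stays within 1 px
   of the skeleton; the ends are extended along their tangents to the mask
   boundary and retracted by the portion of the estimated half-width not
   explained by the perpendicular chord there (a rounded cap retracts a
   full half-width, a flat bar end not at all); the curve is resampled at
   0.5 px arc steps. SC length is the integrated length of this smoothed,
   extended curve — the smoothed curve, not the raw skeleton, because the
   staircase of a discrete skeleton overestimates curved lengths.
   Conversion to micrometers divides by `px_per_um` (default 9.8152, an
   instrument-specific calibration that should be overridden per setup).
5. **Foci and centromere** (`detect_foci`, `locate_centromere`): the image
   is straightened perpendicular to the midline (bilinear interpolation)
   and each channel is profiled as the per-column maximum across the
   ribbon. Foci are local maxima above `background mean + k·SD`, required
   to sit within 75% of the ribbon half-width of the axis, merged when
   closer than 5 px along the arc, and refined to sub-pixel positions by a
   parabolic fit. The default k = 6 (not the 4 one might use for single
   pixels) accounts for the profile being a maximum over ~11 ribbon rows,
   which inflates the background tail. Background statistics come from
   pixels outside a dilated union of all detected objects. The centromere
   is the brightest in-ribbon blue maximum; absence is recorded as a
   missing value plus a `no_centromere` flag, and a tie between two
   distant maxima picks the one nearer an SC end and flags
   `ambiguous_centromere`.
6. **Orient and normalize** (`orient_and_normalize`): positions are
   reflected so the centromere-proximal end is at arc coordinate 0
   (normalized centromere position ≤ 0.5, matching the ~0.25 convention
   for the longest metacentric bivalent), then divided by SC length.
7. **Curate** (`diagnose`, `filter_chromosome1`): merged bivalents are
   flagged from branched skeletons or skeleton lengths beyond a per-cell
   robust bound (median + 3.5 MAD, needing ≥ 5 measured bivalents); extra
   foci from counts above 4 per bivalent or foci failing an off-axis
   re-check; plus `short_skeleton`, centromere flags, and an optional
   reject list standing in for interactive vetting. Chromosome 1 — the
   longest SC with a characteristically placed centromere — is isolated
   by an SC-length window (10–17 µm, bracketing typical per-mouse means),
   a normalized centromere window (0.15–0.40), and a longest-in-cell
   requirement; if the longest bivalent in a cell is itself flagged, the
   cell contributes no chromosome 1 observation rather than a doubtful one.

## Crossover statistics

* **Count summaries** (`summarize_counts`, `pool_group`): mean, sample SD
  (n−1 denominator, which is what makes the published SE/CV arithmetic
  reproduce), SE = SD/√n, CV = 100·SD/mean; group rows pool raw values
  when available and report both the n-weighted and the across-mice
  unweighted mean, since both appear in published tables.
* **Map length** (`map_length_cM`): 50 cM per MLH1 focus times the mean
  count per cell.
* **Interference** (`fit_interference`): inter-focus distances on
  two-focus bivalents, absolute (µm) or normalized by SC length, fitted to
  a gamma distribution by plain maximum likelihood (no small-sample bias
  correction); the shape ν is the interference strength (ν = 1 is no
  interference). The digamma equation is solved by safeguarded Newton to
  1e-8; an all-equal sample is rejected (shape unbounded). Distances below
  a floor (default 1 µm absolute) are excluded and reported, generalizing
  the removal of artifactually close focus pairs that are more plausibly
  one physical focus detected twice.
* **Intra-chromosomal r̄** (`rbar_intra`): with crossover positions
  partitioning the normalized SC into proportions `a_0..a_m`, the
  per-bivalent shuffling measure is ½(1 − Σa²), in [0, 0.5]. The closed
  form equals the probability that a uniformly drawn locus pair is
  separated by an odd number of crossovers on a random chromatid with no
  chromatid interference, and the test suite verifies it against exactly
  that Monte-Carlo simulation rather than trusting the algebra.
* **Position distributions** (`position_histogram`, `ks_compare`): 5%
  bins over the normalized axis for display, with the two-focus class
  split into centromere-proximal and distal series; the two-sample
  Kolmogorov–Smirnov test runs on the raw unbinned positions, because a
  KS test on binned data is ill-defined.
* **Permutation tests** (`permutation_test_variance`): status labels
  (e.g. wild vs laboratory) are permuted at the mouse level; the
  within-mouse level compares mean per-mouse variances, the among-mouse
  level compares variances of per-mouse means. Two-sided with add-one
  correction, p = (1 + #{|T*| ≥ |T|})/(n_perm + 1); two-sidedness is the
  conservative reading of "do the groups differ".
* **Focus-number model** (`logistic_focus_model`): maximum-likelihood
  logistic regression of P(two foci) on SC length, optionally with a
  sampling-month integer covariate; Wald tests per coefficient; a single
  class or perfect separation is an error/flag, never a silent estimate.
  Bivalents with 0 or 3 foci are excluded from position and logistic
  analyses (configurable), as they are too rare to model.

## The synthetic-spread generator

Real validation data with known truth do not exist, so `generate_cell`
renders spreads with exact ground truth: each bivalent is a natural cubic
spline through random heading-walk control points (chord-length
parameterization, resampled at 0.25 px for sub-pixel length integration),
drawn as a soft-edged tube in red; foci are isotropic Gaussians (σ = 2 px,
clipped at 3σ) on the midline in green; the centromere is a Gaussian in
blue. Defaults emulate the study conditions: 23 autosomal bivalents plus an
XY body with attenuated green/blue signal, arc lengths 95–185 px (≈10–19 µm
at the default calibration), focus-count probabilities (0.03, 0.70, 0.25,
0.02) for 0–3 foci giving ≈1.26 foci per bivalent, single foci placed
centrally (Beta(2.5, 2.5)) and double foci displaced toward the ends to
mimic interference, centromeres at 15–35% of the arc from a random end, a
10% corner-to-corner illumination gradient, additive Gaussian noise
(SD 2% of range), optional salt speckle and off-target green clutter, and
16-bit quantization. Placement is rejection-sampled so that at
`overlap_fraction = 0` no two tubes intersect; a nonzero fraction permits
controlled merges for curation experiments.

What the generator deliberately does **not** emulate: chromatin texture,
asynapsis morphology, partial synapsis forks, 3-D defocus, or
heavy-tailed camera noise. Passing tests on synthetic spreads therefore
demonstrate the geometry of the measurement (lengths, positions, counts,
orientation, curation logic) — not robustness to every staining pathology
of real slides, which is exactly why the curation flags and the manual
reject list remain part of the design.

## Numerical and design choices

* Image convention: H×W×3 arrays in [0, 1], (row, col) coordinates,
  channel order red/green/blue = SYCP3/MLH1/CREST.
* The skeleton graph uses m-connectivity (a diagonal edge is dropped when
  its two orthogonal common neighbours exist) so staircase triangles do
  not masquerade as branch points.
* Deterministic tie-breaks everywhere: object indices row-major by
  bounding box; endpoint pairs lexicographic; centromere ties
  nearer-to-end.
* Degenerate inputs are errors, not guesses: cyclic skeletons
  ("degenerate skeleton"), zero-length control polygons, zero-variance
  gamma samples, single-class logistic fits, quality scores outside 1–5.
* Reproducibility: every synthetic image is a pure function of its seed;
  pipeline CSVs carry the tool version and a configuration hash in a
  header comment; permutation seeds are recorded in the report.
* Problem sizes used in the validation suite: clean-accuracy checks use
  7×8 = 56 bivalents on 512² canvases; curation experiments 6 corrupted
  cells; interference recovery 10,000 simulated distances; r̄ checks 100
  random configurations against a 10⁶-pair Monte-Carlo oracle;
  permutation calibration 200 replicates of 9+9 mice at 499 permutations;
  the end-to-end reproducibility run uses 20 cells. These sizes give
  stable statistics while keeping a full validation run on one CPU in the
  minutes range.

## Known limitations

* Merged bivalents are flagged and excluded, never split; watershed
  separation is out of scope, matching the upstream design that leaves
  overlapping bivalents unmeasured.
* The heuristic thresholds were calibrated on synthetic spreads; real
  data from a different microscope will need the configuration revisited,
  starting with `px_per_um` and the segmentation area/length windows.
* SC length integrates a smoothed midline; sub-resolution axis twisting
  is invisible and lengths are slightly biased upward on strongly curved
  bivalents.
* Type I vs type II crossovers cannot be distinguished cytologically;
  MLH1 counts undercount total crossovers by the non-interfering
  fraction.

## A minimal session

```{r example, eval = FALSE}
cfg <- validate_config(list(simulate = list(n_cells = 5, base_seed = 7)))
run_simulate(cfg, "spreads")
run_measure("spreads", cfg, out_dir = "measured")
cur <- run_curate(file.path("measured", "measurements_all.csv"), cfg,
                  out_dir = "curated",
                  reference = file.path("spreads", "manifest.csv"))
cells <- cells_from_measurements(cur$curated)
run_stats(file.path("curated", "curated.csv"), cells, cfg,
          out_dir = "reports")
```
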