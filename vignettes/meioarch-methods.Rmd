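---
title: "Methods: geometric analysis of meiosis-I chromosome architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric analysis of meiosis-I chromosome architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meioarch)
```

## The analysis problem

A human oocyte in meiosis I carries 23 bivalents — pairs of homologous
chromosomes joined by recombination and arm cohesion — for 46 chromosomes
and up to 92 kinetochores. Classically the two sister kinetochores of each
chromosome are assumed to act as one unit, but in human oocytes they are
frequently resolved as two discrete spots, sometimes with prominent gaps.
This separation has geometric consequences that this package quantifies
from 3D spot coordinates:

* **Configuration.** Each sister pair is classified as
  indistinguishable, overlapping, distinct or separated, from the centre
  distance $d$ of its detected spots relative to the spot radii
  ($d < f(r_1{+}r_2)$ overlapping, $d \le r_1{+}r_2$ distinct, otherwise
  separated; a single merged detection is indistinguishable and reported
  at 0 µm). "Split" means distinct or separated.
* **Attachment mode.** From cold-stable k-fibre records: merotelic only
  when end-on fibres reach opposite poles; any lateral contact that is not
  end-on-merotelic is reported as lateral (folding lateral-merotelic into
  the lateral group); end-on to one pole is amphitelic.
* **Fibre topology.** Two separate parallel fibres to one pole-endpoint
  neighbourhood (type A), separate fibres from distant spindle locations
  (type B), or one trunk that branches (type C).
* **Rotation.** With $\beta$ the bivalent-axis/spindle-axis angle and
  $\pi_i$ the pair-axis angles, a bivalent is fully inverted when
  $\beta \ge$ `perpendicular_min` and both $\pi_i \le$ `parallel_max`
  (both sister pairs face opposite poles), half-inverted when exactly one
  pair does, in-axis when aligned with both pairs facing single poles, and
  ambiguous otherwise.
* **Twist.** The angle between the two pair axes; a rotation of one
  homolog by roughly 70° puts them perpendicular. Scorable only when both
  pairs are split.
* **Cohesion.** The surface gap between homolog chromatin envelopes,
  $g = |c_1-c_2| - (e_1+e_2)$: intact at $g \le 0$, weakly associated up
  to the largest gap compatible with shared tension (3.2 µm), and
  disintegrated beyond it — two univalents, verified by whole-oocyte
  accounting $2\,n_{\text{biv}} + n_{\text{uni}} = 46$.
* **Outcome.** A deterministic segregation table: in-axis bivalents
  disjoin normally; inverted bivalents lag (cohesion intact), release one
  univalent plus two chromatids (one pair compromised) or undergo reverse
  segregation into four chromatids (both compromised). Every prediction
  conserves four chromatids.

## Angular and resolution parameters

The source observations are qualitative ("perpendicular", "about 70
degrees"), so reproducible calls need explicit cutoffs, all configurable:

| parameter | default | meaning |
|---|---|---|
| `parallel_max` | 30° | max angle treated as parallel |
| `perpendicular_min` | 60° | min angle treated as perpendicular |
| `twist_min` | 50° | min inter-pair angle for a twisted call |
| `merge_distance_lateral` | 0.30 µm | lateral resolution limit |
| `merge_distance_axial` | 0.65 µm | axial (z) resolution limit |
| `overlap_factor` | 0.6 | overlapping/distinct boundary as a fraction of summed radii |
| `radius_um` | 0.40 µm | nominal kinetochore spot radius |
| `at_pole_fraction` | 0.1 | pole-exclusion zone as a fraction of spindle length |

The 30/60 band leaves an explicit ambiguity zone rather than forcing
borderline bivalents into a class; `twist_min = 50°` sits between the
residual inter-pair angle of undistorted bivalents (≤ ~15°) and the ~70°
rotation of twisted ones. Merge distances mirror the acquisition sampling
(300 nm lateral, 650 nm axial); two spots merge when their displacement
lies inside the resolution ellipsoid
$\sum_i (\Delta_i/m_i)^2 < 1$, which captures the anisotropic z response.

## What the synthetic cohorts emulate

`cohort_profile()` states a complete world for one donor age group;
`baseline_profile("young" | "mid" | "over35")` packages the published
rates: a 60/75/87% split fraction for donors <30 / 30–35 / >35 years,
merotelic rates of 12/17/28% conditional on the unified/distinct/separated
strata, ~90% two-fibre attachments, 20% twist among split-configuration
bivalents, weak arm cohesion and disintegration rates of 10% and 1.2%
(packaged pooled rates), 95% univalent biorientation, separations up to
1.7 µm and cohesion gaps up to 3.2 µm. A generated oocyte is a 12-µm
bipolar spindle parallel to the imaging plane (as in the source data,
where only such spindles were analysed), 23 bivalent slots dart-thrown
onto the metaphase plate with a 1.5-µm spacing floor, Gaussian
localization noise (12 nm lateral / 25 nm axial), and sub-resolution
merging applied before the tables are emitted. Every sampled label is
entailed by the emitted geometry, so a noise-free pipeline recovers the
truth table exactly — that equivalence, plus rate recovery within three
binomial standard errors under default noise, is what a green test
establishes.

Values the text does not print were chosen once and are recorded in the
profiles: the four-way partition of the young mixture (0.25/0.15/0.30/0.30
under the 60% split constraint), the inversion split (1.5% + 1.5% under
the ">2% of all bivalents" constraint), and the over-35 weak/disintegrated
partition (7% + 4%, under the constraints that they sum to 11% of
bivalents and that more than 40% of over-35 oocytes contain univalents).
Separated distances follow a truncated gamma above the touching threshold
(only the 1.7-µm maximum is stated); the packaged young profile keeps the
pooled 10%/1.2% cohesion rates even though the age-stratified under-30
figure is 5%, because the recovery targets are phrased against the pooled
rates.

Deliberate simplifications, hence what a green test does **not**
establish: chromatin has no texture (an envelope centroid plus extent);
k-fibres are straight segments; there is no photophysics, no spindle
microtubule background, and no attachment-error correction dynamics. The
generator also makes three geometric feasibility commitments that real
data would not: twisted bivalents place the ~70°-rotated pair in the
separated category (an out-of-plane pair below ~0.65 µm would be merged by
the axial resolution and the bivalent would simply become unscorable);
half-inverted bivalents carry distinct-category pairs and fully-inverted
ones cap separated distances at 1.4 µm, keeping every sister separation
below the cross-homolog spot distance so that closest-pair assignment is
provably unambiguous. Profile validation rejects parameter combinations
that violate these constraints (error class `meioarch_infeasible_error`).

## Numerical and procedural choices

* **Pairing tie-break.** When two candidate closest pairs tie within
  1 nm, the lexicographically smallest spot-id tuple wins. The
  closest-pair-then-remainder rule itself can differ from minimum-total-
  distance matching on pathological quadruples; the rule is implemented as
  stated and checked against an exhaustive enumeration oracle.
* **Exact test.** `fisher_exact_2x2()` sums hypergeometric probabilities
  of tables no more probable than the observed one, with a relative tie
  slack of 1e-12; it is verified against an independent `lchoose`
  enumeration for every 2×2 table with total ≤ 40. The two-sided
  definition matches common practice; one-sided alternatives are not
  provided because the reported comparisons are two-sided.
* **t test.** Pooled-variance Student's t (the reported method), with
  Welch's correction behind a flag. Zero pooled variance degenerates to
  p = 1 (equal means) or a flagged p = 0.
* **Age bins.** `[0,30)`, `[30,35]`, `(35,∞)`; the boundary at exactly
  35 years goes to the middle bin. Continuous-age cohorts interpolate the
  mixture and cohesion/inversion probabilities linearly between anchors at
  27, 32.5 and 38 years, which reproduces the linear increase of mean
  sister distance with age.
* **Reporting rules.** Bivalents at the poles (within 10% of the spindle
  length) are excluded from configuration statistics — they are not under
  tension. Attachment-mode and twist frequencies exclude inverted
  bivalents and univalents: their bioriented pairs are end-on to both
  poles *by definition*, and counting them as merotelic would conflate
  two different phenomena. Distances of indistinguishable and overlapping
  pairs are reported as 0 µm. No multiple-testing correction is applied
  (per-comparison reporting); a Benjamini–Hochberg adjustment can be
  applied downstream if desired.
* **Time-lapse convention.** All times are NEBD-relative; anaphase onset
  is defined 10 min before the first observed chromosome separation and is
  generated as congression time (mean 16.3 h, s.d. 2.3 h) plus a gamma
  delay. Severity derives from the misaligned count (0 none, 1–3 mild,
  >3 severe).
* **Volumes.** Rendered volumes place voxel centres at half-integer
  world offsets from the origin; detection smooths with a separable
  Gaussian, takes 26-connected maxima, and refines centres by an
  intensity-weighted centroid over a ±2-voxel window of the raw volume,
  which keeps noise-free localization error below 0.05 µm at the default
  0.1/0.1/0.25-µm voxel size.

## Known limitations

The 13% of fully-inverted calls that the source rescued through
kinetochore stretching and chromatin morphology are represented only by
the `ambiguous` label — no morphology heuristic is implemented. The
operational geometry of "lateral" contact is not defined in the source;
it is a generator-assigned contact flag that the classifier round-trips.
Oocyte-level inversion incidence (12.5% → 40% across age) is not
separately calibrated; the profiles target the bivalent-level rates that
the acceptance targets measure. Whether irresolvable pairs (2% in the
source) arise from crowding or signal quality is unknown; the generator
exposes no mechanism for them and the packaged profiles leave them at
zero.

## A minimal run

```{r, eval = FALSE}
cfg <- pipeline_config(profile = "young", seed = 1, outdir = "results")
res <- run_pipeline(cfg)
writeLines(res$report)
```
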