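# meioarch

Geometric analysis of meiosis-I chromosome architecture in human oocytes.

## The problem

Aneuploid eggs are the leading cause of pregnancy loss, and egg aneuploidy
rises steeply with maternal age. One proposed mechanism is architectural:
in human oocytes the two sister kinetochores of a chromosome — classically
assumed to act as a single unit in meiosis I — are frequently resolved as
two discrete spots up to 1.7 µm apart. Separated sisters can each capture
their own microtubule bundle, which permits merotelic attachments (end-on
fibres to *opposite* poles), lets whole bivalents rotate by 90° or twist
by ~70° on the spindle, and, as arm cohesion weakens, lets bivalents
dissociate precociously into univalents. All of these errors become more
frequent with donor age.

`meioarch` is for scientists analysing 3D kinetochore coordinates,
cold-stable k-fibre records and chromatin envelopes from such spindles.
It implements the full measurement pipeline — sister-pair assignment,
configuration classification under an anisotropic resolution model,
attachment-mode and fibre-topology calls, bivalent rotation/twist scoring,
cohesion and univalent detection with 46-chromosome accounting,
deterministic segregation-outcome prediction, and age-stratified cohort
statistics — plus a seeded synthetic cohort generator with a per-unit
ground-truth table, used to validate every classifier by simulation
recovery.

## The core quantities

For each sister pair with detected spots at centre distance $d$ and radii
$r_1, r_2$:

* configuration: merged detection → *indistinguishable* (0 µm);
  $d < f(r_1{+}r_2)$ → *overlapping*; $d \le r_1{+}r_2$ → *distinct*;
  otherwise *separated* ("split" = distinct ∪ separated);
* attachment: *merotelic* iff end-on fibres reach both poles; any lateral
  contact otherwise → *lateral*; end-on to one pole → *amphitelic*.

For each bivalent, with $\beta$ = angle(bivalent axis, spindle axis) and
$\pi_{1,2}$ = angle(pair axis, spindle axis):

* *fully inverted*: $\beta \ge 60°$, both $\pi_i \le 30°$;
  *half-inverted*: exactly one $\pi_i \le 30°$ with the other $\ge 60°$;
  *in-axis*: $\beta \le 30°$, both $\pi_i \ge 60°$;
* *twisted*: inter-pair-axis angle $\ge 50°$ (scorable only when both
  pairs are split);
* cohesion from the chromatin surface gap
  $g = \lVert c_1 - c_2\rVert - (e_1 + e_2)$: intact ($g \le 0$), weakly
  associated ($0 < g \le 3.2$ µm), disintegrated (beyond), with
  whole-oocyte accounting $2\,n_{\mathrm{bivalents}} +
  n_{\mathrm{univalents}} = 46$.

Statistics use Fisher's exact test (full hypergeometric enumeration),
pooled-variance two-tailed Student's t, and least-squares age trends.

## Worked example

```r
library(meioarch)
cfg <- pipeline_config(profile = "young", seed = 1)
res <- run_pipeline(cfg)      # simulate -> detect -> pair -> classify -> stats
writeLines(res$report)
```

```
meioarch classification report
------------------------------
split pairs                    618 /  1050  (58.9%)
merotelic (overall)            178 /  1006  (17.7%)
merotelic | unified             50 /   432  (11.6%)
merotelic | distinct            44 /   284  (15.5%)
merotelic | separated           84 /   290  (29.0%)
two k-fibres | split           513 /   570  (90.0%)
inverted bivalents              17 /   520  (3.3%)
twisted | scorable              46 /   164  (28.0%)
weak arm cohesion               50 /   529  (9.5%)
disintegrated bivalents          5 /   529  (0.9%)
oocytes with univalents          4 /    23  (17.4%)
univalents bioriented            8 /    10  (80.0%)
```

This is a 23-oocyte young-donor (≤30 y) cohort: 1,050 sister pairs after
pole exclusion, of which 58.9% are split (the configured rate is 60%);
merotelic attachments rise monotonically from the unified (11.6%) to the
separated (29.0%) stratum (configured 12/17/28%); 90.0% of split pairs
carry two discrete k-fibres; and a handful of bivalents show weakened or
lost arm cohesion — every percentage is printed alongside the integer
counts it derives from. The `twisted` and `univalent` rows sit on small
denominators at this cohort size and converge to their configured rates
(20% and 95%) in the larger acceptance cohorts.

Single units can be queried directly, e.g. the expected anaphase fate of
a fully inverted bivalent with centromeric cohesion lost in both sister
pairs:

```r
predict_segregation_outcome("fully_inverted", c("compromised", "compromised"))
# event: reverse_segregation; products: 4 chromatids
```

A command-line wrapper is installed at `inst/cli/meioarch`
(subcommands `simulate`, `classify`, `stats`, `run`, `timelapse`; exit
codes 0/2/3 for success / validation error / infeasible profile).

## Layout

* `R/` — geometry, resolution model, classifiers, generator, statistics,
  I/O and CLI
* `tests/testthat/` — unit, property and oracle suites;
  `test-acceptance.R` implements the acceptance criteria
* `vignettes/meioarch-methods.Rmd` — the methods notes: model,
  parameters, generator assumptions, numerical choices, limitations
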