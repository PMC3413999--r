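---
title: "Modelling leukocyte dispersal from a wound as drift-diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling leukocyte dispersal from a wound as drift-diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundwalk)
```

## The question

After acute inflammation, neutrophils leave the wound region. Two
hypotheses compete for what "leaving" means mechanistically:

* **fugetaxis** — cells are actively pushed away from the wound by a
  repellent signal, which shows up as a non-zero *drift* in their
  distance from the wound; or
* **stochastic redistribution** — cells simply stop responding to the
  attractant gradient and spread by their intrinsic random motility,
  i.e. pure *diffusion*.

woundwalk implements the population-level workflow for deciding between
these: reduce each cell's centroid track to a scalar distance-from-wound
coordinate $x(t)$, fit random-walk models to the time courses of the
population moments, and then — crucially — check the *adequacy* of the
preferred model by forward simulation, not only its relative fit.

## The model

Between observations, each cell's distance from the wound is modelled as
a 1-D drift-diffusion process

$$\mathrm{d}x = v\,\mathrm{d}t + \sqrt{2D}\,\mathrm{d}W_t,$$

with a reflecting boundary at the wound edge $x = 0$ (cells are never
observed at negative distances and are not lost through the wound). The
drift coefficient $v$ (µm/min) is signed: $v < 0$ is motion toward the
wound (chemotaxis), $v > 0$ away (fugetaxis); $D$ (µm²/min) is half the
growth rate of the displacement variance. Directional persistence of
real neutrophils decays faster than the interval between observations,
which is what justifies a memoryless (simple) random walk at this
sampling rate.

For a *free* (boundary-ignoring) process with initial mean distance
$m_0$ and initial second moment $s_0$, the population moments are

$$m(t) = m_0 + v t, \qquad
  s(t) = s_0 + (2D + 2 v m_0)\,t + v^2 t^2 .$$

These two curves are what the estimators fit:

| function | regression | coefficients used |
|---|---|---|
| `fit_drift_linear()` | $m(t)$ on $\{1, t\}$ | $v = $ slope |
| `fit_pure_diffusion()` | $s(t)$ on $\{1, t\}$ | $D = \beta_1 / 2$ |
| `fit_drift_diffusion()` | $s(t)$ on $\{1, t, t^2\}$ | $|v| = \sqrt{\max(\beta_2, 0)}$, $D = \beta_1/2$ |

All three are unweighted ordinary least squares on the per-timepoint
moments (not per-track regressions — per-track inference is out of
scope by design). Because $\beta_2 = v^2$ destroys the sign of the
drift, `fit_drift_diffusion()` takes the sign from the slope of the
mean-distance curve. $D$ is deliberately *not* constrained to be
non-negative: an unconstrained fit can return negative diffusion
estimates on real data, and that instability is itself informative (see
"Why the quadratic fit cannot be trusted" below).

`f_test()` compares the nested MSD fits,

$$F = \frac{\mathrm{RSS}_{\text{pure}} - \mathrm{RSS}_{\text{dd}}}
           {\mathrm{RSS}_{\text{dd}} / (n - 3)},$$

with 1 and $n - 3$ degrees of freedom and a conventional decision
threshold of 5 in favour of drift-diffusion.

## Tunable parameters

* **`min_cells`** (default 1) in `population_summary()`: timepoints with
  fewer recorded cells are dropped rather than averaged over nothing;
  sparse late frames in weak subjects produce exactly the "missing
  sections" seen in real summaries.
* **F threshold** (default 5): the screening cut-off on the nested F
  statistic.
* **Bins** (default width 100 µm, centres 50–950 µm): half-open
  $[c - 50, c + 50)$; cells at ≥ 1000 µm are counted separately as
  overflow, never silently dropped. The half-open convention and the
  overflow bookkeeping are this package's choices; edge conventions are
  rarely stated in published histograms.
* **`n_reps`** (default 1000): Monte-Carlo replicates per model in the
  adequacy check.

## The synthetic-data generator

`simulate_cells()` advances each cell by the exact Gaussian propagator
of the SDE, one step per observation interval split into `substeps`
(default 10) sub-intervals with reflection $x \leftarrow |x|$ after
each. Substeps only matter near the boundary: the Gaussian increment is
exact at any step size in the interior, and for a symmetric increment
the reflected chain has exactly the distribution of $|x_0 + W_t|$, so
second moments under $v = 0$ grow as $2Dt$ *exactly* at any substep
count.

The generator's stated world:

* observation grid every **10 min over 960 min** (16 h of time-lapse; the
  10-min interval is a configurable default, chosen as typical for
  overnight widefield time-lapse, not a published value);
* initial condition **uniform on [0, 80] µm** — the width of the
  photolabelling zone at the wound edge — or a point/band release such
  as `init_uniform(800, lo = 400)` for cohorts starting away from the
  wound;
* **reflecting boundary at 0**;
* **dropout** (default 0): each (cell, frame) record is independently
  unrecorded with probability `dropout_rate`, emulating segmentation
  misses; sparse "subject 6"-style data uses a positive rate;
* for the adequacy check, a pooled cohort of **150 cells** — a few tens
  of labelled cells per larva across six larvae — chosen once as a
  realistic pooled count and not revisited.

What it does **not** emulate: continued recruitment of new cells into
the field, 2-D tissue geometry and obstacles, cell-cell interactions,
cell death, or tracking errors other than missing records. A green test
on synthetic data therefore establishes correctness of the estimators
and of the simulation machinery *under the stated model*, not that the
model describes any particular biological dataset.

Seeds: every simulation takes one integer seed; `simulate_ensemble()`
derives replicate seeds as `set.seed(master); sample.int(2^31 - 2,
n_reps)`, so ensembles are bit-reproducible and replicate 1 equals a
single run with the first derived seed.

## Why the quadratic MSD fit cannot be trusted for $D$ (or blindly for $v$)

The moment expansion above shows a structural identifiability problem:
the linear MSD coefficient is $\beta_1 = 2D + 2 v m_0$, so the estimator
$D = \beta_1/2$ is biased by $+v m_0$ whenever the cohort's initial mean
distance $m_0$ and the drift are both non-zero. A cohort released within
80 µm of the wound has $m_0 \approx 40$ µm; with $v = 0.26$ µm/min the
bias is $\approx +10$ µm²/min — larger than the drift-diffusion $D$
estimate itself. The reflecting boundary adds a further, smaller,
positive distortion. This is why, in our own acceptance suite, the
drift-diffusion estimator recovers $v$ within Monte-Carlo error but
*fails* to recover $D$ at the same tolerance: the failure is a property
of the quadratic-MSD method, reproduced faithfully, and it mirrors the
negative and unstable diffusion estimates such fits produce on real
data. It is one half of the scientific point; the other half is next.

## Why the F-test misleads, and the Monte-Carlo check

The F reference distribution assumes independent, homoscedastic errors
across timepoints. Population moments of *persistent* tracks violate
this badly: the error of $\hat s(t)$ is a cumulative (martingale)
process, because the same cells contribute to every timepoint. Spurious
curvature then inflates $F$ far beyond its nominal tail — in our null
simulations ($v = 0$) the empirical $P(F > 5)$ is near 0.5 against a
nominal 0.04. The package keeps the F-test exactly as specified (and
verifies in a unit test that it *is* calibrated in the iid-error regime
where its reference distribution is exact), but treats `prefer_drift`
as a screening indicator.

The decisive check is `compare_models()`: simulate both fitted models
many times, average the binned spatial distributions over the ensemble,
and follow the **population mode** — the bin with the most cells. A
drifting population's mode marches away from the wound; a diffusing
population reflected at the wound keeps its mode in the first bin. The
per-time total-variation distance between normalised distributions is
reported as a quantitative summary (a convenience this package adds — the
original argument was visual), together with the first-bin residual,
which surfaces the known tendency of the free-redistribution model to
underestimate how many cells stay adjacent to the wound (actively
retained cells are outside the model).

```{r dichotomy, eval = FALSE}
times <- seq(0, 960, by = 60)
wound <- simulation_wound()
observed <- bin_distances(compute_distances(simulate_cells(
  simulation_params(v = 0, D = 41.8, n_cells = 150, times = times,
                    seed = 1)), wound), times = times)
dd <- ensemble_mean_distribution(simulate_ensemble(
  simulation_params(v = 0.26, D = 8, n_cells = 150, times = times,
                    seed = 2), 1000), wound, times = times)
pd <- ensemble_mean_distribution(simulate_ensemble(
  simulation_params(v = 0, D = 41.8, n_cells = 150, times = times,
                    seed = 3), 1000), wound, times = times)
compare_models(observed, dd, pd,
               labels = c("drift_diffusion", "pure_diffusion"))
```

## Numerical and design choices

* **Distance definition.** The wound edge is a straight line (a
  transection cut), and distance is the perpendicular distance to it,
  clamped at 0 on or beyond the line. Upstream software computes "the
  distance from the wound" without publishing its geometry; the line
  choice keeps the coordinate 1-D and is documented as this package's
  decision. Distances are invariant under rigid motions applied jointly
  to cells and wound (tested to 1e-6 µm).
* **Units.** $D$ is stored and documented in µm²/min (the dimension of
  an MSD slope), although reports in this literature sometimes print
  µm/min for the same quantity; numbers are comparable either way.
* **Standard errors** are classical OLS standard errors; with
  autocorrelated moment errors they understate uncertainty, one more
  reason the simulation check is the arbiter.
* **Pooling** concatenates cells across subjects (ids namespaced), so
  "all data" moments are over the pooled population; grids are aligned
  by nearest time within a 0.5-min tolerance, anything further errors.
* **Mode ties** break toward the wound (smallest bin centre); all-zero
  times yield `NA` modes, flagged rather than fabricated.
* **Degenerate inputs**: a degenerate wound line ($p_1 = p_2$), fewer
  than 3 (linear) or 4 (quadratic) usable timepoints, mismatched fit
  pairs in `f_test()`, negative fitted $D$ handed to the simulator, and
  inconsistent ensemble grids all raise classed errors
  (`woundwalk_domain_error` / `woundwalk_format_error`).
* **Whole-window reporting.** The adequacy report covers every observed
  timepoint rather than a single display time, since published
  histogram figures are ambiguous about which times they show.

## Known limitations

* Per-track (trajectory-level) inference is deliberately out of scope;
  the estimators see only population moments, and with them comes the
  $v m_0$ confound above.
* The F-test's nominal calibration does not transfer to correlated
  moment data; we report it because it is the field's screening rule,
  with the simulation check as the corrective.
* Recruitment of new cells, retention at the wound, and mixtures of
  behaviours within one population are not modelled; the first-bin
  residual is the hook for seeing the retention signal in data.
* The generator emits `y = 0` tracks (the 1-D coordinate embedded in
  the plane); it is not a 2-D tissue simulator.
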