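---
title: "Models and methods behind bactrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bactrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactrack)
```

# Scope

`bactrack` couples an agent-based generator of *Pseudomonas putida*-style
swimmers to the measurement pipeline used on real phase-contrast movies:
detection linking, trajectory quality control, run/trap segmentation,
speed and MSD statistics, mode tabulation, and colony-spreading fits. The
generator provides ground truth, so the pipeline is validated by
parameter recovery rather than by eye.

# The swimmer model

## Mode switching

A cell is always in one of four states: the three run modes — **push**
(CCW flagellar rotation), **pull** (CW), **wrapped** (CW, slow) — or a
**stop**. Switching is a continuous-time Markov chain built from four base
rates (`push_to_cw`, `cw_to_push`, `run_to_stop`, `stop_to_run`, all 1/s).
Entries into the CW branch are split between pull and wrapped by a
load-dependent propensity (below). The rates are chosen so that the
fraction of run time spent in push equals the strain's `ccw_bias`.
Absolute stop/reversal rates for these strains are not published;
the defaults (reversals about every 1.3 s, stops of ~0.17 s a few times
per ten seconds) are order-of-magnitude choices exposed in the YAML
profiles, and every closed-form comparison in the package derives its
expectation from the same rate matrix (`expected_mode_occupancy()`,
`expected_run_speed()`), so recovery checks do not depend on these
choices being "right", only on their being consistent.

## Speeds and viscosity

Each mode has a speed in water (µm/s); wrapped is the slow mode. Speeds
scale with viscosity as a power law, `v(η) = v(1 cP) · η^(−α)`. The
default exponent α ≈ 0.559 is the least-squares slope of log speed
against log viscosity through the measured wild-type means
(1 cP, 32.1), (5, 11.4), (10, 8.9), (18, 6.3); the power law is a
deliberately simple stand-in for load-dependent stator recruitment, which
is not quantified well enough to model mechanistically. The Ficoll
concentration → viscosity map interpolates the anchors 0/10/15/20 % →
1/5/10/18 cP piecewise-linearly in log-viscosity and refuses to
extrapolate beyond the highest anchor.

## Wrapped-mode propensity

The probability that a CW run is wrapped rather than pulling rises with
mechanical load. Wild-type-like strains use a saturating logistic in
log(load) (midpoint 2 cP, near-1 plateau), so that at 18 cP almost all CW
runs are wrapped. The *ΔmotAB* knockout cannot wrap in water and shows a
rise-then-fall with load; this is encoded as a gamma-shaped curve in
log(load) that is exactly zero at 1 cP, peaks at 10 cP, and declines at
the highest load. A log-normal bump was rejected because it cannot be
exactly zero in water.

## Geometry, reversals, traps

Paths live in two dimensions — imaging is a single focal plane, and
out-of-plane excursions are treated as detection dropouts. During runs the
heading diffuses rotationally (`rot_diffusion`, rad²/s); a switch between
CCW and CW rotation reverses the heading by 180° ± 15° jitter;
pull↔wrapped interchanges keep the heading (no published angles exist for
either, so the simplest geometry is used). In agar, trap events fire as a
Poisson process along the run path with rate `trap_rate / mean pore size`
(encounters per µm, referenced to a 1 µm pore); a trapped cell is frozen
for an exponential dwell (mean 1 s in 0.25 % agar — no dwell statistics
are published, this is a scale choice) and leaves with a uniform random
heading. The mode clock keeps running while a cell is trapped; only
translation is suppressed. Stop and trap timepoints translate exactly
zero, which keeps the ground-truth labels sharp at the price of
quantising sub-frame events to whole frames (see *Limitations*).

## Condition-dependent phenotype

Stator recruitment under confinement changes the phenotype qualitatively:
*ΔmotAB* is barely motile in fluids yet swims nearly like the wild type
inside agar. Strain profiles therefore carry a second speed set
(`agar_mode_speed`) and heading-noise value (`agar_rot_diffusion`) used
whenever the environment is an agar meshwork; both default to the fluid
values. This is phenomenological by design — the package models what the
phenotype is in each environment, not the recruitment kinetics that cause
it.

## Division and spreading

Trapped cells divide (rate 0.5/h; growth is strain-independent) and each
daughter independently resumes swimming with probability
`p_motile_daughter[environment]`. Sessile daughters found or join
clusters that keep dividing; `simulate_division_clusters()` is a Gillespie
branching process over these events. Colony spreading is modelled as a
Fisher reaction–diffusion front: radius speed `c = 2·√(D_eff·g_eff)` with
`D_eff = v²·τ_run/2` (v the expected run speed; 1/τ_run the total
reorientation rate: sense reversals + trap encounters + rotational
decorrelation) and `g_eff = division rate × p_motile_daughter`. The
simulated series reports the **diameter** (what a plate assay measures),
so a fitted diameter slope equals `2c`. This structure is the point of
the model: lowering daughter motility alone lowers the front speed as
√p while leaving every speed statistic untouched — speed and spreading
decouple.

# The measurement pipeline

## Linking

`link_detections()` follows the Crocker–Grier cost principle: between
consecutive frames, active track heads and detections are matched by an
exact assignment minimising summed squared displacement, with pairings
beyond `max_disp` forbidden and unmatched heads/detections allowed at a
fixed birth/death cost chosen large enough that the solver first
maximises the number of gated links, then minimises cost. The assignment
is solved exactly (an O(n³) shortest-augmenting-path solver written for
this package, as no assignment solver is available among the package's
dependencies), not greedily — at typical densities (tens of cells per
field) this is cheap and removes order artefacts. Tracks surviving a gap
re-enter matching at their last known position (no motion prediction);
ties are broken deterministically toward lower indices. The defaults
(`max_disp` 3 µm at 20 fps, `memory` 2) are configuration-exposed
choices; the measured-data values are not published.

## Quality control

Two dialects reproduce the filter cascades used on measured data: bulk —
remove trajectories with mean speed < 10 µm/s, net displacement < 5 µm,
duration < 2 s, or straightness < 0.5; agar — remove only duration
< 1.5 s or displacement < 1 µm. Rules combine by OR; each removal is
tagged with the first rule violated. "Displacement" is read as net
end-to-end displacement (the simplest reading; a maximal-displacement
variant would be easy to add but is not the default), and "highly curved"
is realised as straightness (net displacement over path length) below
0.5, since the original criterion is not restated anywhere in print.
Mean speed for the filter is path length over elapsed time, unsmoothed,
so the 10 µm/s threshold keeps its plain meaning.

## Run/trap segmentation

Two conditions, applied in order. Pass 1: every timepoint whose
instantaneous speed (central finite difference, window 1 frame at 20 fps,
raw not smoothed) is below 7 µm/s is a trap. Pass 2: if the start point
of a later trap lies within 2 µm of the end point of the earlier trap,
the timepoints between them become trap — two nearby traps merge rather
than count as separate events. Pass 2 is iterated to a fixed point: a
merge can bring two larger traps within range, and the fixed point is
unique because merging is monotone (run→trap only) and never disables
another merge; iterating makes the result independent of processing
order. Trap "endpoint"/"start point" are the positions at the last/first
frame of the episode — the most literal reading. The brute-force oracle
in the test suite rescans all trap pairs from scratch in a different
order and must agree exactly on every random trajectory.

## Speed statistics

Both summary dialects use path length over elapsed time. "Whole" averages
it per trajectory and then unweighted across trajectories (matching
mean-speed-per-trajectory distributions); "runs" computes it per run
episode over the episode's internal steps — steps crossing a run/trap
boundary fall outside the episode's index range by construction, so trap
dwells never dilute run speeds — and summarises at two levels: per
episode (distribution, counts) and per trajectory (pooled run path over
run time). The headline mean and SEM are taken across trajectories
because episodes within one trajectory are correlated; a per-point
weighting variant is available but not default. Because both dialects
share the estimator, they agree exactly on a trajectory that is 100 %
run. Sample-size reporting includes both the episode count and the
trajectory count, since "number of samples" is ambiguous in speed tables
of this kind.

## MSD and diffusivity

`compute_msd()` uses overlapping time-averaged windows per trajectory and
ensemble-averages with per-lag pair counts as weights; gap frames from
linking memory are handled by indexing lags on the common frame grid.
`estimate_diffusivity()` fits MSD against lag over a window and divides
the slope by 4 (two dimensions); a log-log slope above 1.5 over the same
window flags the curve as ballistic-like and warns, because a diffusivity
read off a superdiffusive curve is not meaningful.

## Modes and spreading fits

`tabulate_modes()` reports counts, fractions, the CW fraction
(pull + wrapped) and exact Clopper–Pearson intervals — conservative and
appropriate for the few-hundred-run counts typical of manual mode
scoring. `fit_spreading()` finds the lag as the longest initial window
whose slope is consistent with zero (t-test at 5 %; a lag is visible in
plate data but never quantified, so a generic changepoint-free detector
is used) and fits an ordinary least-squares line beyond it.

# Synthetic study conditions and what the tests mean

The shipped profiles reproduce the published phenotype structure: bulk
population means near 32 (wild type), 6.6 (*ΔmotAB*) and 32.5 µm/s
(*ΔmotCD*); agar run means near 24/21/27 µm/s; wrapped fractions rising
with viscosity; *ΔmotCD* daughters mostly sessile in agar (more so at
0.30 %), producing the spreading order WT ≳ *ΔmotAB* > *ΔmotCD* > double
mutant. The 0.30 % agar pore range (500–3200 nm) is a package choice —
only the 0.25 % range (740–4800 nm) is published — following the rule
that pores shrink as agar concentration rises.

Test problem sizes are chosen to keep the whole suite under a minute
while leaving Monte-Carlo error well below the effects being tested:
oracle equivalence on 1000 random ≤30-point trajectories and 200 random
linking instances with ≤5 particles per frame; diffusivity recovery on
hundreds of random walks; full-pipeline run-speed recovery on 500
rendered and re-tracked swimmers, required to land within two standard
errors of the closed-form mixture mean.

What passing does **not** show about real data: the generator has no
hydrodynamics, no flagellar mechanics, no chemotaxis, no cell–cell
interactions, and perfectly Markovian switching; detections are isotropic
Gaussian around truth with uniform false positives, whereas real
segmentation errors are structured (shape-dependent, near-contact
merges). The pipeline's correctness is established against ground truth
and closed forms; its adequacy for a given real data set still depends on
those data matching the stated assumptions (uniform frame rate,
single-plane imaging, approximately Gaussian localisation error).

# Numerical choices and degenerate inputs

- Determinism: every generator takes a seed; populations derive per-path
  seeds from the master seed, and the pipeline derives per-stage seeds,
  so one integer reproduces a whole run.
- Assignment ties (exactly equal costs) are broken toward lower
  track/detection indices; with continuous coordinates ties have measure
  zero.
- `straightness()` returns 1 for a zero-length path; single-point
  trajectories are rejected where a derivative is required.
- A duration-zero simulation returns a single timepoint at the origin;
  `dt ≥ duration` is an error.
- Zero run episodes yield an empty statistics table, not an error; a
  single contributing unit reports SEM as NA rather than 0.
- All thresholds carry their defaults in `pipeline_config()` and are
  echoed into the output manifest, so no processing constant is implicit
  in a result file.

# Limitations

- Sub-frame events are quantised: a stop or trap shorter than one frame
  either vanishes or occupies a whole frame. In expectation the generated
  displacement is unbiased, but threshold-based segmentation then leaks a
  small fraction of brief stops into run episodes, depressing measured
  run speeds by a few tenths of a percent relative to the configured
  mixture — visible only because the recovery tests are that tight.
- The wrapped propensity shapes are descriptive fits to a qualitative
  pattern (monotone vs peaked), not mechanistic torque models.
- The Fisher front formula assumes the linear-front regime; the simulated
  lag is a fixed offset, not an emergent property.
- `fit_spreading()`'s lag detector assumes near-noiseless early points;
  very noisy series may yield a lag of zero and a slightly diluted slope.
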