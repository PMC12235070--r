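---
title: "Motor-unit discharge analysis and paired-unit delta-F estimation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-unit discharge analysis and paired-unit delta-F estimation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-density surface EMG (HD-sEMG) recorded over a muscle during a
controlled isometric contraction can be decomposed into the discharge
times of individual motor units. In Parkinson's disease, the firing
behaviour of these units — how fast they discharge, how variable their
interspike intervals are, at what force they recruit, and how much
persistent inward current (PIC) amplifies their motoneurons — differs
between the more- and the less-affected body side, and that laterality
differs between the sexes. `mudeltaf` implements the full analysis chain
from decomposed spike trains and a synchronized torque signal to the
group-level statistics, together with a synthetic motoneuron-pool
generator whose PIC magnitude is known analytically, so that every stage
of the chain can be validated against ground truth.

The package expects two task types per muscle:

* **ramp-and-hold**: torque ramps to 30 %MVC in 15 s, holds 15 s, ramps
  down 15 s. Discharge metrics (mean rate, variability) are computed on
  the hold phase.
* **triangle**: torque rises at 2 %MVC/s to 30 %MVC and descends at the
  same rate. The paired-unit delta-F analysis uses only this task, whose
  slow symmetric drive exposes recruitment/derecruitment hysteresis.

## Signal conditioning and quality control

Torque is low-pass filtered with a fifth-order Butterworth at 10 Hz,
applied forward and backward so the filter is zero-phase: the torque and
spike clocks stay aligned, which matters because recruitment thresholds
are read off the torque at first-spike times. The signal is extended by
reflection (about a dozen filter lengths per end) before filtering so the
startup transient cannot corrupt the contraction onset. MVC is the
maximum of the filtered maximal-effort trials; submaximal torque is then
expressed in %MVC.

Decomposed trains pass three exclusion rules, applied in a fixed order
and logged per unit:

1. **Pulse-to-noise ratio**: trains below 30 dB (identification accuracy
   below roughly 90%) are removed. The boundary value is kept; trains
   without PNR metadata are kept but flagged.
2. **Interspike-interval bounds**: intervals below 33.3 ms or above
   250 ms (30 and 4 Hz) are non-physiological in a slow isometric task.
   The two violations mean different things, and are handled differently:
   a short interval is almost certainly a decomposition double-pick, so
   the *later spike* is deleted and intervals re-evaluated; a long
   interval is a silent gap, so both spikes are kept but the gap becomes
   a segment boundary — no instantaneous rate is computed across it and
   it never enters interval statistics.
3. **Discharge-rate variability**: units whose discharge-rate CV over the
   analysis window exceeds 30% are excluded (boundary kept). The window
   is the 15-s hold for ramp-and-hold trials and the unit's full active
   span for triangle trials. Units with fewer than three usable
   rate values cannot be scored and are flagged unusable.

The CV used for *exclusion* is the CV of the discharge rate; the CV of
the interspike interval is computed alongside it and reported as an
outcome, because the two are conflated in parts of the literature and
downstream statistics may want either.

## Discharge metrics

The instantaneous discharge rate (IDR) is the reciprocal of each
surviving interspike interval, in pulses per second, with no smoothing.
Each value is timestamped at the *later* spike of its interval — the rate
is only knowable once the interval closes. The mean discharge rate is
the average of IDR values whose timestamps fall in the hold window,
which is taken from the protocol clock (15–30 s) rather than detected
from torque: the protocol fixes the segment durations, and plateau
detection would introduce an unspecified extra algorithm. The
recruitment threshold (RT) is the filtered, normalized torque linearly
interpolated at the unit's first discharge. Sample (n−1) standard
deviations are used throughout because per-unit spike counts are small.

## Delta-F

PIC magnitude is estimated by the paired-motor-unit delta-F method on
triangle trials. For an ordered pair — a lower-threshold *reporter* and a
higher-threshold *test* unit — delta-F is the drop in the reporter's
smoothed discharge rate between the test unit's recruitment and its
derecruitment:

$$\Delta F = f_{rep}(t^{test}_{on}) - f_{rep}(t^{test}_{off})$$

If the test motoneuron needs less synaptic drive to keep firing at
derecruitment than it did to start firing — the reporter having slowed in
between — the difference reflects the persistent inward current that
self-sustains the test unit.

The reporter's rate profile $f_{rep}$ is the IDR smoothed by
epsilon-insensitive support vector regression with a Gaussian kernel,
evaluated on a 10-ms grid restricted to the unit's active span. SVR is
robust to the occasional aberrant interval that survives QC, which is why
it is preferred over polynomial fits here. The hyperparameters are not
standardized in the literature, so they are fixed in configuration and
echoed in every output: kernel width 2 s (several interspike intervals at
physiological rates — wide enough not to chase single intervals, narrow
enough to track drive modulation), epsilon 0.2 pps (about the
quantization scale of IDR values), regularization cost 10. A sensitivity
scan over epsilon 0.05–0.2, cost 10–50 and width 1–2 s moved validated
delta-F recovery by less than 0.05 pps, so nothing hinges on these
defaults. When every observation fits inside the epsilon tube of a
constant (a perfectly regular unit), the SVR dual is empty and the
flattest admissible function — the midrange — is used instead.

Pairs must satisfy three inclusion criteria, all inclusive bounds:

1. the test unit recruits at least **1 s** after the reporter, so the
   reporter's own PIC is fully activated before it starts reporting;
2. the smoothed rate profiles of the two units, resampled on their
   common activity grid, have Pearson correlation at least **0.7**,
   evidence that the pair shares common synaptic drive;
3. the reporter's smoothed rate spans at least **0.5 pps** while the test
   unit is active, so the reporter can actually resolve a rate drop.
   (The source literature prints this criterion with an obvious unit
   typo; it is pulses per second here.)

The test unit's recruitment and derecruitment are its first and last
QC-surviving spikes — the only observable proxies for the underlying
state transitions. A pair whose test span is not covered by the
reporter's active span cannot be evaluated and is rejected with that
reason. One delta-F value per *test unit* ("unit-wise") is the mean over
all accepted reporters, which de-noises the estimate without changing
its expectation.

## The synthetic motoneuron pool

The generator is a validation harness, not a biophysical model. Each of
`n_units` motoneurons has a recruitment threshold `RT` (evenly spaced in
%MVC), a rate gain `g` (decreasing with RT), an onion-skin ceiling
`35 − 0.25·RT` pps (so earlier-recruited units discharge faster, as in
the classic pattern), and a PIC parameter `P` in %MVC of equivalent
drive. The common drive equals the commanded torque profile. A unit is
recruited when drive reaches `RT`; once recruited, `P` is added to its
effective drive as an instantaneous, fully activated step (no decay
dynamics), so it derecruits only when drive falls below `RT − P`. This
step model makes ground truth closed-form: a reporter below its ceiling
at both transitions sees the test unit recruit at drive `RT_test` and
derecruit at `RT_test − P_test`, so

$$\Delta F_{true} = g_{rep} \cdot P_{test}.$$

Spikes are drawn from a renewal process: the next interval is the
reciprocal of the current model rate, multiplied by
`1 + isi_cv · Z` with standard-normal `Z` (floored at 0.05), giving a
controllable interval CV without conductance-based simulation. Torque is
the command plus additive Gaussian noise (SD 0.25 %MVC by default, small
enough that RT estimation error stays below the threshold spacing).
Identical configuration and seed reproduce a trial bit-for-bit.

The frozen validation pool (`deltaf_validation_config()`) has ten units
with equal gains of 0.5 pps/%MVC and PIC amplitudes of
1, 1, 2, 4, 6, 8, 2, 4, 6, 8 %MVC by ascending threshold, injecting true
delta-F levels of 1–4 pps with two test units per level. The two
low-threshold, low-PIC units are dedicated reporters that keep
discharging well past every test unit's derecruitment, and PIC rises
with threshold within each half of the pool so derecruitment drives are
staggered: candidate pairs are either cleanly covered by their reporter
or cleanly rejected, rather than being decided by interval jitter at the
reporter's span edge. An earlier pool draft without this staggering put
several test derecruitments exactly at their reporters' — a geometric
degeneracy of the pool, not a property of the estimator — and was
replaced before the validation studies were frozen.

What the generator does **not** emulate: decomposition errors other than
the optional doublet/pause injection switch, motor-unit action-potential
waveforms or any volume conduction, drive nonlinearities, PIC activation
and decay dynamics, rate adaptation, and recruitment-order violations.
Passing validation therefore shows that the estimator chain is unbiased
to within a few tenths of a pps *under its own assumptions*, not that
real decomposed data meet those assumptions.

### Known estimator bias

Validated recovery shows a small systematic negative bias (a few tenths
of a pps; the acceptance study computes it per level) with three
identified sources, none of which is a bug: (i) the later-spike IDR
timestamp places each rate value at the end of its interval, so the
smoothed profile sits slightly below the instantaneous rate on a rising
limb and above it on a falling limb; (ii) the test unit's derecruitment
is observed at its last spike, up to one interval before the true
threshold crossing, where the descending reporter still fires slightly
faster; (iii) the smooth kernel fit rounds the corner of the
triangle-shaped rate profile, producing a coherent ripple that fixed
evaluation points sample systematically. All three are properties of the
delta-F estimator as defined, and they stay well inside the ±0.5 pps
validation band.

## Group statistics

Subject-side summaries are unweighted means over that side's QC-passed
units. Laterality indices are oriented so that the disease-typical
direction is positive: discharge rate and ISI variability are *higher*
on the more-affected side (`more − less`), the PIC estimate is *lower*
there (`less − more` for delta-F). Between-sex comparisons of these
indices use the pooled-variance two-sided t test (the convention that
reproduces the printed cohort-characteristics p-values from their
summaries, to three decimals), and medication-usage proportions use the
Pearson chi-square without continuity correction on the 2×2 table, for
the same reason. No multiple-testing adjustment is applied anywhere,
matching the analysis convention of the study design; alpha is 0.05
two-sided.

Each outcome (ISI CV, mean discharge rate, delta-F) is modelled with a
linear mixed-effects model: sex, side and their interaction as fixed
effects, a random intercept per subject for the repeated sides, REML
estimation, estimated marginal means with 95% CIs per cell,
Satterthwaite degrees of freedom, and the recruitment threshold as a
covariate for the discharge-rate outcome (rate coding depends strongly
on RT). Whether the published analyses of this design were fitted on
unit-level or subject-aggregated observations is ambiguous; the default
here is subject-side aggregates (matching subject-dot figures), with a
switch for unit-level fits — on balanced data with identical units the
two give identical fixed effects, which the tests verify. A simulation
calibration (`calibrate_mixed_model()`) checks the interaction's type-I
error and CI coverage under the cohort's dimensions; interval methods
beyond the t-based Wald CI (profile likelihood, Kenward-Roger) were
compared during development and did not improve coverage in this
design, so the simple interval is kept.

Correlations with UPDRS Part III use Pearson's r with the t-transform
p-value. The RT/discharge-rate (onion-skin) relationship is summarized
per sex-by-side stratum by Pearson's r plus a robust LOESS curve — local
linear fits over the 75% nearest neighbours with tricube weights and two
bisquare reweighting iterations. LOESS is implemented in the package
(rather than delegated) because the analysis pins down exactly this
variant — evaluation at the observed thresholds, two robustifying
iterations — and because the implementation is cross-checked in the test
suite against an independent closed-form weighted-least-squares solve at
single points, which requires controlling every detail of the weighting.

## Numerical and engineering choices

* Times are seconds on the trial clock; torque shares the spike clock
  (an explicit `t0` offset is available but defaults to zero).
* All interchange files are comma-separated UTF-8 text with header rows
  and full-precision numbers; write-then-read reproduces values exactly,
  and repeated runs produce byte-identical tables.
* All randomness flows through one seeded generator per simulated trial;
  cohort and calibration studies derive their trial seeds from a single
  master seed, which is recorded in the provenance record along with the
  configuration and per-stage unit counts.
* A failing trial (unreadable file, empty torque, no surviving units) is
  isolated and logged; the run continues, and an all-excluding QC
  configuration degrades to empty tables rather than an error.
* Validation problem sizes: delta-F recovery and null studies use 20
  seeded triangle trials of the 10-unit pool at 2048 Hz; the onion-skin
  property uses 20 ramp-and-hold pools; the mixed-model calibration uses
  100 replicates of the 27-subject design. These sizes give standard
  errors comfortably below the corresponding acceptance bands.

## Limitations

* PNR is consumed as decomposition metadata; the package neither
  computes it from raw EMG nor re-runs source separation.
* The delta-F estimator inherits the assumptions of the paired-unit
  method: shared drive, fully activated reporter PIC after 1 s, and a
  reporter below its rate ceiling; the generator can construct pools
  that violate the ceiling assumption, and flags those pairs in ground
  truth.
* The simulator's renewal noise is stationary; real PD trains show
  nonstationary variability, and the 30% CV exclusion will behave
  differently on such data.
* Group results from the original cohort are not reproducible here (the
  patient data are not deposited); the statistical layer is validated on
  printed summary statistics and on synthetic cohorts instead.
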