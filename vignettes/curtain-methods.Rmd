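---
title: "Models and methods behind smcurtain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smcurtain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcurtain)
```

`smcurtain` simulates and analyses single-molecule DNA-curtain experiments on
protein lesion search, together with the solution biochemistry (gel-shift
titrations, steady-state SPR, FRAP) that surrounds them. This vignette is the
package's account of the underlying models, the defaults and why they were
chosen, and what the synthetic generators do and do not emulate.

## The experimental system being emulated

A DNA curtain stretches many lambda phage DNA molecules (48,502 bp) side by
side in a flow cell; fluorescently labelled proteins are imaged as diffraction
limited spots at roughly 1 kbp per pixel. The reference substrate carries a
triple-CPD lesion cassette between 33,513 and 33,630 bp from the
barrier-tethered end. A damage sensor ("U" in the equilibrium module; a
DDB1-DDB2-type lesion reader) binds the cassette tightly and undamaged DNA
weakly; its partner ("X"; an XPC-RAD23B-type sensor) binds undamaged DNA
tightly but barely discriminates the lesion. The package's coordinate system
is kbp from the barrier (0), times in seconds, concentrations in nM, diffusion
coefficients in um^2/s with a configurable extension factor for conversion to
sequence units.

## Synthetic data generators

All generators hang off a single validated configuration, `sim_config()`, and
a single integer seed; independent streams are derived with `split_seed()`, so
a full in-silico experiment is reproducible from one number.

**Sliding trajectories.** 1D Brownian motion with per-frame displacement
variance `2 D dt`, reflecting boundaries at both DNA ends (implemented by
exact path folding), and independent Gaussian localization noise added to the
observed positions. Defaults: `D = 0.025` um^2/s (the scale measured for a
tightly tracking lesion reader), frame interval 0.1 s, observation window
600 s, localization sd 0.5 kbp (half the one-pixel optical resolution), and an
extension of 0.272 um/kbp (about 80% of B-form contour length, typical for a
flow-stretched curtain; the conversion factor is exposed because published D
values are in um^2/s only).

**Lesion-search experiments.** Each molecule either binds the lesion directly
(3D collision; probability `direct_binding_prob`, default 0.19) or searches by
1D diffusion. A diffusing molecule "passes" the lesion window repeatedly; each
pass is captured with probability `capture_prob_per_pass` (default 0.89 — the
value whose geometric closed form `-q ln q / (1 - q)` gives the ~94%
recognition efficiency such experiments report). Once engaged, the dwell is
exponential (`mean_dwell_s`, default 900 s) and right-censored by the window.
The printed residence times in this kind of experiment (575-667 s under a
600 s window) are explicit underestimates, so the true mean is taken somewhat
above the window; 900 s is the package's stated study condition. Two modes
exist: `"fast"` draws outcomes directly from this law (bypass counts
geometric, arrival times uniform over the window for diffusive molecules), and
`"explicit"` simulates the full Brownian path and realizes capture as a
Bernoulli trial at every true pass of the window, so the bypass statistics
emerge from real crossings and the event classifier can be validated
end-to-end against stored ground truth. Molecules whose explicit path never
engages within the window are labelled `"none"`, as a microscope would see
them.

**Snapshots, titrations, FRAP.** Binding-position snapshots mix
lesion-specific events (uniform within the cassette) with a uniform
background, convolved with localization noise and clipped to the DNA.
Titrations compute per-lane expected species fractions from the equilibrium
module (exactly — at zero noise the generated fractions equal the closed-form
depletion solution), then apply multiplicative Gaussian noise and renormalize
each lane. FRAP traces are 1 before the bleach and recover as
`baseline + mobile_fraction (1 - exp(-t / tau))`, sampled at 1 frame/s by
default.

What the generators do *not* emulate: fluorophore photophysics (blinking,
bleaching — censoring is modelled at the event level only), flow-induced drift,
multi-particle crowding on one DNA, chromatin, or kinetic order-of-addition
effects. Passing tests therefore demonstrate correctness of the analysis
chain under the stated stochastic model, not robustness to every artefact of
real microscope data.

## Kymograph rendering and tracking

`render_kymograph()` integrates a Gaussian point-spread function over pixels,
adds uniform background, and draws Poisson counts. `track_kymograph()`
detects per-frame local maxima above `background + 4 sqrt(background)` (a
Poisson 4-sigma rule; configurable), localizes each spot by a bounded
least-squares 1D Gaussian fit on a 7-pixel window (falling back to an
intensity-weighted centroid when the fit runs away from its peak pixel, which
happens for dim noise blobs), suppresses duplicate detections within 2.5 px,
and links detections by greedy nearest-neighbour assignment with a hard jump
limit (3 px) and gap closing over at most one missing frame. This is
deliberately the simplest tracker adequate for the single-particle,
low-density curtain regime; it is validated only against the package's own
synthetic ground truth.

## Diffusion analysis

`compute_msd()` uses time-averaged overlapping displacement pairs — the
standard choice for short single-molecule tracks. `estimate_D()` fits
`MSD = 2 D t + c` by weighted least squares over lags 1-10 by default; short
lags avoid reflecting-boundary and censoring bias, and the intercept estimates
twice the localization variance. Ensemble estimates (`estimate_D_tracks()`)
average per-track D and report a bootstrap-over-tracks standard error, because
the molecule-to-molecule spread dominates the per-fit error. Note the
information floor: at the default localization noise (0.5 kbp against a
0.18 kbp per-frame diffusion step) a single 300-frame track determines D only
to ~20% — recovering D to a few percent requires pooling tens of molecules,
which is what the pipeline does.

`salt_series_call()` encodes the sliding-versus-hopping logic: hopping
(micro-dissociation) makes D rise with ionic strength, sliding does not. The
call uses a measurement-error-weighted regression of D on salt; "hopping"
needs a positive slope interval excluding zero *and* a fitted relative rise
above 25% across the range; "sliding" needs the interval to contain zero, a
below-threshold fitted change, *and* enough power that the upper confidence
bound of the relative change is itself below threshold — two noisy points are
called "inconclusive", not "sliding". The 25% threshold is a package choice
(no standard numeric criterion exists) and is exposed.

`rotational_limit()` evaluates the hydrodynamic speed limit for a particle
tracking the helical groove,
`D_max = kB T / (6 pi eta R [1 + (4/3)(2 pi / p)^2 R^2 + (2 pi / p)^2 R_OC^2])`,
in um^2/s. Temperature defaults to 296.15 K with the matching water
viscosity; the particle radius and axis offset have no defaults because the
published value of this bound depends on hydrodynamic parameters that vary by
construct — they are inputs, not guesses. As the pitch tends to infinity the
bound reduces to the Stokes-Einstein coefficient, and it is strictly
decreasing in both radii — both are tested.

## Event classification and lesion-search statistics

`classify_event()` must make observational calls that mirror what a person
scoring kymographs would do. An *arrest* is a stay of at least 20 s
(configurable; no standard value exists) within 1 kbp of the lesion window,
assessed on running-median-filtered positions (window 5) so single-frame
localization excursions do not fragment a genuine arrest; out-of-zone gaps of
up to 3 frames are closed for the same reason. A shorter terminal stay
(>= 5 s running into the end of the track) also counts, since engagement
truncated by the window end is otherwise invisible. Mode `"direct"` means the
arrest starts within the first 2 frames — a molecule first detected already
arrested; at ~1 kbp resolution, sub-pixel diffusion before detection cannot
be excluded, which is exactly the ambiguity real experiments state. *Bypasses*
are counted as side-to-side crossings of the padded window (including jumps
clean over it between frames), on the raw positions so fast one-frame
transits survive the filter; enter-and-exit-same-side excursions are not
counted, because at ~1 kbp resolution they are indistinguishable from
localization noise. The explicit simulator attempts capture at every true
pass of the sub-pixel window — there, same-side touches are genuine
encounters and are included. On defaults the classifier recovers ground-truth
modes with >= 95% agreement and ground-truth bypass counts with ~97% exact
agreement.

`recognition_efficiency()` is the probability-weighted statistic
`sum_b (1 / (b + 1)) n_b / n_total x 100%` over the bypass histogram of
engaged molecules. For geometric bypasses with per-pass success `q` its
expectation is `-q ln q / (1 - q)`, which the tests verify to 1% at n = 1e5.

`fit_residence_time()` offers two estimators. The *naive* method — a
least-squares single-exponential fit to the histogram of uncensored dwells —
reproduces the conventional analysis and is biased low once the true mean
approaches the observation window, because arrests occur throughout the
window and long dwells are preferentially censored away. The *censored MLE*
`tau = (sum of all observed durations) / (number of uncensored events)` is
unbiased under independent censoring; when every event is censored it reports
a flagged lower bound. The naive method is the default for reproducing
published numbers, the MLE for inference.

## Position statistics

`build_histogram()` uses fixed 1-kbp bins (one pixel) and percentile bootstrap
intervals at the 70% level used for curtain position histograms (15th/85th
percentiles; the percentile method was chosen over BCa for simplicity and
testability). Resampling positions with replacement and re-binning is
implemented exactly as multinomial resampling of the observed counts, which
is equivalent and orders of magnitude faster; measured coverage against known
expected counts is ~71% at the nominal 70%. `fit_peak()` fits a single
Gaussian plus a *flat baseline* — a deliberate extension of the plain
single-Gaussian description, because curtain snapshots contain a uniform
nonspecific background; the baseline can be disabled. The fitted sigma is
bounded below by half a bin, since sub-pixel peak widths are not resolvable
and unbounded widths degenerate the fit on near-delta histograms.
`lesion_enrichment()` compares per-kbp molecule counts inside a 32-36 kbp
window against the rest of the DNA, and `lesion_burden()` is the expected
photolesion count `density x genome length` (at ~0.027 lesions/kbp/ (J/m^2)
a 3x10^9 bp genome carries ~8.1x10^4 lesions per J/m^2).

## Binding equilibria

Gel-shift titrations run at DNA concentrations (4-10 nM) comparable to the
dissociation constants, so `fit_kd()` fits the exact depletion-corrected
quadratic (`bound_fraction()`), never a Hill/Langmuir approximation, with the
Hill coefficient fixed at 1. `spr_steady_state()` fits
`RU = RU_max C / (Kd + C)` in (initial slope, 1/Kd) coordinates: the model is
identical, but non-saturating ladders then converge to the `1/Kd = 0`
boundary and produce a wide-confidence-interval warning instead of a numeric
failure.

`solve_ux()` is the package's quantitative form of the cooperative-loading
model: `U + X <-> UX`, `U + D <-> UD`, `X + D <-> XD`, `UX + D <-> UXD`
(optionally `UD + U <-> U2D`), solved by a damped Newton iteration on log free
concentrations with an analytic Jacobian to a relative mass-balance residual
below 1e-9. The default affinity hierarchy is Kd(U, lesion) = 5 nM,
Kd(U, undamaged) = 26 nM, Kd(X, lesion) = 7 nM, Kd(X, undamaged) = 9 nM. Two
genuinely open choices were resolved as follows. First, the protein-protein
Kd of the UX complex is not published; SPR shows minimal dissociation, so the
default is tight (1 nM) and the parameter is free. Second, the DNA affinity
of the UX complex is unmeasured; the default policy gives the complex the Kd
of whichever subunit binds that substrate more tightly (X on undamaged DNA, U
on the lesion), which is the verbal cooperative-loading model made
quantitative, and any numeric value can be substituted. Under these defaults
the model reproduces the observed asymmetry: X raises the DNA-bound amount of
U (`enhancement_fold()` > 1) while U does not raise bound X. Two caveats are
modelled deliberately: the enhancement fold tends to 1 as the protein-protein
Kd tends to infinity *only* in the non-depleting (DNA-excess) regime — at
stoichiometric DNA a residual competition effect remains, which is plain mass
action, not cooperation; and order-of-addition effects and sub-stoichiometric
recycling are kinetic phenomena outside an equilibrium solver, so the package
reproduces end-state asymmetry only.

## FRAP

`normalize_frap_trace()` divides by the mean pre-bleach intensity (>= 3
frames required) and re-zeroes time at the bleach; `frap_recovery_at()`
interpolates the normalized recovery at a fixed time (default 120 s) and
errors rather than extrapolating when a trace is shorter — synthetic traces
can simply be generated longer, which is how the tension between 1-minute
acquisitions and a 120 s statistic is resolved here. Group comparisons use a
two-sided two-sample t-test, equal-variance by default (the Student form),
with Welch as an option.

## Numerical choices and problem sizes

Tolerances: the equilibrium solver targets 1e-12 and must reach 1e-9;
nonlinear fits use Levenberg-Marquardt (minpack) with bounded parameters;
spot-fit ties at equal intensity resolve toward the lower pixel index.
Degenerate inputs error with classed conditions (`smcurtain_invalid_config`,
`smcurtain_insufficient_data`, ...) rather than returning silent NAs. The
shipped test and benchmark sizes — 100-150 molecules, 300-600 frame tracks,
100 titration noise realizations, 500 bootstrap-coverage replicates — were
chosen so each statistical check has comfortable power while a full run of
the suite and the benchmark script completes in minutes on one CPU; all of
them scale up through the same interfaces.

## Known limitations

The tracker is single-DNA and low-density by design; there is no mixture or
double-peak fitting for position histograms; the equilibrium module stops at
one optional U2D species rather than a full stoichiometric ladder; anomalous
diffusion exponents are not fitted (motion is treated as Brownian, which the
displacement-Gaussian check supports for the simulated regime); and nothing
kinetic (on/off rates, handover, ubiquitination-dependent transfer) is
modelled.
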