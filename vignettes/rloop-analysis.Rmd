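---
title: "Models and methods behind rloopkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rloopkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rloopkin)
```

rloopkin implements the quantitative analysis stack used in mechanistic
studies of CRISPR–Cas9 R-loop dynamics that combine three kinds of
measurement: ensemble cleavage kinetics on supercoiled plasmid substrates,
single-molecule magnetic-tweezers recordings of R-loop formation and
dissociation, and a FRET-based readout of guide-RNA loading into the
ribonucleoprotein (RNP). This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Sequential cleavage kinetics

A Cas9 RNP nicks one strand of a negatively supercoiled plasmid (SC),
producing an open-circle intermediate (OC), and then cuts the second strand
to linearise it (LIN). With both steps approximated as first order, the
two-step scheme is

$$\mathrm{SC} \xrightarrow{k_a} \mathrm{OC} \xrightarrow{k_b} \mathrm{LIN},$$

with apparent rate constants $k_a$ and $k_b$ (s$^{-1}$) for first- and
second-strand cleavage. `simulate_two_step()` evaluates the closed-form
(Bateman) solution; the degenerate branch is switched when
$|k_a - k_b|/k_a < 10^{-9}$, where $\mathrm{OC}(t) = k\,t\,e^{-kt}$.

When R-loop formation itself is rate-limiting, a three-step scheme prepends
a one-step formation reaction with rate constant $k_\mathrm{formation}$:
unbound plasmid U forms an R-loop-bound state R before first-strand
cleavage. Because quenching collapses the R-loop, R co-migrates with SC on
the gel and the *observed* SC signal is U + R. `simulate_three_step()`
integrates this scheme with an adaptive solver (lsoda, relative tolerance
$10^{-8}$), which handles the stiff limit of very fast formation.

Fitting choices, all deliberate:

* **Loss.** Unweighted sum of squared residuals over all three species
  jointly. Scintillation-count depths are similar across lanes, so
  per-species weighting would add a nuisance parameter without information.
* **Normalisation.** Counts are converted to fractions per time point
  before fitting, because scintillation counts scale per lane.
* **Positivity.** Free rate constants are fitted on a log scale by
  Levenberg–Marquardt, which enforces positivity without active-set
  bookkeeping.
* **Multi-start.** Three starts (the initial guess and a factor of ten
  either side) guard against local minima; a replicate is declared
  non-converged when the optimiser fails, and starts whose residual sum of
  squares exceeds five times the best are discarded as failed local
  minima. Non-convergence is reported, never silently dropped — some
  condition/substrate combinations genuinely do not support a satisfactory
  fit.
* **Fixed parameters.** Any subset of rate constants can be held fixed
  (e.g. fixing $k_a$ at a value averaged over well-determined conditions
  when refitting with the formation step free), since
  $k_\mathrm{formation}$ and $k_a$ are not jointly identifiable when
  formation is rate-limiting.
* **Incomplete digestion.** Preparations with low specific activity leave
  a fraction of substrate uncut; an optional active-fraction parameter
  `f_active` scales the reactive SC pool, fixed at 1 by default.
* **Averaging.** Replicates are fitted separately and the constants
  averaged (mean, SD with $n-1$ denominator) over converged replicates
  only, matching standard reporting for these assays.

## Magnetic-tweezers traces

A DNA tether is supercoiled by magnet rotation; R-loop formation absorbs
roughly 1.9 turns of unwinding for a full 20 bp R-loop (one turn per
~10.5 bp), which under negative supercoiling appears as an upward bead
extension step. Dissociation under positive supercoiling is likewise an
upward step. The tweezers protocol alternates negative holds (formation)
and positive holds (dissociation), joined by magnet transits at 10 turns
s$^{-1}$.

* **Smoothing.** A second-order Butterworth low-pass at 2 Hz, applied
  forward–backward (zero phase) so steps are not delayed. The signal is
  mean-subtracted before filtering and odd-reflection padded to suppress
  edge transients.
* **Dwell clock.** Formation and dissociation times are measured from the
  end of the magnet transit (setpoint reached), since dwell times are
  defined under constant applied turns. The transit duration is
  $|\Delta\mathrm{turns}|/\mathrm{rate}$ and those samples are excluded.
* **Step detection.** The method is threshold crossing with a persistence
  check, chosen for robustness and transparency. Within a hold, the
  pre-step baseline is the minimum of a running median (so early events do
  not contaminate it) and the settled level is the median at the end of
  the hold. A level difference of at least 25% of the expected full-R-loop
  step counts as an event; the dwell ends at the first crossing of half
  the observed step that persists for 0.5 s. Holds without an event yield
  a right-censored dwell equal to the hold duration.
* **Partial R-loops.** Steps between 25% and 75% of the expected full step
  are flagged `complete = FALSE`. These thresholds are an implementation
  choice; the expected step itself is supplied via calibration
  (micrometres per turn from the no-enzyme rotation curve), never
  hard-coded.
* **Known limitation.** Events whose dwell is shorter than the smoothing
  timescale (~0.5 s at a 2 Hz cutoff) are still detected, but their
  measured step height is attenuated by blending with the transit, so
  completeness flags are only meaningful for longer dwells. Events that
  occur during the transit itself are not modelled.

## Dwell-time statistics

Collections of dwell times are summarised as the empirical survival
function (inverted cumulative probability) $P(T > t) = 1 - \mathrm{rank}/N$
with ties sharing the largest rank. Fits are least squares to the survival
points — matching how these distributions are conventionally plotted and
fitted — with either

$$S(t) = e^{-t/\tau} \quad\text{or}\quad
S(t) = a\,e^{-t/\tau_\mathrm{slow}} + (1-a)\,e^{-t/\tau_\mathrm{fast}},$$

the two amplitudes constrained to sum to one (the standard convention;
the reported mean time is $\tau$ or $a\tau_\mathrm{slow} +
(1-a)\tau_\mathrm{fast}$). Parameters are transformed (logit amplitude,
log taus) so the optimiser is unconstrained, and standard errors are
mapped back by the delta method. A maximum-likelihood backend on the raw
dwells (exact for one component, EM for the mixture) is provided as an
independent cross-check, and a bootstrap is available when covariance
SEs are unstable at small $N$.

Model selection between one and two components uses the small-sample
corrected information criterion (AICc) computed from the least-squares
fit; the two-component model is kept only if it strictly improves the
score, with ties resolved in favour of one component. Event-count floors
($N \ge 10$ for one component, $N \ge 19$ for two) reflect the smallest
event sets for which such fits are reported in practice. Censored dwells
are excluded by default, matching finite-event-count survival fits.

Formation rates depend on RNP concentration approximately as a power law;
`concentration_dependence()` fits $\mathrm{rate} = k\,C^n$ by linear
regression on log–log axes and reports $n \pm$ SE. A second-order
dependence ($n \approx 2$) can mask torque dependence of formation times.

## R-loop sizing from rotation curves

Bead extension versus applied turns forms a hat-shaped curve with linear
flanks past the buckling transition. A trapped R-loop absorbs turns and
displaces the curve along the turn axis; the number of trapped turns is
estimated by comparing flank lines between a no-enzyme reference curve and
an R-loop-trapped curve, both acquired at 1 turn s$^{-1}$.

* The negative-turn flank is used for sizing because the R-loop is trapped
  under negative torque; the positive flank is supported for symmetry
  checks.
* Flank points lie at least 2 turns beyond the apex and below 90% of the
  plateau (apex and plateau located on a running-median smoothed curve);
  at least 5 points are required and a near-flat fit is rejected.
* The shift is read at the midpoint extension of the two lines' overlap,
  which averages out intercept noise; pairs whose slopes differ by more
  than 20% are rejected as invalid comparisons.
* Every reference curve is compared with every trapped curve (the standard
  design is 20 × 22 = 440 pairs); invalid pairs are dropped and counted,
  and more than 50% invalid is an error.
* Turns convert to base pairs linearly against the mean turn shift of
  conditions taken to carry a full-length (20 bp) R-loop.
* Condition comparisons use one-way ANOVA followed by all-pairs Tukey HSD.
  The choice of Tukey HSD is an assumption of this package — recorded
  here prominently — since "multiple comparison significance test" does
  not pin down a procedure.

## The FRET loading proxy

Spectra are collected under donor excitation (530 nm; emission 550–800 nm)
and direct acceptor excitation (630 nm; emission 650–800 nm). The acceptor
ratio is

$$(\mathrm{ratio})_A = \frac{\text{acceptor peak, donor excitation
(sensitised)}}{\text{acceptor peak, direct excitation}},$$

a proxy for FRET and hence for the conformational state of the labelled
Cas9: high in the compact apo state, lower once gRNA loading moves the
labelled residues apart. The exact published convention includes
supplementary correction terms that are not fully specified; this package
defines its convention as the corrected-sensitised/direct peak ratio, with
optional donor bleed-through subtraction using a scaled donor-only
reference. Peaks are quantified as the mean over ±10 nm around the
acceptor emission maximum, more robust than a single-pixel maximum.
Labelling efficiency follows the standard absorbance arithmetic with
per-dye 280 nm correction fractions (defaults 8% for Cy3, 5% for Cy5).

## The synthetic-data generator

Every analysis step is validated against `synth_config()` data with
ground-truth sidecars. The generator emulates the statistical structure
the analysis assumes:

| Parameter | Default | Why |
|---|---|---|
| camera rate | 60 Hz | standard tracking-camera rate |
| cycling rate | 10 turns s$^{-1}$ | standard for R-loop cycling |
| sizing-curve rate | 1 turn s$^{-1}$ | standard for rotation curves |
| full R-loop | 1.9 turns = 20 bp | one turn per ~10.5 bp |
| extension per turn | 0.05 µm/turn | typical plectoneme slope at sub-pN force; a documented free parameter used only via calibration |
| tracking noise | 0.01 µm SD, white Gaussian | typical bead-tracking noise after magnification |
| formation / dissociation dwell laws | Exp(4 s) / Exp(2 s) | representative cycling timescales; two-component mixtures configurable |
| negative / positive holds | 30 s / 15 s | several dwell means, so censoring is rare |
| lane counts | Poisson, 2000 per lane | scintillation counting statistics |
| emission bands | Gaussians at 565 / 667 nm, SD 15 nm | Cy3/Cy5-like bands; sensitised amplitude linear in FRET efficiency |

Identical configurations (seed included) reproduce identical data, and
every generator returns its ground truth alongside.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: instrument drift (optional to inject,
off by default), bead-tracking outliers, polymer/plectoneme mechanics
(curves and traces are phenomenological piecewise shapes), torque
calibration, sequence-dependent kinetics, and gel densitometry artefacts.
Recovery of generator parameters shows the estimators are correct under
the stated noise models, not that those models exhaust real instruments.

## Validation problem sizes

The shipped test-suite checks run at sizes chosen to give comfortable
statistical power while staying quick on a laptop: a 5 × 5 rate grid for
noiseless kinetic recovery; 20 random rate pairs for the closed-form
versus ODE agreement (max deviation below $10^{-6}$); 200 single-cycle
traces at signal-to-noise 4 for detection recall (≥ 95%) and false
positives (≤ 2%); 5000 dwell draws for the two-component mixture
recovery; 20 × 22 curve pairs for sizing; 1000 simulations of three null
groups for the family-wise error of the Tukey procedure (≤ 0.06); and a
200-cycle end-to-end pipeline run.

## Degenerate inputs and tie-breaks

Equal cleavage rate constants switch to the symmetric closed form; a
survival-fit tie on AICc keeps one component; flank fits reject near-zero
slopes (plateau selected by mistake) and pairs with mismatched slopes;
zero-variance groups are flagged before ANOVA; spectra with a dead direct
acceptor channel are an error rather than an infinite ratio; and
normalising a cleavage lane with zero total counts is an error.
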