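# rloopkin

Quantitative analysis of CRISPR–Cas9 R-loop dynamics from ensemble and
single-molecule experiments.

When a Cas9 ribonucleoprotein (RNP) engages its DNA target it forms an
R-loop — the guide RNA base-pairs with the target strand, displacing the
non-target strand — and only then licenses its two nuclease domains to cut.
Studies of how guide-RNA modifications change this process typically combine
three measurements, and rloopkin implements the analysis for all of them:

1. **Cleavage kinetics.** Supercoiled plasmid (SC) is nicked to an
   open-circle intermediate (OC) and then linearised (LIN). Band abundances
   from quenched time points are fitted to the sequential first-order scheme

   SC →(k_a) OC →(k_b) LIN

   via the closed-form Bateman solution, or to a three-step variant with a
   rate-limiting R-loop formation step, k_formation, before first-strand
   cleavage (observed SC = unbound + R-loop-bound plasmid). Replicates are
   fitted separately and the constants averaged; any parameter can be held
   fixed (e.g. k_a when formation masks it).

2. **Magnetic tweezers.** Bead-extension traces from R-loop cycling
   experiments are low-pass filtered (2 Hz, zero phase), segmented into
   negative/positive supercoiling holds from the magnet protocol, and
   searched for the extension steps that mark R-loop formation and
   dissociation. Dwell times feed empirical survival curves
   P(T > t) fitted with single or double exponentials (AICc-selected);
   trapped R-loop sizes are estimated in turns from 20 × 22 pairwise
   comparisons of rotation ("hat") curve flanks and converted to base pairs
   against full-length calibration conditions, with ANOVA + Tukey HSD
   comparisons across guide conditions.

3. **FRET loading assay.** The acceptor ratio
   (ratio)_A = sensitised acceptor emission / directly excited acceptor
   emission is computed from paired spectra (530 nm and 630 nm excitation)
   as a proxy for RNP loading.

A seeded synthetic-data generator (`synth_config()` and `gen_*()`)
reproduces the statistical structure of each instrument — exponential dwell
laws, stepped traces with Gaussian tracking noise, hat curves, Poisson lane
counts, two-fluorophore spectra — together with ground-truth sidecars, so
every estimator ships with closed-loop validation. See the methods vignette
(`vignettes/rloop-analysis.Rmd`) for the full model and design notes.

## Worked example

Run the whole synthetic study — simulate, analyze, fit, report — in one
call:

```r
library(rloopkin)
cfg <- list(seed = 11, stages = c("cleavage", "dwells", "rloopsize", "fret"),
            dwells = list(n_cycles = 150))
run_pipeline(cfg)
#> <rloop_report> 4 stages: cleavage, dwells, rloopsize, fret
#>   cleavage:
#>  parameter       mean           sd n
#>        k_a 0.10031224 0.0016545119 3
#>        k_b 0.01004531 0.0001642292 3
#>   formation dwells: 1-component fit, mean 3.6 s (N = 150)
#>   dissociation dwells: 2-component fit, mean 1.89 s (N = 150)
#>   R-loop size: 1.89 +/- 0.04 turns -> 20 bp (440 pairs)
#>   ratio_A: high-FRET 0.800, low-FRET 0.200
```

Reading the report: three Poisson-noise cleavage replicates generated at
k_a = 0.1 s⁻¹, k_b = 0.01 s⁻¹ are recovered to within a few percent; 150
cycling events give dwell fits close to the generating laws (formation
Exp(4 s), dissociation Exp(2 s) — the AICc occasionally prefers a
two-component fit whose mixture mean still matches); 440 pairwise rotation-
curve comparisons recover the injected 1.9-turn R-loop and calibrate it to
20 bp; and the FRET proxy tracks the generator's transfer efficiency.

Fitting a biphasic dwell distribution directly:

```r
set.seed(42)
d <- draw_dwells(5000, list(a = 0.61, tau_slow = 36, tau_fast = 3.5))
fit_exponential(survival_curve(d), 2)
#> <survival_fit> double exponential, N = 5000: 60% slow (tau = 35.82 s), tau_fast = 3.642 s
#>   mean dwell 23.03 s
```

A thin command-line front end with subcommands (`simulate`, `fit-cleavage`,
`analyze-traces`, `fit-dwells`, `size-rloop`, `ratio-a`, `run`) is installed
at `inst/scripts/rloopkin`.

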