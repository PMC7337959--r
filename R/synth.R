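# Synthetic instrument-data generator. Emulates the statistical structure the
# analysis assumes -- exponential dwell laws, stepped bead traces with
# Gaussian tracking noise, hat-shaped rotation curves, Poisson-counted gel
# lanes and two-fluorophore emission spectra -- and returns machine-readable
# ground truth alongside every dataset.

#' Synthetic-data configuration
#'
#' Bundles the generator parameters with a seed. Identical configurations
#' (including the seed) produce identical output. Defaults mirror the
#' standard experimental setup: 60 Hz camera, 10 turns/s supercoiling
#' cycling, 1 turn/s sizing curves, a 1.9-turn (20 bp) full R-loop, and
#' 50 nm of extension per turn on the plectonemic flank.
#'
#' @param seed Integer RNG seed.
#' @param trace Overrides for the bead-trace generator: `sample_rate` (Hz),
#'   `noise_sd` (um), `um_per_turn`, `full_rloop_turns`, `rloop_turns`
#'   (turns actually captured; defaults to `full_rloop_turns`), `neg_turns`,
#'   `pos_turns`, `neg_hold`, `pos_hold` (s), `rate` (turns/s),
#'   `baseline_um`.
#' @param dwell Dwell-time laws per event kind: each of `formation` and
#'   `dissociation` is either `list(tau = )` for a single exponential or
#'   `list(a = , tau_slow = , tau_fast = )` for a two-component mixture
#'   (`a` = slow-component amplitude).
#' @param cleavage Overrides for the cleavage generator: `variant`, `rates`
#'   (named, per second), `counts_per_lane`, `times` (s).
#' @param curve Overrides for the rotation-curve generator: `plateau` (um),
#'   `slope` (um/turn), `apex_halfwidth` (turns), `noise_sd` (um), `turns`
#'   (grid).
#' @param spectra Overrides for the spectra generator: `donor_center`,
#'   `donor_sd`, `acceptor_center`, `acceptor_sd` (nm), `donor_amplitude`,
#'   `acceptor_amplitude` (a.u.), `fret_efficiency`, `noise_sd`.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1, trace = list(), dwell = list(),
                         cleavage = list(), curve = list(), spectra = list()) {
  defaults <- list(
    seed = as.integer(seed),
    trace = list(sample_rate = 60, noise_sd = 0.01, um_per_turn = 0.05,
                 full_rloop_turns = 1.9, rloop_turns = NULL,
                 neg_turns = -20, pos_turns = 20, neg_hold = 30,
                 pos_hold = 15, rate = 10, baseline_um = 0.4),
    dwell = list(formation = list(tau = 4), dissociation = list(tau = 2)),
    cleavage = list(variant = "two_step",
                    rates = c(k_a = 0.1, k_b = 0.01),
                    counts_per_lane = 2000,
                    times = c(5, 10, 20, 30, 50, 75, 100, 150, 200, 300,
                              450, 600)),
    curve = list(plateau = 0.9, slope = 0.05, apex_halfwidth = 1,
                 noise_sd = 0.01, turns = seq(-15, 15, by = 0.25)),
    spectra = list(donor_center = 565, donor_sd = 15, acceptor_center = 667,
                   acceptor_sd = 15, donor_amplitude = 1000,
                   acceptor_amplitude = 1000, fret_efficiency = 0.3,
                   noise_sd = 0))
  cfg <- defaults
  for (blk in c("trace", "dwell", "cleavage", "curve", "spectra")) {
    ov <- get(blk)
    for (nm in names(ov)) cfg[[blk]][[nm]] <- ov[[nm]]
  }
  if (is.null(cfg$trace$rloop_turns)) {
    cfg$trace$rloop_turns <- cfg$trace$full_rloop_turns
  }
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  tr <- cfg$trace
  stopifnot(tr$sample_rate > 0, tr$noise_sd >= 0, tr$um_per_turn > 0,
            tr$full_rloop_turns > 0, tr$rloop_turns > 0, tr$rate > 0,
            tr$neg_hold > 0, tr$pos_hold > 0, tr$baseline_um > 0)
  for (law in cfg$dwell) {
    if (!is.null(law$tau)) stopifnot(law$tau > 0)
    else stopifnot(law$a >= 0, law$a <= 1, law$tau_slow > 0, law$tau_fast > 0)
  }
  stopifnot(all(cfg$cleavage$rates > 0), cfg$cleavage$counts_per_lane > 0,
            cfg$curve$plateau > 0, cfg$curve$slope > 0,
            cfg$curve$noise_sd >= 0, cfg$spectra$donor_sd > 0,
            cfg$spectra$acceptor_sd > 0,
            cfg$spectra$fret_efficiency >= 0, cfg$spectra$fret_efficiency <= 1)
  invisible(cfg)
}

#' Draw dwell times from a configured dwell law
#'
#' @param n Number of draws.
#' @param law `list(tau = )` or `list(a = , tau_slow = , tau_fast = )`.
#' @return Numeric vector of dwell times in seconds.
#' @export
draw_dwells <- function(n, law) {
  if (!is.null(law$tau)) {
    stats::rexp(n, rate = 1 / law$tau)
  } else {
    slow <- stats::runif(n) < law$a
    ifelse(slow, stats::rexp(n, rate = 1 / law$tau_slow),
           stats::rexp(n, rate = 1 / law$tau_fast))
  }
}

#' Generate a synthetic bead trace with ground truth
#'
#' Simulates R-loop cycling: alternating negative and positive supercoiling
#' holds joined by magnet transits, with an upward extension step of
#' `rloop_turns x um_per_turn` at the formation dwell (negative hold) and at
#' the dissociation dwell (positive hold), plus white Gaussian tracking
#' noise. Dwells are drawn from the configured laws unless supplied. A
#' formation dwell longer than the hold is censored, and no dissociation
#' event occurs in the following positive hold.
#'
#' @param config A [synth_config()].
#' @param n_cycles Number of negative/positive cycles.
#' @param true_dwells Optional list with `formation` and `dissociation`
#'   dwell vectors (one per cycle) overriding the configured laws.
#' @param trace_id Label.
#' @param seed_offset Added to the config seed so that repeated calls with
#'   the same config yield independent traces.
#' @return List with `trace` ([bead_trace()]), `protocol`
#'   ([rotation_protocol()]), and `truth` (data frame: `cycle`, `kind`,
#'   `dwell_s`, `censored`, `step_um`).
#' @export
gen_bead_trace <- function(config, n_cycles = 1, true_dwells = NULL,
                           trace_id = "synthetic_trace", seed_offset = 0) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + seed_offset)
  tr <- config$trace
  step_um <- tr$rloop_turns * tr$um_per_turn
  protocol <- rotation_protocol(
    target_turns = rep(c(tr$neg_turns, tr$pos_turns), n_cycles),
    hold = rep(c(tr$neg_hold, tr$pos_hold), n_cycles),
    rate = tr$rate)
  fs <- tr$sample_rate
  total_t <- max(protocol$end_time)
  time <- seq(0, total_t - 1 / fs, by = 1 / fs)
  ext <- rep(tr$baseline_um, length(time))
  form_d <- if (!is.null(true_dwells)) {
    rep_len(true_dwells$formation, n_cycles)
  } else draw_dwells(n_cycles, config$dwell$formation)
  diss_d <- if (!is.null(true_dwells)) {
    rep_len(true_dwells$dissociation, n_cycles)
  } else draw_dwells(n_cycles, config$dwell$dissociation)
  truth <- list()
  for (cy in seq_len(n_cycles)) {
    neg <- protocol[2 * cy - 1, ]
    pos <- protocol[2 * cy, ]
    f_cens <- form_d[cy] >= tr$neg_hold
    if (!f_cens) {
      # step up from formation until the end of the negative hold
      on <- time >= neg$transit_end + form_d[cy] & time < neg$end_time
      ext[on] <- ext[on] + step_um
    }
    truth[[length(truth) + 1L]] <- data.frame(
      cycle = cy, kind = "formation", dwell_s = min(form_d[cy], tr$neg_hold),
      censored = f_cens, step_um = if (f_cens) NA_real_ else step_um)
    if (!f_cens) {
      d_cens <- diss_d[cy] >= tr$pos_hold
      if (!d_cens) {
        on <- time >= pos$transit_end + diss_d[cy] & time < pos$end_time
        ext[on] <- ext[on] + step_um
      }
      truth[[length(truth) + 1L]] <- data.frame(
        cycle = cy, kind = "dissociation",
        dwell_s = min(diss_d[cy], tr$pos_hold),
        censored = d_cens, step_um = if (d_cens) NA_real_ else step_um)
    }
  }
  ext <- ext + stats::rnorm(length(time), sd = tr$noise_sd)
  turns <- protocol$target_turns[pmax(1L, findInterval(time,
                                                       protocol$start_time))]
  trace <- bead_trace(time, ext, turns, trace_id = trace_id,
                      sample_rate = fs)
  list(trace = trace, protocol = protocol, truth = do.call(rbind, truth))
}

#' Generate a synthetic rotation (hat) curve
#'
#' Symmetric piecewise-linear hat: a plateau of half-width `apex_halfwidth`
#' with linear flanks of the configured slope, centred at zero applied turns
#' for a reference curve and displaced toward negative turns by
#' `trapped_turns` when an R-loop is trapped, plus Gaussian noise.
#'
#' @param config A [synth_config()].
#' @param trapped_turns Turns absorbed by the trapped R-loop (0 for a
#'   reference curve).
#' @param curve_id Label.
#' @param seed_offset Added to the config seed.
#' @return A [rotation_curve()]; the injected `trapped_turns` is attached as
#'   attribute `truth_trapped_turns`.
#' @export
gen_rotation_curve <- function(config, trapped_turns = 0,
                               curve_id = "synthetic_curve",
                               seed_offset = 0) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + seed_offset)
  cv <- config$curve
  centre <- -trapped_turns
  dist <- pmax(abs(cv$turns - centre) - cv$apex_halfwidth, 0)
  ext <- cv$plateau - cv$slope * dist +
    stats::rnorm(length(cv$turns), sd = cv$noise_sd)
  out <- rotation_curve(cv$turns, ext, curve_id = curve_id,
                        condition = if (trapped_turns == 0) "reference"
                        else "rloop_trapped",
                        rotation_rate = 1)
  attr(out, "truth_trapped_turns") <- trapped_turns
  out
}

#' Generate a set of rotation curves
#'
#' @param config A [synth_config()].
#' @param n Number of curves.
#' @param trapped_turns Injected turn shift shared by all curves.
#' @param id_prefix Curve label prefix.
#' @param seed_offset Base seed offset; curve i uses `seed_offset + i`.
#' @return List of [rotation_curve()]s.
#' @export
gen_rotation_curve_set <- function(config, n, trapped_turns = 0,
                                   id_prefix = "curve", seed_offset = 0) {
  lapply(seq_len(n), function(i) {
    gen_rotation_curve(config, trapped_turns,
                       curve_id = paste0(id_prefix, "_", i),
                       seed_offset = seed_offset + i)
  })
}

#' Generate a synthetic cleavage time course (scintillation counts)
#'
#' Species counts per lane drawn as Poisson with means equal to the model
#' fractions times `counts_per_lane`, emulating scintillation counting of
#' excised gel bands.
#'
#' @param config A [synth_config()].
#' @param replicate_id Label.
#' @param seed_offset Added to the config seed.
#' @return List with `time_course` (a counts [cleavage_time_course()]) and
#'   `truth` (variant, rates and the noiseless fractional time course).
#' @export
gen_time_course <- function(config, replicate_id = "synthetic_rep",
                            seed_offset = 0) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + seed_offset)
  cl <- config$cleavage
  ideal <- if (cl$variant == "two_step") {
    simulate_two_step(cl$rates[["k_a"]], cl$rates[["k_b"]], cl$times)
  } else {
    simulate_three_step(cl$rates[["k_formation"]], cl$rates[["k_a"]],
                        cl$rates[["k_b"]], cl$times)
  }
  counts <- vapply(seq_len(nrow(ideal)), function(i) {
    stats::rpois(3, lambda = c(ideal$sc[i], ideal$oc[i], ideal$lin[i]) *
                   cl$counts_per_lane)
  }, numeric(3))
  tc <- cleavage_time_course(cl$times, counts[1, ], counts[2, ], counts[3, ],
                             replicate_id = replicate_id, is_fraction = FALSE)
  list(time_course = tc,
       truth = list(variant = cl$variant, rates = cl$rates, ideal = ideal))
}

#' Generate synthetic paired emission spectra
#'
#' Gaussian donor (about 565 nm) and acceptor (about 667 nm) emission bands.
#' Under 530 nm excitation the donor band has amplitude
#' `donor_amplitude x (1 - E)` and the sensitised acceptor band amplitude
#' `donor_amplitude x E`, linear in the FRET efficiency `E`; under direct
#' 630 nm excitation only the acceptor band appears, with amplitude
#' `acceptor_amplitude`. A donor-only reference (no acceptor) is returned
#' for bleed-through correction.
#'
#' @param config A [synth_config()]; `config$spectra$fret_efficiency` may be
#'   overridden with `fret_efficiency`.
#' @param fret_efficiency Optional override of the configured E.
#' @param seed_offset Added to the config seed.
#' @return List with `ex530`, `ex630`, `donor_only`
#'   ([emission_spectrum()]s) and `truth` (E and band parameters).
#' @export
gen_spectra <- function(config, fret_efficiency = NULL, seed_offset = 0) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + seed_offset)
  sp <- config$spectra
  E <- if (is.null(fret_efficiency)) sp$fret_efficiency else fret_efficiency
  stopifnot(E >= 0, E <= 1)
  gauss <- function(x, mu, sd) exp(-(x - mu)^2 / (2 * sd^2))
  grid530 <- 550:800
  grid630 <- 650:800
  donor_band <- sp$donor_amplitude * gauss(grid530, sp$donor_center,
                                           sp$donor_sd)
  sens_band <- sp$donor_amplitude * E * gauss(grid530, sp$acceptor_center,
                                              sp$acceptor_sd)
  i530 <- (1 - E) * donor_band + sens_band
  i630 <- sp$acceptor_amplitude * gauss(grid630, sp$acceptor_center,
                                        sp$acceptor_sd)
  if (sp$noise_sd > 0) {
    i530 <- pmax(i530 + stats::rnorm(length(i530), sd = sp$noise_sd), 0)
    i630 <- pmax(i630 + stats::rnorm(length(i630), sd = sp$noise_sd), 0)
  }
  list(ex530 = emission_spectrum(grid530, i530, 530),
       ex630 = emission_spectrum(grid630, i630, 630),
       donor_only = emission_spectrum(grid530, donor_band, 530),
       truth = list(fret_efficiency = E,
                    donor_center = sp$donor_center,
                    acceptor_center = sp$acceptor_center))
}
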