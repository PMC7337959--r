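make_flat_trace <- function(n = 600, level = 1.0, fs = 60, noise = 0) {
  set.seed(99)
  bead_trace(seq(0, by = 1 / fs, length.out = n),
             level + stats::rnorm(n, sd = noise), sample_rate = fs)
}

test_that("low-pass smoothing preserves DC and attenuates out-of-band tones", {
  flat <- make_flat_trace(level = 1.0)
  sm <- smooth_trace(flat, cutoff = 2)
  expect_equal(sm$extension_um, flat$extension_um, tolerance = 1e-9)
  expect_equal(sm$time_s, flat$time_s)

  t <- seq(0, 10 - 1 / 60, by = 1 / 60)
  tone <- bead_trace(t, 1 + 0.1 * sin(2 * pi * 10 * t), sample_rate = 60)
  sm_tone <- smooth_trace(tone, cutoff = 2)
  mid <- seq(120, length(t) - 120)  # ignore edges
  expect_lt(max(abs(sm_tone$extension_um[mid] - 1)), 0.1 * 0.01)

  expect_error(smooth_trace(flat, cutoff = 30), "Nyquist")
})

test_that("smoothing reduces white-noise RMS by at least the filter-gain bound", {
  # ideal low-pass at 2 Hz on 60 Hz white noise cuts noise power by >= 15x
  tr <- make_flat_trace(n = 6000, level = 1.0, noise = 0.02)
  sm <- smooth_trace(tr, cutoff = 2)
  mid <- seq(300, 5700)
  rms_raw <- stats::sd(tr$extension_um[mid] - 1)
  rms_sm <- stats::sd(sm$extension_um[mid] - 1)
  expect_gt(rms_raw / rms_sm, sqrt(60 / 4))
})

test_that("protocol segmentation labels holds and magnet transits", {
  proto <- rotation_protocol(c(-20, 20), hold = 10, rate = 10,
                             start_turns = 0)
  # transit of the second phase spans 40 turns at 10 turns/s
  expect_equal(proto$transit_end[1] - proto$start_time[1], 2)
  expect_equal(proto$transit_end[2] - proto$start_time[2], 4)
  expect_equal(proto$sense, c("negative", "positive"))

  n <- (max(proto$end_time)) * 60
  tr <- bead_trace(seq(0, by = 1 / 60, length.out = n), rep(0.5, n),
                   sample_rate = 60)
  seg <- segment_protocol(tr, proto)
  expect_setequal(unique(seg$phase), c(1, 2))
  expect_true(all(seg$in_transit[seg$time_s < 2]))
  expect_false(any(seg$in_transit[seg$time_s > 2 & seg$time_s < 12]))

  short <- rotation_protocol(-20, hold = 1)
  expect_error(segment_protocol(tr, short), "cover")
})

test_that("segmentation agrees with the generator's phase bookkeeping", {
  cfg <- synth_config(seed = 11)
  sim <- gen_bead_trace(cfg, n_cycles = 3)
  seg <- segment_protocol(sim$trace, sim$protocol)
  for (i in seq_len(nrow(sim$protocol))) {
    ph <- sim$protocol[i, ]
    sel <- seg$time_s >= ph$start_time & seg$time_s < ph$end_time
    expect_true(all(seg$phase[sel] == ph$phase))
    expect_true(all(seg$sense[sel] == ph$sense))
  }
})

test_that("detected dwells match generated ground truth", {
  # SNR 5: noise SD = step / 5
  step <- 1.9 * 0.05
  cfg <- synth_config(seed = 3, trace = list(noise_sd = step / 5))
  sim <- gen_bead_trace(cfg, n_cycles = 1,
                        true_dwells = list(formation = 4.0,
                                           dissociation = 3.0))
  ev <- detect_rloop_events(smooth_trace(sim$trace), sim$protocol,
                            expected_step = step, um_per_turn = 0.05)
  form <- ev[ev$kind == "formation" & !ev$censored, ]
  expect_equal(nrow(form), 1)
  expect_equal(form$dwell_s, 4.0, tolerance = 0.2 / 4.0)
  expect_true(form$complete)
  expect_equal(form$step_turns, 1.9, tolerance = 0.15)
})

test_that("a flat trace yields no events and one censored dwell per hold", {
  cfg <- synth_config(seed = 5)
  proto <- rotation_protocol(c(-20, 20), hold = c(10, 10), rate = 10)
  n <- max(proto$end_time) * 60
  set.seed(5)
  tr <- bead_trace(seq(0, by = 1 / 60, length.out = n),
                   0.4 + stats::rnorm(n, sd = 0.01), sample_rate = 60)
  ev <- detect_rloop_events(smooth_trace(tr), proto, expected_step = 0.095,
                            um_per_turn = 0.05)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$censored))
  expect_equal(ev$dwell_s, c(10, 10), tolerance = 0.05)
})

test_that("half-size steps are detected but flagged as partial R-loops", {
  # 0.78 captured turns versus the 1.9-turn full R-loop
  cfg <- synth_config(seed = 21, trace = list(rloop_turns = 0.78))
  sim <- gen_bead_trace(cfg, n_cycles = 3,
                        true_dwells = list(formation = c(3, 5, 2),
                                           dissociation = c(2, 1, 4)))
  ev <- detect_rloop_events(smooth_trace(sim$trace), sim$protocol,
                            expected_step = 1.9 * 0.05, um_per_turn = 0.05)
  det <- ev[!ev$censored, ]
  expect_gt(nrow(det), 0)
  expect_true(all(!det$complete))
  expect_equal(mean(det$step_turns), 0.78, tolerance = 0.15)
})

test_that("event kinds never cross supercoiling senses", {
  cfg <- synth_config(seed = 31)
  sim <- gen_bead_trace(cfg, n_cycles = 4)
  ev <- detect_rloop_events(smooth_trace(sim$trace), sim$protocol,
                            expected_step = 0.095, um_per_turn = 0.05)
  sense <- sim$protocol$sense[match(ev$phase, sim$protocol$phase)]
  expect_true(all(ev$kind[sense == "negative"] == "formation"))
  expect_true(all(ev$kind[sense == "positive"] == "dissociation"))
})

test_that("detection recall and false-positive rate hold at SNR 4 over 200 traces", {
  step <- 1.9 * 0.05
  cfg <- synth_config(seed = 1234, trace = list(noise_sd = step / 4))
  n_true <- 0; n_recalled <- 0; n_false <- 0; n_phases <- 0
  for (i in 1:200) {
    sim <- gen_bead_trace(cfg, n_cycles = 1, seed_offset = i)
    ev <- detect_rloop_events(smooth_trace(sim$trace), sim$protocol,
                              expected_step = step, um_per_turn = 0.05)
    truth <- sim$truth[!sim$truth$censored, ]
    det <- ev[!ev$censored, ]
    n_phases <- n_phases + nrow(sim$protocol)
    for (j in seq_len(nrow(truth))) {
      hit <- det$kind == truth$kind[j] &
        abs(det$dwell_s - truth$dwell_s[j]) < 1
      n_recalled <- n_recalled + as.integer(any(hit))
    }
    n_true <- n_true + nrow(truth)
    for (j in seq_len(nrow(det))) {
      real <- truth$kind == det$kind[j] &
        abs(truth$dwell_s - det$dwell_s[j]) < 1
      n_false <- n_false + as.integer(!any(real))
    }
  }
  expect_gte(n_recalled / n_true, 0.95)
  expect_lte(n_false / n_phases, 0.02)
})

test_that("dwell estimates are unbiased on noiseless steps", {
  cfg <- synth_config(seed = 8, trace = list(noise_sd = 0))
  dwells <- c(1.5, 4, 8, 12)
  errs <- vapply(dwells, function(d) {
    sim <- gen_bead_trace(cfg, n_cycles = 1,
                          true_dwells = list(formation = d,
                                             dissociation = 1))
    ev <- detect_rloop_events(smooth_trace(sim$trace), sim$protocol,
                              expected_step = 0.095, um_per_turn = 0.05)
    ev$dwell_s[ev$kind == "formation"] - d
  }, numeric(1))
  # within one frame time plus the (zero-phase) smoothing uncertainty
  expect_lt(abs(mean(errs)), 1 / 60 + 0.05)
})
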