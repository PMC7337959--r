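test_that("two-step closed form satisfies initial condition and symmetric maximum", {
  tc0 <- simulate_two_step(0.1, 0.01, 0)
  expect_equal(unlist(tc0[1, c("sc", "oc", "lin")], use.names = FALSE),
               c(1, 0, 0))
  # equal rates: OC(t) = k t exp(-k t), maximal at t = 1/k with value 1/e
  for (k in c(0.02, 0.2, 1)) {
    tc <- simulate_two_step(k, k, c(1 / k, 2 / k))
    expect_equal(tc$oc[1], exp(-1), tolerance = 1e-12)
    expect_equal(tc$oc[2], 2 * k / k * exp(-2), tolerance = 1e-12)
  }
})

test_that("closed-form two-step matches a fine-step RK4 integrator", {
  times <- c(5, 20, 50)
  got <- simulate_two_step(0.1, 0.01, times)
  oracle <- rk4_two_step(0.1, 0.01, times, h = 0.01)
  expect_lt(max(abs(as.matrix(got[, c("sc", "oc", "lin")]) - oracle)), 1e-6)
})

test_that("three-step solver matches a fine-step RK4 integrator", {
  times <- c(10, 60, 300)
  got <- simulate_three_step(0.01, 0.14, 0.06, times)
  oracle <- rk4_three_step(0.01, 0.14, 0.06, times, h = 0.005)
  expect_lt(max(abs(as.matrix(got[, c("sc", "oc", "lin")]) - oracle)), 1e-6)
})

test_that("three-step converges to two-step when R-loop formation is fast", {
  times <- c(0.1, 1, 5, 20, 50, 100, 300)
  fast <- simulate_three_step(1e6, 0.1, 0.01, times)
  two <- simulate_two_step(0.1, 0.01, times)
  expect_lt(max(abs(as.matrix(fast[, -1]) - as.matrix(two[, -1]))), 1e-4)
  expect_equal(simulate_three_step(0.01, 0.1, 0.05, 0)$sc, 1,
               tolerance = 1e-9)
})

test_that("simulated time courses conserve mass and are monotone", {
  set.seed(42)
  for (i in 1:20) {
    k <- stats::runif(2, 1e-3, 1)
    times <- seq(0, 5 / min(k), length.out = 40)
    tc <- simulate_two_step(k[1], k[2], times)
    expect_lt(max(abs(tc$sc + tc$oc + tc$lin - 1)), 1e-9)
    expect_true(all(diff(tc$sc) < 0))
    expect_true(all(diff(tc$lin) > 0))
  }
})

test_that("fast second-strand cleavage suppresses the nicked intermediate", {
  # k_b >= 50 k_a: OC never accumulates measurably
  times <- seq(0, 2000, length.out = 400)
  for (k_a in c(0.005, 0.05, 0.2)) {
    tc <- simulate_two_step(k_a, 50 * k_a, times)
    expect_lt(max(tc$oc), 0.02)
  }
})

test_that("simulation rejects invalid inputs", {
  expect_error(simulate_two_step(-0.1, 0.01, 1:10), "> 0")
  expect_error(simulate_two_step(0.1, 0, 1:10), "> 0")
  expect_error(simulate_two_step(0.1, 0.01, c(5, 1)), "sorted")
  expect_error(simulate_three_step(0, 0.1, 0.01, 1:10), "> 0")
  expect_error(cleavage_time_course(c(0, 10), c(0.9, 0.5), c(0.2, 0.2),
                                    c(0.2, 0.3)), "sum to 1")
})

test_that("noiseless fits recover both rate constants", {
  times <- c(2, 5, 10, 20, 35, 50, 75, 100, 150, 250, 400, 600)
  tc <- simulate_two_step(0.1, 0.01, times)
  fit <- fit_time_course(tc, kinetic_model_spec("two_step"))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["k_a"]], 0.1, tolerance = 1e-4)
  expect_equal(fit$estimates[["k_b"]], 0.01, tolerance = 1e-4)

  # fixing one parameter at its true value still recovers the other
  fit_fixed <- fit_time_course(tc, kinetic_model_spec(
    "two_step", fixed = list(k_a = 0.1)))
  expect_named(fit_fixed$estimates, "k_b")
  expect_equal(fit_fixed$estimates[["k_b"]], 0.01, tolerance = 1e-4)
})

test_that("three-step refit with the first-strand rate fixed recovers the free rates", {
  times <- c(5, 10, 20, 30, 45, 65, 90, 120, 180, 240, 300)
  tc <- simulate_three_step(0.01, 0.14, 0.06, times)
  fit <- fit_time_course(tc, kinetic_model_spec(
    "three_step", fixed = list(k_a = 0.14)))
  expect_true(fit$converged)
  expect_equal(fit$estimates[["k_formation"]], 0.01, tolerance = 1e-3)
  expect_equal(fit$estimates[["k_b"]], 0.06, tolerance = 1e-3)
})

test_that("counts are normalised per lane before fitting", {
  times <- c(5, 15, 40, 80, 150, 300, 500)
  frac <- simulate_two_step(0.08, 0.02, times)
  counts <- cleavage_time_course(times, frac$sc * 1800, frac$oc * 1800,
                                 frac$lin * 1800, is_fraction = FALSE)
  fit <- fit_time_course(counts, kinetic_model_spec("two_step"))
  expect_equal(fit$estimates[["k_a"]], 0.08, tolerance = 1e-4)
})

test_that("averaging pools converged replicates with n-1 SD", {
  mk <- function(ka, id, conv = TRUE) {
    structure(list(replicate_id = id, estimates = c(k_a = ka, k_b = 0.01),
                   fixed = list(), rss = 0.001, converged = conv,
                   variant = "two_step", fitted = NULL),
              class = "cleavage_fit")
  }
  res <- average_fits(list(mk(0.10, "a"), mk(0.12, "b"), mk(0.14, "c")))
  expect_equal(res$averaged$mean[res$averaged$parameter == "k_a"], 0.12)
  expect_equal(res$averaged$sd[res$averaged$parameter == "k_a"], 0.02)
  expect_equal(res$averaged$n[1], 3)

  # non-converged replicates are excluded
  res2 <- average_fits(list(mk(0.10, "a"), mk(0.99, "bad", conv = FALSE)))
  expect_equal(res2$n_converged, 1)
  expect_true(res2$single_replicate)
  expect_true(is.na(res2$averaged$sd[1]))
  expect_error(average_fits(list(mk(0.1, "a", conv = FALSE))),
               "no converged")
})

test_that("Poisson-count replicates recover the true rates on average", {
  cfg <- synth_config(seed = 7, cleavage = list(
    rates = c(k_a = 0.1, k_b = 0.01), counts_per_lane = 2000,
    times = c(5, 10, 20, 30, 50, 75, 100, 150, 200, 300, 450, 600)))
  fits <- lapply(1:3, function(i) {
    sim <- gen_time_course(cfg, replicate_id = paste0("rep", i),
                           seed_offset = i)
    fit_time_course(sim$time_course, kinetic_model_spec("two_step"))
  })
  res <- average_fits(fits)
  means <- stats::setNames(res$averaged$mean, res$averaged$parameter)
  expect_equal(means[["k_a"]], 0.1, tolerance = 0.15)
  expect_equal(means[["k_b"]], 0.01, tolerance = 0.15)
})

test_that("degenerate and insufficient inputs are rejected", {
  expect_error(fit_time_course(simulate_two_step(0.1, 0.01, c(1, 2)),
                               kinetic_model_spec("two_step")),
               "3 time points")
  expect_error(kinetic_model_spec("two_step", fixed = list(k_q = 1)),
               "fixed parameters")
  expect_error(kinetic_model_spec("two_step", fixed = list(k_a = -1)),
               "> 0")
})
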