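fake_curve <- function(time, surv, n = length(time)) {
  structure(list(time = time, surv = surv, n = n), class = "survival_curve")
}

test_that("empirical survival follows shared-rank arithmetic", {
  cv <- survival_curve(c(1, 2, 3))
  expect_equal(cv$surv, c(2 / 3, 1 / 3, 0))
  # ties share the largest rank: all-equal dwells drop straight to zero
  cv2 <- survival_curve(rep(2.5, 5))
  expect_true(all(cv2$surv == 0))
  expect_equal(cv2$time, rep(2.5, 5))
  # survival is non-increasing from below 1
  cv3 <- survival_curve(c(5, 1, 1, 9, 3))
  expect_true(all(diff(cv3$surv) <= 0))
  expect_lt(cv3$surv[1], 1)
  expect_error(survival_curve(numeric(0)), "empty")
  expect_error(survival_curve(c(1, -2)), ">= 0")
})

test_that("empirical survival of exponential draws matches the binomial bound", {
  set.seed(17)
  tau <- 5
  d <- stats::rexp(1e4, 1 / tau)
  cv <- survival_curve(d)
  s_at_tau <- mean(d > tau)
  expect_lt(abs(s_at_tau - exp(-1)), 1.65 / sqrt(1e4))
  expect_equal(cv$surv[max(which(cv$time <= tau))], s_at_tau,
               tolerance = 1e-12)
})

test_that("single-exponential fit is exact on noiseless survival data", {
  t <- seq(0.1, 20, by = 0.1)
  cv <- fake_curve(t, exp(-t / 3.5), n = 200)
  fit <- fit_exponential(cv, 1)
  expect_equal(fit$tau[["tau"]], 3.5, tolerance = 1e-6)
  expect_equal(fit$mean_dwell, 3.5, tolerance = 1e-6)
})

test_that("two-component fits recover a well-separated mixture", {
  set.seed(2024)
  d <- draw_dwells(5000, list(a = 0.61, tau_slow = 36, tau_fast = 3.5))
  fit <- fit_exponential(survival_curve(d), 2)
  expect_equal(fit$slow_fraction, 0.61, tolerance = 0.05 / 0.61)
  expect_equal(fit$tau[["tau_slow"]], 36, tolerance = 0.15)
  expect_equal(fit$tau[["tau_fast"]], 3.5, tolerance = 0.15)
  expect_gt(fit$tau[["tau_slow"]], fit$tau[["tau_fast"]])
  expect_equal(fit$mean_dwell,
               fit$slow_fraction * fit$tau[["tau_slow"]] +
                 (1 - fit$slow_fraction) * fit$tau[["tau_fast"]])
})

test_that("least-squares and maximum-likelihood backends agree on a mixture", {
  set.seed(7)
  d <- draw_dwells(4000, list(a = 0.5, tau_slow = 30, tau_fast = 3))
  ls <- fit_exponential(survival_curve(d), 2)
  ml <- fit_exponential(survival_curve(d), 2, method = "mle")
  expect_equal(ls$slow_fraction, ml$slow_fraction, tolerance = 0.1)
  expect_equal(ls$tau[["tau_slow"]], ml$tau[["tau_slow"]], tolerance = 0.1)
  expect_equal(ls$tau[["tau_fast"]], ml$tau[["tau_fast"]], tolerance = 0.2)
})

test_that("model selection prefers one component on single-exponential data", {
  set.seed(5)
  d <- stats::rexp(500, 1 / 5)
  cv <- survival_curve(d)
  f1 <- fit_exponential(cv, 1)
  f2 <- fit_exponential(cv, 2)
  chosen <- select_model(f1, f2)
  expect_equal(chosen$n_components, 1L)
  # and two components on a well-separated mixture
  dm <- draw_dwells(1000, list(a = 0.5, tau_slow = 50, tau_fast = 5))
  cvm <- survival_curve(dm)
  chosen_m <- select_model(fit_exponential(cvm, 1), fit_exponential(cvm, 2))
  expect_equal(chosen_m$n_components, 2L)
})

test_that("model-selection ties fall back to the single exponential", {
  f1 <- structure(list(n_components = 1L, aicc = -100, n = 50,
                       converged = TRUE), class = "survival_fit")
  f2 <- structure(list(n_components = 2L, aicc = -100, n = 50,
                       converged = TRUE), class = "survival_fit")
  expect_equal(select_model(f1, f2)$n_components, 1L)
  f2$converged <- FALSE
  expect_equal(select_model(f1, f2)$n_components, 1L)
})

test_that("survival fitting is scale-equivariant", {
  set.seed(12)
  d <- stats::rexp(300, 1 / 4)
  fit <- fit_exponential(survival_curve(d), 1)
  fit_scaled <- fit_exponential(survival_curve(d * 7), 1)
  expect_equal(fit_scaled$tau[["tau"]], 7 * fit$tau[["tau"]],
               tolerance = 1e-6)
})

test_that("slow-fraction recovery holds across amplitudes and separations", {
  combos <- expand.grid(a = c(0.3, 0.5, 0.7), ratio = c(5, 10, 20))
  for (i in seq_len(nrow(combos))) {
    a <- combos$a[i]; ratio <- combos$ratio[i]
    rec <- vapply(1:50, function(s) {
      set.seed(1000 * i + s)
      d <- draw_dwells(2000, list(a = a, tau_slow = 5 * ratio, tau_fast = 5))
      f <- try(fit_exponential(survival_curve(d), 2), silent = TRUE)
      if (inherits(f, "try-error")) NA_real_ else f$slow_fraction
    }, numeric(1))
    expect_lt(abs(stats::median(rec, na.rm = TRUE) - a), 0.05)
  }
})

test_that("concentration dependence recovers power-law exponents", {
  conc <- c(1, 2, 5, 10, 20, 50)
  # exactly second order
  res2 <- concentration_dependence(conc, 0.003 * conc^2)
  expect_equal(res2$exponent, 2, tolerance = 1e-10)
  expect_equal(res2$rate_coefficient, 0.003, tolerance = 1e-8)
  # concentration-independent rates
  res0 <- concentration_dependence(conc, rep(0.4, 6))
  expect_equal(res0$exponent, 0, tolerance = 1e-12)
  # first order with 5% lognormal noise
  set.seed(31)
  noisy <- 0.01 * conc * exp(stats::rnorm(6, sd = 0.05))
  res1 <- concentration_dependence(conc, noisy)
  expect_equal(res1$exponent, 1, tolerance = 0.2)
  expect_error(concentration_dependence(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(concentration_dependence(conc, -0.003 * conc), "> 0")
})

test_that("event-count floors guard under-determined fits", {
  expect_error(fit_exponential(survival_curve(stats::rexp(5)), 1), "N >= 10")
  expect_error(fit_exponential(survival_curve(stats::rexp(15)), 2),
               "N >= 19")
})
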