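# Independent fixed-step Runge-Kutta (RK4) integrator for the sequential
# cleavage schemes; used as an oracle against the package's closed-form and
# adaptive-solver implementations.

rk4_two_step <- function(k_a, k_b, times, h = 0.01) {
  deriv <- function(y) c(-k_a * y[1],
                         k_a * y[1] - k_b * y[2],
                         k_b * y[2])
  integrate_to <- function(y, t0, t1) {
    t <- t0
    while (t < t1 - 1e-12) {
      hh <- min(h, t1 - t)
      k1 <- deriv(y)
      k2 <- deriv(y + hh / 2 * k1)
      k3 <- deriv(y + hh / 2 * k2)
      k4 <- deriv(y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    y
  }
  out <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, c("sc", "oc", "lin")))
  y <- c(1, 0, 0); t_prev <- 0
  for (i in order(times)) {
    y <- integrate_to(y, t_prev, times[i])
    t_prev <- times[i]
    out[i, ] <- y
  }
  out
}

rk4_three_step <- function(k_f, k_a, k_b, times, h = 0.01) {
  deriv <- function(y) c(-k_f * y[1],
                         k_f * y[1] - k_a * y[2],
                         k_a * y[2] - k_b * y[3],
                         k_b * y[3])
  out <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, c("sc", "oc", "lin")))
  y <- c(1, 0, 0, 0); t_prev <- 0
  for (i in order(times)) {
    t <- t_prev
    while (t < times[i] - 1e-12) {
      hh <- min(h, times[i] - t)
      k1 <- deriv(y)
      k2 <- deriv(y + hh / 2 * k1)
      k3 <- deriv(y + hh / 2 * k2)
      k4 <- deriv(y + hh * k3)
      y <- y + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + hh
    }
    t_prev <- times[i]
    out[i, ] <- c(y[1] + y[2], y[3], y[4])  # observed SC = U + R
  }
  out
}
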