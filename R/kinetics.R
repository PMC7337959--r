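# Sequential plasmid-cleavage kinetics: supercoiled (SC) -> open circle (OC)
# -> linear (LIN), optionally preceded by a one-step R-loop formation.

#' Replicate-tagged cleavage time course
#'
#' Container for a single replicate of a plasmid cleavage assay: abundances of
#' supercoiled substrate (SC), nicked open-circle intermediate (OC) and linear
#' product (LIN) at each quenched time point. Abundances may be raw counts
#' (e.g. scintillation counts per excised gel band) or fractions; counts are
#' normalised per time point before fitting.
#'
#' @param times Numeric vector of sampling times in seconds, strictly
#'   increasing, with t = 0 at RNP addition.
#' @param sc,oc,lin Non-negative abundances per time point.
#' @param replicate_id Label for the replicate.
#' @param is_fraction Logical; if `TRUE` the three species must sum to 1
#'   (within 2%) at every time point.
#' @return A data frame of class `cleavage_time_course` with columns
#'   `time_s`, `sc`, `oc`, `lin` and attributes `replicate_id`, `is_fraction`.
#' @export
cleavage_time_course <- function(times, sc, oc, lin, replicate_id = "rep1",
                                 is_fraction = TRUE) {
  stopifnot(length(times) == length(sc), length(sc) == length(oc),
            length(oc) == length(lin))
  if (any(times < 0)) stop("times must be >= 0")
  if (is.unsorted(times, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  if (any(c(sc, oc, lin) < 0)) stop("abundances must be non-negative")
  if (is_fraction) {
    tot <- sc + oc + lin
    if (any(abs(tot - 1) > 0.02)) {
      stop("fractional abundances must sum to 1 (+/- 0.02) per time point")
    }
  }
  out <- data.frame(time_s = times, sc = sc, oc = oc, lin = lin)
  attr(out, "replicate_id") <- replicate_id
  attr(out, "is_fraction") <- is_fraction
  class(out) <- c("cleavage_time_course", "data.frame")
  out
}

#' @export
print.cleavage_time_course <- function(x, ...) {
  cat(sprintf("<cleavage_time_course> replicate %s, %d time points (%s)\n",
              attr(x, "replicate_id"), nrow(x),
              if (isTRUE(attr(x, "is_fraction"))) "fractions" else "counts"))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Kinetic model specification
#'
#' Describes which sequential cleavage model to fit and which rate constants
#' are free or fixed. The `two_step` model is SC -> OC -> LIN with apparent
#' first- and second-strand cleavage rate constants `k_a` and `k_b`. The
#' `three_step` model prepends a one-step R-loop formation, `k_formation`,
#' before first-strand cleavage; R-loop-bound uncut plasmid co-migrates with
#' SC after quenching, so the observed SC abundance is the sum of unbound and
#' R-loop-bound plasmid.
#'
#' @param variant `"two_step"` or `"three_step"`.
#' @param fixed Named list of rate constants (per second) held fixed during
#'   fitting, e.g. `list(k_a = 0.14)`.
#' @param initial_guess Named list of starting values for the free rate
#'   constants; sensible data-driven defaults are used when omitted.
#' @param initial_state Named fractions at t = 0 (default all supercoiled).
#' @param f_active Active substrate fraction in (0, 1]; cleavage assays with
#'   low-specific-activity enzyme preparations do not go to completion, which
#'   can be absorbed by scaling the reactive SC pool. Fixed at 1 by default.
#' @return An object of class `kinetic_model_spec`.
#' @export
kinetic_model_spec <- function(variant = c("two_step", "three_step"),
                               fixed = list(), initial_guess = list(),
                               initial_state = c(sc = 1, oc = 0, lin = 0),
                               f_active = 1) {
  variant <- match.arg(variant)
  pars <- kinetic_parameters(variant)
  if (length(fixed) && !all(names(fixed) %in% pars)) {
    stop("fixed parameters must be among: ", paste(pars, collapse = ", "))
  }
  if (any(unlist(fixed) <= 0)) stop("fixed rate constants must be > 0")
  if (length(initial_guess) && !all(names(initial_guess) %in% pars)) {
    stop("initial_guess parameters must be among: ",
         paste(pars, collapse = ", "))
  }
  if (f_active <= 0 || f_active > 1) stop("f_active must be in (0, 1]")
  stopifnot(all(c("sc", "oc", "lin") %in% names(initial_state)))
  structure(list(variant = variant, fixed = fixed,
                 initial_guess = initial_guess,
                 initial_state = initial_state, f_active = f_active),
            class = "kinetic_model_spec")
}

kinetic_parameters <- function(variant) {
  if (variant == "three_step") c("k_formation", "k_a", "k_b") else
    c("k_a", "k_b")
}

#' Simulate the two-step cleavage model
#'
#' Closed-form (Bateman) solution of SC -> OC -> LIN sequential first-order
#' kinetics. The degenerate branch `k_a == k_b` is handled analytically.
#'
#' @param k_a,k_b First- and second-strand apparent cleavage rate constants
#'   (per second), both > 0.
#' @param times Sorted sampling times in seconds.
#' @param initial_state Named fractions `c(sc=, oc=, lin=)` at t = 0.
#' @param replicate_id Label passed to the returned time course.
#' @return A `cleavage_time_course` of fractions summing to 1 per time point.
#' @export
simulate_two_step <- function(k_a, k_b, times,
                              initial_state = c(sc = 1, oc = 0, lin = 0),
                              replicate_id = "sim") {
  if (k_a <= 0 || k_b <= 0) stop("rate constants must be > 0")
  if (is.unsorted(times)) stop("times must be sorted")
  sc0 <- initial_state[["sc"]]; oc0 <- initial_state[["oc"]]
  lin0 <- initial_state[["lin"]]
  sc <- sc0 * exp(-k_a * times)
  if (abs(k_a - k_b) / k_a < 1e-9) {
    oc <- sc0 * k_a * times * exp(-k_a * times) + oc0 * exp(-k_b * times)
  } else {
    oc <- sc0 * k_a / (k_b - k_a) * (exp(-k_a * times) - exp(-k_b * times)) +
      oc0 * exp(-k_b * times)
  }
  lin <- (sc0 + oc0 + lin0) - sc - oc
  cleavage_time_course(times, sc, oc, lin, replicate_id = replicate_id,
                       is_fraction = TRUE)
}

#' Simulate the three-step cleavage model
#'
#' Unbound plasmid (U) forms an R-loop (R) with rate `k_formation`, then
#' first-strand cleavage `k_a` yields OC and second-strand cleavage `k_b`
#' yields LIN. After quenching, R-loop-bound uncut plasmid co-migrates with
#' supercoiled substrate on the gel, so the reported SC column is U + R.
#' Integrated with an adaptive stiff-capable solver (lsoda, rtol 1e-8).
#'
#' @param k_formation,k_a,k_b Rate constants in per second, all > 0.
#' @param times Sorted sampling times in seconds.
#' @param replicate_id Label passed to the returned time course.
#' @param rtol,atol Solver tolerances.
#' @return A `cleavage_time_course` of fractions (SC = U + R).
#' @export
simulate_three_step <- function(k_formation, k_a, k_b, times,
                                replicate_id = "sim",
                                rtol = 1e-8, atol = 1e-10) {
  if (k_formation <= 0 || k_a <= 0 || k_b <= 0) {
    stop("rate constants must be > 0")
  }
  if (is.unsorted(times)) stop("times must be sorted")
  deriv <- function(t, y, p) {
    list(c(-p[1] * y[1],
           p[1] * y[1] - p[2] * y[2],
           p[2] * y[2] - p[3] * y[3],
           p[3] * y[3]))
  }
  tgrid <- sort(unique(c(0, times)))
  if (length(tgrid) == 1) {
    return(cleavage_time_course(times, rep(1, length(times)),
                                rep(0, length(times)), rep(0, length(times)),
                                replicate_id = replicate_id,
                                is_fraction = TRUE))
  }
  sol <- deSolve::ode(y = c(u = 1, r = 0, oc = 0, lin = 0), times = tgrid,
                      func = deriv, parms = c(k_formation, k_a, k_b),
                      method = "lsoda", rtol = rtol, atol = atol)
  idx <- match(times, tgrid)
  sc <- sol[idx, "u"] + sol[idx, "r"]
  oc <- pmax(sol[idx, "oc"], 0)
  lin <- pmax(sol[idx, "lin"], 0)
  tot <- sc + oc + lin
  cleavage_time_course(times, sc / tot, oc / tot, lin / tot,
                       replicate_id = replicate_id, is_fraction = TRUE)
}

simulate_kinetic_model <- function(pars, variant, times, initial_state,
                                   f_active = 1) {
  tc <- if (variant == "two_step") {
    simulate_two_step(pars[["k_a"]], pars[["k_b"]], times, initial_state)
  } else {
    simulate_three_step(pars[["k_formation"]], pars[["k_a"]], pars[["k_b"]],
                        times)
  }
  if (f_active < 1) {
    # inactive substrate stays supercoiled
    tc$sc <- f_active * tc$sc + (1 - f_active)
    tc$oc <- f_active * tc$oc
    tc$lin <- f_active * tc$lin
  }
  tc
}

normalise_fractions <- function(tc) {
  if (isTRUE(attr(tc, "is_fraction"))) return(tc)
  tot <- tc$sc + tc$oc + tc$lin
  if (any(tot <= 0)) stop("cannot normalise a time point with zero total count")
  cleavage_time_course(tc$time_s, tc$sc / tot, tc$oc / tot, tc$lin / tot,
                       replicate_id = attr(tc, "replicate_id"),
                       is_fraction = TRUE)
}

#' Fit a cleavage model to one replicate time course
#'
#' Least-squares fit of the selected sequential model to the SC, OC and LIN
#' fractions of one replicate, minimising the unweighted sum of squared
#' residuals over all three species jointly. Counts are normalised to
#' fractions per time point first. Free rate constants are log-transformed to
#' enforce positivity and fitted by Levenberg-Marquardt; three starting
#' points (the initial guess and a factor of 10 either side) guard against
#' local minima. A replicate is flagged non-converged when the optimiser
#' fails or a start's best RSS exceeds 5x the overall best.
#'
#' @param tc A [cleavage_time_course()].
#' @param spec A [kinetic_model_spec()]; parameters named in `spec$fixed` are
#'   held at their given values.
#' @return A list of class `cleavage_fit` with elements `replicate_id`,
#'   `estimates` (free parameters), `fixed`, `rss`, `converged`, `variant`,
#'   `fitted` (simulated time course at the estimates).
#' @export
fit_time_course <- function(tc, spec) {
  stopifnot(inherits(tc, "cleavage_time_course"),
            inherits(spec, "kinetic_model_spec"))
  if (nrow(tc) < 3 || diff(range(tc$time_s)) <= 0) {
    stop("need at least 3 time points with nonzero spread")
  }
  tc <- normalise_fractions(tc)
  pars <- kinetic_parameters(spec$variant)
  free <- setdiff(pars, names(spec$fixed))
  if (!length(free)) stop("no free parameters to fit")
  guess <- default_kinetic_guess(tc, free, spec)
  obs <- c(tc$sc, tc$oc, tc$lin)
  residual_fun <- function(logp) {
    full <- c(spec$fixed, as.list(exp(logp)))
    names(full) <- c(names(spec$fixed), free)
    sim <- try(suppressWarnings(
      simulate_kinetic_model(full, spec$variant, tc$time_s,
                             spec$initial_state, spec$f_active)),
      silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(obs)))
    c(sim$sc, sim$oc, sim$lin) - obs
  }
  starts <- lapply(c(0.1, 1, 10), function(f) log(unlist(guess) * f))
  runs <- lapply(starts, function(s) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = residual_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(par = exp(fit$par), rss = fit$deviance, info = fit$info)
  })
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) {
    return(structure(list(replicate_id = attr(tc, "replicate_id"),
                          estimates = stats::setNames(rep(NA_real_,
                                                          length(free)), free),
                          fixed = spec$fixed, rss = NA_real_,
                          converged = FALSE, variant = spec$variant,
                          fitted = NULL),
                     class = "cleavage_fit"))
  }
  rsss <- vapply(runs, `[[`, numeric(1), "rss")
  best <- runs[[which.min(rsss)]]
  # converged = the winning start terminated cleanly; starts whose RSS
  # exceeds 5x the best are treated as failed local minima
  converged <- best$info %in% 1:4
  est <- stats::setNames(as.numeric(best$par), free)
  full <- c(spec$fixed, as.list(est))
  fitted_tc <- simulate_kinetic_model(full, spec$variant, tc$time_s,
                                      spec$initial_state, spec$f_active)
  structure(list(replicate_id = attr(tc, "replicate_id"), estimates = est,
                 fixed = spec$fixed, rss = best$rss, converged = converged,
                 variant = spec$variant, fitted = fitted_tc),
            class = "cleavage_fit")
}

default_kinetic_guess <- function(tc, free, spec) {
  g <- spec$initial_guess
  # crude data-driven scale: time over which SC drops towards 1/e
  t_half <- tc$time_s[which.min(abs(tc$sc - exp(-1) * tc$sc[1]))]
  k0 <- if (t_half > 0) 1 / t_half else 0.1
  defaults <- list(k_formation = k0, k_a = k0, k_b = k0 / 5)
  for (p in free) if (is.null(g[[p]])) g[[p]] <- defaults[[p]]
  g[free]
}

#' @export
print.cleavage_fit <- function(x, ...) {
  cat(sprintf("<cleavage_fit> %s model, replicate %s (%s)\n", x$variant,
              x$replicate_id,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  for (p in names(x$estimates)) {
    cat(sprintf("  %-12s %.5g s^-1\n", p, x$estimates[[p]]))
  }
  for (p in names(x$fixed)) {
    cat(sprintf("  %-12s %.5g s^-1 (fixed)\n", p, x$fixed[[p]]))
  }
  cat(sprintf("  RSS %.4g\n", x$rss))
  invisible(x)
}

#' Average kinetic constants across replicate fits
#'
#' Pools per-replicate fits of the same model, averaging each free rate
#' constant over the converged replicates (arithmetic mean, SD with n - 1
#' denominator). Non-converged replicates are excluded and reported.
#'
#' @param fits List of `cleavage_fit` objects from [fit_time_course()].
#' @return A list of class `kinetic_fit_result` with `per_replicate`,
#'   `averaged` (data frame parameter/mean/sd/n), `variant`, `n_converged`.
#' @export
average_fits <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "cleavage_fit")))
  variants <- unique(vapply(fits, `[[`, character(1), "variant"))
  if (length(variants) != 1) stop("all fits must share the same model")
  par_sets <- lapply(fits, function(f) names(f$estimates))
  if (length(unique(vapply(par_sets, paste, character(1), collapse = ","))) != 1) {
    stop("all fits must share the same free parameters")
  }
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop("no converged replicates to average")
  conv <- fits[ok]
  est <- do.call(rbind, lapply(conv, `[[`, "estimates"))
  avg <- data.frame(
    parameter = colnames(est),
    mean = colMeans(est),
    sd = if (nrow(est) > 1) apply(est, 2, stats::sd) else NA_real_,
    n = nrow(est),
    row.names = NULL)
  structure(list(per_replicate = fits, averaged = avg, variant = variants,
                 n_converged = sum(ok), single_replicate = nrow(est) == 1),
            class = "kinetic_fit_result")
}

#' @export
print.kinetic_fit_result <- function(x, ...) {
  cat(sprintf("<kinetic_fit_result> %s model, %d/%d replicates converged\n",
              x$variant, x$n_converged, length(x$per_replicate)))
  print(x$averaged, row.names = FALSE)
  if (isTRUE(x$single_replicate)) {
    cat("  (single replicate: SD undefined)\n")
  }
  invisible(x)
}
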