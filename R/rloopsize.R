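# R-loop sizing from paired rotation ("hat") curves: flank fits, pairwise
# turn-shift estimation, turns-to-bp calibration and group comparisons.

#' Rotation (hat) curve
#'
#' Mean bead extension versus applied magnet turns, peaked near zero net
#' supercoiling with roughly linear flanks past the buckling transition.
#' Sizing curves are acquired at 1 turn per second; a trapped R-loop shifts
#' the curve along the turn axis by the number of turns it absorbs.
#'
#' @param magnet_turns Applied turns, monotonic along acquisition; >= 10
#'   points.
#' @param extension Mean extension in micrometres.
#' @param curve_id Label.
#' @param condition `"reference"` (no enzyme) or `"rloop_trapped"`.
#' @param rotation_rate Turns per second used for acquisition.
#' @return Data frame of class `rotation_curve` with columns `magnet_turns`,
#'   `extension_um`.
#' @export
rotation_curve <- function(magnet_turns, extension, curve_id = "curve1",
                           condition = c("reference", "rloop_trapped"),
                           rotation_rate = 1) {
  condition <- match.arg(condition)
  stopifnot(length(magnet_turns) == length(extension))
  if (length(magnet_turns) < 10) stop("need at least 10 points")
  d <- diff(magnet_turns)
  if (!(all(d >= 0) || all(d <= 0))) {
    stop("magnet_turns must be monotonic along acquisition")
  }
  out <- data.frame(magnet_turns = magnet_turns, extension_um = extension)
  out <- out[order(out$magnet_turns), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "curve_id") <- curve_id
  attr(out, "condition") <- condition
  attr(out, "rotation_rate") <- rotation_rate
  class(out) <- c("rotation_curve", "data.frame")
  out
}

#' @export
print.rotation_curve <- function(x, ...) {
  cat(sprintf("<rotation_curve> %s (%s): %d points, %g to %g turns\n",
              attr(x, "curve_id"), attr(x, "condition"), nrow(x),
              min(x$magnet_turns), max(x$magnet_turns)))
  invisible(x)
}

#' Fit a line to one flank of a rotation curve
#'
#' Ordinary least squares on the post-buckling flank. Flank points are those
#' at least `apex_margin` turns beyond the curve apex on the requested side
#' and below `plateau_fraction` of the plateau maximum (apex and plateau from
#' a running-median smoothed curve, so single noisy points do not move them).
#'
#' @param curve A [rotation_curve()].
#' @param side `"negative"` (turns below the apex) or `"positive"`.
#' @param plateau_fraction Extension must fall below this fraction of the
#'   plateau maximum to count as flank.
#' @param apex_margin Minimum distance from the apex in turns.
#' @param min_points Minimum flank points required.
#' @param min_slope Minimum absolute slope (micrometres per turn) for the
#'   flank fit to be considered valid; a near-flat fit means plateau points
#'   were selected.
#' @return List with `slope` (um/turn), `intercept` (um at 0 turns),
#'   `r_squared`, `n_points`, `turn_range`, `extension_range`, `side`.
#' @export
fit_linear_flank <- function(curve, side = c("negative", "positive"),
                             plateau_fraction = 0.9, apex_margin = 2,
                             min_points = 5, min_slope = 1e-3) {
  side <- match.arg(side)
  stopifnot(inherits(curve, "rotation_curve"))
  sm <- stats::runmed(curve$extension_um, k = min(7L, nrow(curve) -
                                                    (nrow(curve) + 1) %% 2))
  plateau <- max(sm)
  apex <- curve$magnet_turns[which.max(sm)]
  keep <- if (side == "negative") {
    curve$magnet_turns < apex - apex_margin & sm < plateau_fraction * plateau
  } else {
    curve$magnet_turns > apex + apex_margin & sm < plateau_fraction * plateau
  }
  if (sum(keep) < min_points) {
    stop(sprintf("only %d flank points past the buckling shoulder (need %d)",
                 sum(keep), min_points))
  }
  fit <- stats::lm(extension_um ~ magnet_turns, data = curve[keep, ])
  slope <- unname(stats::coef(fit)[2])
  if (abs(slope) < min_slope) {
    stop("flank fit is nearly flat; plateau points selected, not a flank")
  }
  tss <- sum((curve$extension_um[keep] - mean(curve$extension_um[keep]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::resid(fit)^2) / tss else 1
  list(slope = slope, intercept = unname(stats::coef(fit)[1]),
       r_squared = r2, n_points = sum(keep),
       turn_range = range(curve$magnet_turns[keep]),
       extension_range = range(stats::fitted(fit)), side = side)
}

#' Turn shift between a reference and an R-loop-trapped rotation curve
#'
#' Horizontal offset between the two fitted flank lines, read at the
#' midpoint extension of their overlap so intercept noise averages out.
#' A positive shift means the trapped curve is displaced toward negative
#' applied turns, i.e. the R-loop has absorbed that many turns of unwinding.
#'
#' @param reference Flank fit or [rotation_curve()] without enzyme.
#' @param rloop Flank fit or [rotation_curve()] with a trapped R-loop.
#' @param side Flank side; the negative flank is standard for sizing because
#'   the R-loop is trapped under negative torque.
#' @param max_slope_mismatch Relative slope difference above which the pair
#'   is rejected as an invalid comparison.
#' @param ... Passed to [fit_linear_flank()] when curves are supplied.
#' @return Shift in turns (scalar).
#' @export
estimate_turn_shift <- function(reference, rloop, side = "negative",
                                max_slope_mismatch = 0.2, ...) {
  f_ref <- if (inherits(reference, "rotation_curve")) {
    fit_linear_flank(reference, side, ...)
  } else reference
  f_rl <- if (inherits(rloop, "rotation_curve")) {
    fit_linear_flank(rloop, side, ...)
  } else rloop
  mismatch <- abs(f_ref$slope - f_rl$slope) / abs(f_ref$slope)
  if (mismatch > max_slope_mismatch) {
    stop(sprintf("flank slope mismatch %.0f%% exceeds %.0f%%: invalid pair",
                 100 * mismatch, 100 * max_slope_mismatch))
  }
  lo <- max(min(f_ref$extension_range), min(f_rl$extension_range))
  hi <- min(max(f_ref$extension_range), max(f_rl$extension_range))
  e_mid <- (lo + hi) / 2
  turns_at <- function(f, e) (e - f$intercept) / f$slope
  turns_at(f_ref, e_mid) - turns_at(f_rl, e_mid)
}

#' Aggregate pairwise turn shifts into an R-loop size estimate
#'
#' Compares every reference curve against every R-loop-trapped curve (the
#' standard design uses 20 references x 22 trapped curves = 440 pairs),
#' collecting pairwise shift estimates into a distribution. Invalid pairs
#' (slope mismatch, unusable flanks) are dropped and counted; more than 50%
#' invalid pairs is an error.
#'
#' @param references List of reference [rotation_curve()]s (>= 2).
#' @param rloops List of R-loop-trapped [rotation_curve()]s (>= 2).
#' @param side Flank side for the comparison.
#' @param ... Passed to [fit_linear_flank()].
#' @return Object of class `rloop_size_estimate`: `pairwise_shifts`,
#'   `mean_turns`, `sd_turns`, `n_pairs`, `n_invalid`, `cumulative`
#'   (data frame turns / cumulative probability), `bp` (NA until
#'   [turns_to_bp()] is applied).
#' @export
aggregate_shifts <- function(references, rloops, side = "negative", ...) {
  stopifnot(length(references) >= 2, length(rloops) >= 2)
  f_refs <- lapply(references, function(cv)
    try(fit_linear_flank(cv, side, ...), silent = TRUE))
  f_rls <- lapply(rloops, function(cv)
    try(fit_linear_flank(cv, side, ...), silent = TRUE))
  shifts <- numeric(0)
  n_invalid <- 0L
  for (fr in f_refs) {
    for (fl in f_rls) {
      if (inherits(fr, "try-error") || inherits(fl, "try-error")) {
        n_invalid <- n_invalid + 1L
        next
      }
      s <- try(estimate_turn_shift(fr, fl, side), silent = TRUE)
      if (inherits(s, "try-error")) n_invalid <- n_invalid + 1L
      else shifts <- c(shifts, s)
    }
  }
  n_total <- length(references) * length(rloops)
  if (n_invalid > 0.5 * n_total) {
    stop(sprintf("%d of %d curve pairs invalid (> 50%%)", n_invalid, n_total))
  }
  srt <- sort(shifts)
  cumulative <- data.frame(turns = srt,
                           cum_prob = seq_along(srt) / length(srt))
  structure(list(pairwise_shifts = shifts, mean_turns = mean(shifts),
                 sd_turns = stats::sd(shifts), n_pairs = length(shifts),
                 n_invalid = n_invalid, cumulative = cumulative,
                 bp = NA_real_, calibration_set = NULL),
            class = "rloop_size_estimate")
}

#' @export
print.rloop_size_estimate <- function(x, ...) {
  cat(sprintf("<rloop_size_estimate> %.3g +/- %.2g turns (%d pairs, %d invalid)\n",
              x$mean_turns, x$sd_turns, x$n_pairs, x$n_invalid))
  if (!is.na(x$bp)) cat(sprintf("  %.3g bp (calibrated)\n", x$bp))
  invisible(x)
}

#' Convert a turn-shift estimate to base pairs
#'
#' Linear calibration against full-length R-loop conditions: the mean turn
#' shift of the calibration set is assumed to correspond to the full
#' protospacer length (20 bp by default), and the estimate scales
#' proportionally.
#'
#' @param estimate An [aggregate_shifts()] result (or a bare mean in turns).
#' @param fulllength_estimates Mean turn shifts of the conditions taken to
#'   represent a full-length R-loop, all > 0.
#' @param fulllength_bp Base pairs of the full-length R-loop.
#' @param calibration_set Optional labels of the calibration conditions.
#' @return The estimate with `bp` filled in (or a bare bp value when a bare
#'   mean was supplied).
#' @export
turns_to_bp <- function(estimate, fulllength_estimates, fulllength_bp = 20,
                        calibration_set = NULL) {
  if (!length(fulllength_estimates)) stop("empty calibration set")
  if (any(fulllength_estimates <= 0)) {
    stop("calibration estimates must be > 0")
  }
  cal <- mean(fulllength_estimates)
  if (cal <= 0) stop("non-positive calibration mean")
  if (inherits(estimate, "rloop_size_estimate")) {
    estimate$bp <- fulllength_bp * estimate$mean_turns / cal
    estimate$calibration_set <- calibration_set
    estimate
  } else {
    fulllength_bp * estimate / cal
  }
}

#' Multiple-comparison test of R-loop sizes across gRNA conditions
#'
#' One-way ANOVA across conditions followed by all-pairs Tukey honest
#' significant differences, returning adjusted p-values and mean differences
#' for every condition pair.
#'
#' @param groups Named list of numeric vectors (>= 2 conditions with >= 3
#'   estimates each), e.g. mean turn shifts per condition.
#' @return List with `anova` (the `aov` fit), `tukey` (data frame:
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`), and
#'   `degenerate_groups` (names of zero-variance groups, flagged with a
#'   warning).
#' @export
compare_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be named by condition")
  }
  if (any(vapply(groups, length, integer(1)) < 3)) {
    stop("each condition needs at least 3 estimates")
  }
  degenerate <- names(groups)[vapply(groups, function(g)
    stats::sd(g) == 0, logical(1))]
  if (length(degenerate)) {
    warning("zero-variance group(s): ", paste(degenerate, collapse = ", "))
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    condition = factor(rep(names(groups), lengths(groups))))
  fit <- stats::aov(value ~ condition, data = df)
  tk <- stats::TukeyHSD(fit)$condition
  tukey <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova = fit, tukey = tukey, degenerate_groups = degenerate)
}
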