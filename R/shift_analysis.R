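# Optimal time-shift comparison between two tachometric curves.
#
# One curve f1 is the fixed reference; the test curve f2 is transformed by a
# baseline offset (delta_b), a gain (g) and a time shift (delta_x), and the
# parameters minimizing the mean absolute residual
#   E = < | g * (delta_b + f2(x + delta_x)) - f1(x) | >
# over a stated rPT window are reported. The search is exhaustive over
# delta_x on a 1 ms grid (global in the parameter of interest), with a
# Nelder-Mead inner minimization over (delta_b, g) at each shift and a final
# quadratic refinement of delta_x to sub-ms resolution.

#' Optimal time shift between two curves
#'
#' @param f1 Reference `tachometric_curve` (held fixed).
#' @param f2 Test `tachometric_curve` (shifted/scaled to match `f1`).
#' @param window_ms `c(lo, hi)` rPT window in ms over which the residual is
#'   averaged.
#' @param allow_gain,allow_baseline When `FALSE`, hold `g = 1` and/or
#'   `delta_b = 0` fixed, leaving a pure time-shift comparison.
#' @param shift_range_ms Search bounds for `delta_x` (default ±60 ms).
#' @param min_points Minimum number of window points at which both curves
#'   are defined (default 30); fewer raises a coverage error. Points where
#'   either curve is undefined are dropped from the average, not imputed.
#' @return An object of class `shift_result`: list with `delta_b`, `gain`,
#'   `delta_x_ms`, `error` (mean absolute residual at the optimum),
#'   `rpt_window` and `n_points`.
#' @export
optimal_shift <- function(f1, f2, window_ms,
                          allow_gain = TRUE, allow_baseline = TRUE,
                          shift_range_ms = c(-60, 60), min_points = 30) {
  stopifnot(inherits(f1, "tachometric_curve"),
            inherits(f2, "tachometric_curve"),
            length(window_ms) == 2, window_ms[1] < window_ms[2])
  xw <- seq(window_ms[1], window_ms[2], by = 1)
  y1 <- curve_interp(f1, xw)
  if (sum(!is.na(y1)) < min_points)
    stop("reference curve covers too few window points (",
         sum(!is.na(y1)), " < ", min_points, ") in [",
         window_ms[1], ", ", window_ms[2], "] ms")

  shifts <- seq(shift_range_ms[1], shift_range_ms[2], by = 1)
  eval_shift <- function(dx) {
    y2 <- curve_interp(f2, xw + dx)
    ok <- !is.na(y1) & !is.na(y2)
    if (sum(ok) < min_points) return(NULL)
    fit_gain_baseline(y1[ok], y2[ok], allow_gain, allow_baseline)
  }
  fits <- lapply(shifts, eval_shift)
  errs <- vapply(fits, function(f) if (is.null(f)) NA_real_ else f$error, 0)
  if (all(is.na(errs)))
    stop("test curve never covers the window within the shift search range")
  i_best <- which.min(errs)

  # quadratic refinement around the best 1 ms grid point
  dx <- shifts[i_best]
  if (i_best > 1 && i_best < length(shifts) &&
      !is.na(errs[i_best - 1]) && !is.na(errs[i_best + 1])) {
    e0 <- errs[i_best - 1]; e1 <- errs[i_best]; e2 <- errs[i_best + 1]
    denom <- e0 - 2 * e1 + e2
    if (denom > 1e-12) {
      delta <- 0.5 * (e0 - e2) / denom
      dx <- dx + max(-0.5, min(0.5, delta))
    }
  }
  final <- eval_shift(dx)
  if (is.null(final) || final$error > errs[i_best]) {
    dx <- shifts[i_best]
    final <- fits[[i_best]]
  }
  structure(list(delta_b = final$delta_b, gain = final$gain,
                 delta_x_ms = dx, error = final$error,
                 rpt_window = window_ms, n_points = final$n_points),
            class = "shift_result")
}

# Inner minimization over (delta_b, g) at fixed shift. With both free the
# transform is affine in f2, so Nelder-Mead on two parameters from the
# identity (0, 1) is adequate for this least-absolute-deviations problem.
fit_gain_baseline <- function(y1, y2, allow_gain, allow_baseline) {
  n <- length(y1)
  resid <- function(db, g) mean(abs(g * (db + y2) - y1))
  if (!allow_gain && !allow_baseline) {
    out <- list(delta_b = 0, gain = 1, error = resid(0, 1))
  } else if (allow_gain && !allow_baseline) {
    op <- stats::optimize(function(g) resid(0, g), c(0.05, 20))
    out <- list(delta_b = 0, gain = op$minimum, error = op$objective)
  } else if (!allow_gain && allow_baseline) {
    op <- stats::optimize(function(db) resid(db, 1), c(-1, 1))
    out <- list(delta_b = op$minimum, gain = 1, error = op$objective)
  } else {
    op <- stats::optim(c(0, 1), function(p) resid(p[1], p[2]),
                       method = "Nelder-Mead",
                       control = list(maxit = 400, reltol = 1e-10))
    out <- list(delta_b = op$par[1], gain = op$par[2], error = op$value)
  }
  out$n_points <- n
  out
}

#' Pro- versus antisaccade time-shift comparison
#'
#' Inverts the prosaccade curve about chance (`f -> 1 - f`) so that its
#' early rise above chance becomes an early drop, then runs
#' [optimal_shift()] with the antisaccade curve as the fixed reference over
#' the early departure-from-chance window (55–105 ms by default). Under
#' full independence of the exogenous response from task rules, the optimal
#' shift is zero.
#'
#' @param pro_curve,anti_curve `tachometric_curve`s for the two tasks.
#' @param window_ms rPT window, default `c(55, 105)`.
#' @param ... Passed to [optimal_shift()].
#' @return A `shift_result`.
#' @export
pro_anti_shift <- function(pro_curve, anti_curve, window_ms = c(55, 105),
                           ...) {
  optimal_shift(anti_curve, invert_curve(pro_curve), window_ms, ...)
}

#' @export
print.shift_result <- function(x, ...) {
  cat(sprintf(
    paste0("Optimal curve alignment over [%g, %g] ms (%d points):\n",
           "  delta_x = %.2f ms, gain = %.3f, delta_b = %.4f, ",
           "residual = %.4f\n"),
    x$rpt_window[1], x$rpt_window[2], x$n_points,
    x$delta_x_ms, x$gain, x$delta_b, x$error))
  invisible(x)
}
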