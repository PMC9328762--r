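# Tachometric curves: choice accuracy as a function of raw processing time,
# estimated in overlapping bins slid along the rPT axis in 1 ms steps.

#' Build a tachometric curve
#'
#' Slides a bin of width `bin_width_ms` along the rPT axis in steps of
#' `step_ms`, tallying correct and incorrect trials in each bin. Bins are
#' half-open intervals `[center - w/2, center + w/2)` so that no trial is
#' counted twice at `step_ms == bin_width_ms`. The fraction correct is
#' reported only where a bin holds at least `min_bin_n` trials; 95%
#' confidence intervals are exact (Clopper-Pearson) binomial intervals,
#' which remain well defined at observed fractions of 0 and 1.
#'
#' @param trials A scored trial table (typically urgent-filtered first; see
#'   [filter_urgent()]).
#' @param bin_width_ms Bin width in ms (default 21).
#' @param step_ms Grid spacing in ms (default 1).
#' @param min_bin_n Minimum trials per bin for the point to be defined.
#' @param rpt_range Optional `c(lo, hi)` grid limits in ms; defaults to the
#'   span of the observed rPTs.
#' @param task Optional task label stored as metadata.
#' @return An object of class `tachometric_curve`: a list with `rpt` (grid,
#'   ms), `frac` (fraction correct, `NA` where undefined), `n` (trials per
#'   bin), `ci_low`, `ci_high`, `bin_width_ms` and `task`.
#' @export
tachometric <- function(trials, bin_width_ms = 21, step_ms = 1,
                        min_bin_n = 10, rpt_range = NULL, task = NULL) {
  stopifnot(bin_width_ms > 0, step_ms > 0, min_bin_n >= 1)
  rpt <- trials$rpt_ms
  correct <- trials$correct
  keep <- !is.na(rpt) & !is.na(correct)
  rpt <- rpt[keep]; correct <- correct[keep]
  if (length(rpt) == 0) {
    return(new_tachometric_curve(numeric(0), numeric(0), integer(0),
                                 numeric(0), numeric(0), bin_width_ms, task))
  }
  if (is.null(rpt_range)) {
    rpt_range <- c(floor(min(rpt)), ceiling(max(rpt)))
  }
  grid <- seq(rpt_range[1], rpt_range[2], by = step_ms)
  half <- bin_width_ms / 2
  # cumulative counts over sorted rPTs: O(n log n + grid)
  ord <- order(rpt)
  s_rpt <- rpt[ord]
  cum_n <- seq_along(s_rpt)
  cum_k <- cumsum(as.integer(correct[ord]))
  count_upto <- function(x) findInterval(x, s_rpt, left.open = TRUE)
  # half-open bin [c - half, c + half): trials with c - half <= rpt < c + half
  i_hi <- count_upto(grid + half - 1e-9)   # rpt <  c + half
  i_lo <- count_upto(grid - half - 1e-9)   # rpt <  c - half
  n <- i_hi - i_lo
  k <- ifelse(i_hi > 0, cum_k[pmax(i_hi, 1)], 0L) -
       ifelse(i_lo > 0, cum_k[pmax(i_lo, 1)], 0L)
  defined <- n >= min_bin_n
  frac <- ifelse(defined, k / n, NA_real_)
  ci <- binom_ci_exact(k, n)
  ci$low[!defined] <- NA_real_
  ci$high[!defined] <- NA_real_
  new_tachometric_curve(grid, frac, n, ci$low, ci$high, bin_width_ms, task)
}

# Exact (Clopper-Pearson) 95% binomial interval via beta quantiles.
binom_ci_exact <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, pmax(n - k, 0)))
  low[n == 0] <- NA_real_
  high[n == 0] <- NA_real_
  list(low = low, high = high)
}

new_tachometric_curve <- function(rpt, frac, n, ci_low, ci_high,
                                  bin_width_ms, task = NULL,
                                  metadata = list()) {
  structure(
    list(rpt = as.numeric(rpt), frac = as.numeric(frac), n = as.integer(n),
         ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
         bin_width_ms = bin_width_ms, task = task, metadata = metadata),
    class = "tachometric_curve"
  )
}

#' Construct a tachometric curve from explicit values
#'
#' Useful for building analytic reference curves (e.g. an evaluated sigmoid)
#' that downstream operations such as [optimal_shift()] accept.
#'
#' @param rpt Grid in ms.
#' @param frac Fraction correct per grid point (`NA` allowed).
#' @param n Trial counts per point (defaults to a large constant).
#' @param bin_width_ms,task Metadata.
#' @return A `tachometric_curve`.
#' @export
as_tachometric_curve <- function(rpt, frac, n = rep(1000L, length(rpt)),
                                 bin_width_ms = 21, task = NULL) {
  stopifnot(length(rpt) == length(frac))
  ci <- binom_ci_exact(round(frac * n), n)
  new_tachometric_curve(rpt, frac, n, ci$low, ci$high, bin_width_ms, task)
}

#' Invert a curve about its accuracy axis
#'
#' Applies `f(x) -> 1 - f(x)` pointwise; the confidence limits are swapped
#' and reflected. Chance-level points (0.5) are fixed points, so inversion
#' maps an early rise above chance onto an early drop below it.
#'
#' @param curve A `tachometric_curve`.
#' @return The inverted `tachometric_curve`.
#' @export
invert_curve <- function(curve) {
  stopifnot(inherits(curve, "tachometric_curve"))
  new_tachometric_curve(curve$rpt, 1 - curve$frac, curve$n,
                        1 - curve$ci_high, 1 - curve$ci_low,
                        curve$bin_width_ms, curve$task,
                        c(curve$metadata, list(inverted = TRUE)))
}

#' @export
print.tachometric_curve <- function(x, ...) {
  ndef <- sum(!is.na(x$frac))
  cat("Tachometric curve", if (!is.null(x$task)) paste0("(", x$task, ")"),
      "\n  grid:", length(x$rpt), "points,",
      if (length(x$rpt)) paste0("[", min(x$rpt), ", ", max(x$rpt), "] ms"),
      "\n  defined points:", ndef,
      "\n  bin width:", x$bin_width_ms, "ms\n")
  invisible(x)
}

#' @export
as.data.frame.tachometric_curve <- function(x, ...) {
  data.frame(rpt = x$rpt, frac = x$frac, n = x$n,
             ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Write / read a curve as CSV
#'
#' Columns `rpt, frac, n, ci_low, ci_high`; bin width stored in a `#`
#' comment line.
#'
#' @param curve A `tachometric_curve`.
#' @param path File path.
#' @return `path` invisibly (write); a `tachometric_curve` (read).
#' @export
write_curve <- function(curve, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_width_ms=%s task=%s", curve$bin_width_ms,
                     if (is.null(curve$task)) "NA" else curve$task), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  header <- readLines(path, n = 1)
  bin <- 21
  task <- NULL
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("bin_width_ms=([0-9.]+) task=(\\S+)", header))[[1]]
    if (length(m) == 3) {
      bin <- as.numeric(m[2])
      if (m[3] != "NA") task <- m[3]
    }
  }
  df <- utils::read.csv(path, comment.char = "#")
  new_tachometric_curve(df$rpt, df$frac, df$n, df$ci_low, df$ci_high, bin, task)
}

# Linear interpolation between adjacent defined grid points; NA outside the
# grid and NA wherever a bracketing grid point is undefined (gaps are not
# imputed).
curve_interp <- function(curve, x) {
  rpt <- curve$rpt
  frac <- curve$frac
  if (length(rpt) < 2) return(rep(NA_real_, length(x)))
  i <- findInterval(x, rpt)
  out <- rep(NA_real_, length(x))
  at_node <- i >= 1 & i <= length(rpt) & !is.na(i) & x == rpt[pmax(i, 1)]
  out[at_node] <- frac[i[at_node]]
  inside <- i >= 1 & i < length(rpt) & !at_node & !is.na(i)
  if (any(inside)) {
    i0 <- i[inside]
    f0 <- frac[i0]; f1 <- frac[i0 + 1]
    w <- (x[inside] - rpt[i0]) / (rpt[i0 + 1] - rpt[i0])
    out[inside] <- f0 + w * (f1 - f0)   # NA if either endpoint undefined
  }
  out
}
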