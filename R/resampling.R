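# Trial-level bootstrap for curve-derived statistics and permutation tests
# for cross-participant correlations.

#' Bootstrap a trial-table statistic
#'
#' Resamples trials with replacement (trial-wise, matching how the curves
#' are estimated), recomputes `statistic` on each resample and returns the
#' percentile confidence interval (2.5/97.5 by default). Iterations use a
#' prefix-stable seed stream: increasing `n_iter` extends the sequence of
#' resamples without changing the earlier ones.
#'
#' @param trials A trial table (any data.frame; rows are the resampling
#'   unit).
#' @param statistic Function mapping a trial table to a single number, e.g.
#'   `function(tr) rise_point(fit_pro(tachometric(tr)))`.
#' @param n_iter Number of bootstrap iterations (default 2000).
#' @param seed Integer master seed.
#' @param level Confidence level (default 0.95).
#' @return An object of class `bootstrap_result`: list with
#'   `point_estimate`, `samples` (length `n_iter`; `NA` where the refit
#'   failed), `ci_low`, `ci_high`, `n_iter`, `n_failed`, `unreliable`
#'   (TRUE when more than 20% of iterations failed) and `seed`.
#' @export
bootstrap_stat <- function(trials, statistic, n_iter = 2000, seed = NULL,
                           level = 0.95) {
  stopifnot(is.data.frame(trials), nrow(trials) >= 1, n_iter >= 1)
  point <- statistic(trials)
  if (!is.null(seed)) set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1, n_iter)
  n <- nrow(trials)
  samples <- vapply(seq_len(n_iter), function(i) {
    set.seed(iter_seeds[i])
    idx <- sample.int(n, n, replace = TRUE)
    out <- tryCatch(suppressWarnings(statistic(trials[idx, , drop = FALSE])),
                    error = function(e) NA_real_)
    if (length(out) != 1 || !is.numeric(out)) NA_real_ else as.numeric(out)
  }, numeric(1))
  n_failed <- sum(is.na(samples))
  ok <- samples[!is.na(samples)]
  alpha <- 1 - level
  ci <- if (length(ok) > 0)
    stats::quantile(ok, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                    type = 7)
  else c(NA_real_, NA_real_)
  structure(list(point_estimate = point, samples = samples,
                 ci_low = ci[1], ci_high = ci[2], n_iter = n_iter,
                 n_failed = n_failed,
                 unreliable = n_failed > 0.2 * n_iter, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap (%d iterations%s): %.4g, 95%% CI [%.4g, %.4g]%s\n",
    x$n_iter,
    if (x$n_failed > 0) paste0(", ", x$n_failed, " failed") else "",
    x$point_estimate, x$ci_low, x$ci_high,
    if (x$unreliable) " [UNRELIABLE: >20% failed refits]" else ""))
  invisible(x)
}

#' Permutation test for a Pearson correlation
#'
#' Computes the Pearson correlation of paired observations and its
#' two-sided significance by randomly re-pairing `y` against `x` `n_perm`
#' times. The p value uses add-one smoothing,
#' `p = (1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`, so it is never
#' exactly zero.
#'
#' @param x,y Numeric vectors of equal length (>= 3), one value per
#'   participant.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @return List with `rho`, `p`, `n`, `n_perm`.
#' @export
permutation_correlation <- function(x, y, n_perm = 10000, seed = NULL) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in x or y")
  rho <- stats::cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  perm <- vapply(seq_len(n_perm),
                 function(i) stats::cor(x, y[sample.int(n)]),
                 numeric(1))
  p <- (1 + sum(abs(perm) >= abs(rho))) / (n_perm + 1)
  list(rho = rho, p = p, n = n, n_perm = n_perm)
}
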