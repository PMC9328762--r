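# Analytic psychometric functions fitted to tachometric curves by mean
# absolute error (MAE), and the timing landmarks derived from them.
#
# Prosaccade curves are fitted with a single rising sigmoid whose midpoint C
# is the rise point. Antisaccade curves are fitted with the pointwise
# maximum of a falling sigmoid (left limb), a rising sigmoid (right limb)
# and zero; the left midpoint CL is the drop point and the right midpoint CR
# is the rise point. MAE is non-smooth, so minimization uses the
# derivative-free Nelder-Mead simplex with several jittered restarts from
# moment-based initial guesses.

#' Rising sigmoid (prosaccade psychometric function)
#'
#' `s(x) = B + (A - B) / (1 + exp(-(x - C)/D))`, where `B` is the chance
#' baseline, `A` the asymptote, `C` the rise point (accuracy halfway between
#' `B` and `A`) and `D` the slope scale in ms.
#'
#' @param x rPT values in ms.
#' @param A,B,C,D Parameters.
#' @return Function values.
#' @export
sigmoid_pro <- function(x, A, B, C, D) {
  B + (A - B) / (1 + exp(-(x - C) / D))
}

#' Drop-recover function (antisaccade psychometric function)
#'
#' `v(x) = max(sL(x), sR(x), 0)` with a falling limb
#' `sL(x) = BLR + (AL - BLR) / (1 + exp((x - CL)/DL))` that descends from
#' the chance level `AL` to the shared minimum `BLR`, and a rising limb
#' `sR(x) = BLR + (AR - BLR) / (1 + exp(-(x - CR)/DR))` that climbs from
#' `BLR` to the asymptote `AR`. `CL` (drop point) is where accuracy is
#' halfway between `AL` and `BLR`; `CR` (rise point) is halfway between
#' `BLR` and `AR`.
#'
#' @param x rPT values in ms.
#' @param AL,AR,BLR,CL,CR,DL,DR Parameters.
#' @return Function values.
#' @export
sigmoid_anti <- function(x, AL, AR, BLR, CL, CR, DL, DR) {
  sL <- BLR + (AL - BLR) / (1 + exp((x - CL) / DL))
  sR <- BLR + (AR - BLR) / (1 + exp(-(x - CR) / DR))
  pmax(sL, sR, 0)
}

# Evaluate an expression with the global RNG stream saved and restored, so
# fits are deterministic without perturbing the caller's stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

curve_xy <- function(curve) {
  stopifnot(inherits(curve, "tachometric_curve"))
  ok <- !is.na(curve$frac)
  x <- curve$rpt[ok]
  y <- curve$frac[ok]
  ord <- order(x)   # sorted grid: fits are invariant to point order
  list(x = x[ord], y = y[ord])
}

mae_of <- function(pred, y) mean(abs(pred - y))

#' Fit the rising sigmoid to a tachometric curve
#'
#' Minimizes the mean absolute error between the curve's defined grid
#' points (equally weighted; gaps are not interpolated) and [sigmoid_pro()].
#' With `fix_chance = TRUE` the baseline is frozen at `B = 0.5`; free it
#' when analyzing bias-conditioned curves whose guessing baseline deviates
#' from chance. A fit whose dynamic range `A - B` is below 0.05 is flagged
#' degenerate and its rise point is reported as `NA`.
#'
#' @param curve A `tachometric_curve` with at least 20 defined points.
#' @param fix_chance Freeze `B` at 0.5? Default `TRUE`.
#' @param n_restarts Number of jittered optimizer restarts (default 10).
#' @param init Optional named list overriding the initial guess.
#' @return An object of class `pro_fit`: list with `A`, `B`, `C`, `D`,
#'   `mae`, `degenerate`, `fix_chance`.
#' @export
fit_pro <- function(curve, fix_chance = TRUE, n_restarts = 10, init = NULL) {
  d <- curve_xy(curve)
  if (length(d$x) < 20)
    stop("need at least 20 defined curve points to fit")
  x <- d$x; y <- d$y

  B0 <- if (fix_chance) 0.5 else clamp01(mean(y[x <= stats::quantile(x, 0.15)]))
  if (!is.finite(B0)) B0 <- 0.5
  A0 <- clamp01(max(y))
  C0 <- midpoint_crossing(x, y, (A0 + B0) / 2, rising = TRUE)
  if (!is.finite(C0)) C0 <- stats::median(x)
  D0 <- 10

  # theta: [qlogis(A), C, log(D)] (+ qlogis(B) when free)
  pack <- function(A, B, C, D) {
    th <- c(stats::qlogis(clamp01(A)), C, log(D))
    if (!fix_chance) th <- c(th, stats::qlogis(clamp01(B)))
    th
  }
  unpack <- function(th) {
    list(A = stats::plogis(th[1]), C = th[2], D = exp(th[3]),
         B = if (fix_chance) 0.5 else stats::plogis(th[4]))
  }
  # soft box constraints: the midpoint must lie within the measured range
  # and the slope scale must keep curvature inside it, otherwise the limb
  # flattens and the baseline becomes unidentifiable
  span <- diff(range(x))
  obj <- function(th) {
    p <- unpack(th)
    mae_of(sigmoid_pro(x, p$A, p$B, p$C, p$D), y) +
      1e-3 * (max(0, min(x) - p$C) + max(0, p$C - max(x)) +
              max(0, p$D - span / 4))
  }
  th0 <- pack(if (is.null(init$A)) A0 else init$A,
              if (is.null(init$B)) B0 else init$B,
              if (is.null(init$C)) C0 else init$C,
              if (is.null(init$D)) D0 else init$D)
  best <- run_restarts(obj, th0, n_restarts,
                       jitter_sd = c(0.4, 15, 0.4, if (!fix_chance) 0.4))
  p <- unpack(best$par)
  mae <- mae_of(sigmoid_pro(x, p$A, p$B, p$C, p$D), y)
  degenerate <- (p$A - p$B) < 0.05
  if (degenerate)
    warning("degenerate fit: dynamic range < 0.05; rise point undefined")
  structure(list(A = p$A, B = p$B, C = if (degenerate) NA_real_ else p$C,
                 D = p$D, mae = mae, degenerate = degenerate,
                 fix_chance = fix_chance),
            class = "pro_fit")
}

#' Fit the drop-recover function to a tachometric curve
#'
#' Minimizes MAE between the curve and [sigmoid_anti()]. With
#' `fix_chance = TRUE` the chance plateau is frozen at `AL = 0.5`; free it
#' (together with the other parameters, which always vary) for
#' bias-conditioned curves. `CR` is parameterized as `CL + exp(g)` so the
#' drop point always precedes the rise point. Curves without a discernible
#' drop (dynamic range `AL - BLR < 0.05`) are flagged degenerate with `CL`
#' reported as `NA`.
#'
#' @inheritParams fit_pro
#' @return An object of class `anti_fit`: list with `AL`, `AR`, `BLR`,
#'   `CL`, `CR`, `DL`, `DR`, `mae`, `degenerate`, `fix_chance`.
#' @export
fit_anti <- function(curve, fix_chance = TRUE, n_restarts = 10, init = NULL) {
  d <- curve_xy(curve)
  if (length(d$x) < 20)
    stop("need at least 20 defined curve points to fit")
  x <- d$x; y <- d$y

  i_min <- which.min(stats::filter(y, rep(1 / 5, 5), sides = 2))
  if (length(i_min) == 0 || is.na(i_min)) i_min <- which.min(y)
  x_min <- x[i_min]
  BLR0 <- clamp01(min(y))
  AL0 <- if (fix_chance) 0.5 else {
    left <- y[x < x_min - 20]
    clamp01(if (length(left) >= 3) mean(left) else 0.5)
  }
  AR0 <- clamp01(max(y[x > x_min]))
  CL0 <- midpoint_crossing(x[x <= x_min], y[x <= x_min],
                           (AL0 + BLR0) / 2, rising = FALSE)
  CR0 <- midpoint_crossing(x[x >= x_min], y[x >= x_min],
                           (AR0 + BLR0) / 2, rising = TRUE)
  if (!is.finite(CL0)) CL0 <- x_min - 20
  if (!is.finite(CR0)) CR0 <- x_min + 30
  if (CR0 <= CL0) CR0 <- CL0 + 30

  # theta: [qlogis(AR), qlogis(BLR), CL, log(CR - CL), log(DL), log(DR)]
  #        (+ free AL when fix_chance = FALSE). The free chance plateau is
  #        parameterized as AL = BLR + (1 - BLR) * plogis(theta7) so the
  #        falling limb always descends (AL >= BLR); without this the
  #        optimizer can invert the limb and lose the chance level.
  pack <- function(AL, AR, BLR, CL, CR, DL, DR) {
    th <- c(stats::qlogis(clamp01(AR)), stats::qlogis(clamp01(BLR)),
            CL, log(CR - CL), log(DL), log(DR))
    if (!fix_chance)
      th <- c(th, stats::qlogis(clamp01((AL - BLR) / max(1 - BLR, 1e-3))))
    th
  }
  unpack <- function(th) {
    BLR <- stats::plogis(th[2])
    list(AR = stats::plogis(th[1]), BLR = BLR,
         CL = th[3], CR = th[3] + exp(th[4]),
         DL = exp(th[5]), DR = exp(th[6]),
         AL = if (fix_chance) 0.5
              else BLR + (1 - BLR) * stats::plogis(th[7]))
  }
  # soft box constraints as in fit_pro: both midpoints inside the measured
  # range, slope scales bounded by a quarter of the span. Without these an
  # unbounded DL lets the left limb collapse to a constant, leaving the
  # chance parameter AL unidentified on plateau-heavy curves.
  span <- diff(range(x))
  obj <- function(th) {
    p <- unpack(th)
    mae_of(sigmoid_anti(x, p$AL, p$AR, p$BLR, p$CL, p$CR, p$DL, p$DR), y) +
      1e-3 * (max(0, min(x) - p$CL) + max(0, p$CL - max(x)) +
              max(0, min(x) - p$CR) + max(0, p$CR - max(x)) +
              max(0, p$DL - span / 4) + max(0, p$DR - span / 4))
  }
  ini <- function(name, default) if (is.null(init[[name]])) default else init[[name]]
  th0 <- pack(ini("AL", AL0), ini("AR", AR0), ini("BLR", BLR0),
              ini("CL", CL0), ini("CR", CR0), ini("DL", 5), ini("DR", 10))
  best <- run_restarts(obj, th0, n_restarts,
                       jitter_sd = c(0.4, 0.4, 10, 0.3, 0.3, 0.3,
                                     if (!fix_chance) 0.4))
  p <- unpack(best$par)
  mae <- mae_of(sigmoid_anti(x, p$AL, p$AR, p$BLR, p$CL, p$CR, p$DL, p$DR), y)
  degenerate <- (p$AL - p$BLR) < 0.05
  if (degenerate)
    warning("degenerate fit: drop range < 0.05; drop point undefined")
  structure(list(AL = p$AL, AR = p$AR, BLR = p$BLR,
                 CL = if (degenerate) NA_real_ else p$CL,
                 CR = p$CR, DL = p$DL, DR = p$DR,
                 mae = mae, degenerate = degenerate,
                 fix_chance = fix_chance),
            class = "anti_fit")
}

clamp01 <- function(p, eps = 1e-3) pmin(pmax(p, eps), 1 - eps)

# x where a (noisy) curve first crosses level `mid` going up (rising) or
# down (falling), using a 5-point running mean to stabilize the estimate.
midpoint_crossing <- function(x, y, mid, rising = TRUE) {
  if (length(x) < 5) return(NA_real_)
  ys <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  hit <- if (rising) which(ys >= mid) else which(ys <= mid)
  if (length(hit) == 0) return(NA_real_)
  x[hit[1]]
}

run_restarts <- function(obj, th0, n_restarts, jitter_sd) {
  with_local_seed(20221101L, {
    best <- stats::optim(th0, obj, method = "Nelder-Mead",
                         control = list(maxit = 800, reltol = 1e-9))
    if (n_restarts > 1) {
      for (i in seq_len(n_restarts - 1)) {
        th <- th0 + stats::rnorm(length(th0), 0, jitter_sd)
        fit <- stats::optim(th, obj, method = "Nelder-Mead",
                            control = list(maxit = 800, reltol = 1e-9))
        if (fit$value < best$value) best <- fit
      }
    }
    # polish from the incumbent
    best2 <- stats::optim(best$par, obj, method = "Nelder-Mead",
                          control = list(maxit = 800, reltol = 1e-10))
    if (best2$value < best$value) best <- best2
    best
  })
}

#' Timing landmarks of a fitted psychometric function
#'
#' `rise_point()` returns the rPT at which accuracy climbs halfway to its
#' asymptote: `C` for a prosaccade fit, `CR` for an antisaccade fit.
#' `drop_point()` returns `CL`, the rPT at which antisaccade accuracy falls
#' halfway from chance to its minimum (undefined for prosaccade fits).
#'
#' @param fit A `pro_fit` or `anti_fit`.
#' @return Time in ms (`NA` for degenerate fits).
#' @export
rise_point <- function(fit) UseMethod("rise_point")

#' @export
rise_point.pro_fit <- function(fit) fit$C

#' @export
rise_point.anti_fit <- function(fit) fit$CR

#' @rdname rise_point
#' @export
drop_point <- function(fit) UseMethod("drop_point")

#' @export
drop_point.anti_fit <- function(fit) fit$CL

#' @export
drop_point.pro_fit <- function(fit) {
  stop("drop point is defined only for antisaccade (drop-recover) fits")
}

#' Chance level of a fit
#'
#' The guessing-regime baseline: `B` for prosaccade fits, `AL` for
#' antisaccade fits. Equal to 0.5 unless the fit freed the chance
#' parameter.
#'
#' @param fit A `pro_fit` or `anti_fit`.
#' @return Chance level in `[0, 1]`.
#' @export
chance_level <- function(fit) UseMethod("chance_level")

#' @export
chance_level.pro_fit <- function(fit) fit$B

#' @export
chance_level.anti_fit <- function(fit) fit$AL

#' Evaluate a fitted psychometric function
#'
#' @param object A `pro_fit` or `anti_fit`.
#' @param x rPT values in ms.
#' @param ... Unused.
#' @return Predicted fraction correct.
#' @export
predict.pro_fit <- function(object, x, ...) {
  sigmoid_pro(x, object$A, object$B, object$C, object$D)
}

#' @rdname predict.pro_fit
#' @export
predict.anti_fit <- function(object, x, ...) {
  sigmoid_anti(x, object$AL, object$AR, object$BLR,
               object$CL, object$CR, object$DL, object$DR)
}

#' @export
print.pro_fit <- function(x, ...) {
  cat(sprintf(
    "Prosaccade sigmoid fit: A=%.3f B=%.3f C=%.1f ms D=%.1f ms (MAE %.4f)%s\n",
    x$A, x$B, x$C, x$D, x$mae, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' @export
print.anti_fit <- function(x, ...) {
  cat(sprintf(
    paste0("Antisaccade drop-recover fit: AL=%.3f AR=%.3f BLR=%.3f ",
           "CL=%.1f CR=%.1f DL=%.1f DR=%.1f (MAE %.4f)%s\n"),
    x$AL, x$AR, x$BLR, x$CL, x$CR, x$DL, x$DR, x$mae,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
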