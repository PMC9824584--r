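#' Second-stage diagnostic F(t, beta)
#'
#' `F = -t / log(1 - Rtilde^(1/beta))`.  If the normalized size follows the
#' coil-expansion master curve with the same beta, F is constant and equal
#' to tau_c; too small a beta makes F increase with t, too large a beta
#' makes it decrease.  Values with `Rtilde >= 1` (divergent logarithm) are
#' masked as `NA`.
#'
#' @param t times (> 0 for a finite value).
#' @param Rtilde normalized size R/RF, in (0, 1).
#' @param beta trial exponent.
#' @return F values (same length as t), `NA` where undefined.
#' @export
diagnostic_F <- function(t, Rtilde, beta) {
  out <- rep(NA_real_, length(t))
  ok <- is.finite(Rtilde) & Rtilde > 0 & Rtilde < 1
  out[ok] <- -t[ok] / log(1 - Rtilde[ok]^(1 / beta))
  out
}

#' Second-stage diagnostic G(t, tau_c)
#'
#' `G = log(1 - exp(-t/tau_c)) / log(Rtilde)`; converges to 1/beta (about
#' 5) when the curve follows the master law with the assumed tau_c.
#'
#' @param t times.
#' @param Rtilde normalized size in (0, 1).
#' @param tau_c assumed characteristic time.
#' @return G values, `NA` where the logs are undefined.
#' @export
diagnostic_G <- function(t, Rtilde, tau_c) {
  out <- rep(NA_real_, length(t))
  ok <- is.finite(Rtilde) & Rtilde > 0 & Rtilde < 1 & t > 0
  out[ok] <- log(1 - exp(-t[ok] / tau_c)) / log(Rtilde[ok])
  out
}

#' First-stage diagnostic H(t, tau_s)
#'
#' `H = log(Rprime) / log(1 + t/tau_s)`; converges to alpha when the early
#' expansion follows the spherical-swelling law with the assumed tau_s.
#' The first point (t = 0, Rprime = 1) is undefined and masked.
#'
#' @param t times.
#' @param Rprime size normalized by the initial value, R/R0 (> 1 for a
#'   finite value).
#' @param tau_s assumed first-stage characteristic time.
#' @return H values, `NA` where undefined.
#' @export
diagnostic_H <- function(t, Rprime, tau_s) {
  out <- rep(NA_real_, length(t))
  ok <- is.finite(Rprime) & Rprime > 0 & t > 0
  out[ok] <- log(Rprime[ok]) / log(1 + t[ok] / tau_s)
  out
}

.fit_result <- function(estimate, stderr, window, iterations, converged,
                        residual_norm) {
  structure(list(estimate = estimate, stderr = stderr, window = window,
                 iterations = iterations, converged = converged,
                 residual_norm = residual_norm),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit result", if (!x$converged) "(NOT converged)", "\n")
  for (nm in names(x$estimate))
    cat(sprintf("  %-6s %.6g +/- %.3g\n", nm, x$estimate[[nm]],
                x$stderr[[nm]]))
  cat(sprintf("  window [%.4g, %.4g], %d iterations\n",
              x$window[1], x$window[2], x$iterations))
  invisible(x)
}

#' Single-parameter fit of the coil-expansion time tau_c
#'
#' Least-squares fit of `R/RF = (1 - exp(-t/tau_c))^beta` restricted to the
#' large-time regime `t > 0.3 * tau_c`; because the window depends on the
#' estimate, the fit is iterated until the estimate is self-consistent
#' (relative change < 0.1%).  Levenberg-Marquardt via minpack.lm.
#'
#' @param times sample times.
#' @param R ensemble size curve R(t).
#' @param RF final size (see [estimate_RF()]).
#' @param beta fixed exponent (1/5).
#' @param weights optional per-point weights (e.g. 1/stderr^2).
#' @param max_iter window-iteration limit.
#' @return A `fit_result` with estimate `tau_c`.
#' @export
fit_stage2 <- function(times, R, RF, beta = 1 / 5, weights = NULL,
                       max_iter = 50) {
  rt <- R / RF
  ok <- is.finite(rt) & rt > 0 & rt < 1 & times > 0
  # initial guess: time at which the master curve reaches (1-e^-1)^beta
  i0 <- which.min(abs(rt - (1 - exp(-1))^beta))
  tau <- max(times[i0], min(times[times > 0]))
  converged <- FALSE
  iter <- 0
  fit <- NULL
  tau_hist <- numeric(0)
  for (iter in seq_len(max_iter)) {
    win <- ok & times > 0.3 * tau
    if (sum(win) < 3) break
    df <- data.frame(t = times[win], y = rt[win])
    w <- if (is.null(weights)) rep(1, sum(win)) else weights[win]
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ (1 - exp(-t / tau_c))^beta, data = df,
                        start = list(tau_c = tau), weights = w,
                        control = nls.control(maxiter = 200,
                                              warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) break
    new_tau <- coef(fit)[["tau_c"]]
    if (abs(new_tau - tau) < 1e-3 * tau) {
      tau <- new_tau
      # self-consistency also demands the data reach beyond the window edge
      converged <- max(times[ok]) > 0.3 * tau
      break
    }
    if (length(tau_hist) >= 2 &&
        abs(new_tau - tau_hist[length(tau_hist) - 1]) < 1e-3 * new_tau) {
      # the discrete window edge hops one sample point back and forth:
      # a two-cycle, not a divergence; settle on the cycle mean
      tau <- (new_tau + tau) / 2
      converged <- max(times[ok]) > 0.3 * tau
      break
    }
    tau_hist <- c(tau_hist, new_tau)
    tau <- new_tau
  }
  if (is.null(fit))
    return(.fit_result(list(tau_c = tau), list(tau_c = NA_real_),
                       c(0.3 * tau, max(times)), iter, FALSE, NA_real_))
  se <- tryCatch(sqrt(diag(vcov(fit)))[["tau_c"]], error = function(e) NA_real_)
  .fit_result(list(tau_c = tau), list(tau_c = se),
              c(0.3 * tau, max(times[ok])), iter, converged,
              sqrt(sum(stats::resid(fit)^2)))
}

#' Iterative two-parameter fit of the spherical-expansion stage
#'
#' Levenberg-Marquardt fit of `R = R0 (1 + t/tau_s)^alpha` on the window
#' `[0, 10 * tau_s]`, with the window recomputed from the current estimate
#' until tau_s is self-consistent (relative change < 0.5%).
#'
#' With `alpha_fixed` the exponent is held at a supplied value and only
#' `tau_s` is fitted (same iterative window).  The kinetic exponent is
#' expected to be independent of chain length at a given confinement, so
#' scaling analyses of `tau_s` versus N gain a lot of stability from
#' fitting each N with a common alpha (pooled from first-pass
#' two-parameter fits): in the free fit, alpha and tau_s are strongly
#' correlated, and per-N alpha fluctuations would otherwise leak straight
#' into the tau_s ratios.
#'
#' @param times sample times (dense early coverage recommended).
#' @param R ensemble size curve.
#' @param R0 initial size, fixed from R(0).
#' @param weights optional per-point weights.
#' @param start optional list with starting `tau_s` and `alpha`.
#' @param alpha_fixed optional fixed exponent; switches to a
#'   single-parameter fit of `tau_s`.
#' @param max_iter window-iteration limit.
#' @return A `fit_result` with estimates `tau_s` and `alpha`.
#' @export
fit_stage1 <- function(times, R, R0, weights = NULL, start = NULL,
                       alpha_fixed = NULL, max_iter = 50) {
  rp <- R / R0
  ok <- is.finite(rp) & times >= 0
  fixed <- !is.null(alpha_fixed)
  alpha <- if (fixed) alpha_fixed else if (is.null(start)) 0.1
           else start$alpha
  tau <- if (is.null(start)) {
    # start near the time at which R has grown by ~2^alpha, i.e. t ~ tau_s;
    # starting low keeps the window clear of the second-stage regime
    i0 <- which(rp >= 2^alpha)[1]
    if (is.na(i0)) max(times) / 20 else max(times[i0], min(times[times > 0]))
  } else start$tau_s
  converged <- FALSE
  fit <- NULL
  iter <- 0
  for (iter in seq_len(max_iter)) {
    win <- ok & times <= 10 * tau
    if (sum(win) < 5) stop("fit window collapsed below 5 samples")
    df <- data.frame(t = times[win], y = rp[win])
    w <- if (is.null(weights)) rep(1, sum(win)) else weights[win]
    fit <- tryCatch(
      if (fixed) {
        af <- alpha_fixed
        minpack.lm::nlsLM(y ~ (1 + t / tau_s)^af, data = df,
                          start = list(tau_s = tau), weights = w,
                          lower = 1e-8,
                          control = nls.control(maxiter = 200,
                                                warnOnly = TRUE))
      } else {
        minpack.lm::nlsLM(y ~ (1 + t / tau_s)^alpha, data = df,
                          start = list(tau_s = tau, alpha = alpha),
                          weights = w, lower = c(1e-8, 1e-4),
                          control = nls.control(maxiter = 200,
                                                warnOnly = TRUE))
      },
      error = function(e) NULL)
    if (is.null(fit)) break
    cf <- coef(fit)
    if (!fixed) alpha <- cf[["alpha"]]
    if (abs(cf[["tau_s"]] - tau) < 5e-3 * tau) {
      tau <- cf[["tau_s"]]
      converged <- TRUE
      break
    }
    tau <- cf[["tau_s"]]
  }
  if (is.null(fit))
    return(.fit_result(list(tau_s = tau, alpha = alpha),
                       list(tau_s = NA_real_, alpha = NA_real_),
                       c(0, 10 * tau), iter, FALSE, NA_real_))
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(tau_s = NA_real_, alpha = NA_real_))
  .fit_result(list(tau_s = tau, alpha = alpha),
              list(tau_s = se[["tau_s"]],
                   alpha = if (fixed) 0 else se[["alpha"]]),
              c(0, 10 * tau), iter, converged,
              sqrt(sum(stats::resid(fit)^2)))
}

#' Power-law exponent by log-log regression
#'
#' Weighted least squares of `log(y)` on `log(x)`; exact on noiseless
#' power-law data for any weights.
#'
#' @param x,y positive data vectors (>= 3 points).
#' @param weights optional regression weights (applied in log space).
#' @return A list with `exponent`, `prefactor`, `stderr` (1-sigma of the
#'   exponent) and `stderr_prefactor`.
#' @export
#' @examples
#' fit_power_law(c(1, 2, 4), 2 * c(1, 2, 4)^3)  # exponent 3, prefactor 2
fit_power_law <- function(x, y, weights = NULL) {
  if (length(x) < 3) stop("at least 3 points required")
  if (any(x <= 0) || any(y <= 0)) stop("x and y must be positive")
  df <- data.frame(lx = log(x), ly = log(y))
  fit <- if (is.null(weights)) lm(ly ~ lx, data = df)
         else lm(ly ~ lx, data = df, weights = weights)
  # exact power-law input is legitimate here; summary.lm warns on it
  cf <- suppressWarnings(summary(fit))$coefficients
  list(exponent = cf[2, 1], prefactor = exp(cf[1, 1]),
       stderr = cf[2, 2], stderr_prefactor = exp(cf[1, 1]) * cf[1, 2])
}

#' Master-curve collapse factor
#'
#' Curves of normalized size versus time, indexed by `g = log2(N)`, are
#' rescaled in time by `factor^(ref_g - g)` and superposed; the collapse
#' objective is the across-curve variance of the interpolated values,
#' integrated over log scaled time on the common support ("finest neck").
#' The factor grid is searched coarsely and refined to `resolution`.
#'
#' @param curves list of data.frames with columns `t` and `value`
#'   (normalized size), one per chain length.
#' @param g numeric vector of `log2(N)` for each curve.
#' @param ref_g reference curve index (default: largest g present).
#' @param range factor search range.
#' @param resolution final grid resolution in the factor.
#' @param n_grid interpolation grid size.
#' @return An object of class `collapse_result` with `factor`, `objective`,
#'   `grid` and `objectives`.
#' @export
collapse_factor <- function(curves, g, ref_g = max(g), range = c(1, 8),
                            resolution = 0.01, n_grid = 200) {
  stopifnot(length(curves) >= 2, length(curves) == length(g))
  objective <- function(f) {
    scaled <- lapply(seq_along(curves), function(i) {
      cu <- curves[[i]]
      keep <- cu$t > 0 & is.finite(cu$value)
      data.frame(lt = log(cu$t[keep] * f^(ref_g - g[i])),
                 v = cu$value[keep])
    })
    lo <- max(vapply(scaled, function(s) min(s$lt), 0))
    hi <- min(vapply(scaled, function(s) max(s$lt), 0))
    if (hi <= lo) return(Inf)
    grid <- seq(lo, hi, length.out = n_grid)
    vals <- vapply(scaled, function(s)
      approx(s$lt, s$v, xout = grid, rule = 2)$y, numeric(n_grid))
    mean(apply(vals, 1, var))
  }
  coarse <- seq(range[1], range[2], by = max(resolution, 0.05))
  obj_c <- vapply(coarse, objective, 0)
  f0 <- coarse[which.min(obj_c)]
  fine <- seq(max(range[1], f0 - 0.06), min(range[2], f0 + 0.06),
              by = resolution)
  obj_f <- vapply(fine, objective, 0)
  best <- fine[which.min(obj_f)]
  structure(list(factor = best, objective = min(obj_f),
                 grid = c(coarse, fine), objectives = c(obj_c, obj_f),
                 ref_g = ref_g),
            class = "collapse_result")
}

#' @export
print.collapse_result <- function(x, ...) {
  cat(sprintf("Collapse factor: %.2f (objective %.4g, reference g = %g)\n",
              x$factor, x$objective, x$ref_g))
  invisible(x)
}
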