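#' Radius of gyration of a snapshot
#'
#' Root-mean-square distance of the beads from the chain's centre of mass.
#'
#' @param snapshot a [chain_snapshot()] or an N x 3 position matrix.
#' @return Rg in sigma.
#' @export
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0)))  # 0.5
radius_of_gyration <- function(snapshot) {
  pos <- if (inherits(snapshot, "chain_snapshot")) snapshot$positions
         else as.matrix(snapshot)
  ctr <- sweep(pos, 2, colMeans(pos))
  sqrt(sum(ctr^2) / nrow(pos))
}

#' Gyration tensor of a snapshot
#'
#' Second-moment tensor of bead positions about the centre of mass,
#' `G_ab = (1/N) * sum_i (r_ia - r_cm,a)(r_ib - r_cm,b)`.  Symmetric and
#' positive semidefinite; its trace equals Rg^2.
#'
#' @inheritParams radius_of_gyration
#' @return A 3 x 3 symmetric matrix.
#' @export
gyration_tensor <- function(snapshot) {
  pos <- if (inherits(snapshot, "chain_snapshot")) snapshot$positions
         else as.matrix(snapshot)
  ctr <- sweep(pos, 2, colMeans(pos))
  crossprod(ctr) / nrow(pos)
}

#' Sorted eigenvalues of a gyration tensor
#'
#' @param tensor a symmetric positive-semidefinite 3 x 3 matrix.
#' @param tol asymmetry/negativity tolerance.
#' @return Numeric vector `(lambda1, lambda2, lambda3)`, descending,
#'   clamped at 0 within `tol`.
#' @export
shape_eigenvalues <- function(tensor, tol = 1e-10) {
  if (max(abs(tensor - t(tensor))) > tol * max(1, max(abs(tensor))))
    stop("gyration tensor must be symmetric")
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -tol * max(1, max(abs(ev)))))
    stop("gyration tensor must be positive semidefinite")
  sort(pmax(ev, 0), decreasing = TRUE)
}

#' Asphericity from sorted eigenvalues
#'
#' `A = 3(l1^2+l2^2+l3^2) / (2(l1+l2+l3)^2) - 1/2`, in `[0, 1]`: 0 for a
#' perfect sphere (three equal eigenvalues), 1 for a rod.
#'
#' @param lambda1,lambda2,lambda3 eigenvalues, `lambda1 >= lambda2 >=
#'   lambda3 >= 0`, not all zero.  Vectorized.
#' @return Asphericity value(s).
#' @export
asphericity <- function(lambda1, lambda2, lambda3) {
  s <- lambda1 + lambda2 + lambda3
  if (any(s <= 0)) stop("eigenvalues must not all be zero")
  3 * (lambda1^2 + lambda2^2 + lambda3^2) / (2 * s^2) - 0.5
}

#' Rescaled prolateness (bounded in [-1, 1])
#'
#' `P = 27 (l1 - lbar)(l2 - lbar)(l3 - lbar) / (2 l1^3)`: positive for
#' prolate (elongated) shapes, negative for oblate (flattened) ones; +1 for
#' a rod, -1 for a disc.
#'
#' @inheritParams asphericity
#' @return Prolateness value(s) in `[-1, 1]`.
#' @export
prolateness <- function(lambda1, lambda2, lambda3) {
  if (any(lambda1 <= 0)) stop("lambda1 must be positive")
  lb <- (lambda1 + lambda2 + lambda3) / 3
  27 * (lambda1 - lb) * (lambda2 - lb) * (lambda3 - lb) / (2 * lambda1^3)
}

#' Conventional prolateness (range [-0.25, 2])
#'
#' `Pc = (l1 - lbar)(l2 - lbar)(l3 - lbar) / lbar^3`.
#'
#' @inheritParams asphericity
#' @return Conventional prolateness value(s).
#' @export
conventional_prolateness <- function(lambda1, lambda2, lambda3) {
  lb <- (lambda1 + lambda2 + lambda3) / 3
  if (any(lb <= 0)) stop("mean eigenvalue must be positive")
  (lambda1 - lb) * (lambda2 - lb) * (lambda3 - lb) / lb^3
}

#' Shape trace from sampled gyration-tensor components
#'
#' Builds the per-time sorted eigenvalues and the shape factors A, P, Pc
#' from a matrix of sampled tensor components.
#'
#' @param times sample times.
#' @param gyr matrix with columns `xx, yy, zz, xy, xz, yz` (one row per
#'   sample), as produced by the engine.
#' @return A data.frame with columns `t`, `lambda1..3`, `A`, `P`, `Pc`.
#' @export
shape_trace <- function(times, gyr) {
  gyr <- matrix(as.numeric(gyr), ncol = 6)
  ev <- t(apply(gyr, 1, function(g) {
    m <- matrix(c(g[1], g[4], g[5],
                  g[4], g[2], g[6],
                  g[5], g[6], g[3]), 3, 3)
    sort(pmax(eigen(m, symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  }))
  data.frame(t = times, lambda1 = ev[, 1], lambda2 = ev[, 2],
             lambda3 = ev[, 3],
             A = asphericity(ev[, 1], ev[, 2], ev[, 3]),
             P = prolateness(ev[, 1], ev[, 2], ev[, 3]),
             Pc = conventional_prolateness(ev[, 1], ev[, 2], ev[, 3]))
}

#' Ensemble-averaged chain size R(t)
#'
#' Averages Rg^2 across replicas at each time and takes the square root:
#' `R(t) = sqrt(<Rg^2(t)>)` (mean-then-root, not root-then-mean).  The
#' standard error of R is propagated from the Rg^2 variance via
#' `se(R) = se(Rg^2) / (2 R)`.
#'
#' @param x an `ensemble_record` (see [run_ensemble()]) or a time x replica
#'   matrix of Rg^2 values.
#' @param times required when `x` is a bare matrix.
#' @return A data.frame of class `ensemble_curves` with columns `t`, `R`,
#'   `stderr`, and `n` (replica count), plus mean shape quantities when
#'   eigenvalue traces are available.
#' @export
ensemble_mean_size <- function(x, times = NULL) {
  if (inherits(x, "ensemble_record")) {
    times <- x$times
    rg2 <- x$rg2
  } else {
    rg2 <- as.matrix(x)
    if (is.null(times)) stop("times required for a bare Rg^2 matrix")
    if (length(times) != nrow(rg2)) stop("mismatched time grid")
  }
  n <- ncol(rg2)
  if (n < 1) stop("at least one replica required")
  m <- rowMeans(rg2)
  se2 <- if (n > 1) apply(rg2, 1, sd) / sqrt(n) else rep(0, nrow(rg2))
  R <- sqrt(m)
  out <- data.frame(t = times, R = R,
                    stderr = ifelse(R > 0, se2 / (2 * pmax(R, 1e-300)), 0),
                    n = n)
  if (inherits(x, "ensemble_record") && !is.null(x$lambda1)) {
    out$lambda1 <- rowMeans(x$lambda1)
    out$lambda2 <- rowMeans(x$lambda2)
    out$lambda3 <- rowMeans(x$lambda3)
    out$A <- rowMeans(asphericity(x$lambda1, x$lambda2, x$lambda3))
    out$P <- rowMeans(prolateness(x$lambda1, x$lambda2, x$lambda3))
    out$Pc <- rowMeans(conventional_prolateness(x$lambda1, x$lambda2,
                                                x$lambda3))
  }
  class(out) <- c("ensemble_curves", class(out))
  out
}

#' Expansion velocity from per-run Rg series
#'
#' Differentiates each replica's Rg(t) with the three-point formula
#' (central at interior points, one-sided at the ends) on a uniform time
#' grid, then averages the derivatives across replicas.  `VR(0)` is forced
#' to 0: the chain starts from a static confined state.
#'
#' @param times uniformly spaced sample times.
#' @param rg either a time x replica matrix of Rg values (not squared) or a
#'   single series.
#' @return A data.frame with columns `t`, `VR`, and `VR_max` as an
#'   attribute (also returned by [max()] of the column).
#' @export
expansion_velocity <- function(times, rg) {
  rg <- as.matrix(rg)
  nt <- length(times)
  if (nt < 3) stop("at least 3 samples required for differentiation")
  if (nrow(rg) != nt) stop("rg rows must match times")
  h <- diff(times)
  if (max(abs(h - h[1])) > 1e-8 * max(h))
    stop("three-point differentiation requires a uniform time grid")
  h <- h[1]
  d <- apply(rg, 2, function(y) {
    dy <- numeric(nt)
    dy[1] <- (-3 * y[1] + 4 * y[2] - y[3]) / (2 * h)
    dy[nt] <- (3 * y[nt] - 4 * y[nt - 1] + y[nt - 2]) / (2 * h)
    dy[2:(nt - 1)] <- (y[3:nt] - y[1:(nt - 2)]) / (2 * h)
    dy
  })
  vr <- rowMeans(as.matrix(d))
  vr[1] <- 0  # static initial condition inside the cavity
  out <- data.frame(t = times, VR = vr)
  attr(out, "VR_max") <- max(vr)
  out
}

#' Initial chain size R0 of an ensemble curve
#'
#' @param curves an `ensemble_curves` data.frame including t = 0.
#' @return `R(0)`.
#' @export
estimate_R0 <- function(curves) {
  i <- which.min(abs(curves$t))
  if (curves$t[i] > 1e-9 * max(curves$t))
    stop("curve does not include t = 0")
  curves$R[i]
}

#' Final chain size RF of an ensemble curve
#'
#' With a fitted characteristic time, RF is the mean of R(t) over the
#' relaxed regime `t/tau_c > 3`; without one, the trailing `frac` of the
#' samples is used and flagged `provisional` unless that window passes a
#' stationarity check.
#'
#' @param curves an `ensemble_curves` data.frame.
#' @param tau_c optional fitted second-stage characteristic time.
#' @param frac trailing fraction used when `tau_c` is missing.
#' @return RF with attributes `provisional` (logical) and `window`.
#' @export
estimate_RF <- function(curves, tau_c = NULL, frac = 0.2) {
  if (!is.null(tau_c)) {
    i <- which(curves$t > 3 * tau_c)
    if (!length(i)) stop("no samples in the relaxed regime t > 3 tau_c")
    prov <- FALSE
  } else {
    i <- which(curves$t >= stats::quantile(curves$t, 1 - frac))
    prov <- !.is_stationary(curves$t[i], curves$R[i])
  }
  rf <- mean(curves$R[i])
  attr(rf, "provisional") <- prov
  attr(rf, "window") <- range(curves$t[i])
  rf
}
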