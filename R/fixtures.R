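#' Specification of a synthetic two-stage expansion ensemble
#'
#' Describes noisy replicas of the two-stage size law for validating the
#' fitting and collapse machinery without molecular dynamics.  The
#' generating curve is `max(stage1(t), stage2(t))` -- the first-stage
#' variation is an add-on that joins the principal second-stage curve on
#' contact -- and each replica multiplies it by log-normal noise, optionally
#' AR(1)-correlated in time (single-run size curves fluctuate in a visibly
#' correlated, zigzag fashion).
#'
#' The default parameters mimic a released chain whose first-stage time is
#' orders of magnitude shorter than the second-stage time, so both regimes
#' are identifiable.
#'
#' @param R0 initial size (sigma).
#' @param tau_s,alpha first-stage parameters.
#' @param RF,tau_c,beta second-stage parameters.
#' @param bc second-stage amplitude (1 for the master curve).
#' @param noise_sd multiplicative log-normal noise amplitude (default 5%).
#' @param noise_rho AR(1) correlation of the noise between consecutive
#'   samples (0 = independent).
#' @param replicas number of replicas.
#' @param times sample time grid.
#' @param seed RNG seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(R0 = 4, tau_s = 5, alpha = 0.1, RF = 16,
                         tau_c = 1e5, beta = 1 / 5, bc = 1,
                         noise_sd = 0.05, noise_rho = 0, replicas = 100,
                         times = log_times(0.05, 6e5, 300), seed = 1) {
  stopifnot(noise_sd >= 0, replicas >= 1, noise_rho >= 0, noise_rho < 1)
  s2_0 <- RF * (1 - bc)^beta
  if (s2_0 > R0)
    stop("inconsistent stages at t = 0: stage2(0) > stage1(0)")
  structure(list(R0 = R0, tau_s = tau_s, alpha = alpha, RF = RF,
                 tau_c = tau_c, beta = beta, bc = bc, noise_sd = noise_sd,
                 noise_rho = noise_rho, replicas = replicas, times = times,
                 seed = seed),
            class = "fixture_spec")
}

#' Generating curve of a fixture spec
#'
#' @param spec a [fixture_spec()].
#' @param times optional alternative time grid.
#' @return The noiseless two-stage size curve `max(stage1, stage2)`.
#' @export
fixture_truth <- function(spec, times = spec$times) {
  pmax(stage1_size(times, spec$R0, spec$tau_s, spec$alpha),
       stage2_size(times, spec$RF, spec$tau_c, spec$beta, spec$bc))
}

#' Generate a synthetic replica ensemble
#'
#' Per-replica `Rg^2(t) = (truth(t) * noise(t))^2` with log-normal
#' multiplicative noise of amplitude `noise_sd` and optional AR(1)
#' correlation between samples.  The noise mean is corrected so that
#' `E[noise^2] = 1`: the ensemble estimator averages squared sizes, and
#' this keeps it unbiased for the generating curve.  Deterministic for a
#' given seed.
#'
#' @param spec a [fixture_spec()].
#' @return An `ensemble_record` with `times`, `rg2` matrix, the generating
#'   `truth` curve and the spec in `config`.
#' @export
synth_ensemble <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  truth <- fixture_truth(spec)
  nt <- length(spec$times)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  s <- spec$noise_sd
  rho <- spec$noise_rho
  rg2 <- vapply(seq_len(spec$replicas), function(i) {
    z <- numeric(nt)
    z[1] <- rnorm(1)
    if (nt > 1) {
      eps <- rnorm(nt - 1)
      for (j in 2:nt) z[j] <- rho * z[j - 1] + sqrt(1 - rho^2) * eps[j - 1]
    }
    noise <- exp(s * z - s^2)  # E[noise^2] = 1
    (truth * noise)^2
  }, numeric(nt))
  structure(list(times = spec$times, rg2 = rg2, lambda1 = NULL,
                 lambda2 = NULL, lambda3 = NULL,
                 seeds = spec$seed + seq_len(spec$replicas) - 1,
                 failed = 0L, truth = truth, config = unclass(spec)),
            class = "ensemble_record")
}
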