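#' First-stage (spherical expansion) size law
#'
#' `R(t) = R0 * (1 + t/tau_s)^alpha`: the confined chain swells as a sphere
#' with kinetic exponent alpha tied to the blob exponent nu_b through
#' [alpha_from_nub()].
#'
#' @param t time(s), >= 0 (tu).
#' @param R0 initial chain size (sigma).
#' @param tau_s first-stage characteristic time (tu).
#' @param alpha kinetic exponent (dimensionless, < 1/2).
#' @return Chain size R(t).
#' @export
stage1_size <- function(t, R0, tau_s, alpha) {
  if (any(t < 0)) stop("t must be non-negative")
  stopifnot(R0 > 0, tau_s > 0)
  R0 * (1 + t / tau_s)^alpha
}

#' Second-stage (coil expansion) size law
#'
#' `R(t) = RF * (1 - bc * exp(-t/tau_c))^beta` with beta = 1/5 and bc = 1
#' by default; the normalized form `R/RF = (1 - exp(-t/tau_c))^(1/5)` is
#' the master curve of the late expansion.
#'
#' @param t time(s), >= 0 (tu).
#' @param RF final (relaxed coil) chain size (sigma).
#' @param tau_c second-stage characteristic time (tu).
#' @param beta kinetic exponent (default 1/5).
#' @param bc amplitude parameter (default 1).
#' @return Chain size R(t).
#' @export
stage2_size <- function(t, RF, tau_c, beta = 1 / 5, bc = 1) {
  if (any(t < 0)) stop("t must be non-negative")
  stopifnot(RF > 0, tau_c > 0)
  base <- 1 - bc * exp(-t / tau_c)
  if (any(base < 0)) stop("bc > 1 makes the base negative at small t")
  RF * base^beta
}

#' First-stage expansion velocity
#'
#' Analytic derivative of [stage1_size()]:
#' `dR/dt = alpha * R0 / tau_s * (1 + t/tau_s)^(alpha - 1)`.  Note the
#' non-zero value `alpha * R0 / tau_s` at t = 0, a known artefact of the
#' quasi-equilibrium derivation.
#'
#' @inheritParams stage1_size
#' @return dR/dt.
#' @export
stage1_velocity <- function(t, R0, tau_s, alpha) {
  if (any(t < 0)) stop("t must be non-negative")
  alpha * R0 / tau_s * (1 + t / tau_s)^(alpha - 1)
}

#' Second-stage expansion velocity
#'
#' Analytic derivative of [stage2_size()] with bc = 1:
#' `dR/dt = beta * RF / tau_c * (1 - exp(-t/tau_c))^(beta-1) * exp(-t/tau_c)`.
#' Divergent as t -> 0+ (signalled by `Inf`).
#'
#' @inheritParams stage2_size
#' @return dR/dt (`Inf` at t = 0).
#' @export
stage2_velocity <- function(t, RF, tau_c, beta = 1 / 5) {
  if (any(t < 0)) stop("t must be non-negative")
  e <- exp(-t / tau_c)
  out <- beta * RF / tau_c * (1 - e)^(beta - 1) * e
  out[t == 0] <- Inf
  out
}

#' Kinetic exponent alpha from the blob exponent nu_b
#'
#' `alpha = (3 nu_b - 1) / (6 nu_b + 1)`; the inverse of [nub_from_alpha()].
#'
#' @param nu_b blob scaling exponent (> 1/3 for positive alpha).
#' @return alpha.
#' @export
#' @examples
#' alpha_from_nub(0.5)  # 0.125, the melt-blob limit
alpha_from_nub <- function(nu_b) {
  (3 * nu_b - 1) / (6 * nu_b + 1)
}

#' Blob exponent nu_b from the kinetic exponent alpha
#'
#' `nu_b = (1 + alpha) / (3 - 6 alpha)`; requires alpha < 1/2.
#'
#' @param alpha kinetic exponent (< 1/2).
#' @return nu_b.
#' @export
nub_from_alpha <- function(alpha) {
  if (any(alpha >= 0.5)) stop("alpha must be < 1/2")
  (1 + alpha) / (3 - 6 * alpha)
}

#' Predicted characteristic-time scaling forms
#'
#' Theory forms up to user-supplied prefactors: the first-stage time
#' `tau_s = a_s * (eta sigma^2 / kBT) * (R0/sigma)^(1/alpha) *
#' N^(-1/(3 nu_b - 1))` and the second-stage time
#' `tau_c = a_c * (eta sigma^2 / kBT) * N^x` with the N-exponent `x`
#' defaulting to the theoretical value 2 (the empirical fit gives 2.36).
#' The prefactors are fit constants and are never fixed silently.
#'
#' @param N chain length.
#' @param R0 initial size (sigma), for the tau_s form.
#' @param params a [model_params()].
#' @param alpha,nu_b first-stage exponents.
#' @param a_s,a_c prefactors.
#' @param xc N-exponent of the tau_c form (2 theoretical, 2.36 empirical).
#' @return A list with `tau_s` and `tau_c`.
#' @export
predicted_times <- function(N, R0, params = model_params(),
                            alpha = alpha_from_nub(0.5), nu_b = 0.5,
                            a_s = 1, a_c = 1, xc = 2) {
  if (abs(3 * nu_b - 1) < 1e-12) stop("nu_b = 1/3 is singular")
  pref <- params$eta * params$sigma^2 / params$kBT
  list(tau_s = a_s * pref * (R0 / params$sigma)^(1 / alpha) *
         N^(-1 / (3 * nu_b - 1)),
       tau_c = a_c * pref * N^xc)
}

#' Predicted N-exponent of tau_s
#'
#' For an initial-size scaling `R0 ~ N^(1/3 + delta)` the theory gives
#' `x_s = (1/3 + delta)/alpha - 1/(3 nu_b - 1)`.
#'
#' @param delta deviation of the R0 exponent from 1/3.
#' @param alpha first-stage kinetic exponent.
#' @param nu_b blob exponent (not 1/3).
#' @return Predicted exponent x_s.
#' @export
predicted_xs <- function(delta, alpha, nu_b) {
  if (abs(3 * nu_b - 1) < 1e-12) stop("nu_b = 1/3 is singular")
  (1 / 3 + delta) / alpha - 1 / (3 * nu_b - 1)
}

#' Free-energy forms of the two stages
#'
#' Blob (confined sphere) form `F_blob ~ kBT * N^(3 nu_b/(3 nu_b - 1)) *
#' (R/sigma)^(-3/(3 nu_b - 1))` and Flory coil form `F_flory ~ kBT *
#' (R^2/(N sigma^2) + v_ex N^2 / R^3)`, both with O(1) prefactors taken
#' as 1.
#'
#' @param R chain size(s) (> 0).
#' @param N chain length.
#' @param params a [model_params()].
#' @param nu_b blob exponent (not 1/3).
#' @param v_ex excluded volume of a monomer (default sigma^3).
#' @return A list with vectors `F_blob` and `F_flory` (kBT units).
#' @export
free_energies <- function(R, N, params = model_params(), nu_b = 0.5,
                          v_ex = NULL) {
  if (any(R <= 0)) stop("R must be positive")
  if (abs(3 * nu_b - 1) < 1e-12) stop("nu_b = 1/3 is singular")
  if (is.null(v_ex)) v_ex <- params$sigma^3
  kBT <- params$kBT
  list(
    F_blob = kBT * N^(3 * nu_b / (3 * nu_b - 1)) *
      (R / params$sigma)^(-3 / (3 * nu_b - 1)),
    F_flory = kBT * (R^2 / (N * params$sigma^2) + v_ex * N^2 / R^3))
}

#' Map simulation units to SI
#'
#' Fixes the length, mass and energy units in SI; the simulation time unit
#' follows as `tu = sigma * sqrt(m / kBT)`.  The reference mapping for a
#' single-stranded nucleic acid (sigma = 3.4 Angstrom, m = 320 g/mol,
#' kBT at 300 K) gives tu = 3.86 ps.
#'
#' @param sigma_SI length unit in metres.
#' @param mass_SI bead mass in kg (320 g/mol / Avogadro by default).
#' @param kBT_SI thermal energy in joules.
#' @return An object of class `unit_map` with the derived `tu_SI` (s).
#' @export
#' @examples
#' simulation_time_unit(unit_map()) * 1e12  # ~3.86 ps
unit_map <- function(sigma_SI = 3.4e-10, mass_SI = 0.320 / 6.02214076e23,
                     kBT_SI = 4.14e-21) {
  stopifnot(sigma_SI > 0, mass_SI > 0, kBT_SI > 0)
  structure(list(sigma_SI = sigma_SI, mass_SI = mass_SI, kBT_SI = kBT_SI,
                 tu_SI = sigma_SI * sqrt(mass_SI / kBT_SI)),
            class = "unit_map")
}

#' Simulation time unit in seconds
#' @param map a [unit_map()].
#' @return `sigma_SI * sqrt(mass_SI / kBT_SI)` in seconds.
#' @export
simulation_time_unit <- function(map = unit_map()) map$tu_SI

#' Convert a simulation time to SI seconds
#'
#' @param map a [unit_map()].
#' @param t_sim time(s) in simulation units tu.
#' @return Time(s) in seconds.
#' @export
to_real_units <- function(map, t_sim) t_sim * map$tu_SI

#' Total expansion time
#'
#' Defined as three second-stage characteristic times, `tau = 3 tau_c`,
#' by which the master curve has reached `(1 - e^-3)^(1/5) ~ 0.99` of the
#' final size.
#'
#' @param tau_c second-stage characteristic time.
#' @return `3 * tau_c`.
#' @export
expansion_time <- function(tau_c) 3 * tau_c

#' Demarcation power laws of the expansion diagram
#'
#' Power-law boundaries in the (scaled time, size) plane: on the `t/tau_s`
#' scale the coil state is reached along `t'' ~ R^((xc - xs)/nu_c)`; on the
#' `t/tau_c` scale the sphere-like state is left along
#' `t* ~ R^((xs - xc)/nu_s)`.  Prefactors are taken as 1 (they are fit to
#' data when drawing).
#'
#' @param xs,xc fitted N-exponents of tau_s and tau_c.
#' @param nu_s,nu_c size exponents of the sphere-like (~1/3) and coil
#'   (~0.6) states.
#' @return A list of two functions of R: `t_coil` and `t_sphere`, with the
#'   exponents attached as attributes.
#' @export
demarcation_lines <- function(xs, xc, nu_s = 1 / 3, nu_c = 0.6) {
  e1 <- (xc - xs) / nu_c
  e2 <- (xs - xc) / nu_s
  f1 <- function(R) R^e1
  f2 <- function(R) R^e2
  attr(f1, "exponent") <- e1
  attr(f2, "exponent") <- e2
  list(t_coil = f1, t_sphere = f2)
}
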