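#' Force-field, thermostat and integration parameters
#'
#' Bundles the constants of the bead-spring model in simulation units
#' (length sigma, mass m, energy kBT, time tu = sigma*sqrt(m/kBT)).
#' Defaults are the production values used throughout: WCA strength
#' 1.2 kBT, bond length 1 sigma, spring constant 6000 kBT/sigma^2,
#' friction 20 sqrt(m kBT)/sigma and time step 0.005 tu.
#'
#' @param epsilon WCA interaction strength (kBT).
#' @param sigma bead diameter / length unit.
#' @param b0 equilibrium bond length (sigma).
#' @param k_spring harmonic bond constant (kBT/sigma^2).
#' @param mass bead mass (m).
#' @param kBT thermal energy.
#' @param eta Langevin friction coefficient (sqrt(m kBT)/sigma).
#' @param dt integration time step (tu).
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params()
#' wca_energy(1, p)  # equals epsilon at r = sigma
model_params <- function(epsilon = 1.2, sigma = 1.0, b0 = 1.0,
                         k_spring = 6000, mass = 1.0, kBT = 1.0,
                         eta = 20.0, dt = 0.005) {
  vals <- c(epsilon = epsilon, sigma = sigma, b0 = b0, k_spring = k_spring,
            mass = mass, kBT = kBT, eta = eta, dt = dt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all model parameters must be finite and strictly positive")
  if (dt * eta / mass >= 1)
    warning("dt * eta / mass >= 1: Langevin integration may be unstable")
  structure(as.list(vals), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Bead-spring model parameters (simulation units):\n")
  for (nm in names(x)) cat(sprintf("  %-9s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Spherical cavity specification
#'
#' The confining cavity diameter follows from the chain length and the
#' confinement volume fraction phi0 = N sigma^3 / D^3, i.e.
#' D = sigma * (N / phi0)^(1/3).
#'
#' @param N number of beads (>= 2 for a chain; N = 1 accepted as degenerate).
#' @param phi0 confinement volume fraction, in (0, 1) (1 accepted only for
#'   the degenerate N = 1 case).
#' @param sigma length unit.
#' @return An object of class `cavity_spec` with fields `N`, `phi0`, `D`.
#' @export
cavity_spec <- function(N, phi0, sigma = 1.0) {
  D <- cavity_diameter(N, phi0, sigma)
  structure(list(N = as.integer(N), phi0 = phi0, D = D, sigma = sigma),
            class = "cavity_spec")
}

#' Cavity diameter at a given volume fraction
#'
#' @inheritParams cavity_spec
#' @return `sigma * (N / phi0)^(1/3)`.
#' @export
#' @examples
#' cavity_diameter(512, 0.4)
cavity_diameter <- function(N, phi0, sigma = 1.0) {
  if (any(N < 1)) stop("N must be >= 1")
  if (any(phi0 <= 0) || any(phi0 > 1))
    stop("phi0 must lie in (0, 1]")
  sigma * (N / phi0)^(1 / 3)
}

#' Chain snapshot
#'
#' Positions and velocities of the N beads at one time point.
#'
#' @param positions N x 3 matrix (sigma).
#' @param velocities N x 3 matrix (sigma/tu).
#' @param time time stamp (tu).
#' @return An object of class `chain_snapshot`.
#' @export
chain_snapshot <- function(positions, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (is.null(velocities)) velocities <- matrix(0, nrow(positions), 3)
  velocities <- as.matrix(velocities)
  if (!identical(dim(velocities), dim(positions)))
    stop("velocities must match positions in shape")
  structure(list(positions = positions, velocities = velocities,
                 time = time),
            class = "chain_snapshot")
}

#' @export
print.chain_snapshot <- function(x, ...) {
  cat(sprintf("Chain snapshot: N = %d, t = %g tu, Rg = %.4g sigma\n",
              nrow(x$positions), x$time, radius_of_gyration(x)))
  invisible(x)
}

#' WCA pair potential
#'
#' Purely repulsive truncated-and-shifted Lennard-Jones potential,
#' `4*eps*((sigma/r)^12 - (sigma/r)^6 + 1/4)` for `r <= 2^(1/6) sigma` and
#' exactly zero beyond; continuous at the cutoff.
#'
#' @param r pair distance(s), > 0.
#' @param params a [model_params()] object.
#' @return Energy in kBT units.
#' @export
wca_energy <- function(r, params = model_params()) {
  if (any(r <= 0)) stop("r must be strictly positive")
  rc <- 2^(1 / 6) * params$sigma
  sr6 <- (params$sigma / r)^6
  u <- 4 * params$epsilon * (sr6^2 - sr6 + 0.25)
  ifelse(r <= rc, u, 0)
}

#' WCA radial force magnitude
#'
#' Minus the radial derivative of [wca_energy()]; positive (repulsive,
#' outward) below the cutoff, zero at and beyond `2^(1/6) sigma`.
#'
#' @inheritParams wca_energy
#' @return Force in kBT/sigma units.
#' @export
wca_force <- function(r, params = model_params()) {
  if (any(r <= 0)) stop("r must be strictly positive")
  rc <- 2^(1 / 6) * params$sigma
  sr6 <- (params$sigma / r)^6
  f <- 24 * params$epsilon * (2 * sr6^2 - sr6) / r
  ifelse(r < rc, f, 0)
}

#' Harmonic bond energy
#'
#' `(k/2) * (b - b0)^2` for actual bond length `b`.
#'
#' @param b bond length(s), >= 0.
#' @param params a [model_params()] object.
#' @return Energy in kBT units.
#' @export
bond_energy <- function(b, params = model_params()) {
  0.5 * params$k_spring * (b - params$b0)^2
}

#' Harmonic bond restoring-force magnitude
#'
#' @inheritParams bond_energy
#' @return `-k * (b - b0)`; negative when the bond is stretched (pulls in).
#' @export
bond_force <- function(b, params = model_params()) {
  -params$k_spring * (b - params$b0)
}

#' Total forces on every bead
#'
#' Sum of harmonic bond forces and WCA pair forces (cell-list neighbour
#' search with cutoff `2^(1/6) sigma`; the WCA term acts on every pair,
#' bonded neighbours included).  The reflecting cavity contributes no force
#' (the wall acts by specular reflection, see [reflect_wall()]), so
#' `cavity` is accepted for interface symmetry and ignored.
#'
#' @param snapshot a [chain_snapshot()].
#' @param params a [model_params()] object.
#' @param cavity optional [cavity_spec()]; ignored (reflective wall).
#' @param force_cap optional cap on the pair-force magnitude (kBT/sigma),
#'   used only during initialization push-off; `Inf` disables capping.
#' @return N x 3 matrix of forces.
#' @export
total_forces <- function(snapshot, params = model_params(), cavity = NULL,
                         force_cap = Inf) {
  pos <- snapshot$positions
  d <- stats::dist(pos)
  if (any(d < 0.3 * params$sigma))
    warning("overlapping beads (r < 0.3 sigma) present")
  cpp_total_forces(pos, params$epsilon, params$sigma, params$b0,
                   params$k_spring,
                   if (is.finite(force_cap)) force_cap else -1)
}

#' Specular reflection at the cavity wall
#'
#' Beads whose centre exceeds the allowed radius `D/2 - 0.5 sigma` (the
#' bead radius is 0.5 sigma) are mirrored about the bounding sphere along
#' the radial direction and their radial velocity component is negated;
#' speed is conserved exactly.
#'
#' @param snapshot a [chain_snapshot()].
#' @param D cavity diameter (sigma).
#' @param sigma bead diameter.
#' @return The reflected [chain_snapshot()].
#' @export
reflect_wall <- function(snapshot, D, sigma = 1.0) {
  Rw <- D / 2 - 0.5 * sigma
  if (Rw <= 0) stop("cavity too small: D/2 - 0.5 sigma <= 0")
  res <- cpp_reflect_wall(snapshot$positions, snapshot$velocities, Rw)
  chain_snapshot(res$positions, res$velocities, snapshot$time)
}

#' Allowed wall radius for bead centres
#' @inheritParams reflect_wall
#' @return `D/2 - 0.5*sigma`.
#' @export
wall_radius <- function(D, sigma = 1.0) {
  Rw <- D / 2 - 0.5 * sigma
  if (Rw <= 0) stop("cavity too small: D/2 - 0.5 sigma <= 0")
  Rw
}
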