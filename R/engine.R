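#' Deterministic per-replica seeds from a master seed
#'
#' Seeds are derived with a splitmix64 counter chain, so the same master
#' seed always yields the same sequence and different replicas get distinct
#' streams.
#'
#' @param master master seed (positive integer-valued scalar).
#' @param n number of seeds.
#' @return Numeric vector of `n` distinct positive 31-bit seeds.
#' @export
replica_seeds <- function(master, n) {
  s <- cpp_split_seeds(as.numeric(master), as.integer(n) + 8L)
  s <- unique(s)
  if (length(s) < n) stop("seed derivation collision; choose another master")
  s[seq_len(n)]
}

# convert requested sample times (tu) to unique sorted step indices
.steps_from_times <- function(times, dt, nsteps) {
  st <- unique(pmin(nsteps, pmax(0L, as.integer(round(times / dt)))))
  sort(st)
}

#' Logarithmically spaced sample times
#'
#' Dense early, sparse late: appropriate for a process spanning decades.
#' Always includes t = 0.
#'
#' @param t_min first positive sample time (tu).
#' @param t_max last sample time (tu).
#' @param n number of positive samples.
#' @return Numeric vector of times, starting at 0.
#' @export
log_times <- function(t_min, t_max, n = 200) {
  c(0, exp(seq(log(t_min), log(t_max), length.out = n)))
}

#' Linearly spaced sample times
#'
#' Uniform grid from 0 to `t_max`; required for three-point velocity
#' differentiation.
#'
#' @param t_max last sample time (tu).
#' @param by sample spacing (tu).
#' @return Numeric vector of times.
#' @export
lin_times <- function(t_max, by) seq(0, t_max, by = by)

#' One or more raw Langevin integration steps
#'
#' Advances a snapshot by `nsteps` BAOAB steps.  With `noise = FALSE` the
#' stochastic kick is suppressed (friction retained) -- a test hook: a free
#' particle's velocity then decays geometrically with per-step factor
#' `exp(-eta*dt/mass)`.
#'
#' @param snapshot a [chain_snapshot()].
#' @param params a [model_params()].
#' @param nsteps number of steps.
#' @param wall_D cavity diameter for an active reflecting wall, or `NULL`.
#' @param seed RNG seed for the noise stream.
#' @param noise logical; `FALSE` zeroes the random force (test hook).
#' @return The advanced [chain_snapshot()].
#' @export
langevin_step <- function(snapshot, params = model_params(), nsteps = 1,
                          wall_D = NULL, seed = 1, noise = TRUE) {
  Rw <- if (is.null(wall_D)) -1 else wall_radius(wall_D, params$sigma)
  res <- cpp_md_run(snapshot$positions, snapshot$velocities,
                    params$epsilon, params$sigma, params$b0, params$k_spring,
                    params$mass, if (noise) params$kBT else 0,
                    params$eta, params$dt, Rw, as.integer(nsteps),
                    integer(0), snapshot$time, as.numeric(seed), -1, FALSE)
  chain_snapshot(res$positions, res$velocities, res$time)
}

#' Initialize an equilibrable confined chain
#'
#' Grows a random walk inside the cavity (soft self-avoidance), removes
#' residual overlaps with a short capped-force push-off run against the
#' reflecting wall, and draws Maxwell-Boltzmann velocities at kBT.
#'
#' @param N chain length.
#' @param phi0 confinement volume fraction (feasible packing requires
#'   roughly phi0 <= 0.5 for this bead model).
#' @param params a [model_params()].
#' @param seed RNG seed.
#' @param pushoff_steps capped-force steps used to resolve overlaps.
#' @param force_cap pair-force cap (kBT/sigma) during push-off.
#' @return A [chain_snapshot()] entirely inside radius `D/2 - 0.5 sigma`.
#' @export
initialize_confined <- function(N, phi0, params = model_params(), seed = 1,
                                pushoff_steps = 2000, force_cap = 1e4) {
  D <- cavity_diameter(N, phi0, params$sigma)
  Rw <- wall_radius(D, params$sigma)
  pos <- cpp_pack_chain(as.integer(N), params$b0, Rw, as.numeric(seed))
  vel <- cpp_mb_velocities(as.integer(N), params$mass, params$kBT,
                           as.numeric(seed))
  # push-off: capped forces so random overlaps cannot blow up
  res <- cpp_md_run(pos, vel, params$epsilon, params$sigma, params$b0,
                    params$k_spring, params$mass, params$kBT, params$eta,
                    params$dt, Rw, as.integer(pushoff_steps), integer(0),
                    0, as.numeric(seed) + 0.5, force_cap, FALSE)
  chain_snapshot(res$positions, res$velocities, 0)
}

#' Initialize a free (unconfined) chain
#'
#' Growth-style self-avoiding chain with bond length b0, optionally
#' decorrelated by hard-core pivot Monte Carlo moves (the standard way to
#' reach the equilibrium coil ensemble without waiting out the Rouse time),
#' plus Maxwell-Boltzmann velocities.
#'
#' @param N chain length.
#' @param params a [model_params()].
#' @param seed RNG seed.
#' @param min_sep minimum non-bonded separation enforced during growth and
#'   by the pivot acceptance test.
#' @param pivot_moves number of attempted pivot moves (0 disables; ~25 N
#'   equilibrates the global conformation).
#' @return A [chain_snapshot()].
#' @export
initialize_free <- function(N, params = model_params(), seed = 1,
                            min_sep = 0.9, pivot_moves = 0) {
  pos <- cpp_saw_chain(as.integer(N), params$b0, min_sep * params$sigma,
                       as.numeric(seed))
  if (pivot_moves > 0)
    pos <- cpp_pivot_chain(pos, min_sep * params$sigma,
                           as.integer(pivot_moves), as.numeric(seed))
  vel <- cpp_mb_velocities(as.integer(N), params$mass, params$kBT,
                           as.numeric(seed))
  chain_snapshot(pos, vel, 0)
}

# simple stationarity check: linear trend of the last half of a series
.is_stationary <- function(t, y, rel_tol = 0.02) {
  n <- length(y)
  if (n < 8) return(TRUE)
  i <- seq.int(floor(n / 2), n)
  fit <- lm(y[i] ~ t[i])
  sl <- summary(fit)$coefficients
  drift <- abs(coef(fit)[2]) * (t[max(i)] - t[min(i)])
  p <- if (nrow(sl) > 1) sl[2, 4] else 1
  (p > 0.01) || (drift < rel_tol * mean(y[i]))
}

#' Equilibrate a confined chain in its cavity
#'
#' Runs `equil_steps` Langevin steps with the reflecting wall active,
#' recording an Rg^2 series for a stationarity check on its last half.
#' The time stamp of the returned snapshot is reset to 0 (equilibration is
#' preparation, not part of the release clock).
#'
#' @param snapshot an initialized confined [chain_snapshot()].
#' @param params a [model_params()].
#' @param cavity a [cavity_spec()].
#' @param equil_steps number of integration steps.
#' @param sample_every record Rg^2 every this many steps.
#' @param seed RNG seed.
#' @param warn logical; warn when the trend test fails.
#' @return A list with `snapshot`, `times`, `rg2`, `stationary`,
#'   `max_radius` (largest bead-centre radius seen at samples) and
#'   `bond_rel_fluct` (sd(b)/b0 of the final state).
#' @export
equilibrate <- function(snapshot, params, cavity, equil_steps = 2e5,
                        sample_every = 1000, seed = 1, warn = TRUE) {
  Rw <- wall_radius(cavity$D, params$sigma)
  st <- seq(sample_every, equil_steps, by = sample_every)
  res <- cpp_md_run(snapshot$positions, snapshot$velocities,
                    params$epsilon, params$sigma, params$b0, params$k_spring,
                    params$mass, params$kBT, params$eta, params$dt,
                    Rw, as.integer(equil_steps), as.integer(st),
                    snapshot$time, as.numeric(seed), -1, FALSE)
  stat <- .is_stationary(res$times, res$rg2)
  if (!stat && warn)
    warning("Rg^2 trend test failed: equilibration may be too short")
  out <- chain_snapshot(res$positions, res$velocities, 0)
  b <- sqrt(rowSums((out$positions[-1, , drop = FALSE] -
                     out$positions[-nrow(out$positions), , drop = FALSE])^2))
  list(snapshot = out, times = res$times, rg2 = res$rg2, stationary = stat,
       max_radius = max(res$max_radius),
       bond_rel_fluct = sd(b) / params$b0)
}

#' Release a confined chain and record observables
#'
#' Switches the wall off at t = 0 and integrates forward, sampling Rg^2 and
#' the gyration tensor at the requested times (rounded to the step grid).
#'
#' @param snapshot an equilibrated confined [chain_snapshot()] at time 0.
#' @param params a [model_params()].
#' @param sample_times sample times in tu (see [log_times()],
#'   [lin_times()]); 0 is always included.
#' @param seed RNG seed.
#' @param traj logical; also return position frames at the sample times.
#' @return A list with `size_curve` (data.frame `t`, `Rg2`), `shape_trace`
#'   (see [shape_trace()]), `snapshot` (final state), `min_nonbonded`
#'   (minimum non-bonded pair distance between consecutive samples) and
#'   optionally `trajectory` (list of N x 3 matrices).
#' @export
release_run <- function(snapshot, params = model_params(),
                        sample_times = log_times(0.05, 1000), seed = 1,
                        traj = FALSE) {
  nsteps <- as.integer(ceiling(max(sample_times) / params$dt))
  st <- .steps_from_times(unique(c(0, sample_times)), params$dt, nsteps)
  res <- cpp_md_run(snapshot$positions, snapshot$velocities,
                    params$epsilon, params$sigma, params$b0, params$k_spring,
                    params$mass, params$kBT, params$eta, params$dt,
                    -1, nsteps, as.integer(st), 0, as.numeric(seed), -1,
                    isTRUE(traj))
  out <- list(
    size_curve = data.frame(t = res$times, Rg2 = res$rg2),
    shape_trace = shape_trace(res$times, res$gyr),
    snapshot = chain_snapshot(res$positions, res$velocities, res$time),
    min_nonbonded = res$min_nonbonded)
  if (isTRUE(traj)) {
    tr <- res$trajectory
    out$trajectory <- lapply(seq_along(res$times), function(i)
      t(matrix(tr[, , i], nrow = 3)))
  }
  out
}

#' Replica ensemble of confined-release runs
#'
#' Prepares `replicas` independent equilibrated confined states and releases
#' each on a shared time grid.  Per-replica seeds derive deterministically
#' from the master seed.  To amortize equilibration, `branch > 1` harvests
#' several decorrelated snapshots (spaced by `branch_spacing` steps) from
#' each equilibration chain and releases each with its own noise stream.
#'
#' @param N chain length.
#' @param phi0 confinement volume fraction.
#' @param params a [model_params()].
#' @param replicas number of release runs.
#' @param sample_times shared sampling grid (tu).
#' @param equil_steps equilibration steps before the first harvest.
#' @param branch release runs harvested per equilibration chain.
#' @param branch_spacing decorrelation steps between harvested snapshots.
#' @param seed master seed.
#' @return An object of class `ensemble_record`: `times`, `rg2` (time x
#'   replica matrix), `lambda1/2/3` (matrices of sorted gyration-tensor
#'   eigenvalues), `seeds`, `failed` (count), and the full `config`.
#' @export
run_ensemble <- function(N, phi0, params = model_params(), replicas = 8,
                         sample_times = log_times(0.05, 1000),
                         equil_steps = 2e5, branch = 1,
                         branch_spacing = 2e4, seed = 1) {
  stopifnot(replicas >= 1, branch >= 1)
  n_chains <- ceiling(replicas / branch)
  seeds <- replica_seeds(seed, n_chains * (branch + 1))
  cav <- cavity_spec(N, phi0, params$sigma)
  Rw <- wall_radius(cav$D, params$sigma)
  runs <- vector("list", replicas)
  used_seeds <- numeric(replicas)
  failed <- 0L
  r <- 1L
  for (ch in seq_len(n_chains)) {
    s_ch <- seeds[(ch - 1) * (branch + 1) + 1]
    snap <- initialize_confined(N, phi0, params, seed = s_ch)
    eq <- equilibrate(snap, params, cav, equil_steps = equil_steps,
                      seed = s_ch + 1, warn = FALSE)
    cur <- eq$snapshot
    for (b in seq_len(branch)) {
      if (r > replicas) break
      s_rel <- seeds[(ch - 1) * (branch + 1) + 1 + b]
      rr <- tryCatch(
        release_run(cur, params, sample_times, seed = s_rel),
        error = function(e) NULL)
      if (is.null(rr)) failed <- failed + 1L else runs[[r]] <- rr
      used_seeds[r] <- s_rel
      r <- r + 1L
      if (b < branch && r <= replicas) {
        adv <- cpp_md_run(cur$positions, cur$velocities, params$epsilon,
                          params$sigma, params$b0, params$k_spring,
                          params$mass, params$kBT, params$eta, params$dt,
                          Rw, as.integer(branch_spacing), integer(0), 0,
                          s_rel + 0.25, -1, FALSE)
        cur <- chain_snapshot(adv$positions, adv$velocities, 0)
      }
    }
  }
  ok <- !vapply(runs, is.null, logical(1))
  runs <- runs[ok]
  if (!length(runs)) stop("all replicas failed")
  times <- runs[[1]]$size_curve$t
  rg2 <- vapply(runs, function(x) x$size_curve$Rg2, numeric(length(times)))
  l1 <- vapply(runs, function(x) x$shape_trace$lambda1, numeric(length(times)))
  l2 <- vapply(runs, function(x) x$shape_trace$lambda2, numeric(length(times)))
  l3 <- vapply(runs, function(x) x$shape_trace$lambda3, numeric(length(times)))
  structure(list(times = times, rg2 = rg2, lambda1 = l1, lambda2 = l2,
                 lambda3 = l3, seeds = used_seeds[ok], failed = failed,
                 config = list(N = N, phi0 = phi0, params = params,
                               replicas = replicas, equil_steps = equil_steps,
                               branch = branch,
                               branch_spacing = branch_spacing, seed = seed)),
            class = "ensemble_record")
}

#' @export
print.ensemble_record <- function(x, ...) {
  cat(sprintf(
    "Ensemble record: N = %d, phi0 = %g, %d replicas (%d failed), %d times\n",
    x$config$N, x$config$phi0, ncol(x$rg2), x$failed, length(x$times)))
  invisible(x)
}

#' Equilibrium samples of a free chain (hybrid pivot + Langevin sampler)
#'
#' Samples the equilibrium coil ensemble by alternating Metropolis pivot
#' moves evaluated on the WCA energy (which decorrelate the global
#' conformation in O(N) accepted moves) with short Langevin runs (which
#' thermalize bonds and local structure).  Both kernels preserve the
#' Boltzmann distribution of the chain, so the sampled states are
#' equilibrium states without waiting out the Rouse time; plain dynamics
#' from a grown chain would need of order the coil relaxation time per
#' independent sample.  Used for the relaxed-coil reference values (final
#' size RF, coil shape factors A, P, Pc).
#'
#' @param N chain length.
#' @param params a [model_params()].
#' @param replicas independent chains.
#' @param burn_cycles pivot+dynamics cycles discarded per chain.
#' @param samples recorded cycles per chain.
#' @param pivot_per_cycle attempted pivot moves per cycle (default 4 N).
#' @param md_per_cycle Langevin steps per cycle.
#' @param seed master seed.
#' @return A list with `rg2` (matrix sample x replica), `lambda1/2/3`
#'   matrices, `times` (cycle end times of one replica) and
#'   `pivot_acceptance` (overall acceptance fraction).
#' @export
equilibrium_free_ensemble <- function(N, params = model_params(),
                                      replicas = 8, burn_cycles = 4,
                                      samples = 12,
                                      pivot_per_cycle = 4 * N,
                                      md_per_cycle = 2000, seed = 1) {
  seeds <- replica_seeds(seed, replicas)
  nt <- samples
  rg2 <- l1 <- l2 <- l3 <- matrix(NA_real_, nt, replicas)
  acc <- att <- 0
  for (i in seq_len(replicas)) {
    snap <- initialize_free(N, params, seed = seeds[i])
    pos <- snap$positions
    vel <- snap$velocities
    k <- 0
    for (cyc in seq_len(burn_cycles + samples)) {
      pv <- cpp_wca_pivot(pos, params$epsilon, params$sigma, params$kBT,
                          as.integer(pivot_per_cycle),
                          seeds[i] + 977 * cyc)
      acc <- acc + pv$accepted; att <- att + pivot_per_cycle
      res <- cpp_md_run(pv$positions, vel, params$epsilon, params$sigma,
                        params$b0, params$k_spring, params$mass,
                        params$kBT, params$eta, params$dt, -1,
                        as.integer(md_per_cycle),
                        as.integer(md_per_cycle), 0,
                        seeds[i] + 977 * cyc + 1, -1, FALSE)
      pos <- res$positions
      vel <- res$velocities
      if (cyc > burn_cycles) {
        k <- k + 1
        rg2[k, i] <- res$rg2[1]
        ev <- shape_trace(res$times, res$gyr)
        l1[k, i] <- ev$lambda1; l2[k, i] <- ev$lambda2
        l3[k, i] <- ev$lambda3
      }
    }
  }
  list(times = seq_len(nt) * md_per_cycle * params$dt, rg2 = rg2,
       lambda1 = l1, lambda2 = l2, lambda3 = l3,
       pivot_acceptance = acc / att)
}

#' Equilibrium in-cavity ensemble (confined chain size R0)
#'
#' Initializes and equilibrates confined chains, then keeps sampling Rg^2
#' with the wall active over a production window.  The ensemble mean of
#' Rg^2 over samples and replicas gives the initial size R0 of a release.
#'
#' @inheritParams run_ensemble
#' @param production_steps sampled steps after equilibration.
#' @param sample_every sampling interval in steps.
#' @return A list with `rg2` (matrix), `times`, `R0` (= sqrt(mean Rg^2))
#'   and `stationary` (fraction of replicas passing the trend check).
#' @export
equilibrium_confined_ensemble <- function(N, phi0, params = model_params(),
                                          replicas = 8, equil_steps = 2e5,
                                          production_steps = 2e5,
                                          sample_every = 2000, seed = 1) {
  seeds <- replica_seeds(seed, replicas)
  cav <- cavity_spec(N, phi0, params$sigma)
  Rw <- wall_radius(cav$D, params$sigma)
  st <- seq(equil_steps + sample_every, equil_steps + production_steps,
            by = sample_every)
  nt <- length(st)
  rg2 <- matrix(NA_real_, nt, replicas)
  stat <- logical(replicas)
  for (i in seq_len(replicas)) {
    snap <- initialize_confined(N, phi0, params, seed = seeds[i])
    res <- cpp_md_run(snap$positions, snap$velocities, params$epsilon,
                      params$sigma, params$b0, params$k_spring, params$mass,
                      params$kBT, params$eta, params$dt, Rw,
                      as.integer(equil_steps + production_steps),
                      as.integer(st), 0, seeds[i] + 0.5, -1, FALSE)
    rg2[, i] <- res$rg2
    stat[i] <- .is_stationary(res$times, res$rg2)
  }
  list(times = st * params$dt, rg2 = rg2, R0 = sqrt(mean(rg2)),
       stationary = mean(stat))
}
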