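test_that("radius of gyration matches direct evaluation", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(1, 0, 0))), 0.5)
  expect_equal(radius_of_gyration(matrix(2, 5, 3)), 0)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(0.5), tolerance = 1e-10)
})

test_that("gyration tensor is symmetric PSD with trace Rg^2", {
  line <- cbind(seq(-2, 2, by = 0.5), 0, 0)
  G <- gyration_tensor(line)
  expect_equal(G[2:3, 2:3], matrix(0, 2, 2))
  expect_gt(G[1, 1], 0)
  set.seed(4)
  pos <- matrix(rnorm(30), 10, 3)
  G <- gyration_tensor(pos)
  expect_equal(G, t(G))
  expect_equal(sum(diag(G)), radius_of_gyration(pos)^2, tolerance = 1e-12)
  # brute-force double-loop oracle
  ctr <- sweep(pos, 2, colMeans(pos))
  Gb <- matrix(0, 3, 3)
  for (a in 1:3) for (b in 1:3) Gb[a, b] <- mean(ctr[, a] * ctr[, b])
  expect_equal(G, Gb, tolerance = 1e-12)
})

test_that("eigenvalues are sorted, clamped, and validated", {
  expect_equal(shape_eigenvalues(diag(c(3, 1, 2))), c(3, 2, 1))
  expect_equal(shape_eigenvalues(diag(3)), c(1, 1, 1))
  expect_equal(shape_eigenvalues(diag(c(5, 0, 0))), c(5, 0, 0))
  m <- matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1), 3, 3)
  expect_error(shape_eigenvalues(m), "symmetric")
})

test_that("shape factors reproduce the limiting geometries", {
  expect_equal(asphericity(1, 1, 1), 0)
  expect_equal(asphericity(1, 0, 0), 1)
  expect_equal(asphericity(332.9, 68.6, 22.8), 0.4669, tolerance = 1e-4)
  expect_equal(prolateness(1, 0, 0), 1)
  expect_equal(prolateness(1, 1, 0), -1)
  expect_equal(prolateness(1, 1, 1), 0)
  expect_equal(conventional_prolateness(1, 0, 0), 2)
  expect_equal(conventional_prolateness(1, 1, 1), 0)
  expect_error(asphericity(0, 0, 0), "zero")
  # bounds on random valid spectra
  set.seed(9)
  for (i in 1:50) {
    l <- sort(runif(3), decreasing = TRUE)
    expect_gte(asphericity(l[1], l[2], l[3]), 0)
    expect_lte(asphericity(l[1], l[2], l[3]), 1)
    expect_gte(prolateness(l[1], l[2], l[3]), -1)
    expect_lte(prolateness(l[1], l[2], l[3]), 1)
    expect_gte(conventional_prolateness(l[1], l[2], l[3]), -0.25)
    expect_lte(conventional_prolateness(l[1], l[2], l[3]), 2)
  }
})

test_that("eigenvalue sum equals Rg^2 on every sampled frame of a run", {
  p <- model_params()
  snap <- initialize_confined(32, 0.4, p, seed = 31)
  rr <- release_run(snap, p, log_times(0.05, 50, 40), seed = 32)
  lsum <- rr$shape_trace$lambda1 + rr$shape_trace$lambda2 +
    rr$shape_trace$lambda3
  expect_equal(lsum, rr$size_curve$Rg2, tolerance = 1e-10)
})

test_that("ensemble averaging is mean-then-root with propagated errors", {
  times <- 0:3
  rg2 <- cbind(rep(1, 4), rep(3, 4))
  cur <- ensemble_mean_size(rg2, times = times)
  expect_equal(cur$R, rep(sqrt(2), 4))
  # identical replicas: zero stderr
  cur0 <- ensemble_mean_size(cbind(rep(4, 4), rep(4, 4)), times = times)
  expect_equal(cur0$stderr, rep(0, 4))
  expect_error(ensemble_mean_size(rg2, times = 0:4), "mismatch")
  # replica permutation invariance
  set.seed(2)
  m <- matrix(rexp(40), 10, 4)
  c1 <- ensemble_mean_size(m, times = 1:10)
  c2 <- ensemble_mean_size(m[, c(3, 1, 4, 2)], times = 1:10)
  expect_equal(c1$R, c2$R)
})

test_that("synthetic ensembles recover their generating mean", {
  spec <- fixture_spec(replicas = 400, noise_sd = 0.05, seed = 5,
                       times = log_times(0.5, 5e4, 80))
  ens <- synth_ensemble(spec)
  cur <- ensemble_mean_size(ens)
  # within 2 standard errors at (nearly) every point; allow a couple of
  # marginal exceedances out of 81
  z <- abs(cur$R - ens$truth) / pmax(cur$stderr, 1e-12)
  expect_lt(mean(z > 2), 0.1)
})

test_that("three-point velocity is exact on quadratics and matches theory", {
  t <- seq(0, 10, by = 0.5)
  v <- expansion_velocity(t, t^2)
  expect_equal(v$VR[-1], (2 * t)[-1], tolerance = 1e-10)
  expect_equal(v$VR[1], 0)  # enforced static start
  vc <- expansion_velocity(t, rep(3, length(t)))
  expect_equal(vc$VR, rep(0, length(t)))
  expect_error(expansion_velocity(c(0, 1), c(1, 2)), "3 samples")
  expect_error(expansion_velocity(c(0, 1, 3), c(1, 2, 3)), "uniform")
  # stage-2 law: numerical derivative matches the closed form
  tau <- 50; RF <- 10
  tg <- seq(5, 200, by = 0.5)
  R <- stage2_size(tg, RF, tau)
  vn <- expansion_velocity(tg, R)
  va <- stage2_velocity(tg, RF, tau)
  i <- 2:(length(tg) - 1)
  expect_equal(vn$VR[i][-1], va[i][-1], tolerance = 1e-3)
  # differentiation then averaging == averaging then differentiation
  m <- cbind(tg^1.5, 2 * tg^1.5)
  d1 <- expansion_velocity(tg, m)$VR
  d2 <- expansion_velocity(tg, rowMeans(m))$VR
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("R0 and RF estimation behave per contract", {
  tau <- 100
  t <- c(0, exp(seq(log(0.1), log(2000), length.out = 150)))
  cur <- data.frame(t = t, R = stage2_size(t, 8, tau))
  expect_equal(estimate_R0(cur), 0)
  rf <- estimate_RF(cur, tau_c = tau)
  expect_lt(abs(rf - 8) / 8, 0.005)
  const <- data.frame(t = 0:20, R = rep(4, 21))
  expect_equal(estimate_R0(const), 4)
  expect_equal(as.numeric(estimate_RF(const)), 4)
  mono <- data.frame(t = 0:50, R = (0:50)^0.8 + 1)
  expect_true(attr(estimate_RF(mono), "provisional"))
})
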