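test_that("F, G, H diagnostics are exact identities on model curves", {
  tau_c <- 4.03e5
  t <- exp(seq(log(1e3), log(2e6), length.out = 60))
  rt <- stage2_size(t, 1, tau_c)
  expect_equal(diagnostic_F(t, rt, 1 / 5), rep(tau_c, 60), tolerance = 1e-10)
  expect_equal(diagnostic_G(t, rt, tau_c), rep(5, 60), tolerance = 1e-10)
  # wrong beta trends: beta too small rises, too large falls
  F4 <- diagnostic_F(t, rt, 1 / 4)
  F6 <- diagnostic_F(t, rt, 1 / 6)
  expect_true(all(diff(F4) > 0))
  expect_true(all(diff(F6) < 0))
  # H on an exact stage-1 curve
  tau_s <- 50; alpha <- 0.098
  ts <- seq(0, 500, by = 1)
  rp <- stage1_size(ts, 1, tau_s, alpha)
  H <- diagnostic_H(ts, rp, tau_s)
  expect_true(is.na(H[1]))  # undefined at t = 0
  expect_equal(H[-1], rep(alpha, length(ts) - 1), tolerance = 1e-10)
  # out-of-domain masking
  expect_true(is.na(diagnostic_F(10, 1.0, 0.2)))
  expect_true(is.na(diagnostic_G(10, 1.2, 5)))
})

test_that("stage-2 fit recovers tau_c and flags truncated curves", {
  tau_c <- 1e4
  t <- c(0, exp(seq(log(10), log(8e4), length.out = 200)))
  R <- stage2_size(t, 12, tau_c)
  fit <- fit_stage2(t, R, 12)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate$tau_c - tau_c) / tau_c, 1e-3)
  # curve truncated before 0.3 tau_c cannot support the window
  t2 <- seq(1, 0.2 * tau_c, length.out = 50)
  fit2 <- fit_stage2(t2, stage2_size(t2, 12, tau_c), 12)
  expect_false(fit2$converged)
})

test_that("stage-1 iterative fit recovers both parameters", {
  tau_s <- 50; alpha <- 0.1
  t <- seq(0, 2000, by = 2)
  R <- stage1_size(t, 4, tau_s, alpha)
  fit <- fit_stage1(t, R, 4)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimate$tau_s - tau_s) / tau_s, 5e-3)
  expect_lt(abs(fit$estimate$alpha - alpha) / alpha, 5e-3)
  expect_lt(fit$window[2], max(t))  # window shrank to [0, 10 tau_s]
})

test_that("stage-1 fit tracks the early regime of a two-stage curve only", {
  spec <- fixture_spec(R0 = 4, tau_s = 20, alpha = 0.1, RF = 17,
                       tau_c = 2e5, noise_sd = 0, replicas = 1,
                       times = c(0, exp(seq(log(0.1), log(2e6),
                                            length.out = 400))))
  ens <- synth_ensemble(spec)
  R <- sqrt(ens$rg2[, 1])
  fit <- fit_stage1(ens$times, R, 4)
  expect_true(fit$converged)
  # early segment reproduced
  early <- ens$times <= 10 * fit$estimate$tau_s
  pred <- stage1_size(ens$times, 4, fit$estimate$tau_s, fit$estimate$alpha)
  expect_lt(max(abs(pred[early] - R[early]) / R[early]), 0.02)
  # late segment systematically under-predicted by the stage-1 law
  late <- ens$times > 5 * spec$tau_c
  expect_true(all(pred[late] < 0.8 * R[late]))
  # alpha maps to a physical blob exponent
  nub <- nub_from_alpha(fit$estimate$alpha)
  expect_gt(nub, 0.34); expect_lt(nub, 0.6)
})

test_that("power-law regression is exact on clean data and covers under noise", {
  f <- fit_power_law(c(1, 2, 4, 8), 2 * c(1, 2, 4, 8)^3)
  expect_equal(f$exponent, 3, tolerance = 1e-12)
  expect_equal(f$prefactor, 2, tolerance = 1e-12)
  N <- c(32, 64, 128, 256, 512)
  f2 <- fit_power_law(N, 0.18 * N^2.36)
  expect_equal(f2$exponent, 2.36, tolerance = 1e-10)
  expect_equal(f2$prefactor, 0.18, tolerance = 1e-10)
  expect_error(fit_power_law(c(1, 2), c(1, 2)), "3 points")
  # Monte-Carlo coverage: exponent within 2 stderr in >= 90% of repetitions
  set.seed(31)
  Ng <- 2^(3:10)
  hits <- replicate(100, {
    y <- 0.5 * Ng^1.7 * exp(rnorm(length(Ng), sd = 0.05))
    fr <- fit_power_law(Ng, y)
    abs(fr$exponent - 1.7) <= 2 * fr$stderr
  })
  expect_gte(mean(hits), 0.9)
})

test_that("fixture parameter recovery stays within two standard errors", {
  set.seed(7)
  ok2 <- ok1 <- logical(40)
  for (i in 1:40) {
    spec <- fixture_spec(noise_sd = 0.05, replicas = 100, seed = 1000 + i)
    cur <- ensemble_mean_size(synth_ensemble(spec))
    w <- 1 / pmax(cur$stderr, 1e-9)^2
    f2 <- fit_stage2(cur$t, cur$R, spec$RF, weights = w)
    ok2[i] <- abs(f2$estimate$tau_c - spec$tau_c) <=
      2 * max(f2$stderr$tau_c, 1)
    f1 <- fit_stage1(cur$t, cur$R, spec$R0, weights = w)
    ok1[i] <- abs(f1$estimate$tau_s - spec$tau_s) <=
      2 * max(f1$stderr$tau_s, 1e-6)
  }
  expect_gte(mean(ok2), 0.9)
  expect_gte(mean(ok1), 0.9)
})

test_that("collapse optimizer recovers a constructed scaling factor", {
  theta <- 2^2.36
  tgrid <- exp(seq(log(1), log(1e6), length.out = 300))
  master <- function(t) (1 - exp(-t / 4e5))^0.2
  gs <- 5:9
  curves <- lapply(gs, function(g) {
    tt <- tgrid / theta^(9 - g)  # unscaled time of the smaller system
    data.frame(t = tt, value = master(tt * theta^(9 - g)))
  })
  res <- collapse_factor(curves, gs, range = c(3, 8))
  expect_equal(res$factor, 5.13, tolerance = 0.011)
  # objective away from the optimum is worse (cf. visibly broader necks)
  obj_at <- function(f) {
    i <- which.min(abs(res$grid - f))
    res$objectives[i]
  }
  expect_gt(obj_at(4.51), res$objective)
  expect_gt(obj_at(5.71), res$objective)
  # identical curves need no shift: factor 1 is already perfect
  same <- lapply(1:3, function(i) data.frame(t = tgrid, value = master(tgrid)))
  res1 <- collapse_factor(same, c(7, 8, 9), range = c(1, 3))
  expect_equal(res1$factor, 1, tolerance = 1e-9)
  expect_equal(res1$objective, 0, tolerance = 1e-14)
})

test_that("collapse factor is invariant to a global time rescale", {
  theta <- 1.7
  master <- function(t) (1 + t)^0.1
  tgrid <- exp(seq(log(0.01), log(100), length.out = 200))
  mk <- function(scale) lapply(7:9, function(g) {
    tt <- tgrid / theta^(9 - g) * scale
    data.frame(t = tt, value = master(tt / scale * theta^(9 - g)))
  })
  r1 <- collapse_factor(mk(1), 7:9, range = c(1.2, 2.2))
  r2 <- collapse_factor(mk(100), 7:9, range = c(1.2, 2.2))
  expect_equal(r1$factor, r2$factor, tolerance = 1e-9)
  expect_equal(r1$factor, theta, tolerance = 0.011)
})
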