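test_that("synthetic ensembles are deterministic and honour the spec", {
  spec <- fixture_spec(replicas = 5, seed = 9)
  e1 <- synth_ensemble(spec)
  e2 <- synth_ensemble(spec)
  expect_identical(e1$rg2, e2$rg2)
  # zero noise, one replica: exactly the generating law
  s0 <- fixture_spec(noise_sd = 0, replicas = 1, seed = 2)
  e0 <- synth_ensemble(s0)
  expect_equal(sqrt(e0$rg2[, 1]), e0$truth, tolerance = 1e-12)
  # inconsistent stages at t = 0 rejected: bc < 1 lifts stage2(0) above R0
  expect_error(fixture_spec(R0 = 1, RF = 20, bc = 0.2), "inconsistent")
})

test_that("fixture ensemble mean converges to the generating law at CLT rate", {
  tgrid <- exp(seq(log(10), log(5e4), length.out = 40))
  dev <- vapply(c(10, 100, 1000), function(n) {
    ens <- synth_ensemble(fixture_spec(noise_sd = 0.05, replicas = n,
                                       times = tgrid, seed = 4))
    max(abs(rowMeans(sqrt(ens$rg2)) / ens$truth - 1))
  }, 0)
  expect_lt(dev[3], 0.005)                # 0.5% at 1000 replicas
  expect_lt(dev[3], dev[1])               # error shrinks with replicas
})

test_that("observable tables round-trip losslessly and validate input", {
  df <- data.frame(t = c(0, 0.1, 0.2), Rg2 = c(pi, exp(1), sqrt(2)),
                   lambda1 = c(1e-17, 2e8, 3.333333333333333))
  f <- tempfile(fileext = ".tsv")
  write_observables(df, f)
  back <- read_observables(f)
  expect_identical(back$t, df$t)
  expect_identical(back$Rg2, df$Rg2)
  expect_identical(back$lambda1, df$lambda1)
  # descending times rejected with the line number
  writeLines(c("t\tx", "1\t1", "0.5\t2"), f)
  expect_error(read_observables(f), "non-monotone time at line 3")
  # unknown extra columns preserved
  writeLines(c("t\tx\tmystery", "1\t1\tfoo", "2\t2\tbar"), f)
  expect_equal(read_observables(f)$mystery, c("foo", "bar"))
  writeLines(c("x\ty", "1\t1"), f)
  expect_error(read_observables(f), "missing required column")
})

test_that("XYZ trajectories round-trip and validate frames", {
  frames <- list(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3))
  f <- tempfile(fileext = ".xyz")
  write_xyz(frames, f, times = c(0, 2.5))
  expect_equal(length(readLines(f)), 8)  # (1 + 1 + 2) x 2 frames
  back <- read_xyz(f)
  expect_equal(back$frames[[2]], frames[[2]], tolerance = 1e-9)
  expect_equal(back$times, c(0, 2.5))
  expect_error(write_xyz(list(matrix(0, 2, 3), matrix(0, 3, 3)), f),
               "inconsistent")
  expect_warning(write_xyz(list(), f), "zero frames")
  expect_equal(length(readLines(f)), 0)
})

test_that("manifests capture config, seeds and checksums reproducibly", {
  d <- tempfile(); dir.create(d)
  obs <- data.frame(t = 0:2, Rg2 = c(1, 2, 3))
  fo <- file.path(d, "run.tsv")
  write_observables(obs, fo)
  fm <- file.path(d, "manifest.yaml")
  write_manifest(fm, config = list(N = 32, phi0 = 0.4, seed = 7),
                 seeds = c(11, 12), files = fo)
  m <- read_manifest(fm)
  expect_equal(m$config$N, 32)
  expect_equal(m$seeds, c(11, 12))
  expect_equal(m$inventory[[1]]$md5, unname(tools::md5sum(fo)))
})

test_that("the CLI covers help, units, and the fixture fitting path", {
  expect_output(st0 <- chainexpand_cli(character()), "Subcommands")
  expect_equal(st0, 0L)
  expect_output(chainexpand_cli("--help"), "Subcommands")
  expect_output(suppressMessages(stbad <- chainexpand_cli(c("nonsense"))),
                "Subcommands")
  expect_equal(stbad, 2L)
  expect_output(suppressMessages(stuse <- chainexpand_cli(
    c("units", "--badflag"))), "Subcommands")
  expect_equal(stuse, 2L)
  expect_output(st <- chainexpand_cli(
    c("units", "--sigma", "3.4e-10", "--mass", "5.3137e-25",
      "--kBT", "4.14e-21")), "3.8[56]")
  expect_equal(st, 0L)
  d <- tempfile(); dir.create(d)
  out <- file.path(d, "fx")
  expect_output(st1 <- chainexpand_cli(
    c("make-fixtures", "--replicas", "50", "--seed", "3", "--tau_c", "5000",
      "--out", out)), "wrote")
  expect_equal(st1, 0L)
  expect_true(file.exists(paste0(out, "_ensemble.tsv")))
  expect_output(st2 <- chainexpand_cli(
    c("fit-stage2", "--in", paste0(out, "_ensemble.tsv"),
      "--out", file.path(d, "f2"))), "tau_c")
  expect_equal(st2, 0L)
  rep <- yaml::read_yaml(file.path(d, "f2_fit.yaml"))
  expect_true(rep$converged)
  expect_lt(abs(rep$estimate$tau_c - 5000) / 5000, 0.1)
})

test_that("CLI ensemble runs are manifest-reproducible", {
  d <- tempfile(); dir.create(d)
  a <- file.path(d, "a"); b <- file.path(d, "b")
  expect_output(chainexpand_cli(c("ensemble", "--N", "16", "--phi0", "0.4",
    "--replicas", "2", "--seed", "5", "--tmax", "5", "--equil_steps", "5000",
    "--out", a)), "wrote")
  expect_output(chainexpand_cli(c("ensemble", "--N", "16", "--phi0", "0.4",
    "--replicas", "2", "--seed", "5", "--tmax", "5", "--equil_steps", "5000",
    "--out", b)), "wrote")
  ma <- read_manifest(paste0(a, "_manifest.yaml"))
  mb <- read_manifest(paste0(b, "_manifest.yaml"))
  expect_equal(ma$inventory[[1]]$md5, mb$inventory[[1]]$md5)
  expect_equal(ma$seeds, mb$seeds)
})
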