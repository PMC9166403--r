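# synthetic force-relaxation data with known ground truth

test_that("noiseless generation equals the resampled forward simulation", {
  cfg <- tiny_config()
  prot <- indentation_protocol()
  truth <- ref_params()
  g <- generate_curve(truth, prot, noise_sd = 0, config = cfg)
  direct <- resample_force_curve(run_stress_relaxation(truth, prot, cfg))
  expect_identical(g$force_N, direct$force_N)
  expect_identical(g$time_s, direct$time_s)
  expect_equal(attr(g, "provenance"), "synthetic")
  expect_identical(attr(g, "truth"), truth)
})

test_that("generation is deterministic under a seed and noise is unbiased", {
  cfg <- tiny_config()
  prot <- indentation_protocol()
  truth <- ref_params()
  a <- generate_curve(truth, prot, noise_sd = 3.5e-3, seed = 99, config = cfg)
  b <- generate_curve(truth, prot, noise_sd = 3.5e-3, seed = 99, config = cfg)
  expect_identical(a$force_N, b$force_N)
  c2 <- generate_curve(truth, prot, noise_sd = 3.5e-3, seed = 100, config = cfg)
  expect_false(identical(a$force_N, c2$force_N))
  # noise model: (noisy - clean) is centred Gaussian with the stated sd
  clean <- attr(a, "clean")
  sd0 <- 3.5e-3
  set.seed(1)
  eps <- unlist(lapply(1:40, function(i) {
    g <- generate_curve(truth, prot, noise_sd = sd0, seed = i, config = cfg)
    g$force_N - attr(g, "clean")$force_N
  }))
  n <- length(eps)
  expect_gt(n, 1000)
  expect_lt(abs(mean(eps)), 3 * sd0 / sqrt(n))
  expect_equal(sd(eps), sd0, tolerance = 0.1)
  expect_error(generate_curve(truth, prot, noise_sd = -1), "noise_sd")
})

test_that("sample sets honour distributions, bounds and determinism", {
  cfg <- tiny_config()
  # zero-variance distributions reproduce exactly the means
  s1 <- generate_sample_set(n = 1, seed = 5,
                            sds = c(E_f = 0, E_nf = 0, k_0 = 0, M = 0),
                            thickness_sd = 0, noise_sd = 0, config = cfg)
  expect_equal(s1$E_f, 3.13)
  expect_equal(s1$E_nf, 0.83)
  expect_equal(s1$k_0, 3.3e-3)
  expect_equal(s1$M, 1.67)
  expect_equal(s1$thickness, 0.13)
  # default-size cohort: n = 6 rows, all parameters inside the fit bounds
  s6 <- generate_sample_set(n = 6, seed = 7, config = cfg)
  expect_equal(nrow(s6), 6)
  fb <- fit_config()
  for (nm in c("E_f", "E_nf", "k_0", "M")) {
    expect_true(all(s6[[nm]] >= fb$lower[[nm]] & s6[[nm]] <= fb$upper[[nm]]))
  }
  expect_true(all(s6$thickness >= 0.11 & s6$thickness <= 0.18))
  expect_length(s6$curve, 6)
  # same seed regenerates identical draws and curves
  s6b <- generate_sample_set(n = 6, seed = 7, config = cfg)
  expect_identical(s6$E_f, s6b$E_f)
  expect_identical(s6$curve[[3]]$force_N, s6b$curve[[3]]$force_N)
  expect_error(generate_sample_set(n = 0), "n must")
})

test_that("recovery study reports one row per sample and exact noiseless recovery", {
  cfg <- tiny_config()
  set <- generate_sample_set(n = 2, seed = 3,
                             sds = c(E_f = 0.5, E_nf = 0.1, k_0 = 1e-3, M = 0.2),
                             noise_sd = 0, config = cfg)
  fc <- fit_config(n_starts = 2, maxit = 60, n_restarts = 0, reltol = 1e-6,
                   config = cfg)
  rep <- recovery_study(set, fc)
  expect_equal(nrow(rep), 2)
  expect_true(all(c("E_f_true", "E_f_fit", "E_f_relerr", "r_squared",
                    "nmse", "accepted", "ok") %in% names(rep)))
  expect_true(all(rep$ok))
  # inverse crime: noiseless self-generated curves recover the truth
  for (nm in c("E_f", "E_nf", "k_0", "M"))
    expect_true(all(rep[[paste0(nm, "_relerr")]] < 0.01))
  expect_true(all(rep$r_squared > 0.999))
})
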