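# objective functions and inverse identification machinery

toy_curve <- function(t, f) {
  structure(tibble::tibble(time_s = t, force_N = f),
            class = c("force_curve", class(tibble::tibble())))
}

test_that("NMSE matches hand arithmetic and its scaling identities", {
  t <- c(0, 1, 2, 3)
  meas <- toy_curve(t, c(1, 2, 3, 4))
  expect_equal(nmse(meas, meas), 0)
  # doubling the simulated curve: mean((f)^2)/mean(f^2) = 1
  sim2 <- toy_curve(t, 2 * c(1, 2, 3, 4))
  expect_equal(nmse(sim2, meas), 1, tolerance = 1e-12)
  # short printed series evaluated by hand:
  # diffs (0.5, -0.5, 1, 0): mse = (0.25+0.25+1)/4 = 0.375
  # mean(meas^2) = (1+4+9+16)/4 = 7.5 -> nmse = 0.05
  sim <- toy_curve(t, c(1.5, 1.5, 4, 4))
  expect_equal(nmse(sim, meas), 0.375 / 7.5, tolerance = 1e-12)
  # peak normalization divides by max(meas)^2 = 16
  expect_equal(nmse(sim, meas, normalization = "peak"), 0.375 / 16,
               tolerance = 1e-12)
  expect_error(nmse(sim, toy_curve(t, rep(0, 4))), "signal")
})

test_that("R-squared matches hand arithmetic and its limits", {
  t <- 0:3
  meas <- toy_curve(t, c(1, 2, 3, 4))
  expect_equal(r_squared(meas, meas), 1)
  # predicting the mean gives exactly zero
  mean_curve <- toy_curve(t, rep(2.5, 4))
  expect_equal(r_squared(mean_curve, meas), 0, tolerance = 1e-12)
  # hand evaluation: ss_res = 1.5, ss_tot = 5 -> 0.7
  sim <- toy_curve(t, c(1.5, 1.5, 4, 4))
  expect_equal(r_squared(sim, meas), 1 - 1.5 / 5, tolerance = 1e-12)
  expect_error(r_squared(sim, toy_curve(t, rep(1, 4))), "variance")
})

test_that("fit configuration validates bounds and start counts", {
  expect_error(fit_config(lower = c(E_f = -1, E_nf = 0.1, k_0 = 1e-4, M = 0.1)),
               "positive")
  expect_error(fit_config(n_starts = 1), "two starts")
  expect_error(fit_config(upper = c(E_f = 0.1, E_nf = 3, k_0 = 5e-2, M = 5)),
               "upper")
  fc <- fit_config()
  expect_equal(fc$nu_nf, 0.42)
  expect_named(fc$lower, c("E_f", "E_nf", "k_0", "M"))
})

test_that("parameter transform and box reflection are consistent", {
  est <- c(E_f = 3.13, E_nf = 0.83, k_0 = 3.3e-3, M = 1.67)
  th <- frpefit:::theta_from_params(as.list(est))
  expect_equal(frpefit:::params_from_theta(th), est)
  lo <- c(0, 0, -4, 0); hi <- c(10, 3, -1, 5)
  # inside the box: unchanged
  expect_equal(frpefit:::reflect_into(c(5, 1, -2, 2), lo, hi), c(5, 1, -2, 2))
  # outside: reflected back inside
  r <- frpefit:::reflect_into(c(12, -1, -5, 6), lo, hi)
  expect_true(all(r >= lo & r <= hi))
  expect_equal(r[1], 8)   # 12 reflects off 10 to 8
})

test_that("objective distinguishes each free parameter (identifiability smoke)", {
  cfg <- quick_config()
  prot <- indentation_protocol()
  truth <- ref_params()
  meas <- generate_curve(truth, prot, noise_sd = 0, config = cfg)
  # margins a +/-20% perturbation must produce; M only enters through the
  # compression-induced permeability change, so its imprint on the force
  # curve is orders of magnitude weaker than the other three parameters
  margin <- c(E_f = 1e-4, E_nf = 1e-4, k_0 = 1e-4, M = 1e-6)
  base <- c(E_f = 3.13, E_nf = 0.83, k_0 = 3.3e-3, M = 1.67)
  f0 <- nmse(run_stress_relaxation(truth, prot, cfg), meas)
  expect_lt(f0, 1e-20)
  for (nm in names(base)) {
    for (fac in c(0.8, 1.2)) {
      est <- base
      est[nm] <- est[nm] * fac
      p <- frpe_params(E_f = est[["E_f"]], E_nf = est[["E_nf"]], nu_nf = 0.42,
                       k_0 = est[["k_0"]], M = est[["M"]])
      fv <- nmse(run_stress_relaxation(p, prot, cfg), meas)
      expect_gt(fv, margin[[nm]])
    }
  }
})

test_that("parametric sweep reports the reference and all grid variants", {
  cfg <- tiny_config()
  prot <- indentation_protocol()
  # reference-only sweep equals a single reference run
  ref_only <- sweep_parameters(ref_params(), prot,
                               grids = list(E_f = 3.13), config = cfg)
  expect_equal(nrow(ref_only), 2)
  expect_true(all(ref_only$is_reference))
  expect_equal(ref_only$peak_force[1], ref_only$peak_force[2])
  single <- run_stress_relaxation(ref_params(), prot, cfg)
  expect_equal(ref_only$peak_force[1], max(single$force_N), tolerance = 1e-12)
  # the full grid set contains 1 reference + 8 variant runs
  g <- table2_grids()
  expect_equal(sum(lengths(g)), 12)
  expect_equal(g$k_0, c(0.1e-3, 3.3e-3, 6.5e-3), tolerance = 1e-12)
})
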