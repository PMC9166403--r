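# testing protocols: stress relaxation, contact criterion, compression modes

test_that("zero ramp amplitude yields an identically zero force curve", {
  prot <- indentation_protocol(ramp_amplitude = 0)
  cv <- run_stress_relaxation(ref_params(), prot, tiny_config())
  expect_true(all(cv$force_N == 0))
  expect_s3_class(cv, "force_curve")
})

test_that("stress relaxation peaks at the end of the ramp and decays monotonically", {
  cv <- run_stress_relaxation(ref_params(), indentation_protocol(),
                              quick_config())
  ipk <- which.max(cv$force_N)
  expect_equal(cv$time_s[ipk], 1)   # ramp = 0.04 mm / 0.04 mm/s
  expect_gt(cv$force_N[ipk], 0)
  post <- cv$force_N[ipk:nrow(cv)]
  expect_true(all(diff(post) <= 1e-9))
  # decays towards a positive equilibrium well below the peak
  expect_gt(utils::tail(post, 1), 0)
  expect_lt(utils::tail(post, 1), 0.9 * max(post))
})

test_that("identical configurations give bit-identical force curves", {
  a <- run_stress_relaxation(ref_params(), indentation_protocol(), tiny_config())
  b <- run_stress_relaxation(ref_params(), indentation_protocol(), tiny_config())
  expect_identical(a$force_N, b$force_N)
  expect_identical(a$time_s, b$time_s)
})

test_that("a stiffer fibril network raises the peak indentation force", {
  cfg <- quick_config()
  prot <- indentation_protocol()
  f1 <- max(run_stress_relaxation(cartilage_params(E_f = 3.13), prot, cfg)$force_N)
  f2 <- max(run_stress_relaxation(cartilage_params(E_f = 6.26), prot, cfg)$force_N)
  expect_gt(f2, f1)
})

test_that("peak force increases with ramp amplitude", {
  cfg <- tiny_config()
  peaks <- sapply(c(0.02, 0.03, 0.04), function(a) {
    prot <- indentation_protocol(ramp_amplitude = a)
    max(run_stress_relaxation(ref_params(), prot, cfg)$force_N)
  })
  expect_true(all(diff(peaks) > 0))
})

test_that("contact criterion offset inverts the force-displacement relation", {
  # synthetic linear force-displacement curve F = a * d, a = 1 N/mm
  curve <- tibble::tibble(displacement_mm = seq(0, 0.1, by = 0.001),
                          force_N = seq(0, 0.1, by = 0.001))
  expect_equal(apply_contact_criterion(curve, 0.01), 0.01, tolerance = 1e-12)
  # a curve already above the criterion needs no offset
  high <- tibble::tibble(displacement_mm = c(0, 1), force_N = c(0.5, 1))
  expect_equal(apply_contact_criterion(high, 0.01), 0)
  # criterion never reached
  low <- tibble::tibble(displacement_mm = c(0, 1), force_N = c(0, 1e-4))
  expect_error(apply_contact_criterion(low, 0.01), "never reached")
  expect_error(apply_contact_criterion(curve, -1), "criterion")
  # simulated curves reconstruct displacement from the protocol
  cv <- run_stress_relaxation(ref_params(), indentation_protocol(), tiny_config())
  off <- apply_contact_criterion(cv, 0.01)
  expect_gt(off, 0)
  expect_lt(off, 0.04)
})

test_that("unconfined compression recovers the drained isotropic limit", {
  cfg <- solver_config("default", nr = 8, nz = 6)
  # no fibrils: apparent ratio equals the matrix Poisson ratio
  u <- run_unconfined_compression(cartilage_params(E_f = 1e-9, nu_nf = 0.42),
                                  strain = 0.02, config = cfg)
  expect_true(u$equilibrated)
  expect_equal(u$apparent_poisson, 0.42, tolerance = 0.05)
  # zero matrix ratio and no fibrils: apparent ratio near zero
  u0 <- run_unconfined_compression(cartilage_params(E_f = 1e-9, nu_nf = 1e-9),
                                   strain = 0.02, config = cfg)
  expect_lt(abs(u0$apparent_poisson), 0.02)
})

test_that("confined compression behaves like 1-D consolidation", {
  p <- cartilage_params(E_f = 1e-9, M = 0)
  res <- run_confined_compression(p, strain = 1e-3, thickness = 1,
                                  config = quick_config(nz = 10))
  # pressure rises during loading and decays to zero at drained equilibrium
  expect_gt(max(res$p_base_MPa), 0)
  expect_lt(utils::tail(res$p_base_MPa, 1), 0.02 * max(res$p_base_MPa))
  expect_error(run_confined_compression(p, strain = 0.5), "strain")
})

test_that("force-curve resampling is dense on the ramp and log-spaced after", {
  cv <- run_stress_relaxation(ref_params(), indentation_protocol(), tiny_config())
  rs <- resample_force_curve(cv)
  expect_true(all(diff(rs$time_s) > 0))
  # uniform 10 Hz over the ramp
  ramp <- rs$time_s[rs$time_s <= 1 + 1e-9]
  expect_equal(diff(ramp), rep(0.1, length(ramp) - 1), tolerance = 1e-9)
  # resampled values interpolate the original curve
  expect_equal(max(abs(rs$force_N -
                         approx(cv$time_s, cv$force_N, rs$time_s)$y)), 0)
})
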