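# point-wise constitutive model: moduli, stresses, permeability, architecture

test_that("derived moduli follow the isotropic conversion formulas", {
  expect_equal(derived_moduli(1, 0), list(K_nf = 1 / 3, G_nf = 1 / 2))
  m <- derived_moduli(0.83, 0.42)
  expect_equal(m$K_nf, 0.83 / (3 * (1 - 0.84)), tolerance = 1e-12)
  expect_equal(m$G_nf, 0.83 / (2 * 1.42), tolerance = 1e-12)
  expect_equal(m$K_nf, 1.7292, tolerance = 1e-4)
  expect_equal(m$G_nf, 0.29225, tolerance = 1e-4)
  # near-incompressible trend: bulk modulus blows up relative to shear
  m2 <- derived_moduli(0.83, 0.499)
  expect_gt(m2$K_nf / m2$G_nf, 100)
  expect_error(derived_moduli(0.83, 0.5), "incompressible")
  expect_error(derived_moduli(-1, 0.3), "E_nf")
})

test_that("neo-Hookean matrix stress is zero at rest and matches the oracle", {
  m <- derived_moduli(0.83, 0.42)
  expect_equal(nonfibrillar_stress(diag(3), m), matrix(0, 3, 3),
               tolerance = 1e-14)
  # pure volumetric stretch: hydrostatic, deviatoric part vanishes
  lam <- 1.01
  s <- nonfibrillar_stress(diag(rep(lam, 3)), m)
  J <- lam^3
  expect_equal(s, 0.5 * m$K_nf * (J - 1 / J) * diag(3), tolerance = 1e-12)
  # uniaxial stretch vs independent R-side tensor arithmetic
  F <- diag(c(1.05, 1, 1))
  expect_equal(nonfibrillar_stress(F, m), oracle_neo_hookean(F, m$K_nf, m$G_nf),
               tolerance = 1e-12)
  # random states
  set.seed(42)
  for (i in 1:20) {
    F <- random_F()
    expect_equal(nonfibrillar_stress(F, m),
                 oracle_neo_hookean(F, m$K_nf, m$G_nf), tolerance = 1e-10)
  }
  expect_error(nonfibrillar_stress(diag(c(-1, 1, 1)), m), "det")
})

test_that("small-strain limit of the matrix stress is linear elasticity", {
  m <- derived_moduli(0.83, 0.42)
  eps <- 1e-5
  set.seed(7)
  H <- matrix(runif(9, -1, 1), 3, 3)
  F <- diag(3) + eps * H
  s <- nonfibrillar_stress(F, m)
  E_small <- 0.5 * (H + t(H)) * eps
  s_lin <- m$K_nf * sum(diag(E_small)) * diag(3) +
    2 * m$G_nf * (E_small - sum(diag(E_small)) / 3 * diag(3))
  expect_equal(s, s_lin, tolerance = 0.01)
})

test_that("fibril strain is the nominal stretch change along the direction", {
  expect_equal(fibril_strain(diag(3), c(1, 0, 0)), 0)
  expect_equal(fibril_strain(diag(3), c(0, 0, 1)), 0)
  expect_equal(fibril_strain(diag(c(1.1, 1, 1)), c(1, 0, 0)), 0.1,
               tolerance = 1e-12)
  # simple shear leaves a fibril along the shear plane unstretched
  Fs <- diag(3); Fs[1, 2] <- 0.2
  expect_equal(fibril_strain(Fs, c(1, 0, 0)), 0, tolerance = 1e-14)
  expect_error(fibril_strain(diag(3), c(1, 1, 0)), "unit")
})

test_that("fibril network stress is tension-only and matches hand evaluation", {
  p <- ref_params()
  arch <- build_cartilage_architecture(0)
  expect_equal(fibril_network_stress(diag(3), arch, p), matrix(0, 3, 3))
  # uniform compression leaves every fibril slack
  expect_equal(fibril_network_stress(0.9 * diag(3), arch, p), matrix(0, 3, 3),
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:10) {
    F <- diag(runif(3, 0.7, 1))  # all principal stretches <= 1
    expect_equal(fibril_network_stress(F, arch, p), matrix(0, 3, 3),
                 tolerance = 1e-12)
  }
  # single primary fibril along r: sigma_xx = C * E_f * eps
  arch1 <- structure(list(primary = matrix(c(1, 0, 0), 1, 3),
                          secondary = matrix(numeric(0), 0, 3), h = 0),
                     class = "fibril_architecture")
  s <- fibril_network_stress(diag(c(1.1, 1, 1)), arch1, p)
  expect_equal(s[1, 1], 12.16 * 3.13 * 0.1, tolerance = 1e-4)
  expect_equal(s[2:3, 1:3], matrix(0, 2, 3))
  # full architecture vs independent R oracle (up to the documented C1 blend
  # offset of at most w * E_f * 5e-6 per fibril, absolute)
  F <- diag(c(1.08, 0.95, 1.02))
  expect_lt(max(abs(fibril_network_stress(F, arch, p) -
                      oracle_fibril_network(F, arch, p))), 1e-3)
})

test_that("total stress obeys the effective-stress decomposition", {
  p <- ref_params()
  arch <- build_cartilage_architecture(0.5)
  st <- total_stress(diag(3), 0.5, arch, p)
  expect_equal(st$sigma_tot, -0.5 * diag(3))
  st0 <- total_stress(diag(3), 0, arch, p)
  expect_equal(st0$sigma_tot, matrix(0, 3, 3), tolerance = 1e-14)
  # identity holds to machine precision for random states
  set.seed(3)
  for (i in 1:20) {
    F <- random_F()
    pr <- runif(1, -1, 1)
    st <- total_stress(F, pr, arch, p)
    lhs <- st$sigma_tot
    rhs <- st$sigma_f + st$sigma_nf - pr * diag(3)
    expect_lt(max(abs(lhs - rhs)), 1e-12 * max(1, max(abs(lhs))))
    expect_equal(st$sigma_tot, t(st$sigma_tot), tolerance = 1e-12)
  }
})

test_that("both effective stresses transform objectively under rotations", {
  p <- ref_params()
  arch <- build_cartilage_architecture(0.2)
  set.seed(5)
  for (i in 1:10) {
    F <- random_F()
    Q <- random_rotation()
    a <- total_stress(F, 0, arch, p)
    b <- total_stress(Q %*% F, 0, arch, p)
    expect_equal(b$sigma_nf, Q %*% a$sigma_nf %*% t(Q), tolerance = 1e-9)
    expect_equal(b$sigma_f, Q %*% a$sigma_f %*% t(Q), tolerance = 1e-9)
  }
})

test_that("strain-dependent permeability follows k0 * J^M", {
  expect_equal(permeability(1, 3.3e-3, 1.67), 3.3e-3)
  expect_equal(permeability(0.8, 3.3e-3, 1.67), 3.3e-3 * 0.8^1.67,
               tolerance = 1e-12)
  expect_equal(permeability(c(0.5, 0.8, 1.3), 1, 0), rep(1, 3))
  # monotone increasing in J for M > 0
  J <- seq(0.5, 1.5, by = 0.1)
  expect_true(all(diff(permeability(J, 3.3e-3, 1.67)) > 0))
  expect_error(permeability(-0.1, 1, 1), "J")
})

test_that("void ratio and fluid-fraction profile match their definitions", {
  expect_equal(void_ratio(0.5), 1)
  expect_equal(void_ratio(0.72), 0.72 / 0.28, tolerance = 1e-12)
  expect_equal(void_ratio(0.8), 4, tolerance = 1e-12)
  expect_error(void_ratio(1), "inside")
  expect_equal(fluid_fraction_profile(0), 0.8)
  expect_equal(fluid_fraction_profile(1), 0.65)
  expect_equal(fluid_fraction_profile(0.5), 0.725)
  expect_error(fluid_fraction_profile(1.2), "depth")
})

test_that("meniscus fibril modulus spreads the circumferential stiffness", {
  expect_equal(meniscus_fibril_modulus(184, 12.16, 4), 184 / (12.16 * 4))
  # within one unit in the last printed digit of the reference value 3.79 MPa
  expect_lte(abs(meniscus_fibril_modulus(184, 12.16, 4) - 3.79), 0.011)
  expect_equal(meniscus_fibril_modulus(10 * 2, 10, 2), 1)
  expect_equal(meniscus_fibril_modulus(100, 10, 2), 5)
  expect_error(meniscus_fibril_modulus(0, 1, 1), "positive")
  m <- meniscus_params()
  expect_equal(m$E_f, 184 / (12.16 * 4), tolerance = 1e-12)
  expect_equal(m$n_fl_surface, 0.72)
})

test_that("fibril architecture rotates from surface-parallel to surface-normal", {
  a0 <- build_cartilage_architecture(0)
  expect_true(all(abs(a0$primary[, 2]) < 1e-14))  # no normal component
  a1 <- build_cartilage_architecture(1)
  expect_true(all(abs(a1$primary[, c(1, 3)]) < 1e-14))  # fully along normal
  for (h in c(0, 0.05, 0.25, 0.5, 0.77, 1)) {
    a <- build_cartilage_architecture(h)
    expect_equal(sqrt(rowSums(a$primary^2)), rep(1, 4), tolerance = 1e-12)
    expect_equal(sqrt(rowSums(a$secondary^2)), rep(1, 13), tolerance = 1e-12)
    # secondary set identical at all depths
    expect_identical(a$secondary, a0$secondary)
  }
  # continuous rotation: the angle from the surface plane grows with depth
  ang <- sapply(c(0.1, 0.2, 0.3, 0.4), function(h)
    asin(build_cartilage_architecture(h)$primary[1, 2]))
  expect_true(all(diff(ang) >= 0))
  expect_error(build_cartilage_architecture(1.5), "h must")
  expect_error(architecture_config(zone_superficial = 0.5, zone_middle = 0.3),
               "zone")
})

test_that("parameter container validates its invariants", {
  expect_error(frpe_params(E_f = -1), "E_f")
  expect_error(frpe_params(nu_nf = 0.5), "nu_nf")
  expect_error(frpe_params(k_0 = 0), "k_0")
  expect_error(frpe_params(M = -0.1), "M")
  expect_error(frpe_params(C = 0), "C")
  expect_error(frpe_params(n_fl_surface = 1.2), "fluid fraction")
  expect_equal(k0_from_si(3.30), 3.3e-3)
  p <- cartilage_params()
  expect_equal(p$E_f, 3.13)
  expect_equal(p$E_nf, 0.83)
  expect_equal(p$nu_nf, 0.42)
  expect_equal(p$k_0, 3.3e-3)
  expect_equal(p$M, 1.67)
  expect_equal(p$C, 12.16)
})
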