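# shared small fixtures for the test suite

# reference cartilage parameter set (mean fitted values)
ref_params <- function(...) cartilage_params(...)

# a quick coarse solver configuration for cheap runs
quick_config <- function(...) {
  solver_config("fit", ...)
}

# a very small protocol/solver pair for plumbing-only tests
tiny_config <- function() {
  solver_config("fit", nr = 5, nz = 3, n_ramp_steps = 4, dt_ratio = 2.5,
                dt_max = 150)
}

# random rotation matrix (Haar-ish via QR), deterministic under set.seed
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# random deformation gradient near identity with positive determinant
random_F <- function(spread = 0.1) {
  repeat {
    F <- diag(3) + matrix(runif(9, -spread, spread), 3, 3)
    if (det(F) > 0.2) return(F)
  }
}

# independent R-side evaluation of the neo-Hookean law (test oracle)
oracle_neo_hookean <- function(F, K_nf, G_nf) {
  J <- det(F)
  0.5 * K_nf * (J - 1 / J) * diag(3) +
    (G_nf / J) * (F %*% t(F) - J^(2 / 3) * diag(3))
}

# independent R-side fibril-network stress (test oracle, exact kink law)
oracle_fibril_network <- function(F, arch, params) {
  dirs <- rbind(arch$primary, arch$secondary)
  w <- c(rep(params$C, nrow(arch$primary)), rep(1, nrow(arch$secondary)))
  S <- matrix(0, 3, 3)
  for (i in seq_len(nrow(dirs))) {
    fe <- as.numeric(F %*% dirs[i, ])
    L <- sqrt(sum(fe^2))
    eps <- L - 1
    if (eps > 0) {
      eh <- fe / L
      S <- S + w[i] * params$E_f * eps * (eh %o% eh)
    }
  }
  S
}
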