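# Independent oracles used across the suite. None of these share code with
# the package's computational path.

# 2D quadrature of the Coulomb kernel k*sigma/|r - r'| over the disk,
# in polar coordinates centred on the field point: the Jacobian cancels the
# 1/s singularity, leaving the integral of the chord length to the boundary.
oracle_bg_potential <- function(rho, sigma, radius) {
  k <- 1 / (4 * pi * 8.8541878128e-12)
  vapply(rho, function(r0) {
    chord <- function(th) sqrt(radius^2 - r0^2 * sin(th)^2) - r0 * cos(th)
    k * sigma * stats::integrate(chord, 0, 2 * pi, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Brute-force triple-loop total energy; u3 uses the quadrature oracle.
oracle_total_energy <- function(ions, sites, params) {
  k <- 1 / (4 * pi * 8.8541878128e-12)
  q <- params$ion_charge
  n <- nrow(ions)
  u1 <- 0
  if (n > 0 && nrow(sites) > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(nrow(sites))) {
        d <- sqrt((ions$x[i] - sites$x[j])^2 + (ions$y[i] - sites$y[j])^2)
        u1 <- u1 + k * q * params$site_charge / d
      }
    }
  }
  u2 <- 0
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        d <- sqrt((ions$x[i] - ions$x[j])^2 + (ions$y[i] - ions$y[j])^2)
        u2 <- u2 + k * q^2 / d
      }
    }
  }
  u3 <- if (n > 0 && params$sigma != 0) {
    sum(q * oracle_bg_potential(sqrt(ions$x^2 + ions$y^2), params$sigma, params$radius))
  } else 0
  c(u1 = u1, u2 = u2, u3 = u3, total = u1 + u2 + u3)
}

# Pairwise ion-ion energy via stats::dist (independent pair enumeration).
oracle_u2_dist <- function(ions, q) {
  k <- 1 / (4 * pi * 8.8541878128e-12)
  k * q^2 * sum(1 / stats::dist(cbind(ions$x, ions$y)))
}

make_sites <- function(x, y, charge) {
  s <- tibble::tibble(angle = atan2(y, x), x = x, y = y)
  attr(s, "charge_per_site") <- charge
  s
}

# Smooth validation Hamiltonian for exact Boltzmann comparisons: a strongly
# confining background bowl plus one fixed charge OUTSIDE the disk at
# (2R, 0), giving angular structure without the 1/r collapse an on-rim
# attractor would cause at 300 K.
boltzmann_validation_scenario <- function(barrier = 0, n_rings = 5, seed = 11) {
  e <- physical_constants()$e
  R <- 1e-3
  params <- seed_model_params(
    n_ions = 1, n_ext_sites = 1, site_charge = -8e4 * e,
    radius = R, temperature = 300, barrier = barrier, n_rings = n_rings,
    step_size = R / 5, rng_seed = seed, background_sigma = -1.84e-9
  )
  list(params = params,
       sites = make_sites(2 * R, 0, -8e4 * e),
       ions = tibble::tibble(x = 0, y = 0))
}

# Grid-integrated Boltzmann density of the validation Hamiltonian on an
# nr x ntheta polar partition; each cell integrated on a fine subgrid
# (sub_r x sub_t per cell, 200 x 192 points overall with the defaults).
boltzmann_grid_oracle <- function(params, sites, nr = 20, nt = 16,
                                  sub_r = 10, sub_t = 12) {
  kB <- physical_constants()$kB
  k <- physical_constants()$k
  beta <- 1 / (kB * params$temperature)
  R <- params$radius
  q <- params$ion_charge
  out <- matrix(0, nr, nt)
  for (ir in seq_len(nr)) {
    rs <- ((ir - 1) + (seq_len(sub_r) - 0.5) / sub_r) * R / nr
    for (it in seq_len(nt)) {
      ts <- ((it - 1) + (seq_len(sub_t) - 0.5) / sub_t) * 2 * pi / nt
      g <- expand.grid(r = rs, th = ts)
      u <- q * background_potential(g$r, params$sigma, R)
      for (j in seq_len(nrow(sites))) {
        d <- sqrt((g$r * cos(g$th) - sites$x[j])^2 + (g$r * sin(g$th) - sites$y[j])^2)
        u <- u + k * q * params$site_charge / d
      }
      out[ir, it] <- sum(exp(-beta * u) * g$r)
    }
  }
  out / sum(out)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))
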