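e_ch <- physical_constants()$e

test_that("background potential matches its special values and the quadrature oracle", {
  p <- seed_model_params()  # sigma = -5.0997e-11 C/m^2, R = 1 mm
  eps0 <- physical_constants()$eps0

  expect_equal(background_potential(0, p$sigma, p$radius),
               p$sigma * p$radius / (2 * eps0), tolerance = 1e-12)
  expect_equal(background_potential(p$radius, p$sigma, p$radius),
               p$sigma * p$radius / (pi * eps0), tolerance = 1e-12)
  expect_equal(background_potential(0, p$sigma, p$radius), -2.880e-3, tolerance = 1e-3)
  expect_equal(background_potential(p$radius, p$sigma, p$radius), -1.833e-3,
               tolerance = 1e-3)
  expect_equal(background_potential(c(0.2, 0.7), 0, 1), c(0, 0))
  expect_error(background_potential(1.1, p$sigma, 1), class = "ionseed_out_of_domain")

  rho <- seq(0, p$radius, length.out = 50)
  closed <- background_potential(rho, p$sigma, p$radius)
  quad <- oracle_bg_potential(rho, p$sigma, p$radius)
  expect_lt(max(abs(closed / quad - 1)), 1e-6)
})

test_that("elliptic integral agrees with an independent implementation", {
  skip_if_not_installed("pracma")
  k <- seq(0, 0.9999, length.out = 200)
  ours <- vapply(k, ionseed:::ellip_e_cpp, numeric(1))
  ref <- vapply(k, function(kk) pracma::ellipke(kk^2)$e, numeric(1))
  expect_lt(max(abs(ours - ref)), 1e-12)
})

test_that("ion-site energy matches direct arithmetic and is linear in the charges", {
  p <- seed_model_params()
  ions <- tibble::tibble(x = 0, y = 0)
  sites <- make_sites(p$radius, 0, p$site_charge)

  expect_equal(energy_u1(ions, sites, p$ion_charge), -9.228e-20, tolerance = 1e-3)
  expect_equal(energy_u1(ions, sites[0, ], p$ion_charge), 0)

  set.seed(4)
  cfg <- sample_uniform_disk(20, p$radius)
  s2 <- sample_surface_sites(3, p$radius, p$site_charge)
  u <- energy_u1(cfg, s2, p$ion_charge)
  expect_equal(energy_u1(cfg, s2, p$ion_charge, site_charge = 2 * p$site_charge),
               2 * u, tolerance = 1e-12)
  expect_equal(energy_u1(cfg, s2, 3 * p$ion_charge), 3 * u, tolerance = 1e-12)
  expect_lt(u, 0)  # opposite charges attract
})

test_that("ion-ion energy counts each pair once and scales quadratically", {
  expect_equal(energy_u2(tibble::tibble(x = 0, y = 0), e_ch), 0)

  two <- tibble::tibble(x = c(0, 5e-4), y = c(0, 0))
  expect_equal(energy_u2(two, e_ch), 4.614e-25, tolerance = 1e-3)

  # three collinear equally spaced ions: k q^2 (1/d + 1/d + 1/(2d))
  d <- 2e-4
  three <- tibble::tibble(x = c(0, d, 2 * d), y = 0)
  kq2 <- physical_constants()$k * e_ch^2
  expect_equal(energy_u2(three, e_ch), kq2 * (2 / d + 1 / (2 * d)),
               tolerance = 1e-12)

  set.seed(5)
  cfg <- sample_uniform_disk(200, 1e-3)
  expect_equal(energy_u2(cfg, e_ch), oracle_u2_dist(cfg, e_ch), tolerance = 1e-10)
  expect_equal(energy_u2(cfg, 2 * e_ch), 4 * energy_u2(cfg, e_ch), tolerance = 1e-12)
})

test_that("background term is linear in sigma and minimised at the centre", {
  p <- seed_model_params()
  centre <- tibble::tibble(x = 0, y = 0)
  expect_equal(energy_u3(centre, p), -4.614e-22, tolerance = 1e-3)

  p0 <- seed_model_params(n_ions = 0)  # sigma = 0
  expect_equal(energy_u3(centre, p0), 0)

  set.seed(6)
  cfg <- sample_uniform_disk(30, p$radius)
  p2 <- seed_model_params(background_sigma = 2 * p$sigma)
  expect_equal(energy_u3(cfg, p2), 2 * energy_u3(cfg, p), tolerance = 1e-12)

  # |V| of the uniform disk is maximal at the centre (quadrature oracle)
  grid <- seq(0, p$radius, length.out = 21)
  vq <- oracle_bg_potential(grid, p$sigma, p$radius)
  expect_true(all(diff(vq) > 0))  # negative, increasing toward the rim
})

test_that("total energy equals the brute-force triple-loop oracle", {
  p <- seed_model_params(n_ions = 5, n_ext_sites = 2)
  set.seed(7)
  ions <- sample_uniform_disk(5, p$radius)
  sites <- sample_surface_sites(2, p$radius, p$site_charge)

  eb <- total_energy(ions, sites, p)
  expect_equal(eb$total, eb$u1 + eb$u2 + eb$u3, tolerance = 1e-15)
  expect_equal(eb$per_ion_total, eb$total / 5, tolerance = 1e-15)

  orc <- oracle_total_energy(ions, sites, p)
  expect_equal(eb$u1, unname(orc["u1"]), tolerance = 1e-10)
  expect_equal(eb$u2, unname(orc["u2"]), tolerance = 1e-10)
  expect_equal(eb$u3, unname(orc["u3"]), tolerance = 1e-6)
  expect_equal(eb$total, unname(orc["total"]), tolerance = 1e-6)

  empty <- total_energy(tibble::tibble(x = numeric(0), y = numeric(0)),
                        sites[0, ], p)
  expect_equal(empty$total, 0)
  expect_true(is.na(empty$per_ion_total))
})

test_that("single-move energy difference matches a full recompute", {
  p <- seed_model_params(n_ions = 50, n_ext_sites = 4)
  set.seed(8)
  ions <- sample_uniform_disk(50, p$radius)
  sites <- sample_surface_sites(4, p$radius, p$site_charge)
  u0 <- total_energy(ions, sites, p)$total

  expect_equal(delta_energy(ions, sites, p, 1, c(ions$x[1], ions$y[1])), 0)

  for (rep in 1:50) {
    i <- sample.int(50, 1)
    np <- sample_uniform_disk(1, p$radius)
    newpos <- c(np$x, np$y)
    du <- delta_energy(ions, sites, p, i, newpos)
    moved <- ions
    moved$x[i] <- newpos[1]; moved$y[i] <- newpos[2]
    full <- total_energy(moved, sites, p)$total - u0
    expect_equal(du, full, tolerance = 1e-10)
  }

  # moving toward an opposite-signed site lowers the site term
  one <- tibble::tibble(x = 0, y = 0)
  s <- make_sites(p$radius, 0, p$site_charge)
  closer <- c(p$radius / 2, 0)
  expect_lt(energy_u1(tibble::tibble(x = closer[1], y = closer[2]), s, p$ion_charge),
            energy_u1(one, s, p$ion_charge))
})

test_that("sub-min_separation distances raise singularity errors", {
  p <- seed_model_params(n_ions = 2, min_separation = 1e-9)
  ions <- tibble::tibble(x = c(0, 1e-10), y = c(0, 0))
  sites <- sample_surface_sites(0, p$radius)
  expect_error(total_energy(ions, sites, p), "min_separation")

  ions2 <- tibble::tibble(x = c(0, 5e-4), y = c(0, 0))
  s_on_ion <- make_sites(5e-4 + 1e-11, 0, p$site_charge)
  expect_error(total_energy(ions2, s_on_ion, p), "min_separation")
  expect_error(delta_energy(ions2, s_on_ion[0, ], p, 2, c(1e-11, 0)),
               "min_separation")
})
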