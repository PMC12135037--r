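kB <- physical_constants()$kB

test_that("proposals are isotropic, bounded by the step size, and flagged at the wall", {
  ions <- tibble::tibble(x = 0, y = 0)
  set.seed(10)
  step <- 0.02
  prop <- purrr::map_dfr(1:5000, ~propose_move(ions, 1, step, 1))
  d <- sqrt(prop$x^2 + prop$y^2)
  expect_true(all(d <= step + 1e-15))
  # isotropy: each coordinate of a uniform-disk displacement has sd = step/2
  expect_lt(abs(mean(prop$x)), 3 * (step / 2) / sqrt(5000))
  expect_lt(abs(mean(prop$y)), 3 * (step / 2) / sqrt(5000))
  expect_true(all(prop$valid))

  # from the wall, proposals leaving the disk are flagged invalid
  wall <- tibble::tibble(x = 1, y = 0)
  pw <- purrr::map_dfr(1:500, ~propose_move(wall, 1, step, 1))
  expect_true(all(pw$valid == (pw$x^2 + pw$y^2 <= 1)))
  expect_gt(sum(!pw$valid), 0)

  expect_error(propose_move(ions, 1, 0, 1), class = "ionseed_invalid_parameter")
  expect_error(propose_move(ions, 2, 0.1, 1), class = "ionseed_invalid_parameter")
})

test_that("acceptance probability reproduces the canonical form with the barrier factor", {
  kT <- kB * 300
  expect_equal(acceptance_probability(0, 0, 300, 0), 1)
  expect_equal(acceptance_probability(kT, 0, 300, 0), 0.36788, tolerance = 1e-4)
  expect_equal(acceptance_probability(0, 1, 300, 4 * kT), 0.018316, tolerance = 1e-4)
  # downhill moves without crossings are always accepted
  expect_equal(acceptance_probability(-5 * kT, 0, 300, 4 * kT), 1)
  # barrier factor multiplies per crossing
  expect_equal(acceptance_probability(0, 2, 300, kT), exp(-2), tolerance = 1e-12)
  expect_error(acceptance_probability(0, 0, -1, 0), class = "ionseed_invalid_parameter")
})

test_that("zero iterations leave the configuration unchanged with an empty trace", {
  s <- gen_mc_scenario("tiny", rng_seed = 1)$params
  run <- run_mc(s, 0)
  expect_identical(nrow(run$trace), 0L)
  expect_equal(run$final$x, run$initial$x)
  expect_equal(run$final$y, run$initial$y)
})

test_that("runs are bit-reproducible given seed and parameters", {
  s <- gen_mc_scenario("tiny", rng_seed = 42)$params
  r1 <- suppressWarnings(run_mc(s, 2e4))
  r2 <- suppressWarnings(run_mc(s, 2e4))
  expect_identical(r1$final, r2$final)
  expect_identical(r1$trace, r2$trace)
  expect_identical(summarise_run(r1), summarise_run(r2))
})

test_that("energy per ion decreases in expectation from the random initial state", {
  diffs <- vapply(1:20, function(seed) {
    s <- gen_mc_scenario("tiny", rng_seed = seed)$params
    r <- suppressWarnings(run_mc(s, 1e4, record_every = 100))
    tail(r$trace$energy_per_ion, 1) - r$initial_energy_per_ion
  }, numeric(1))
  expect_lt(mean(diffs), 0)
  expect_gte(sum(diffs < 0), 15)
})

test_that("convergence detection matches closed-form window means", {
  # constant trace: converged at the end of the second window
  const <- gen_trace("constant", n = 400, record_every = 100)
  expect_equal(detect_convergence(const, window = 50), 100 * 100)

  # strictly linear decrease never stabilises
  lin <- tibble::tibble(iteration = 100 * (1:400),
                        energy_per_ion = -seq(1, 400) * 1e-22)
  expect_true(is.na(detect_convergence(lin, window = 50, rel_tol = 1e-4)))

  # exponential decay with known tau: window means are A*(tau/w)*exp(-t/tau)*(1-exp(-w/tau))
  tau <- 1e4; w_rec <- 50; rec <- 100; w_it <- w_rec * rec
  tr <- gen_trace("exponential_decay", n = 2000, value = -1, amplitude = 0.3,
                  tau = tau, record_every = rec)
  got <- detect_convergence(tr, window = w_rec, rel_tol = 1e-4)
  # oracle: first window pair whose means differ by < rel_tol relatively
  wm <- vapply(seq_len(2000 / w_rec), function(b) {
    mean(-1 + 0.3 * exp(-(rec * ((b - 1) * w_rec + seq_len(w_rec))) / tau))
  }, numeric(1))
  first <- which(abs(diff(wm)) / abs(wm[-length(wm)]) < 1e-4)[1]
  expect_equal(got, (first + 1) * w_it)
  expect_gte(got, 3 * tau)
  expect_lte(got, 8 * tau)

  expect_error(detect_convergence(tr[1:40, ], window = 50),
               class = "ionseed_insufficient_data")
})

test_that("equilibrium energy estimator is unbiased with a sound batch-means error", {
  const <- gen_trace("constant", n = 500, value = -1.45e-20)
  eq <- equilibrium_energy(const, burn_in = 0.5)
  expect_equal(eq$mean, -1.45e-20)
  expect_equal(eq$se, 0)

  # i.i.d. gaussian recordings: mean within 3 SE of truth
  set.seed(12)
  iid <- tibble::tibble(iteration = 1:4000,
                        energy_per_ion = rnorm(4000, -1e-20, 1e-22))
  eqi <- equilibrium_energy(iid, burn_in = 0.25)
  expect_lt(abs(eqi$mean - (-1e-20)), 3 * 1e-22 / sqrt(3000))

  # AR(1): asymptotic sd of the mean is innov_sd / ((1 - phi) sqrt(n))
  set.seed(13)
  ar <- gen_trace("ar1", n = 2e4, value = 0, phi = 0.9, innov_sd = 1e-22)
  eqa <- equilibrium_energy(ar, burn_in = 0, n_batches = 40)
  analytic <- 1e-22 / (1 - 0.9) / sqrt(2e4)
  expect_lt(abs(eqa$se / analytic - 1), 0.2)

  expect_error(equilibrium_energy(const[0, ]), class = "ionseed_insufficient_data")
})

test_that("tidy and glance expose the trace and the run summary", {
  s <- gen_mc_scenario("tiny", rng_seed = 3)$params
  r <- suppressWarnings(run_mc(s, 1e4))
  expect_identical(tidy(r), r$trace)
  g <- glance(r)
  expect_identical(g, summarise_run(r))
  expect_equal(g$n_ions, 20L)
  expect_equal(g$equilibrium_energy_per_ion,
               equilibrium_energy(r$trace, burn_in = 0.5)$mean)
})
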