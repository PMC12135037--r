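test_that("etch-depth calibration is linear and matches both protocols", {
  a <- etch_protocol("a")
  b <- etch_protocol("b")
  expect_equal(depth_from_cycles(a, 0), 0)
  expect_equal(depth_from_cycles(b, 10), 216, tolerance = 1e-12)
  expect_equal(depth_from_cycles(a, 15), 100.5, tolerance = 1e-12)
  expect_true(b$pre_etch)
  expect_false(a$pre_etch)

  cyc <- 0:10
  expect_equal(depth_from_cycles(b, cyc), cyc * 21.6, tolerance = 1e-12)
  expect_error(depth_from_cycles(b, 11), class = "ionseed_invalid_parameter")
  expect_error(depth_from_cycles(a, -1), class = "ionseed_invalid_parameter")
  expect_error(etch_protocol("c", rate_nm_per_cycle = -1, n_cycles = 5),
               class = "ionseed_invalid_parameter")
})

test_that("silicate oxygen correction subtracts 2 O per Si and clamps at zero", {
  expect_equal(as.numeric(organic_oxygen(12.3, 0)), 12.3)
  expect_equal(as.numeric(organic_oxygen(37.6, 4.8)), 28.0, tolerance = 1e-12)
  expect_equal(as.numeric(organic_oxygen(9.2, 0.4)), 8.4, tolerance = 1e-12)

  expect_warning(res <- organic_oxygen(c(10, 1), c(1, 3)),
                 class = "ionseed_oxygen_clamped")
  expect_equal(as.numeric(res), c(8, 0))
  expect_identical(attr(res, "clamped"), c(FALSE, TRUE))

  set.seed(30)
  o <- runif(100, 0, 50); si <- runif(100, 0, 30)
  expect_true(all(suppressWarnings(organic_oxygen(o, si)) >= 0))

  # alternate stoichiometry for sensitivity analysis
  expect_equal(as.numeric(organic_oxygen(37.6, 4.8, sio2_ratio = 1.5)),
               37.6 - 1.5 * 4.8)
})

test_that("element ratios match direct arithmetic and are scale invariant", {
  t1 <- tibble::tibble(cycle = c(0, 1), C = c(88.5, 52.8), O = c(9.2, 37.6),
                       Si = c(0.4, 4.8), N = c(0.8, 2.1))
  r <- element_ratio(t1, "O", "C")
  expect_equal(r$ratio_O_C, c(9.2 / 88.5, 37.6 / 52.8), tolerance = 1e-12)
  expect_equal(r$ratio_O_C[1], 0.1040, tolerance = 1e-3)

  red <- reduce_depth_profile(t1, etch_protocol("a", n_cycles = 1))
  ro <- element_ratio(red, "O", "C", use_organic_o = TRUE)
  expect_equal(ro$ratio_O_C[2], 28.0 / 52.8, tolerance = 1e-12)
  expect_equal(ro$ratio_O_C[2], 0.5303, tolerance = 1e-3)

  rn <- element_ratio(t1, "N", "C")
  expect_equal(rn$ratio_N_C[1], 0.00904, tolerance = 1e-3)

  expect_equal(element_ratio(t1, "C", "C")$ratio_C_C, c(1, 1))

  # multiplying all percentages by a constant leaves ratios unchanged
  t2 <- dplyr::mutate(t1, dplyr::across(c("C", "O", "Si", "N"), ~ .x * 3.7))
  expect_equal(element_ratio(t2, "O", "C")$ratio_O_C, r$ratio_O_C,
               tolerance = 1e-12)

  t3 <- tibble::tibble(cycle = 0, O = 5, C = 0)
  expect_warning(rz <- element_ratio(t3, "O", "C"),
                 class = "ionseed_undefined_ratio")
  expect_true(is.na(rz$ratio_O_C))
  expect_error(element_ratio(t1, "K", "C"), class = "ionseed_invalid_parameter")
})

test_that("delimited profiles are read from both comma and tab dialects", {
  tbl <- tibble::tibble(cycle = 0:3, C = c(60, 58, 57, 55), O = c(30, 31, 32, 33),
                        K = c(2, 1.8, 1.7, 1.6))
  fc <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl, fc)
  ft <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tbl, ft)
  expect_equal(as.data.frame(read_depth_profile(fc)), as.data.frame(tbl))
  expect_equal(as.data.frame(read_depth_profile(ft)), as.data.frame(tbl))

  # cycle column inferred from row order when absent
  fn <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tbl[-1], fn)
  inferred <- read_depth_profile(fn)
  expect_equal(inferred$cycle, 0:3)
})

test_that("treated-vs-control comparison recovers known enrichment structure", {
  proto <- etch_protocol("a")
  base <- tibble::tibble(cycle = 0:15)
  base$depth_nm <- depth_from_cycles(proto, base$cycle)
  control <- dplyr::mutate(base, K = 0.6, Ca = 0.3, N = 0.8)

  # identical tables: ratios 1, ties count one half
  same <- enrichment_summary(control, control, c("K", "Ca", "N"))
  expect_equal(same$ratio, rep(1, 3))
  expect_equal(same$frac_treated_higher, rep(0.5, 3))

  # constant +1% potassium everywhere
  up <- dplyr::mutate(control, K = K + 1)
  s <- enrichment_summary(up, control, "K")
  expect_equal(s$frac_treated_higher, 1)
  expect_equal(s$mean_treated - s$mean_control, 1, tolerance = 1e-12)

  # generated pair with known amplitudes: enrichment detected in K, Ca, N
  spec_t <- profile_gen_spec(noise_cv = 0.05, protocol = proto, rng_seed = 31)
  spec_c <- profile_gen_spec(
    amplitude = c(O = 0, Si = 0, N = 0, K = 0, P = 0, Ca = 0),
    noise_cv = 0.05, protocol = proto, rng_seed = 32
  )
  summ <- enrichment_summary(
    reduce_depth_profile(gen_depth_profile(spec_t), proto),
    reduce_depth_profile(gen_depth_profile(spec_c), proto),
    c("K", "Ca", "N")
  )
  expect_true(all(summ$ratio > 1))
  expect_true(all(summ$frac_treated_higher >= 0.8))

  # non-overlapping depth grids are refused
  shifted <- dplyr::mutate(control, depth_nm = depth_nm + 1e4)
  expect_error(enrichment_summary(shifted, control, "K"),
               class = "ionseed_incomparable_profiles")
})

test_that("noiseless exponential enrichment is recovered to numerical precision", {
  proto <- etch_protocol("a", n_cycles = 30)
  spec <- profile_gen_spec(noise_cv = 0, protocol = proto)
  tbl <- gen_depth_profile(spec)
  fit <- fit_depth_enrichment(tbl, "K")
  expect_equal(fit$decay_length, 100, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1.1, tolerance = 1e-6)
  expect_equal(fit$baseline, 0.6, tolerance = 1e-6)
})
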