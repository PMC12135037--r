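#' Specification for a synthetic XPS depth profile
#'
#' Describes the expected composition of a seed-hull depth profile: a deep
#' (matrix) baseline per element, a surface enrichment amplitude decaying
#' exponentially with depth, multiplicative lognormal measurement noise, and
#' an etching protocol fixing the depth grid. One element (carbon, by
#' default) acts as the balance: its expected value is `100 - sum(others)`,
#' so expected compositions sum to exactly 100 at every depth and surface
#' enrichment of minority elements is mirrored by carbon depletion, as
#' observed on plasma-treated seeds.
#'
#' Defaults are anchored to measured surface compositions of control and
#' plasma-treated barley seeds: the baseline is the control composition
#' (C 88.5, O 9.2, Si 0.4, N 0.8, K 0.6, P 0.2, Ca 0.3 atomic %) and the
#' default amplitudes reproduce the treated surface composition at depth 0
#' (C 52.8, O 37.6, Si 4.8, N 2.1, K 1.7, P 0.2, Ca 0.8).
#'
#' @param baseline Named numeric vector of deep-matrix atomic % for every
#'   element except the balance element.
#' @param amplitude Named numeric vector of surface enrichment amplitudes
#'   (atomic % at depth 0), same names as `baseline`.
#' @param decay_length Named numeric vector of 1/e depths (nm), same names.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (>= 0).
#' @param protocol An [etch_protocol()] fixing cycles and depth per cycle.
#' @param balance_element Name of the balance element (default `"C"`).
#' @param rng_seed Optional integer seed.
#' @return An object of class `profile_gen_spec`.
#' @export
profile_gen_spec <- function(baseline = c(O = 9.2, Si = 0.4, N = 0.8,
                                          K = 0.6, P = 0.2, Ca = 0.3),
                             amplitude = c(O = 28.4, Si = 4.4, N = 1.3,
                                           K = 1.1, P = 0, Ca = 0.5),
                             decay_length = c(O = 80, Si = 50, N = 100,
                                              K = 100, P = 50, Ca = 100),
                             noise_cv = 0.05,
                             protocol = etch_protocol("a"),
                             balance_element = "C",
                             rng_seed = NULL) {
  els <- names(baseline)
  if (is.null(els) || !identical(sort(els), sort(names(amplitude))) ||
      !identical(sort(els), sort(names(decay_length)))) {
    abort("`baseline`, `amplitude` and `decay_length` must share element names.",
          class = "ionseed_invalid_parameter")
  }
  amplitude <- amplitude[els]
  decay_length <- decay_length[els]
  if (any(baseline < 0) || sum(baseline) > 100) {
    abort("`baseline` must be >= 0 and sum to <= 100.",
          class = "ionseed_invalid_parameter")
  }
  if (any(decay_length <= 0)) {
    abort("`decay_length` must be > 0.", class = "ionseed_invalid_parameter")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.", class = "ionseed_invalid_parameter")
  if (sum(baseline + amplitude) > 100) {
    abort("Infeasible composition: baseline + amplitude exceeds 100% at the surface.",
          class = "ionseed_invalid_spec")
  }
  structure(
    list(baseline = baseline, amplitude = amplitude,
         decay_length = decay_length, noise_cv = noise_cv,
         protocol = protocol, balance_element = balance_element,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "profile_gen_spec"
  )
}

#' Generate a synthetic XPS depth profile
#'
#' Element `e` at depth `z` has expected atomic %
#' `baseline_e + amplitude_e * exp(-z / decay_length_e)`; the balance
#' element takes up the remainder to 100. Mean-one multiplicative lognormal
#' noise with the requested coefficient of variation is applied per cell and
#' rows are renormalised to sum to 100 (compositions are closed).
#'
#' @param spec A [profile_gen_spec()].
#' @return A depth-profile tibble (`cycle`, `depth_nm`, one column per
#'   element) with attribute `truth` carrying the generating spec.
#' @export
gen_depth_profile <- function(spec) {
  stopifnot(inherits(spec, "profile_gen_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  cycles <- 0:spec$protocol$n_cycles
  z <- depth_from_cycles(spec$protocol, cycles)
  els <- names(spec$baseline)

  expected <- vapply(els, function(e) {
    spec$baseline[[e]] + spec$amplitude[[e]] * exp(-z / spec$decay_length[[e]])
  }, numeric(length(z)))
  expected <- matrix(expected, nrow = length(z),
                     dimnames = list(NULL, els))
  bal <- 100 - rowSums(expected)
  if (any(bal < 0)) {
    abort("Infeasible composition: minority elements exceed 100% at some depth.",
          class = "ionseed_invalid_spec")
  }
  comp <- cbind(expected, setNames(data.frame(bal), spec$balance_element))
  comp <- as.matrix(comp[, c(spec$balance_element, els)])

  if (spec$noise_cv > 0) {
    sdlog <- sqrt(log(1 + spec$noise_cv^2))
    noise <- matrix(rlnorm(length(comp), meanlog = -sdlog^2 / 2, sdlog = sdlog),
                    nrow = nrow(comp))
    comp <- comp * noise
  }
  comp <- comp / rowSums(comp) * 100

  out <- dplyr::bind_cols(tibble(cycle = cycles, depth_nm = z), as_tibble(comp))
  attr(out, "truth") <- spec
  out
}

#' Reference simulation scenarios
#'
#' Named parameter presets with a descriptor of the behaviour each is
#' expected to show:
#' * `"reference"` - the reference conditions: N = 1000 singly charged cations,
#'   N_ext = 10 perimeter sites of -4e5 elementary charges each, R = 1 mm,
#'   T = 300 K, E0 = 4 kT. Expected: surface enrichment at equilibrium.
#' * `"tiny"` - N = 20, N_ext = 2; fast smoke-test scale.
#' * `"no_plasma"` - N_ext = 0: the neutral, untreated seed. Expected:
#'   near-uniform equilibrium profile.
#' * `"single_ion"` - N = 1 with a single, milder perimeter charge
#'   (-2e4 elementary charges) whose Boltzmann density a quadrature grid
#'   can resolve; used for exact sampler validation.
#'
#' @param preset One of `"reference"`, `"tiny"`, `"no_plasma"`, `"single_ion"`.
#' @param rng_seed Optional seed stored in the parameters.
#' @return List with elements `params` ([seed_model_params()]) and `expect`
#'   (a descriptor list with a human-readable `behaviour` field).
#' @export
gen_mc_scenario <- function(preset = c("reference", "tiny", "no_plasma", "single_ion"),
                            rng_seed = NULL) {
  preset <- match.arg(preset)
  e <- physical_constants()$e
  params <- switch(preset,
    reference = seed_model_params(rng_seed = rng_seed),
    tiny = seed_model_params(n_ions = 20, n_ext_sites = 2, rng_seed = rng_seed),
    no_plasma = seed_model_params(n_ext_sites = 0, rng_seed = rng_seed),
    single_ion = seed_model_params(n_ions = 1, n_ext_sites = 1,
                                   site_charge = -2e4 * e, rng_seed = rng_seed)
  )
  expect <- switch(preset,
    reference = list(behaviour = "outer-ring concentration exceeds the uniform reference at equilibrium",
                 enrichment = "ratio > 1"),
    tiny = list(behaviour = "fast smoke-test scale; same qualitative enrichment"),
    no_plasma = list(behaviour = "no external drive: equilibrium ring occupancy stays near uniform",
                     enrichment = "ratio ~ 1"),
    single_ion = list(behaviour = "sampled density matches the grid-integrated Boltzmann density")
  )
  list(params = params, expect = expect)
}

#' Generate synthetic energy traces with known ground truth
#'
#' For testing the convergence detector and the equilibrium-energy
#' estimator on traces whose limiting behaviour is known in closed form.
#'
#' @param kind `"constant"`, `"exponential_decay"` or `"ar1"`.
#' @param n Number of recordings.
#' @param value Stationary (or constant) energy per ion (J).
#' @param amplitude Initial excess above `value` for the exponential decay.
#' @param tau Decay time constant in iterations.
#' @param phi AR(1) coefficient (|phi| < 1).
#' @param innov_sd AR(1) innovation standard deviation.
#' @param record_every Iterations between recordings.
#' @return A trace tibble (`iteration`, `energy_per_ion`) with attribute
#'   `truth` describing the generating process.
#' @export
gen_trace <- function(kind = c("constant", "exponential_decay", "ar1"),
                      n, value = -1.45e-20, amplitude = 2e-21,
                      tau = 1e4, phi = 0.9, innov_sd = 1e-22,
                      record_every = 100) {
  kind <- match.arg(kind)
  it <- record_every * seq_len(n)
  energy <- switch(kind,
    constant = rep(value, n),
    exponential_decay = value + amplitude * exp(-it / tau),
    ar1 = {
      if (abs(phi) >= 1) abort("`phi` must satisfy |phi| < 1.",
                               class = "ionseed_invalid_parameter")
      x <- numeric(n)
      x[1] <- rnorm(1, 0, innov_sd / sqrt(1 - phi^2))
      for (i in seq_len(n - 1)) x[i + 1] <- phi * x[i] + rnorm(1, 0, innov_sd)
      value + x
    }
  )
  out <- tibble(iteration = it, energy_per_ion = energy,
                acceptance_rate = NA_real_)
  attr(out, "truth") <- list(kind = kind, value = value, amplitude = amplitude,
                             tau = tau, phi = phi, innov_sd = innov_sd,
                             record_every = record_every,
                             stationary_var = if (kind == "ar1") innov_sd^2 / (1 - phi^2) else 0)
  out
}
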