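#' Propose an isotropic single-ion displacement
#'
#' The candidate position is the current one plus a displacement uniform in
#' a disk of radius `step_size`. Candidates falling outside the seed disk are
#' flagged invalid; the sampler rejects them outright (hard confinement).
#'
#' @param ions Tibble of cation positions.
#' @param ion 1-based index of the cation to move.
#' @param step_size Proposal disk radius (metre, > 0).
#' @param radius Seed disk radius (metre), used for the validity flag.
#' @return One-row tibble with `x`, `y`, `valid`.
#' @export
propose_move <- function(ions, ion, step_size, radius) {
  if (step_size <= 0) abort("`step_size` must be > 0.", class = "ionseed_invalid_parameter")
  if (ion < 1 || ion > nrow(ions)) {
    abort("`ion` index out of range.", class = "ionseed_invalid_parameter")
  }
  repeat {
    dx <- runif(1, -step_size, step_size)
    dy <- runif(1, -step_size, step_size)
    if (dx^2 + dy^2 <= step_size^2) break
  }
  x <- ions$x[ion] + dx
  y <- ions$y[ion] + dy
  tibble(x = x, y = y, valid = x^2 + y^2 <= radius^2)
}

#' Metropolis acceptance probability with a cell-crossing barrier
#'
#' The sampler targets the canonical distribution `exp(-U / kT) / Z`. Moves
#' between neighbouring equal-area cells additionally pay an activation
#' energy `barrier` per boundary crossed, entering as a symmetric factor
#' `exp(-barrier * n_crossed / kT)` that slows diffusion without changing the
#' stationary distribution (the crossing count is the same in both
#' directions, so detailed balance is preserved).
#'
#' @param delta_u Energy difference `U(after) - U(before)` (joule).
#' @param n_boundaries_crossed Number of ring boundaries the move crosses.
#' @param temperature Absolute temperature (kelvin, > 0).
#' @param barrier Activation energy per crossing (joule, >= 0).
#' @return Acceptance probability in `[0, 1]` (vectorised).
#' @examples
#' kT <- physical_constants()$kB * 300
#' acceptance_probability(kT, 0, 300, 0)      # exp(-1)
#' acceptance_probability(0, 1, 300, 4 * kT)  # exp(-4)
#' @export
acceptance_probability <- function(delta_u, n_boundaries_crossed,
                                   temperature, barrier) {
  if (any(temperature <= 0)) {
    abort("`temperature` must be > 0.", class = "ionseed_invalid_parameter")
  }
  if (any(barrier < 0)) {
    abort("`barrier` must be >= 0.", class = "ionseed_invalid_parameter")
  }
  beta <- 1 / (physical_constants()$kB * temperature)
  exp(-beta * barrier * n_boundaries_crossed) * pmin(1, exp(-beta * delta_u))
}

#' Run the Metropolis sampler for the charged-disk seed model
#'
#' One iteration is one attempted single-ion move: a cation chosen uniformly
#' at random receives an isotropic displacement proposal (see
#' [propose_move()]) which is accepted with the probability of
#' [acceptance_probability()]. The perimeter charges never move. Energy per
#' ion and the window acceptance rate are recorded every `record_every`
#' iterations; after the burn-in, equal-area ring occupancies are accumulated
#' every `sample_every` iterations to build the equilibrium radial profile.
#'
#' If `params$rng_seed` is set, setup (initial positions, site angles) uses
#' `set.seed(seed)` and the dynamics use `set.seed(seed + 1)`, so runs are
#' bit-reproducible and the setup draw count does not perturb the dynamics
#' stream.
#'
#' @param params A [seed_model_params()] object.
#' @param n_iterations Number of attempted moves.
#' @param ions Optional starting configuration (tibble `x`, `y`); sampled
#'   uniformly over the disk when `NULL`.
#' @param sites Optional perimeter sites; sampled uniformly on the circle
#'   when `NULL`.
#' @param record_every Recording period for the energy trace (iterations).
#' @param sample_every Decorrelation gap between configurations entering the
#'   equilibrium profile (iterations).
#' @param burn_in Fraction of iterations discarded before profile sampling.
#' @param histogram Optional list `list(nr =, ntheta =, every =)` requesting
#'   a polar occupancy histogram accumulated every `every` iterations after
#'   burn-in (used for validation against grid-integrated Boltzmann
#'   densities).
#' @param convergence_window,convergence_rel_tol Passed to
#'   [detect_convergence()].
#' @return An object of class `mc_run`; see [tidy.mc_run()],
#'   [glance.mc_run()], [summarise_run()].
#' @export
run_mc <- function(params, n_iterations,
                   ions = NULL, sites = NULL,
                   record_every = 100, sample_every = 1000,
                   burn_in = 0.5, histogram = NULL,
                   convergence_window = 100, convergence_rel_tol = 1e-4) {
  stopifnot(inherits(params, "seed_model_params"))
  if (n_iterations < 0) {
    abort("`n_iterations` must be >= 0.", class = "ionseed_invalid_parameter")
  }
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  if (is.null(ions)) ions <- sample_uniform_disk(params$n_ions, params$radius)
  if (is.null(sites)) {
    sites <- sample_surface_sites(params$n_ext_sites, params$radius,
                                  params$site_charge)
  }
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed + 1L)

  partition <- make_equal_area_rings(params$radius, params$n_rings)
  h <- histogram %||% list(nr = 0L, ntheta = 0L, every = 0L)

  res <- run_mc_cpp(
    ions$x, ions$y,
    if (nrow(sites) > 0) sites$x else numeric(0),
    if (nrow(sites) > 0) sites$y else numeric(0),
    params$ion_charge, params$site_charge, params$sigma, params$radius,
    params$temperature, params$barrier,
    partition$edges, params$step_size, params$min_separation,
    n_iterations, as.integer(record_every), as.integer(sample_every),
    floor(burn_in * n_iterations),
    as.integer(h$nr), as.integer(h$ntheta), as.integer(h$every)
  )

  trace <- tibble(
    iteration = res$iteration,
    energy_per_ion = res$energy_per_ion,
    acceptance_rate = res$acceptance_rate
  )

  drift <- abs(res$tracked_energy - res$recomputed_energy)
  if (res$recomputed_energy != 0 && drift / abs(res$recomputed_energy) > 1e-8) {
    warn("Incremental energy drifted by more than 1e-8 relative to a full recompute.",
         class = "ionseed_energy_drift")
  }
  if (params$n_ions > 0 && n_iterations > 0) {
    acc <- res$n_accept / n_iterations
    if (acc < 0.1 || acc > 0.7) {
      warn(sprintf("Overall acceptance rate %.3f outside [0.1, 0.7]; consider tuning `step_size`.", acc),
           class = "ionseed_acceptance_rate")
    }
  }

  converged_at <- if (nrow(trace) >= 2 * convergence_window) {
    detect_convergence(trace, window = convergence_window,
                       rel_tol = convergence_rel_tol)
  } else {
    NA_real_
  }

  profile <- if (res$n_profile_samples > 0 && params$n_ions > 0) {
    profile_from_counts(res$ring_counts, res$n_profile_samples, partition,
                        params$n_ions, params$ion_charge)
  } else {
    NULL
  }

  structure(
    list(
      params = params,
      partition = partition,
      sites = sites,
      initial = ions,
      final = tibble(x = res$x, y = res$y,
                     ring = if (params$n_ions > 0) {
                       ring_index(pmin(sqrt(res$x^2 + res$y^2), params$radius), partition)
                     } else integer(0)),
      trace = trace,
      converged_at = converged_at,
      profile = profile,
      histogram = if (res$hist_samples > 0) res$hist else NULL,
      histogram_samples = res$hist_samples,
      initial_energy_per_ion = if (params$n_ions > 0) res$initial_energy / params$n_ions else NA_real_,
      n_iterations = n_iterations,
      n_accept = res$n_accept,
      burn_in = burn_in,
      sample_every = sample_every,
      seed = params$rng_seed
    ),
    class = "mc_run"
  )
}

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("Metropolis run: N = %d ions, %d perimeter sites, %g iterations\n",
              x$params$n_ions, nrow(x$sites), x$n_iterations))
  cat(sprintf("  initial energy %.4g J/ion", x$initial_energy_per_ion))
  if (nrow(x$trace) > 0) {
    cat(sprintf(", final recorded %.4g J/ion",
                x$trace$energy_per_ion[nrow(x$trace)]))
  }
  cat("\n")
  cat(sprintf("  converged at: %s, acceptance %.3f\n",
              if (is.na(x$converged_at)) "not detected" else format(x$converged_at),
              if (x$n_iterations > 0) x$n_accept / x$n_iterations else NA))
  invisible(x)
}

#' Detect stabilisation of the energy trace
#'
#' Compares means of consecutive non-overlapping windows of recorded
#' energies; the run is declared converged at the end of the first window
#' whose mean differs from its predecessor's by less than `rel_tol` in
#' relative terms.
#'
#' @param trace Tibble with `iteration` and `energy_per_ion` (as produced by
#'   [run_mc()] or [gen_trace()]).
#' @param window Window length in number of recordings (>= 1; at least two
#'   full windows must fit in the trace).
#' @param rel_tol Relative tolerance on consecutive window means.
#' @return The iteration at which convergence is declared, or `NA` if the
#'   trace never stabilises.
#' @export
detect_convergence <- function(trace, window = 100, rel_tol = 1e-4) {
  n <- nrow(trace)
  nw <- floor(n / window)
  if (nw < 2) {
    abort("Trace shorter than two windows.", class = "ionseed_insufficient_data")
  }
  e <- trace$energy_per_ion[seq_len(nw * window)]
  m <- colMeans(matrix(e, nrow = window))
  scale <- pmax(abs(m[-nw]), .Machine$double.xmin)
  rel <- abs(diff(m)) / scale
  hit <- which(rel < rel_tol)
  if (length(hit) == 0) return(NA_real_)
  trace$iteration[(hit[1] + 1) * window]
}

#' Equilibrium energy per ion with a batch-means standard error
#'
#' Discards the first `burn_in` fraction of the recorded trace and returns
#' the mean energy per ion together with a batch-means standard error
#' (consecutive recordings are autocorrelated, so a naive i.i.d. standard
#' error would be too small).
#'
#' @param trace Tibble with `iteration` and `energy_per_ion`.
#' @param burn_in Fraction of recordings discarded (default 0.5).
#' @param n_batches Number of batches for the standard error (default 20).
#' @return One-row tibble with `mean`, `se` and `n_recordings`.
#' @export
equilibrium_energy <- function(trace, burn_in = 0.5, n_batches = 20) {
  drop <- floor(burn_in * nrow(trace))
  e <- if (drop > 0) trace$energy_per_ion[-seq_len(drop)] else trace$energy_per_ion
  if (length(e) == 0) {
    abort("No recordings left after burn-in.", class = "ionseed_insufficient_data")
  }
  if (length(e) < n_batches) n_batches <- max(1L, length(e))
  bsize <- floor(length(e) / n_batches)
  bm <- colMeans(matrix(e[seq_len(bsize * n_batches)], nrow = bsize))
  se <- if (n_batches > 1) sd(bm) / sqrt(n_batches) else 0
  tibble(mean = mean(e), se = se, n_recordings = length(e))
}

#' @rdname run_mc
#' @param x An `mc_run` object.
#' @param ... Unused.
#' @export
tidy.mc_run <- function(x, ...) {
  x$trace
}

#' @rdname run_mc
#' @export
glance.mc_run <- function(x, ...) {
  summarise_run(x)
}
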