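# Build a radial_profile tibble from accumulated per-ring occupancy counts.
profile_from_counts <- function(counts, n_samples, partition, n_ions, ion_charge) {
  areas <- ring_areas(partition)
  mean_counts <- counts / n_samples
  out <- tibble(
    ring = seq_len(partition$n_rings),
    rho_mid = ring_midpoints(partition),
    ions_per_area = mean_counts / areas,
    concentration = ion_charge * mean_counts / areas,
    uniform_reference = n_ions * ion_charge / (pi * partition$radius^2)
  )
  class(out) <- c("radial_profile", class(out))
  attr(out, "n_samples") <- n_samples
  attr(out, "n_ions") <- n_ions
  attr(out, "ion_charge") <- ion_charge
  attr(out, "partition") <- partition
  out
}

#' Radial concentration profile over equal-area rings
#'
#' Counts cations per equal-area ring, averaged over one or more
#' configurations, and divides by the ring area. The uniform reference line
#' `N q / (pi R^2)` is the concentration of the homogeneous initial state;
#' by charge neutrality its magnitude equals `|sigma|`.
#'
#' @param configs A single configuration tibble (`x`, `y`) or a list of such
#'   tibbles, all with the same number of cations.
#' @param partition A [make_equal_area_rings()] partition.
#' @param ion_charge Cation charge `q` (coulomb).
#' @return A `radial_profile` tibble with columns `ring`, `rho_mid`,
#'   `ions_per_area`, `concentration` (charge per area) and
#'   `uniform_reference`.
#' @export
radial_concentration <- function(configs, partition, ion_charge) {
  if (is.data.frame(configs)) configs <- list(configs)
  if (length(configs) == 0 || any(vapply(configs, nrow, 1L) == 0)) {
    abort("No configurations (or empty configurations) supplied.",
          class = "ionseed_insufficient_data")
  }
  n_ions <- nrow(configs[[1]])
  if (any(vapply(configs, nrow, 1L) != n_ions)) {
    abort("All configurations must contain the same number of cations.",
          class = "ionseed_invalid_parameter")
  }
  counts <- numeric(partition$n_rings)
  for (cfg in configs) {
    rho <- sqrt(cfg$x^2 + cfg$y^2)
    idx <- ring_index(rho, partition)
    counts <- counts + tabulate(idx, nbins = partition$n_rings)
  }
  profile_from_counts(counts, length(configs), partition, n_ions, ion_charge)
}

#' Surface enrichment ratio of a radial profile
#'
#' Mean concentration of the outermost `outer_rings` equal-area rings
#' divided by the uniform reference. Values above 1 indicate accumulation of
#' cations near the surface, the signature of the plasma-deposited negative
#' charge.
#'
#' @param profile A `radial_profile`.
#' @param outer_rings How many outermost rings to average (>= 1).
#' @return A dimensionless ratio.
#' @export
enrichment_ratio <- function(profile, outer_rings = 1) {
  m <- nrow(profile)
  if (outer_rings < 1 || outer_rings > m) {
    abort("`outer_rings` must be in 1..M.", class = "ionseed_invalid_parameter")
  }
  uref <- profile$uniform_reference[1]
  if (uref == 0) {
    abort("Uniform reference concentration is zero; ratio undefined.",
          class = "ionseed_undefined_ratio")
  }
  mean(profile$concentration[(m - outer_rings + 1):m]) / uref
}

#' Flat summary record of a sampler run
#'
#' @param run An `mc_run` object.
#' @param outer_rings Rings entering the [enrichment_ratio()] (default 1).
#' @return A one-row tibble with the model parameters, seed, initial and
#'   equilibrium energy per ion, convergence iteration and enrichment ratio.
#' @export
summarise_run <- function(run, outer_rings = 1) {
  stopifnot(inherits(run, "mc_run"))
  eq <- if (nrow(run$trace) > 1) {
    equilibrium_energy(run$trace, burn_in = run$burn_in)
  } else {
    tibble(mean = NA_real_, se = NA_real_, n_recordings = 0L)
  }
  enr <- if (!is.null(run$profile)) enrichment_ratio(run$profile, outer_rings) else NA_real_
  p <- run$params
  tibble(
    n_ions = p$n_ions,
    ion_charge = p$ion_charge,
    n_ext_sites = p$n_ext_sites,
    site_charge = p$site_charge,
    radius = p$radius,
    temperature = p$temperature,
    barrier = p$barrier,
    sigma = p$sigma,
    n_rings = p$n_rings,
    step_size = p$step_size,
    rng_seed = if (is.null(p$rng_seed)) NA_integer_ else p$rng_seed,
    n_iterations = run$n_iterations,
    acceptance_rate = if (run$n_iterations > 0) run$n_accept / run$n_iterations else NA_real_,
    initial_energy_per_ion = run$initial_energy_per_ion,
    equilibrium_energy_per_ion = eq$mean,
    equilibrium_energy_se = eq$se,
    converged_at = run$converged_at,
    enrichment_ratio = enr
  )
}

#' Plot a radial concentration profile
#'
#' Concentration of positive charge versus the distance to the disk centre,
#' with the uniform reference drawn as a horizontal line (the concentration
#' of the homogeneous initial state).
#'
#' @param object A `radial_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rho_mid, y = .data$concentration)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$uniform_reference[1]),
                        linetype = "solid", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = expression(rho ~ "(m)"),
      y = expression("concentration (C" * m^-2 * ")"),
      title = "Radial concentration of positive charge at equilibrium"
    ) +
    ggplot2::theme_minimal()
}

#' Plot diagnostics of a sampler run
#'
#' @param object An `mc_run`.
#' @param type `"trace"` for the energy-per-ion trace, `"positions"` for the
#'   initial/final configurations with the perimeter charges, `"profile"`
#'   for the equilibrium radial profile.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mc_run <- function(object, type = c("trace", "positions", "profile"), ...) {
  type <- match.arg(type)
  if (type == "trace") {
    return(
      ggplot2::ggplot(object$trace,
                      ggplot2::aes(x = .data$iteration, y = .data$energy_per_ion)) +
        ggplot2::geom_line() +
        ggplot2::labs(x = "iteration (attempted moves)", y = "energy per ion (J)") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "profile") {
    if (is.null(object$profile)) abort("Run has no sampled profile.")
    return(autoplot.radial_profile(object$profile))
  }
  pos <- dplyr::bind_rows(
    dplyr::mutate(object$initial, stage = "initial"),
    dplyr::mutate(object$final[c("x", "y")], stage = "final")
  )
  ggplot2::ggplot(pos, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 0.5, colour = "steelblue") +
    ggplot2::geom_point(data = object$sites, colour = "red", size = 2) +
    ggplot2::facet_wrap(~stage) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}
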