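#' Uniform negative background density restoring charge neutrality
#'
#' Before plasma treatment the model seed is electrically neutral: the charge
#' of the `N` mobile cations is compensated by a uniform negative surface
#' density `sigma` spread over the disk, so that `N q + sigma pi R^2 = 0`.
#'
#' @param n_ions Number of mobile cations `N` (>= 0).
#' @param ion_charge Charge per cation `q` in coulomb.
#' @param radius Disk radius `R` in metre (> 0).
#' @return The neutralising density `sigma` in C m^-2 (non-positive for
#'   positive `q`).
#' @examples
#' neutrality_sigma(1000, physical_constants()$e, 1e-3)
#' @export
neutrality_sigma <- function(n_ions, ion_charge, radius) {
  if (!is.numeric(radius) || any(radius <= 0)) {
    abort("`radius` must be positive.", class = "ionseed_invalid_parameter")
  }
  if (any(n_ions < 0)) {
    abort("`n_ions` must be non-negative.", class = "ionseed_invalid_parameter")
  }
  -n_ions * ion_charge / (pi * radius^2)
}

#' Parameters of the charged-disk seed model
#'
#' Bundles every physical and algorithmic parameter of the two-dimensional
#' disk model: `n_ions` mobile cations of charge `ion_charge` confined to a
#' disk of radius `radius`, attracted by `n_ext_sites` fixed negative charges
#' of `site_charge` each on the perimeter, neutralised by a uniform background
#' density (computed via [neutrality_sigma()]), at temperature `temperature`,
#' with an activation barrier `barrier` for moves that cross the boundaries of
#' the `n_rings` concentric equal-area cells.
#'
#' Defaults are the reference scenario used throughout: 1000 singly charged
#' cations in a 1 mm disk at 300 K, ten perimeter sites of -4e5 elementary
#' charges each, and a barrier of 4 kT (equivalent to a potential of about
#' 0.103 V per elementary charge, the order of a plant resting membrane
#' potential).
#'
#' @param n_ions Count of mobile cations `N`.
#' @param ion_charge Cation charge `q` (coulomb); defaults to one elementary
#'   charge.
#' @param n_ext_sites Count of fixed perimeter charges `N_ext`.
#' @param site_charge Charge per perimeter site `Q_ext` (coulomb, <= 0).
#' @param radius Disk radius `R` (metre).
#' @param temperature Absolute temperature `T` (kelvin).
#' @param barrier Activation energy `E0` (joule) paid per ring boundary
#'   crossed by a proposed move.
#' @param n_rings Number `M` of concentric equal-area cells.
#' @param step_size Radius (metre) of the isotropic proposal disk; defaults to
#'   `radius / 50`.
#' @param min_separation Smallest admissible distance (metre) between any two
#'   charges; proposals below it are rejected, guarding the `1/r` singularity.
#'   Defaults to `1e-6 * radius`.
#' @param rng_seed Optional integer seed recorded in outputs; `NULL` leaves
#'   the RNG state untouched.
#' @param background_sigma Optional override of the background charge
#'   density (C m^-2). By default the neutrality value
#'   `-n_ions * ion_charge / (pi radius^2)` is used; supplying a value
#'   disables neutrality (useful for validation scenarios with a stronger
#'   confining background).
#' @return An object of class `seed_model_params`: a named list with the
#'   fields above plus the derived neutrality density `sigma`.
#' @examples
#' p <- seed_model_params(n_ions = 100)
#' p$sigma * pi * p$radius^2 + p$n_ions * p$ion_charge  # ~ 0: neutrality
#' @export
seed_model_params <- function(n_ions = 1000,
                              ion_charge = physical_constants()$e,
                              n_ext_sites = 10,
                              site_charge = -4e5 * physical_constants()$e,
                              radius = 1e-3,
                              temperature = 300,
                              barrier = 4 * physical_constants()$kB * temperature,
                              n_rings = 20,
                              step_size = radius / 50,
                              min_separation = 1e-6 * radius,
                              rng_seed = NULL,
                              background_sigma = NULL) {
  if (n_ions < 0) abort("`n_ions` must be >= 0.", class = "ionseed_invalid_parameter")
  if (n_ext_sites < 0) abort("`n_ext_sites` must be >= 0.", class = "ionseed_invalid_parameter")
  if (radius <= 0) abort("`radius` must be > 0.", class = "ionseed_invalid_parameter")
  if (temperature <= 0) abort("`temperature` must be > 0.", class = "ionseed_invalid_parameter")
  if (barrier < 0) abort("`barrier` must be >= 0.", class = "ionseed_invalid_parameter")
  if (n_rings < 1) abort("`n_rings` must be >= 1.", class = "ionseed_invalid_parameter")
  if (step_size <= 0) abort("`step_size` must be > 0.", class = "ionseed_invalid_parameter")
  if (min_separation < 0) abort("`min_separation` must be >= 0.", class = "ionseed_invalid_parameter")
  if (ion_charge != 0 && site_charge != 0 && ion_charge * site_charge > 0) {
    abort("`site_charge` must have the opposite sign of `ion_charge` (plasma deposits negative charge).",
          class = "ionseed_invalid_parameter")
  }
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)

  structure(
    list(
      n_ions = as.integer(n_ions),
      ion_charge = ion_charge,
      n_ext_sites = as.integer(n_ext_sites),
      site_charge = site_charge,
      radius = radius,
      temperature = temperature,
      barrier = barrier,
      sigma = background_sigma %||% neutrality_sigma(n_ions, ion_charge, radius),
      neutral = is.null(background_sigma),
      n_rings = as.integer(n_rings),
      step_size = step_size,
      min_separation = min_separation,
      rng_seed = rng_seed
    ),
    class = "seed_model_params"
  )
}

#' @export
print.seed_model_params <- function(x, ...) {
  kB <- physical_constants()$kB
  cat("Charged-disk seed model parameters\n")
  cat(sprintf("  N = %d cations, q = %.6g C\n", x$n_ions, x$ion_charge))
  cat(sprintf("  N_ext = %d perimeter sites, Q_ext = %.6g C each\n",
              x$n_ext_sites, x$site_charge))
  cat(sprintf("  R = %.3g m, T = %.4g K, E0 = %.4g J (%.3g kT)\n",
              x$radius, x$temperature, x$barrier, x$barrier / (kB * x$temperature)))
  cat(sprintf("  sigma = %.6g C/m^2 (neutrality), M = %d rings\n",
              x$sigma, x$n_rings))
  cat(sprintf("  step = %.3g m, min separation = %.3g m, seed = %s\n",
              x$step_size, x$min_separation,
              if (is.null(x$rng_seed)) "none" else x$rng_seed))
  invisible(x)
}

#' Read model parameters from a JSON or YAML configuration file
#'
#' Keys mirror the arguments of [seed_model_params()]; all quantities are SI.
#' Unknown keys raise an error so that typos in configuration files do not
#' silently fall back to defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `seed_model_params` object.
#' @export
read_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    abort(sprintf("Unsupported config format '%s' (use JSON or YAML).", ext),
          class = "ionseed_invalid_parameter")
  )
  known <- names(formals(seed_model_params))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0) {
    abort(sprintf("Unknown config keys: %s", paste(extra, collapse = ", ")),
          class = "ionseed_invalid_parameter")
  }
  do.call(seed_model_params, cfg)
}
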