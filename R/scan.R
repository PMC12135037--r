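#' Barrier height expressed as a potential
#'
#' The activation barrier divided by the ion charge, `V0 = E0 / q`; for the
#' default barrier of 4 kT at 300 K and a single elementary charge this is
#' about 0.103 V, the order of magnitude of a plant resting membrane
#' potential.
#'
#' @param barrier Activation energy (joule).
#' @param ion_charge Ion charge (coulomb).
#' @return Potential in volt.
#' @examples
#' barrier_potential(4 * physical_constants()$kB * 300)
#' @export
barrier_potential <- function(barrier, ion_charge = physical_constants()$e) {
  if (any(ion_charge == 0)) {
    abort("`ion_charge` must be nonzero.", class = "ionseed_invalid_parameter")
  }
  barrier / ion_charge
}

#' Initial-state energy under both readings of the surface charge
#'
#' The reference scenario fixes the surface charge as `Q_ext = -4e5`
#' elementary charges with `N_ext = 10` sites, but whether that figure is
#' the charge per site or the total over all sites is a genuine ambiguity
#' (as is the magnitude of the mobile-ion charge `q`). This scan computes
#' the mean total energy per ion of random initial configurations under
#' both readings, so the two candidate values can be compared against any
#' external reference side by side.
#'
#' The mean of `sum_j 1 / |r - R_j|` over an area-uniform `r` is
#' `4 N_ext / (pi R)`, so the ion-site term has closed-form expectation
#' `k q Q_ext 4 N_ext / (pi R)`; the scan reports it alongside the Monte
#' Carlo average as a cross-check.
#'
#' @param n_configs Number of random initial configurations (>= 2).
#' @param rng_seed Optional seed.
#' @return A tibble with one row per reading (`per_site`, `total`):
#'   `site_charge`, `mean_energy_per_ion` (J), `se`, `analytic_u1_per_ion`
#'   (J), `n_configs`.
#' @export
initial_energy_scan <- function(n_configs = 20, rng_seed = NULL) {
  if (n_configs < 2) {
    abort("`n_configs` must be >= 2.", class = "ionseed_invalid_parameter")
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  e <- physical_constants()$e
  k <- physical_constants()$k
  readings <- tibble(
    reading = c("per_site", "total"),
    site_charge = c(-4e5 * e, -4e5 * e / 10)
  )
  purrr::pmap_dfr(readings, function(reading, site_charge) {
    params <- seed_model_params(site_charge = site_charge)
    per_ion <- vapply(seq_len(n_configs), function(i) {
      ions <- sample_uniform_disk(params$n_ions, params$radius)
      sites <- sample_surface_sites(params$n_ext_sites, params$radius,
                                    params$site_charge)
      total_energy(ions, sites, params)$per_ion_total
    }, numeric(1))
    tibble(
      reading = reading,
      site_charge = site_charge,
      mean_energy_per_ion = mean(per_ion),
      se = sd(per_ion) / sqrt(n_configs),
      analytic_u1_per_ion = k * params$ion_charge * site_charge *
        4 * params$n_ext_sites / (pi * params$radius),
      n_configs = n_configs
    )
  })
}
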