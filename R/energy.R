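#' In-plane potential of the uniform background charge
#'
#' Electrostatic potential, with the 3D Coulomb kernel, created by the
#' uniform neutralising density `sigma` spread over the disk of radius `R`,
#' evaluated in the plane of the disk at distance `rho` from the centre:
#' `V(rho) = sigma R E(rho / R) / (pi eps0)`, with `E` the complete elliptic
#' integral of the second kind. Special values: `V(0) = sigma R / (2 eps0)`,
#' `V(R) = sigma R / (pi eps0)`.
#'
#' @param rho Radial coordinate(s), metre, in `[0, radius]`.
#' @param sigma Background surface charge density (C m^-2).
#' @param radius Disk radius (metre).
#' @return Potential in volt, same length as `rho`.
#' @examples
#' p <- seed_model_params()
#' background_potential(c(0, p$radius), p$sigma, p$radius)
#' @export
background_potential <- function(rho, sigma, radius) {
  if (any(rho < 0 | rho > radius)) {
    abort("`rho` outside [0, radius].", class = "ionseed_out_of_domain")
  }
  vapply(rho, bg_potential_cpp, numeric(1), sigma = sigma, R = radius)
}

.site_charge <- function(sites, site_charge) {
  if (!is.null(site_charge)) return(site_charge)
  sc <- attr(sites, "charge_per_site")
  if (is.null(sc)) {
    abort("`site_charge` not given and `sites` carries no charge attribute.",
          class = "ionseed_invalid_parameter")
  }
  sc
}

#' Ion to surface-site interaction energy
#'
#' Total Coulomb energy between the mobile cations and the fixed negative
#' perimeter charges: `k q Q_ext * sum_i sum_j 1 / |r_i - R_j|`. Non-positive
#' whenever the charges are opposite-signed.
#'
#' @param ions Tibble of cation positions (`x`, `y` in metre).
#' @param sites Tibble of perimeter sites (from [sample_surface_sites()]).
#' @param ion_charge Cation charge `q` (coulomb).
#' @param site_charge Charge per site (coulomb); defaults to the
#'   `charge_per_site` attribute of `sites`.
#' @param min_separation Distances below this raise a singularity error.
#' @return Energy in joule.
#' @export
energy_u1 <- function(ions, sites, ion_charge,
                      site_charge = NULL, min_separation = 0) {
  if (nrow(sites) == 0 || nrow(ions) == 0) return(0)
  sc <- .site_charge(sites, site_charge)
  eb <- energy_breakdown_cpp(ions$x, ions$y, sites$x, sites$y,
                             ion_charge, sc, 0,
                             max(1, sqrt(max(ions$x^2 + ions$y^2))),
                             min_separation)
  unname(eb[["u1"]])
}

#' Ion to ion interaction energy
#'
#' Total Coulomb repulsion `k q^2 sum_{i<j} 1 / |r_i - r_j|`; each pair is
#' counted once (the conventional 1/2 factor in per-ion sums cancels the
#' double counting). Always non-negative.
#'
#' @inheritParams energy_u1
#' @return Energy in joule.
#' @export
energy_u2 <- function(ions, ion_charge, min_separation = 0) {
  if (nrow(ions) < 2) return(0)
  eb <- energy_breakdown_cpp(ions$x, ions$y, numeric(0), numeric(0),
                             ion_charge, 0, 0,
                             max(1, sqrt(max(ions$x^2 + ions$y^2))),
                             min_separation)
  unname(eb[["u2"]])
}

#' Ion to background interaction energy
#'
#' `sum_i q V(rho_i)` with `V` the uniformly charged disk potential of
#' [background_potential()].
#'
#' @param ions Tibble of cation positions.
#' @param params A [seed_model_params()] object (supplies `q`, `sigma`, `R`).
#' @return Energy in joule.
#' @export
energy_u3 <- function(ions, params) {
  if (nrow(ions) == 0) return(0)
  rho <- sqrt(ions$x^2 + ions$y^2)
  sum(params$ion_charge * background_potential(rho, params$sigma, params$radius))
}

#' Full energy breakdown of a configuration
#'
#' @param ions Tibble of cation positions.
#' @param sites Tibble of perimeter sites.
#' @param params A [seed_model_params()] object.
#' @return One-row tibble with columns `u1`, `u2`, `u3`, `total` and
#'   `per_ion_total` (`NA` for an empty configuration).
#' @export
total_energy <- function(ions, sites, params) {
  n <- nrow(ions)
  eb <- energy_breakdown_cpp(
    ions$x, ions$y,
    if (nrow(sites) > 0) sites$x else numeric(0),
    if (nrow(sites) > 0) sites$y else numeric(0),
    params$ion_charge, params$site_charge, params$sigma, params$radius,
    params$min_separation
  )
  total <- sum(eb)
  tibble(
    u1 = unname(eb[["u1"]]), u2 = unname(eb[["u2"]]), u3 = unname(eb[["u3"]]),
    total = total,
    per_ion_total = if (n > 0) total / n else NA_real_
  )
}

#' Energy difference of a single-ion move
#'
#' Computes `U(after) - U(before)` for moving one cation to `new_position`,
#' touching only the O(N + N_ext) terms that involve the moved ion. This is
#' the incremental update the Metropolis sampler relies on.
#'
#' @param ions Tibble of cation positions.
#' @param sites Tibble of perimeter sites.
#' @param params A [seed_model_params()] object.
#' @param ion 1-based index of the cation to move.
#' @param new_position Numeric length-2 vector `c(x, y)` inside the disk.
#' @return Energy difference in joule.
#' @export
delta_energy <- function(ions, sites, params, ion, new_position) {
  if (ion < 1 || ion > nrow(ions)) {
    abort("`ion` index out of range.", class = "ionseed_invalid_parameter")
  }
  delta_energy_cpp(
    ions$x, ions$y,
    if (nrow(sites) > 0) sites$x else numeric(0),
    if (nrow(sites) > 0) sites$y else numeric(0),
    params$ion_charge, params$site_charge, params$sigma, params$radius,
    params$min_separation, as.integer(ion) - 1L,
    new_position[1], new_position[2]
  )
}
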