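#' Partition the disk into concentric cells of equal area
#'
#' The disk of radius `R` is segmented into `M` concentric annuli of equal
#' area `pi R^2 / M`; the edge radii follow `R sqrt(m / M)`. These cells serve
#' two purposes: a proposed move pays the activation barrier once per cell
#' boundary it crosses, and equilibrium concentration profiles are estimated
#' per cell.
#'
#' @param radius Disk radius (metre, > 0).
#' @param n_rings Number of annuli `M` (>= 1).
#' @return An object of class `ring_partition`: list with `edges` (length
#'   `M + 1`, from 0 to `radius`), `radius` and `n_rings`.
#' @examples
#' make_equal_area_rings(1, 4)$edges
#' @export
make_equal_area_rings <- function(radius, n_rings) {
  if (!is.numeric(radius) || length(radius) != 1 || radius <= 0) {
    abort("`radius` must be a positive scalar.", class = "ionseed_invalid_parameter")
  }
  if (!is.numeric(n_rings) || length(n_rings) != 1 || n_rings < 1) {
    abort("`n_rings` must be a positive count.", class = "ionseed_invalid_parameter")
  }
  n_rings <- as.integer(n_rings)
  structure(
    list(
      edges = radius * sqrt(seq.int(0L, n_rings) / n_rings),
      radius = radius,
      n_rings = n_rings
    ),
    class = "ring_partition"
  )
}

#' @export
print.ring_partition <- function(x, ...) {
  cat(sprintf("Equal-area ring partition: M = %d cells, R = %.3g m\n",
              x$n_rings, x$radius))
  invisible(x)
}

#' Ring areas of a partition (all equal by construction)
#' @param partition A `ring_partition`.
#' @return Numeric vector of the `M` annulus areas (m^2).
#' @export
ring_areas <- function(partition) {
  diff(pi * partition$edges^2)
}

#' Midpoint radius of each ring (average of its two edges)
#' @param partition A `ring_partition`.
#' @return Numeric vector of length `M`.
#' @export
ring_midpoints <- function(partition) {
  e <- partition$edges
  (e[-1] + e[-length(e)]) / 2
}

#' Index of the ring containing a point
#'
#' Returns the 1-based ring index `m` such that `edges[m] <= rho <
#' edges[m + 1]`. A point exactly on the outer boundary (`rho == R`, surface
#' contact) is assigned to the outermost ring.
#'
#' @param rho Radial coordinate(s), metre; must satisfy `0 <= rho <= R`.
#' @param partition A `ring_partition`.
#' @return Integer vector of ring indices in `1..M`.
#' @examples
#' p <- make_equal_area_rings(1, 4)
#' ring_index(c(0, 0.6, 1), p)
#' @export
ring_index <- function(rho, partition) {
  if (any(rho < 0 | rho > partition$radius)) {
    abort("`rho` outside the disk.", class = "ionseed_out_of_domain")
  }
  idx <- findInterval(rho, partition$edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  pmin.int(as.integer(idx), partition$n_rings)
}

#' Sample cation positions uniformly over the disk
#'
#' Area-uniform sampling (`rho = R sqrt(u)`, angle uniform), matching the
#' homogeneous cation distribution of the untreated, electrically neutral
#' seed.
#'
#' @param n Number of cations.
#' @param radius Disk radius (metre).
#' @return A tibble with columns `x`, `y` (metre), one row per cation.
#' @examples
#' set.seed(1)
#' sample_uniform_disk(5, 1e-3)
#' @export
sample_uniform_disk <- function(n, radius) {
  if (n < 0) abort("`n` must be >= 0.", class = "ionseed_invalid_parameter")
  if (radius <= 0) abort("`radius` must be > 0.", class = "ionseed_invalid_parameter")
  n <- as.integer(n)
  rho <- radius * sqrt(runif(n))
  theta <- runif(n, 0, 2 * pi)
  tibble(x = rho * cos(theta), y = rho * sin(theta))
}

#' Place fixed negative charges at random positions on the perimeter
#'
#' The plasma sheath deposits negative charge preferentially at surface
#' asperities; the model represents this as `n_ext` point charges at angles
#' uniform on `[0, 2 pi)`, exactly on the circle of radius `R`. The sites
#' never move during sampling.
#'
#' @param n_ext Number of surface sites.
#' @param radius Disk radius (metre).
#' @param charge_per_site Charge per site (coulomb); stored alongside the
#'   positions.
#' @return A tibble with columns `angle` (radian), `x`, `y` (metre) and
#'   attribute `charge_per_site`.
#' @export
sample_surface_sites <- function(n_ext, radius,
                                 charge_per_site = -4e5 * physical_constants()$e) {
  if (n_ext < 0) abort("`n_ext` must be >= 0.", class = "ionseed_invalid_parameter")
  if (radius <= 0) abort("`radius` must be > 0.", class = "ionseed_invalid_parameter")
  n_ext <- as.integer(n_ext)
  theta <- runif(n_ext, 0, 2 * pi)
  out <- tibble(angle = theta, x = radius * cos(theta), y = radius * sin(theta))
  attr(out, "charge_per_site") <- charge_per_site
  out
}
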