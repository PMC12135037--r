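#' Gas-cluster-ion-beam etching protocol
#'
#' Two calibrated protocols are built in. Protocol `"a"`: 300-atom Ar
#' clusters at 8 keV, 6.7 nm removed per cycle, 15 cycles (~100 nm total).
#' Protocol `"b"`: a brief monatomic Ar+ pre-sputter followed by 1000-atom
#' clusters at 6 keV, 21.6 nm per cycle, 10 cycles (216 nm total). The
#' pre-sputter removes an unquantified thickness, so protocol-b depths are
#' relative to the post-pre-etch surface (flagged by `pre_etch = TRUE`).
#'
#' @param name `"a"`, `"b"` or a custom label (then supply the other
#'   arguments).
#' @param rate_nm_per_cycle Etch rate in nm per cycle (> 0).
#' @param n_cycles Number of etch cycles (>= 1).
#' @param pre_etch Whether a monatomic pre-sputter preceded the profile.
#' @return An object of class `etch_protocol`.
#' @examples
#' etch_protocol("b")
#' @export
etch_protocol <- function(name = c("a", "b"),
                          rate_nm_per_cycle = NULL,
                          n_cycles = NULL,
                          pre_etch = NULL) {
  if (is.null(rate_nm_per_cycle)) {
    name <- match.arg(name)
    preset <- switch(name,
      a = list(rate = 6.7, cycles = 15L, pre = FALSE),
      b = list(rate = 21.6, cycles = 10L, pre = TRUE)
    )
    rate_nm_per_cycle <- preset$rate
    n_cycles <- n_cycles %||% preset$cycles
    pre_etch <- pre_etch %||% preset$pre
  }
  if (rate_nm_per_cycle <= 0) {
    abort("`rate_nm_per_cycle` must be > 0.", class = "ionseed_invalid_parameter")
  }
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.", class = "ionseed_invalid_parameter")
  structure(
    list(name = as.character(name)[1],
         rate_nm_per_cycle = rate_nm_per_cycle,
         n_cycles = as.integer(n_cycles),
         pre_etch = isTRUE(pre_etch)),
    class = "etch_protocol"
  )
}

#' @export
print.etch_protocol <- function(x, ...) {
  cat(sprintf("Etch protocol '%s': %.1f nm/cycle x %d cycles = %.1f nm%s\n",
              x$name, x$rate_nm_per_cycle, x$n_cycles,
              x$rate_nm_per_cycle * x$n_cycles,
              if (x$pre_etch) " (after monatomic pre-sputter; depth relative to pre-etched surface)" else ""))
  invisible(x)
}

#' Convert etch cycles to depth
#'
#' Linear calibration `depth = cycle * rate`. For pre-etched protocols the
#' unquantified pre-sputter thickness contributes zero and the result is
#' relative to the post-pre-etch surface.
#'
#' @param protocol An [etch_protocol()].
#' @param cycle Cycle number(s), `0 <= cycle <= n_cycles`.
#' @return Depth in nm.
#' @examples
#' depth_from_cycles(etch_protocol("b"), 10)  # 216 nm
#' @export
depth_from_cycles <- function(protocol, cycle) {
  stopifnot(inherits(protocol, "etch_protocol"))
  if (any(cycle < 0 | cycle > protocol$n_cycles)) {
    abort("`cycle` outside 0..n_cycles.", class = "ionseed_invalid_parameter")
  }
  cycle * protocol$rate_nm_per_cycle
}

#' Read an XPS depth-profile composition table
#'
#' Expects delimited text (comma or tab, auto-detected), one row per etch
#' cycle, with a `cycle` column (or one is inferred from row order starting
#' at 0) and one column of atomic % per element symbol.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_depth_profile <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           trim_ws = TRUE)
  names(out)[tolower(names(out)) == "cycle"] <- "cycle"
  if (!"cycle" %in% names(out)) out <- mutate(out, cycle = dplyr::row_number() - 1)
  out
}

#' Oxygen associated with the organic matrix
#'
#' Part of the measured O 1s signal comes from the SiO2 agglomerates present
#' on seed surfaces. Assuming SiO2 stoichiometry, two oxygen atoms are
#' subtracted per silicon atom; the remainder estimates oxygen bound to
#' water or organic components. Negative values (over-subtraction) are
#' clamped to zero and flagged.
#'
#' @param o_total Measured oxygen atomic % (vectorised).
#' @param si Measured silicon atomic %.
#' @param sio2_ratio O:Si stoichiometric factor (default 2; alternate
#'   stoichiometries allow sensitivity analyses).
#' @return Numeric vector of organic oxygen atomic %, with attribute
#'   `clamped` (logical vector marking rows where the correction
#'   over-subtracted).
#' @examples
#' organic_oxygen(37.6, 4.8)  # 28.0
#' @export
organic_oxygen <- function(o_total, si, sio2_ratio = 2) {
  if (any(o_total < 0) || any(si < 0)) {
    abort("Atomic percentages must be >= 0.", class = "ionseed_invalid_parameter")
  }
  raw <- o_total - sio2_ratio * si
  clamped <- raw < 0
  if (any(clamped)) {
    warn(sprintf("SiO2 correction over-subtracts in %d row(s); clamped to 0.",
                 sum(clamped)),
         class = "ionseed_oxygen_clamped")
  }
  out <- pmax(raw, 0)
  attr(out, "clamped") <- clamped
  out
}

#' Reduce a depth-profile table
#'
#' Adds the derived columns used throughout the analysis: `depth_nm` from
#' the etch calibration, `O_organic` (silicate-corrected oxygen, when both
#' `O` and `Si` are present) and its clamping flag.
#'
#' @param table Depth-profile tibble (see [read_depth_profile()]).
#' @param protocol An [etch_protocol()].
#' @param sio2_ratio O:Si factor passed to [organic_oxygen()].
#' @return The table with derived columns appended.
#' @export
reduce_depth_profile <- function(table, protocol, sio2_ratio = 2) {
  out <- mutate(table, depth_nm = depth_from_cycles(protocol, .data$cycle))
  if (all(c("O", "Si") %in% names(out))) {
    oo <- organic_oxygen(out$O, out$Si, sio2_ratio)
    out$O_organic <- as.numeric(oo)
    out$O_organic_clamped <- attr(oo, "clamped")
  }
  attr(out, "protocol") <- protocol
  out
}

#' Row-wise element ratio
#'
#' @param table Depth-profile tibble.
#' @param numerator,denominator Element column names (e.g. `"O"`, `"C"`).
#' @param use_organic_o Replace an `"O"` numerator by the silicate-corrected
#'   `O_organic` column (requires [reduce_depth_profile()] first).
#' @return The table with a `ratio_<num>_<den>` column appended; rows with a
#'   zero denominator get `NA` and a warning.
#' @examples
#' t1 <- tibble::tibble(cycle = 0, C = 88.5, O = 9.2, Si = 0.4)
#' element_ratio(t1, "O", "C")$ratio_O_C  # 0.104
#' @export
element_ratio <- function(table, numerator, denominator, use_organic_o = FALSE) {
  num_col <- if (use_organic_o && numerator == "O") "O_organic" else numerator
  for (col in c(num_col, denominator)) {
    if (!col %in% names(table)) {
      abort(sprintf("Column '%s' not present.", col),
            class = "ionseed_invalid_parameter")
    }
  }
  den <- table[[denominator]]
  if (any(den == 0)) {
    warn(sprintf("Denominator '%s' is zero in %d row(s); ratio set to NA.",
                 denominator, sum(den == 0)),
         class = "ionseed_undefined_ratio")
  }
  ratio <- ifelse(den == 0, NA_real_, table[[num_col]] / den)
  table[[paste0("ratio_", numerator, "_", denominator)]] <- ratio
  table
}

#' Treated-versus-control depth-profile comparison
#'
#' Interpolates the treated profile linearly onto the control depth grid
#' (restricted to the overlapping depth range, no extrapolation) and
#' summarises, per element: the depth-averaged atomic %, their ratio and the
#' fraction of depths at which the treated value exceeds the control (ties
#' count one half).
#'
#' @param treated,control Reduced depth-profile tibbles (must contain
#'   `depth_nm` and the requested element columns).
#' @param elements Character vector of element columns to compare.
#' @return A tibble with one row per element: `mean_control`,
#'   `mean_treated`, `ratio`, `frac_treated_higher`, `n_depths`.
#' @export
enrichment_summary <- function(treated, control, elements) {
  lo <- max(min(treated$depth_nm), min(control$depth_nm))
  hi <- min(max(treated$depth_nm), max(control$depth_nm))
  if (lo > hi) {
    abort("Depth ranges do not overlap.", class = "ionseed_incomparable_profiles")
  }
  grid <- control$depth_nm[control$depth_nm >= lo & control$depth_nm <= hi]
  purrr::map_dfr(elements, function(el) {
    for (tbl_name in c("treated", "control")) {
      tbl <- if (tbl_name == "treated") treated else control
      if (!el %in% names(tbl)) {
        abort(sprintf("Element '%s' missing from %s table.", el, tbl_name),
              class = "ionseed_invalid_parameter")
      }
    }
    tr <- approx(treated$depth_nm, treated[[el]], xout = grid)$y
    ct <- approx(control$depth_nm, control[[el]], xout = grid)$y
    higher <- mean((tr > ct) + 0.5 * (tr == ct))
    tibble(
      element = el,
      mean_control = mean(ct),
      mean_treated = mean(tr),
      ratio = mean(tr) / mean(ct),
      frac_treated_higher = higher,
      n_depths = length(grid)
    )
  })
}

#' Fit a surface-enrichment decay to one element of a depth profile
#'
#' Fits `pct(z) = baseline + amplitude * exp(-z / decay_length)` by
#' Levenberg-Marquardt nonlinear least squares, the model the synthetic
#' generator uses for plasma-induced surface enrichment.
#'
#' @param table Reduced depth-profile tibble with `depth_nm`.
#' @param element Element column to fit.
#' @param start Optional named list of starting values (`baseline`,
#'   `amplitude`, `decay_length`).
#' @return One-row tibble with the three estimates and `converged`.
#' @export
fit_depth_enrichment <- function(table, element, start = NULL) {
  z <- table$depth_nm
  yv <- table[[element]]
  if (is.null(start)) {
    b0 <- min(yv)
    a0 <- max(yv[which.min(z)] - b0, 1e-3)
    l0 <- max(diff(range(z)) / 3, 1e-3)
    start <- list(baseline = b0, amplitude = a0, decay_length = l0)
  }
  fit <- minpack.lm::nlsLM(
    yv ~ baseline + amplitude * exp(-z / decay_length),
    start = start,
    lower = c(0, 0, 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  tibble(
    element = element,
    baseline = unname(est["baseline"]),
    amplitude = unname(est["amplitude"]),
    decay_length = unname(est["decay_length"]),
    converged = fit$convInfo$isConv
  )
}
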