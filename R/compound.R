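# Compounds (drug, polymer, coformer) and mixtures thereof.

.STATE_FLAGS <- c("solid", "liquid", "waxy", "decomposes")

#' Construct a compound
#'
#' A compound bundles a sigma-profile with the metadata the funnel needs:
#' molar volume (for the Hansen activity model), melting behaviour (for
#' the process-window map) and molecular weight.
#'
#' @param name identifier.
#' @param profile a [sigma_profile()], or `NULL` for candidates screened on
#'   solubility parameters only.
#' @param molar_volume molar volume in cm^3/mol.
#' @param melting_point melting (or decomposition) temperature in degrees
#'   Celsius; required when `state_flag` is `"solid"` or `"decomposes"`,
#'   and must be absent otherwise.
#' @param state_flag one of `"solid"`, `"liquid"`, `"waxy"`, `"decomposes"`.
#' @param molecular_weight molecular weight in g/mol.
#' @return object of class `compound`.
#' @export
#' @examples
#' g <- default_sigma_grid()
#' a <- rep(0, 51); a[26] <- 100
#' p <- sigma_profile(g, a, cavity_area = 100, cavity_volume = 120)
#' compound("neutral_probe", p, molar_volume = 90, melting_point = 150,
#'          state_flag = "solid", molecular_weight = 180)
compound <- function(name, profile = NULL, molar_volume,
                     melting_point = NA_real_,
                     state_flag = "solid", molecular_weight) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.null(profile) && !inherits(profile, "sigma_profile")) {
    stop("`profile` must be a sigma_profile or NULL", call. = FALSE)
  }
  if (!is.numeric(molar_volume) || molar_volume <= 0) {
    stop("`molar_volume` must be positive", call. = FALSE)
  }
  if (!is.numeric(molecular_weight) || molecular_weight <= 0) {
    stop("`molecular_weight` must be positive", call. = FALSE)
  }
  state_flag <- match.arg(state_flag, .STATE_FLAGS)
  has_tm <- length(melting_point) == 1L && is.finite(melting_point)
  needs_tm <- state_flag %in% c("solid", "decomposes")
  if (needs_tm && !has_tm) {
    stop("melting_point is required for state_flag '", state_flag, "'",
         call. = FALSE)
  }
  if (!needs_tm && has_tm) {
    stop("melting_point must be absent for state_flag '", state_flag, "'",
         call. = FALSE)
  }
  structure(
    list(name = name, profile = profile,
         molar_volume = as.numeric(molar_volume),
         melting_point = if (has_tm) as.numeric(melting_point) else NA_real_,
         state_flag = state_flag,
         molecular_weight = as.numeric(molecular_weight)),
    class = "compound")
}

#' @export
print.compound <- function(x, ...) {
  tm <- if (is.finite(x$melting_point)) sprintf("Tm %g C", x$melting_point)
        else x$state_flag
  cat(sprintf("compound '%s': V = %g cm^3/mol, MW = %g g/mol, %s, %s\n",
              x$name, x$molar_volume, x$molecular_weight, tm,
              if (is.null(x$profile)) "no sigma-profile" else "sigma-profile attached"))
  invisible(x)
}

#' Construct a mixture
#'
#' @param components list of [compound()]s (each must carry a
#'   sigma-profile).
#' @param x mole fractions, non-negative, summing to 1 within 1e-9.
#' @param temperature temperature in Kelvin.
#' @return object of class `mixture`.
#' @export
mixture <- function(components, x, temperature = 298.15) {
  if (inherits(components, "compound")) components <- list(components)
  if (length(components) < 1L) {
    stop("a mixture needs at least one component", call. = FALSE)
  }
  if (!all(vapply(components, inherits, logical(1L), "compound"))) {
    stop("`components` must be a list of compound objects", call. = FALSE)
  }
  x <- as.numeric(x)
  if (length(x) != length(components)) {
    stop("`x` must give one mole fraction per component", call. = FALSE)
  }
  if (any(x < 0) || abs(sum(x) - 1) > 1e-9) {
    stop("mole fractions must be non-negative and sum to 1 within 1e-9",
         call. = FALSE)
  }
  if (!is.numeric(temperature) || temperature <= 0) {
    stop("`temperature` must be positive (Kelvin)", call. = FALSE)
  }
  structure(list(components = components, x = x,
                 temperature = as.numeric(temperature)),
            class = "mixture")
}

#' Pure-liquid mixture of one compound
#' @param comp a [compound()].
#' @param temperature Kelvin.
#' @return a one-component [mixture()].
#' @export
pure_mixture <- function(comp, temperature = 298.15) {
  mixture(list(comp), 1, temperature)
}

#' Ensemble sigma-profile of a mixture
#'
#' The solvent ensemble of the segment thermodynamics: the area-weighted
#' mixture profile p_S(sigma) = sum_k x_k p_k(sigma) normalised by
#' sum_k x_k A_k so that it sums to one — a probability distribution over
#' surface contacts.
#'
#' @param mix a [mixture()] whose components all carry profiles on a
#'   common grid (use [rebin_profile()] first if they do not).
#' @return object of class `ensemble_profile` with fields `grid`, `p`
#'   (normalised weights summing to 1), `area` (ensemble area
#'   sum_k x_k A_k in A^2), `volume` (sum_k x_k V_k in A^3).
#' @export
ensemble_profile <- function(mix) {
  stopifnot(inherits(mix, "mixture"))
  profs <- lapply(mix$components, function(cc) {
    if (is.null(cc$profile)) {
      stop("component '", cc$name, "' has no sigma-profile", call. = FALSE)
    }
    cc$profile
  })
  grid <- profs[[1L]]$grid
  for (p in profs[-1L]) {
    if (length(p$grid) != length(grid) ||
        any(abs(p$grid - grid) > 1e-12)) {
      stop("component profiles are on different grids; rebin them onto a ",
           "common grid first (see rebin_profile)", call. = FALSE)
    }
  }
  w <- numeric(length(grid))
  area <- 0
  volume <- 0
  for (k in seq_along(profs)) {
    w <- w + mix$x[k] * profs[[k]]$areas
    area <- area + mix$x[k] * sum(profs[[k]]$areas)
    volume <- volume + mix$x[k] * profs[[k]]$cavity_volume
  }
  if (area <= 0) {
    stop("degenerate mixture: ensemble surface area is zero", call. = FALSE)
  }
  structure(list(grid = grid, p = w / area, area = area, volume = volume),
            class = "ensemble_profile")
}
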