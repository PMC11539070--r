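# Segment statistical thermodynamics on sigma-profiles: pair interaction
# energies, the self-consistent sigma-potential, pseudochemical potentials,
# activity coefficients, and mixing (excess) enthalpy.
#
# Convention: the sigma-potential mu_S(sigma) is carried per surface
# contact (one segment of area a_eff), so the fixed point reads
#   mu_S(sigma) = -RT ln sum_sigma' p_S(sigma') exp[(mu_S(sigma') - E(sigma,sigma'))/RT]
# and the surface integral of a compound X is
#   mu_X = mu_comb + (1/a_eff) sum_sigma p_X(sigma) mu_S(sigma),
# with p_X in A^2 per bin. This is algebraically identical to the
# per-unit-area formulation in which a_eff appears inside the exponent.

#' Interaction energy of a surface segment pair
#'
#' Electrostatic misfit plus hydrogen bonding, per contact:
#' `E = (alpha'/2) (sigma1 + sigma2)^2
#'      + c_hb * min(0, min(sigma1, sigma2) + sigma_hb)
#'             * max(0, max(sigma1, sigma2) - sigma_hb)`.
#' The hydrogen-bond term is active (and negative, i.e. attractive) only
#' when one segment is a sufficiently strong donor (sigma below
#' `-sigma_hb`) and the other a sufficiently strong acceptor (sigma above
#' `+sigma_hb`). A surface-proportional van der Waals energy, if
#' configured, is added as a constant per contact; it cancels in all
#' mixing properties. Symmetric in its arguments and vectorized.
#'
#' @param sigma1,sigma2 screening charge densities in e/A^2.
#' @param params a [cosmo_parameters()] object.
#' @return energy per contact in kcal/mol.
#' @export
#' @examples
#' pair_interaction_energy(0, 0, cosmo_parameters())           # 0
#' pair_interaction_energy(0.02, -0.02, cosmo_parameters())    # strongly negative
pair_interaction_energy <- function(sigma1, sigma2, params = cosmo_parameters()) {
  lo <- pmin(sigma1, sigma2)
  hi <- pmax(sigma1, sigma2)
  misfit <- (params$alpha_prime / 2) * (sigma1 + sigma2)^2
  hb <- params$c_hb * pmin(0, lo + params$sigma_hb) * pmax(0, hi - params$sigma_hb)
  misfit + hb + 2 * params$vdw_coefficient * params$a_eff
}

#' Solve the self-consistent sigma-potential of a mixture
#'
#' Damped successive substitution of the fixed point written above,
#' starting from `init` (zero by default), accelerated by a depth-one
#' Anderson (secant) update once the iteration is under way. If a step
#' increases the residual the step length is halved, which tames the
#' oscillations that strongly hydrogen-bonding ensembles can produce;
#' the Anderson update is safeguarded the same way. The converged
#' solution is independent of the initialization.
#'
#' @param mix a [mixture()] (or a precomputed [ensemble_profile()]).
#' @param params a [cosmo_parameters()] object.
#' @param init optional initial sigma-potential values, one per grid bin.
#' @param temperature optional override of the mixture temperature, K.
#' @return object of class `sigma_potential` with fields `grid`, `mu`
#'   (kcal/mol per contact), `temperature`, `converged`, `residual`,
#'   `iterations`.
#' @export
solve_sigma_potential <- function(mix, params = cosmo_parameters(),
                                  init = NULL, temperature = NULL) {
  ens <- if (inherits(mix, "ensemble_profile")) mix else ensemble_profile(mix)
  if (is.null(temperature)) {
    temperature <- if (inherits(mix, "mixture")) mix$temperature else
      stop("`temperature` is required when passing an ensemble profile",
           call. = FALSE)
  }
  grid <- ens$grid
  p <- ens$p
  if (!any(p > 0)) {
    stop("degenerate ensemble: all-zero profile", call. = FALSE)
  }
  RT <- .R_KCAL * temperature
  E <- outer(grid, grid, pair_interaction_energy, params = params)
  mu <- if (is.null(init)) numeric(length(grid)) else {
    stopifnot(length(init) == length(grid))
    as.numeric(init)
  }
  boltz <- exp(-E / RT)           # n x n, fixed during iteration
  G <- function(m) -RT * log(as.vector(boltz %*% (p * exp(m / RT))))
  step <- 1 - params$damping
  history <- numeric(0)
  f <- G(mu) - mu
  res <- max(abs(f))
  mu_prev <- NULL
  f_prev <- NULL
  for (it in seq_len(params$max_iter)) {
    if (!is.finite(res)) {
      stop("sigma-potential iteration diverged (non-finite residual)",
           call. = FALSE)
    }
    history <- c(history, res)
    if (res < params$tol) {
      return(structure(
        list(grid = grid, mu = mu, temperature = temperature,
             converged = TRUE, residual = res, iterations = it,
             ensemble = ens),
        class = "sigma_potential"))
    }
    accepted <- FALSE
    if (!is.null(f_prev)) {
      # depth-one Anderson (secant) step, accepted on strict contraction
      df <- f - f_prev
      denom <- sum(df * df)
      if (denom > 0) {
        gam <- sum(f * df) / denom
        cand <- (mu + f) - gam * ((mu - mu_prev) + df)
        if (all(is.finite(cand))) {
          f_c <- G(cand) - cand
          res_c <- max(abs(f_c))
          if (is.finite(res_c) && res_c < 0.9 * res) {
            mu_prev <- mu; f_prev <- f
            mu <- cand; f <- f_c; res <- res_c
            accepted <- TRUE
          }
        }
      }
    }
    if (!accepted) {
      cand <- mu + step * f
      f_c <- G(cand) - cand
      res_c <- max(abs(f_c))
      if (is.finite(res_c) && res_c > res) step <- max(step / 2, 0.05)
      else step <- min(step * 1.05, 0.95)
      mu_prev <- mu; f_prev <- f
      mu <- cand; f <- f_c; res <- res_c
    }
  }
  stop(sprintf(
    "sigma-potential did not converge in %d iterations (last residuals: %s)",
    params$max_iter,
    paste(signif(utils::tail(history, 5L), 4L), collapse = ", ")),
    call. = FALSE)
}

#' @export
print.sigma_potential <- function(x, ...) {
  cat(sprintf(
    "sigma-potential at %.2f K: %d bins, converged in %d iterations (residual %.2e)\n",
    x$temperature, length(x$grid), x$iterations, x$residual))
  invisible(x)
}

# Staverman-Guggenheim combinatorial activity coefficient (log scale) of
# `comp` in `mix`. Dimensionless size/shape term; exactly zero for a pure
# component, and purely entropic (no temperature dependence on the ln
# gamma scale), so it drops out of Gibbs-Helmholtz enthalpies.
.sg_lngamma <- function(comp, mix, params) {
  r_of <- function(cc) cc$profile$cavity_volume / params$comb_r0
  q_of <- function(cc) cc$profile$cavity_area / params$comb_q0
  r_i <- r_of(comp)
  q_i <- q_of(comp)
  r_all <- vapply(mix$components, r_of, numeric(1L))
  q_all <- vapply(mix$components, q_of, numeric(1L))
  sr <- sum(mix$x * r_all)
  sq <- sum(mix$x * q_all)
  z <- params$comb_z
  l_of <- function(r, q) (z / 2) * (r - q) - (r - 1)
  phi_by_x <- r_i / sr
  theta_by_phi <- (q_i / sq) / phi_by_x
  log(phi_by_x) + (z / 2) * q_i * log(theta_by_phi) +
    l_of(r_i, q_i) - phi_by_x * sum(mix$x * l_of(r_all, q_all))
}

#' Pseudochemical potential of a compound in a mixture
#'
#' The surface integral of the sigma-potential over the compound's
#' sigma-profile, plus the area- and volume-dependent combinatorial term
#' computed from the cavity geometries of all mixture components.
#'
#' @param comp a [compound()] with a sigma-profile on the mixture grid.
#'   It need not carry a nonzero mole fraction in `mix` (an infinitely
#'   dilute tracer is valid).
#' @param mix a [mixture()].
#' @param params a [cosmo_parameters()] object.
#' @param potential optional precomputed [solve_sigma_potential()] result
#'   for `mix`.
#' @return pseudochemical potential in kcal/mol (the pure-liquid
#'   combinatorial reference is zero).
#' @export
pseudochemical_potential <- function(comp, mix, params = cosmo_parameters(),
                                     potential = NULL) {
  stopifnot(inherits(comp, "compound"))
  if (is.null(comp$profile)) {
    stop("compound '", comp$name, "' has no sigma-profile", call. = FALSE)
  }
  if (is.null(potential)) potential <- solve_sigma_potential(mix, params)
  if (length(comp$profile$grid) != length(potential$grid) ||
      any(abs(comp$profile$grid - potential$grid) > 1e-12)) {
    stop("compound profile is not on the mixture grid; rebin first",
         call. = FALSE)
  }
  RT <- .R_KCAL * potential$temperature
  residual <- sum(comp$profile$areas * potential$mu) / params$a_eff
  comb <- RT * .sg_lngamma(comp, mix, params)
  residual + comb
}

#' Activity coefficient of a compound in a mixture
#'
#' `ln gamma = (mu_X^S - mu_X^X) / RT`, the pseudochemical potential in
#' the mixture relative to the compound's own pure liquid at the same
#' temperature.
#'
#' @inheritParams pseudochemical_potential
#' @return dimensionless activity coefficient gamma (> 0).
#' @export
activity_coefficient <- function(comp, mix, params = cosmo_parameters(),
                                 potential = NULL) {
  T <- mix$temperature
  RT <- .R_KCAL * T
  mu_mix <- pseudochemical_potential(comp, mix, params, potential)
  mu_pure <- pseudochemical_potential(comp, pure_mixture(comp, T), params)
  exp((mu_mix - mu_pure) / RT)
}

#' Partial molar enthalpy of a compound in a mixture
#'
#' Gibbs-Helmholtz route: `H = d(mu/T) / d(1/T)` evaluated by a central
#' finite difference over `[T - dT, T + dT]`. The combinatorial term is
#' athermal and drops out exactly; the temperature dependence of the
#' sigma-potential carries the enthalpic content.
#'
#' @inheritParams pseudochemical_potential
#' @param T temperature in Kelvin (defaults to the mixture temperature).
#' @param dT finite-difference half-width in K (defaults to the value in
#'   `params`).
#' @return enthalpy in kcal/mol.
#' @export
partial_enthalpy <- function(comp, mix, T = mix$temperature,
                             params = cosmo_parameters(), dT = params$dT) {
  stopifnot(dT > 0, T - dT > 0)
  mu_at <- function(temp) {
    m <- mixture(mix$components, mix$x, temp)
    pseudochemical_potential(comp, m, params)
  }
  t1 <- T - dT
  t2 <- T + dT
  (mu_at(t2) / t2 - mu_at(t1) / t1) / (1 / t2 - 1 / t1)
}

#' Excess (mixing) enthalpy of a drug-coformer pair
#'
#' `H_ex = sum_k x_k (H_k^mix - H_k^pure)` over the two components,
#' the enthalpy change on mixing the supercooled-liquid components
#' relative to their pure states. Defaults follow the screening
#' convention: equimolar mixture at 25 degrees C. Negative values signal
#' favourable specific drug-coformer interactions.
#'
#' @param drug,coformer [compound()]s with sigma-profiles on a common grid.
#' @param x mole fractions `c(x_drug, x_coformer)`; default 1:1.
#' @param T temperature in Kelvin; default 298.15 (25 C).
#' @param params a [cosmo_parameters()] object.
#' @return excess enthalpy in kcal/mol (per mole of mixture).
#' @export
excess_enthalpy <- function(drug, coformer, x = c(0.5, 0.5), T = 298.15,
                            params = cosmo_parameters()) {
  comps <- list(drug, coformer)
  mix <- mixture(comps, x, T)
  h <- 0
  for (k in seq_along(comps)) {
    if (x[k] == 0) next
    h_mix <- partial_enthalpy(comps[[k]], mix, T, params)
    h_pure <- partial_enthalpy(comps[[k]], pure_mixture(comps[[k]], T), T, params)
    h <- h + x[k] * (h_mix - h_pure)
  }
  h
}

#' Infinite-dilution activity coefficient via the segment engine
#'
#' ln gamma of a solute infinitely dilute in a solvent, computed with the
#' solute at mole fraction 1e-6 (a numerically stable proxy for the
#' infinite-dilution limit).
#'
#' @param solute,solvent [compound()]s with sigma-profiles on a common grid.
#' @param T temperature, K.
#' @param params a [cosmo_parameters()] object.
#' @param x_dilute solute mole fraction representing infinite dilution.
#' @return `ln gamma` (dimensionless, natural log).
#' @export
engine_lngamma_inf <- function(solute, solvent, T = 298.15,
                               params = cosmo_parameters(),
                               x_dilute = 1e-6) {
  mix <- mixture(list(solute, solvent), c(x_dilute, 1 - x_dilute), T)
  log(activity_coefficient(solute, mix, params))
}
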