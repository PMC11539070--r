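# Hansen partial solubility parameters estimated by virtual solubility
# screening: activity coefficients from the segment engine over a set of
# reference solvents are matched, through a sigmoidal good/bad-solvent
# transform, against the regular-solution activity model, and the partial
# parameters are fitted by least squares.

#' Hansen solubility parameters
#'
#' @param delta_d,delta_p,delta_h dispersive, polar and hydrogen-bonding
#'   partial parameters, MPa^0.5, each in \[0, 40\].
#' @return object of class `hansen_parameters` with `delta_total =
#'   sqrt(delta_d^2 + delta_p^2 + delta_h^2)`.
#' @export
#' @examples
#' hansen_parameters(3, 4, 0) # total 5
hansen_parameters <- function(delta_d, delta_p, delta_h) {
  v <- c(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 40)) {
    stop("partial solubility parameters must lie in [0, 40] MPa^0.5",
         call. = FALSE)
  }
  structure(
    list(delta_d = delta_d, delta_p = delta_p, delta_h = delta_h,
         delta_total = sqrt(delta_d^2 + delta_p^2 + delta_h^2)),
    class = "hansen_parameters")
}

#' @export
print.hansen_parameters <- function(x, ...) {
  cat(sprintf(
    "Hansen parameters (MPa^0.5): delta_d = %.2f, delta_p = %.2f, delta_h = %.2f; total %.2f\n",
    x$delta_d, x$delta_p, x$delta_h, x$delta_total))
  invisible(x)
}

#' Regular-solution activity coefficient from Hansen distances
#'
#' `ln gamma = (V_x / RT) * [alpha (dd_x - dd_i)^2 + (dp_x - dp_i)^2 +
#' (dh_x - dh_i)^2]` with the universal weighting factor `alpha = 4` on
#' the dispersive term. Squared parameter differences (MPa) convert to
#' cohesive energy densities (J/cm^3) through [mpa_to_J_cm3()]; with the
#' molar volume in cm^3/mol the product is in J/mol against RT in J/mol.
#' Always non-negative; zero only when solute and solvent parameters
#' coincide.
#'
#' @param solute a [hansen_parameters()] object for the solute.
#' @param solvent a [hansen_parameters()] object (or a one-row reference
#'   solvent data frame with `delta_d`, `delta_p`, `delta_h` columns).
#' @param V_x solute molar volume, cm^3/mol.
#' @param T temperature, K.
#' @param alpha universal dispersive weighting factor.
#' @return `ln gamma` (dimensionless).
#' @export
hansen_lngamma <- function(solute, solvent, V_x, T = 298.15, alpha = 4) {
  stopifnot(V_x > 0, T > 0)
  d2 <- alpha * (solute$delta_d - solvent$delta_d)^2 +
    (solute$delta_p - solvent$delta_p)^2 +
    (solute$delta_h - solvent$delta_h)^2
  V_x * mpa_to_J_cm3(d2) / (.R_J * T)
}

#' Sigmoid configuration for the good/bad-solvent transform
#'
#' @param steepness positive slope parameter.
#' @param center `ln gamma` at which the transform crosses 0.5. The
#'   default 2 (gamma about 7.4) separates good from bad solvents.
#' @return object of class `sigmoid_config`.
#' @export
sigmoid_config <- function(steepness = 1, center = 2) {
  stopifnot(steepness > 0, is.finite(center))
  structure(list(steepness = steepness, center = center),
            class = "sigmoid_config")
}

#' Sigmoidal good/bad-solvent transform
#'
#' `f = 1 / (1 + exp(steepness * (lngamma - center)))`: close to one for
#' good solvents (low ln gamma), close to zero for bad ones, 0.5 at the
#' center. Monotone decreasing.
#'
#' @param lngamma activity coefficient on the natural-log scale.
#' @param config a [sigmoid_config()].
#' @return value in (0, 1); vectorized.
#' @export
sigmoid_f <- function(lngamma, config = sigmoid_config()) {
  stats::plogis(-(config$steepness) * (lngamma - config$center))
}

#' Bundled reference solvent table
#'
#' Twenty-nine common solvents spanning dispersive, polar and
#' hydrogen-bonding space, with literature Hansen partial parameters
#' (MPa^0.5) and molar volumes (cm^3/mol). Shipped as plain CSV in
#' `inst/extdata/reference_solvents.csv`; replace it with your own table
#' via [read_solvent_table()].
#'
#' @return data frame with columns `name`, `delta_d`, `delta_p`,
#'   `delta_h`, `molar_volume_cm3mol`.
#' @export
reference_solvents <- function() {
  read_solvent_table(system.file("extdata", "reference_solvents.csv",
                                 package = "cosmoform", mustWork = TRUE))
}

#' Read a reference solvent table from CSV
#'
#' Expected columns: `name`, `delta_d`, `delta_p`, `delta_h`,
#' `molar_volume_cm3mol`, optionally `profile_path`.
#'
#' @param path CSV file.
#' @return validated data frame.
#' @export
read_solvent_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "delta_d", "delta_p", "delta_h", "molar_volume_cm3mol")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("solvent table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("delta_d", "delta_p", "delta_h")) {
    if (any(!is.finite(df[[col]])) || any(df[[col]] < 0)) {
      stop("solvent table column ", col, " must be non-negative", call. = FALSE)
    }
  }
  df
}

.hansen_objective <- function(par, f_target, solvents, V_x, T, alpha, config) {
  solute <- list(delta_d = par[1L], delta_p = par[2L], delta_h = par[3L])
  lg <- V_x * mpa_to_J_cm3(
    alpha * (par[1L] - solvents$delta_d)^2 +
      (par[2L] - solvents$delta_p)^2 +
      (par[3L] - solvents$delta_h)^2) / (.R_J * T)
  sum((f_target - sigmoid_f(lg, config))^2)
}

#' Fit Hansen solubility parameters to activity coefficients
#'
#' The estimator of the virtual solubility screen: given one activity
#' coefficient (natural log) of the solute in each reference solvent —
#' typically from [engine_lngamma_inf()] — the partial parameters
#' `(delta_d, delta_p, delta_h)` of the regular-solution model are varied
#' to minimise the squared differences of the sigmoid-transformed
#' activities, `sum_i [f(lngamma_i) - f(lngamma_hansen,i)]^2`. The
#' transform concentrates the information where it matters: whether a
#' solvent is good or bad.
#'
#' The objective is multimodal, so optimisation is multi-started from a
#' coarse grid over the parameter box and the best local optimum is kept.
#'
#' @param lngamma numeric vector of solute ln gamma values, one per
#'   solvent row.
#' @param solvents reference solvent table (see [reference_solvents()]).
#' @param V_x solute molar volume, cm^3/mol.
#' @param T temperature, K.
#' @param alpha dispersive weighting factor of the Hansen distance.
#' @param config a [sigmoid_config()].
#' @param lower,upper box constraints on each partial parameter, MPa^0.5.
#' @param n_keep number of grid starts polished with L-BFGS-B.
#' @return object of class `hansen_fit`; see [coef.hansen_fit()],
#'   [summary.hansen_fit()], [predict.hansen_fit()], [plot.hansen_fit()].
#' @export
#' @examples
#' solv <- reference_solvents()
#' truth <- hansen_parameters(17, 8, 10)
#' lg <- vapply(seq_len(nrow(solv)), function(i)
#'   hansen_lngamma(truth, solv[i, ], V_x = 150), numeric(1))
#' fit <- fit_hansen(lg, solv, V_x = 150)
#' coef(fit)
fit_hansen <- function(lngamma, solvents, V_x, T = 298.15, alpha = 4,
                       config = sigmoid_config(),
                       lower = c(10, 0, 0), upper = c(40, 40, 40),
                       n_keep = 10L) {
  stopifnot(length(lngamma) == nrow(solvents), V_x > 0)
  if (nrow(solvents) < 4L) {
    stop("need at least 4 reference solvents", call. = FALSE)
  }
  spread <- vapply(c("delta_d", "delta_p", "delta_h"),
                   function(col) stats::sd(solvents[[col]]), numeric(1L))
  if (all(spread < 1e-8)) {
    stop("ill-posed fit: all reference solvents are identical", call. = FALSE)
  }
  f_target <- sigmoid_f(lngamma, config)
  obj <- function(par) .hansen_objective(par, f_target, solvents, V_x, T,
                                         alpha, config)
  grid_d <- seq(max(lower[1L], 12), min(upper[1L], 22), by = 2.5)
  grid_p <- seq(lower[2L], min(upper[2L], 20), by = 4)
  grid_h <- seq(lower[3L], min(upper[3L], 28), by = 4)
  starts <- as.matrix(expand.grid(grid_d, grid_p, grid_h))
  start_obj <- apply(starts, 1L, obj)
  keep <- order(start_obj)[seq_len(min(n_keep, nrow(starts)))]
  best <- NULL
  n_fail <- 0L
  for (i in keep) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("Hansen fit failed: no multi-start converged (", n_fail,
         " optimizer failures)", call. = FALSE)
  }
  par <- as.numeric(best$par)
  est <- hansen_parameters(par[1L], par[2L], par[3L])
  lg_fit <- vapply(seq_len(nrow(solvents)), function(i)
    hansen_lngamma(est, solvents[i, ], V_x, T, alpha), numeric(1L))
  structure(
    list(coefficients = c(delta_d = est$delta_d, delta_p = est$delta_p,
                          delta_h = est$delta_h,
                          delta_total = est$delta_total),
         hansen = est,
         objective = best$value,
         start_objectives = start_obj[keep],
         lngamma = as.numeric(lngamma),
         f_target = f_target,
         fitted_lngamma = lg_fit,
         fitted_f = sigmoid_f(lg_fit, config),
         solvents = solvents, V_x = V_x, T = T, alpha = alpha,
         config = config,
         convergence = best$convergence),
    class = "hansen_fit")
}

#' @export
coef.hansen_fit <- function(object, ...) object$coefficients

#' @export
print.hansen_fit <- function(x, ...) {
  cat("Hansen solubility parameter fit (virtual solubility screening)\n")
  cat(sprintf("  %d reference solvents, V_x = %g cm^3/mol, T = %.2f K\n",
              nrow(x$solvents), x$V_x, x$T))
  print(x$hansen)
  cat(sprintf("  objective (sum of squared f-residuals): %.4g\n", x$objective))
  invisible(x)
}

#' @export
summary.hansen_fit <- function(object, ...) {
  r <- object$f_target - object$fitted_f
  structure(
    list(fit = object,
         residual_summary = summary(r),
         n_good = sum(object$f_target > 0.5),
         n_solvents = nrow(object$solvents)),
    class = "summary.hansen_fit")
}

#' @export
print.summary.hansen_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  good solvents (f > 0.5): %d of %d\n", x$n_good, x$n_solvents))
  cat("  f-residuals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' Predict solvent quality from a Hansen fit
#'
#' @param object a [fit_hansen()] result.
#' @param newdata solvent table (defaults to the fitting solvents).
#' @param type `"lngamma"` for the regular-solution ln gamma, `"f"` for
#'   the sigmoid-transformed solvent quality.
#' @param ... unused.
#' @return numeric vector, one value per solvent row.
#' @export
predict.hansen_fit <- function(object, newdata = NULL,
                               type = c("lngamma", "f"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$solvents
  lg <- vapply(seq_len(nrow(newdata)), function(i)
    hansen_lngamma(object$hansen, newdata[i, ], object$V_x, object$T,
                   object$alpha), numeric(1L))
  if (type == "f") sigmoid_f(lg, object$config) else lg
}

#' @export
residuals.hansen_fit <- function(object, ...) {
  object$f_target - object$fitted_f
}

#' @export
fitted.hansen_fit <- function(object, ...) object$fitted_f

#' Diagnostic plot of a Hansen fit
#'
#' Target versus fitted sigmoid solvent quality, one point per reference
#' solvent, with the identity line.
#'
#' @param x a [fit_hansen()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hansen_fit <- function(x, ...) {
  graphics::plot(x$f_target, x$fitted_f,
                 xlab = "target f(ln gamma)", ylab = "fitted f(ln gamma)",
                 xlim = c(0, 1), ylim = c(0, 1), pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Fit Hansen parameters of a compound through the segment engine
#'
#' Convenience wrapper chaining [engine_lngamma_inf()] over a solvent set
#' that carries sigma-profiles into [fit_hansen()].
#'
#' @param solute a [compound()] with a sigma-profile.
#' @param solvent_compounds list of [compound()]s, one per solvent row.
#' @param solvents reference solvent table aligned with
#'   `solvent_compounds`.
#' @param params engine [cosmo_parameters()].
#' @param ... passed on to [fit_hansen()].
#' @param T temperature, K.
#' @return a `hansen_fit` object.
#' @export
fit_hansen_engine <- function(solute, solvent_compounds, solvents,
                              params = cosmo_parameters(), T = 298.15, ...) {
  stopifnot(length(solvent_compounds) == nrow(solvents))
  lg <- vapply(solvent_compounds, function(sv)
    engine_lngamma_inf(solute, sv, T, params), numeric(1L))
  fit_hansen(lg, solvents, V_x = solute$molar_volume, T = T, ...)
}
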