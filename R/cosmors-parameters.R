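# Engine parameter set: the published open COSMO-RS/COSMO-SAC constants.
# The screening literature plots excess enthalpies computed with a
# proprietary fragment-based engine whose parameterization is undisclosed;
# this package uses the open literature defaults below, stored in one
# versioned, checksummable parameter object.

#' Engine parameters for the segment thermodynamics
#'
#' Defaults are the widely used open parameterization on the TZVP level:
#' effective contact area 7.5 A^2, misfit constant 16466.72
#' kcal A^4/(mol e^2), hydrogen-bond constant 85580 kcal A^4/(mol e^2)
#' with threshold 0.0084 e/A^2, and the Staverman-Guggenheim
#' combinatorial term with normalisation volume 66.69 A^3, area
#' 79.53 A^2 and coordination number 10.
#'
#' @param alpha_prime misfit energy constant, kcal A^4/(mol e^2).
#' @param c_hb hydrogen-bond strength constant, kcal A^4/(mol e^2).
#' @param sigma_hb hydrogen-bond threshold, e/A^2.
#' @param a_eff effective contact area, A^2.
#' @param comb_r0,comb_q0,comb_z combinatorial normalisation volume (A^3),
#'   area (A^2) and coordination number.
#' @param vdw_coefficient surface-proportional van der Waals energy,
#'   kcal/(mol A^2); zero by default because a surface-proportional term
#'   cancels identically in mixing properties.
#' @param tol fixed-point convergence tolerance (max-norm on the
#'   sigma-potential, kcal/mol).
#' @param max_iter iteration cap for the fixed-point solver.
#' @param damping initial damping of the successive substitution (fraction
#'   of the old iterate retained).
#' @param dT half-width of the Gibbs-Helmholtz finite difference, K.
#' @return object of class `cosmo_parameters`.
#' @export
#' @examples
#' cosmo_parameters()
cosmo_parameters <- function(alpha_prime = 16466.72,
                             c_hb = 85580,
                             sigma_hb = 0.0084,
                             a_eff = 7.5,
                             comb_r0 = 66.69,
                             comb_q0 = 79.53,
                             comb_z = 10,
                             vdw_coefficient = 0,
                             tol = 1e-10,
                             max_iter = 2000L,
                             damping = 0.4,
                             dT = 5) {
  stopifnot(a_eff > 0, sigma_hb >= 0, c_hb >= 0, alpha_prime >= 0,
            tol > 0, max_iter >= 1, damping >= 0, damping < 1, dT > 0)
  structure(
    list(version = "cosmoform-params-1",
         alpha_prime = alpha_prime, c_hb = c_hb, sigma_hb = sigma_hb,
         a_eff = a_eff,
         comb_r0 = comb_r0, comb_q0 = comb_q0, comb_z = comb_z,
         vdw_coefficient = vdw_coefficient,
         tol = tol, max_iter = as.integer(max_iter),
         damping = damping, dT = dT),
    class = "cosmo_parameters")
}

#' @export
print.cosmo_parameters <- function(x, ...) {
  cat("COSMO-RS engine parameters (", x$version, ")\n", sep = "")
  cat(sprintf("  alpha' = %g, c_hb = %g kcal A^4/(mol e^2), sigma_hb = %g e/A^2\n",
              x$alpha_prime, x$c_hb, x$sigma_hb))
  cat(sprintf("  a_eff = %g A^2; combinatorial r0 = %g A^3, q0 = %g A^2, z = %g\n",
              x$a_eff, x$comb_r0, x$comb_q0, x$comb_z))
  cat(sprintf("  solver: tol %g, max %d iterations, damping %g; dT = %g K\n",
              x$tol, x$max_iter, x$damping, x$dT))
  invisible(x)
}

#' Write and read an engine parameter file
#'
#' Flat `key = value` text, carrying the parameter-set version so that a
#' report can record exactly which constants produced it.
#'
#' @param params a [cosmo_parameters()] object.
#' @param path file location.
#' @return `write_cosmo_parameters` returns `path` invisibly;
#'   `read_cosmo_parameters` returns a [cosmo_parameters()] object.
#' @export
write_cosmo_parameters <- function(params, path) {
  stopifnot(inherits(params, "cosmo_parameters"))
  keys <- setdiff(names(params), "version")
  lines <- c(sprintf("version = %s", params$version),
             vapply(keys, function(k) sprintf("%s = %.15g", k, params[[k]]),
                    character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cosmo_parameters
#' @export
read_cosmo_parameters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1L), 1L)
  vals <- vapply(kv, `[`, character(1L), 2L)
  named <- stats::setNames(as.list(vals), trimws(keys))
  version <- named$version
  named$version <- NULL
  args <- lapply(named, as.numeric)
  if (any(vapply(args, is.na, logical(1L)))) {
    stop("unreadable parameter file: ", path, call. = FALSE)
  }
  p <- do.call(cosmo_parameters, args)
  if (!is.null(version) && !identical(trimws(version), p$version)) {
    warning("parameter file version '", trimws(version),
            "' differs from current '", p$version, "'")
  }
  p
}

#' Checksum of a parameter file for report provenance
#' @param path parameter file.
#' @return md5 digest string.
#' @export
parameter_checksum <- function(path) {
  unname(tools::md5sum(path))
}
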