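# Sigma-profiles: the molecular input of the COSMO-RS-style engine.
# A profile is a histogram p^X(sigma) of a molecule's surface screening
# charge densities, together with the total cavity surface area and volume.

#' Default screening-charge-density grid
#'
#' The conventional COSMO-RS grid: 51 bins from -0.025 to +0.025 e/A^2 in
#' steps of 0.001. Hydrogen-bond-donor surfaces carry negative sigma
#' (the screening charge mirrors the molecular charge), acceptor surfaces
#' positive sigma.
#'
#' @return numeric vector of 51 sigma values in e/A^2.
#' @export
#' @examples
#' length(default_sigma_grid())
default_sigma_grid <- function() {
  seq.int(-25L, 25L) / 1000
}

#' Construct a sigma-profile
#'
#' @param grid screening charge densities sigma in e/A^2; strictly
#'   increasing with uniform spacing.
#' @param areas surface area per bin in A^2; non-negative.
#' @param cavity_area total molecular surface area in A^2. Must agree with
#'   `sum(areas)` to within 0.1\% relative.
#' @param cavity_volume molecular cavity volume in A^3.
#' @return object of class `sigma_profile`.
#' @export
#' @examples
#' g <- default_sigma_grid()
#' a <- rep(0, length(g)); a[26] <- 120
#' sigma_profile(g, a, cavity_area = 120, cavity_volume = 150)
sigma_profile <- function(grid, areas, cavity_area = sum(areas), cavity_volume) {
  grid <- as.numeric(grid)
  areas <- as.numeric(areas)
  if (length(grid) != length(areas)) {
    stop("`grid` and `areas` must have the same length", call. = FALSE)
  }
  if (length(grid) < 2L) {
    stop("a sigma-profile needs at least two bins", call. = FALSE)
  }
  .check_uniform_grid(grid)
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("bin areas must be finite and non-negative", call. = FALSE)
  }
  if (sum(areas) <= 0) {
    stop("profile has zero total area", call. = FALSE)
  }
  if (!is.numeric(cavity_area) || length(cavity_area) != 1L || cavity_area <= 0) {
    stop("`cavity_area` must be a single positive number", call. = FALSE)
  }
  if (missing(cavity_volume) || !is.numeric(cavity_volume) ||
      length(cavity_volume) != 1L || cavity_volume <= 0) {
    stop("`cavity_volume` must be a single positive number", call. = FALSE)
  }
  s <- sum(areas)
  if (s <= 0) {
    stop("profile has zero total area", call. = FALSE)
  }
  if (abs(s - cavity_area) > 1e-3 * cavity_area) {
    stop(sprintf(
      "sum of bin areas (%.6g) disagrees with cavity_area (%.6g) by more than 0.1%%",
      s, cavity_area), call. = FALSE)
  }
  structure(
    list(grid = grid, areas = areas,
         cavity_area = as.numeric(cavity_area),
         cavity_volume = as.numeric(cavity_volume)),
    class = "sigma_profile")
}

.check_uniform_grid <- function(grid) {
  d <- diff(grid)
  if (any(d <= 0)) {
    stop("malformed profile: sigma grid must be strictly increasing", call. = FALSE)
  }
  h <- d[1L]
  if (any(abs(d - h) > 1e-12 * max(abs(grid), h))) {
    stop("malformed profile: sigma grid spacing is not uniform", call. = FALSE)
  }
  invisible(h)
}

#' @export
print.sigma_profile <- function(x, ...) {
  cat(sprintf(
    "sigma-profile: %d bins on [%g, %g] e/A^2 (step %g)\n",
    length(x$grid), x$grid[1L], x$grid[length(x$grid)], x$grid[2L] - x$grid[1L]))
  cat(sprintf("  cavity area %.3f A^2, volume %.3f A^3\n",
              x$cavity_area, x$cavity_volume))
  invisible(x)
}

#' Read a sigma-profile from tabulated text
#'
#' The file dialect is two whitespace-separated numeric columns
#' (sigma in e/A^2, area in A^2), optionally preceded by comment lines
#' starting with `#`. Cavity metadata is taken from header comment keys
#' `area=` and `volume=`, or supplied through the arguments; it is never
#' silently defaulted.
#'
#' @param path file to read.
#' @param cavity_area,cavity_volume cavity metadata, overriding any header
#'   values. Required if the header does not carry them.
#' @return a validated [sigma_profile()].
#' @export
read_sigma_profile <- function(path, cavity_area = NULL, cavity_volume = NULL) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  header <- lines[is_comment]
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) == 0L) {
    stop("malformed profile: no data rows in ", path, call. = FALSE)
  }
  grab <- function(key) {
    hit <- regmatches(header,
                      regexpr(paste0(key, "\\s*=\\s*[-0-9.eE+]+"), header))
    hit <- unlist(hit)
    if (length(hit) == 0L) return(NULL)
    as.numeric(sub(paste0(key, "\\s*=\\s*"), "", hit[1L]))
  }
  if (is.null(cavity_area)) cavity_area <- grab("area")
  if (is.null(cavity_volume)) cavity_volume <- grab("volume")
  if (is.null(cavity_area) || is.null(cavity_volume)) {
    stop("metadata required: cavity area/volume not found in header of ", path,
         " and not supplied", call. = FALSE)
  }
  fields <- strsplit(trimws(body), "\\s+")
  if (any(lengths(fields) != 2L)) {
    stop("malformed profile: expected two numeric columns in ", path,
         call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 2L, byrow = TRUE)
  if (any(!is.finite(m))) {
    stop("malformed profile: non-numeric values in ", path, call. = FALSE)
  }
  sigma_profile(m[, 1L], m[, 2L],
                cavity_area = cavity_area, cavity_volume = cavity_volume)
}

#' Write a sigma-profile to tabulated text
#'
#' Inverse of [read_sigma_profile()]: cavity metadata goes into `#` header
#' lines, followed by the two data columns printed at 15 significant
#' digits so a write/read round trip reproduces the profile.
#'
#' @param profile a [sigma_profile()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_sigma_profile <- function(profile, path) {
  stopifnot(inherits(profile, "sigma_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# sigma-profile (sigma e/A^2, area A^2)",
    sprintf("# area=%.15g", profile$cavity_area),
    sprintf("# volume=%.15g", profile$cavity_volume),
    sprintf("%.15g %.15g", profile$grid, profile$areas)), con)
  invisible(path)
}

#' Rebin a sigma-profile onto a new grid
#'
#' Each source bin is treated as a point mass at its bin centre and split
#' between the two bracketing target bins in proportion to proximity, so
#' the total surface area is conserved exactly.
#'
#' @param profile a [sigma_profile()].
#' @param target_grid uniform ascending sigma values.
#' @return a [sigma_profile()] on `target_grid`.
#' @export
rebin_profile <- function(profile, target_grid) {
  stopifnot(inherits(profile, "sigma_profile"))
  target_grid <- as.numeric(target_grid)
  .check_uniform_grid(target_grid)
  src <- profile$grid
  mass <- profile$areas
  nz <- mass > 0
  if (any(nz)) {
    support <- range(src[nz])
    if (support[1L] < target_grid[1L] - 1e-12 ||
        support[2L] > target_grid[length(target_grid)] + 1e-12) {
      stop("target grid is narrower than the profile support; area would be lost",
           call. = FALSE)
    }
  }
  h <- target_grid[2L] - target_grid[1L]
  out <- numeric(length(target_grid))
  pos <- (src - target_grid[1L]) / h
  j <- pmin(pmax(floor(pos), 0), length(target_grid) - 2L)
  frac <- pos - j
  frac <- pmin(pmax(frac, 0), 1)
  for (k in which(nz)) {
    out[j[k] + 1L] <- out[j[k] + 1L] + mass[k] * (1 - frac[k])
    out[j[k] + 2L] <- out[j[k] + 2L] + mass[k] * frac[k]
  }
  sigma_profile(target_grid, out,
                cavity_area = profile$cavity_area,
                cavity_volume = profile$cavity_volume)
}
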