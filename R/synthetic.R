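# Synthetic fixture generator: sigma-profiles with realistic
# neutral/donor/acceptor peak structure, fixture drugs, and candidate
# coformer libraries with known ground truth, so that every stage of the
# funnel is testable without external data. All profiles produced here
# are synthetic constructions, not reproductions of any real molecule.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so fixture generation never leaks hidden global state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic sigma-profile
#'
#' A profile is described as a mixture of Gaussian peaks on the sigma
#' axis: neutral surface near sigma = 0, hydrogen-bond donors at negative
#' sigma, acceptors at positive sigma.
#'
#' @param peaks data frame with columns `center` (e/A^2), `width`
#'   (Gaussian sd, e/A^2, > 0) and `share` (area fractions summing to 1).
#' @param total_area cavity surface area, A^2.
#' @param total_volume cavity volume, A^3.
#' @return object of class `profile_spec`.
#' @export
#' @examples
#' profile_spec(data.frame(center = 0, width = 0.004, share = 1),
#'              total_area = 200, total_volume = 240)
profile_spec <- function(peaks, total_area, total_volume) {
  stopifnot(is.data.frame(peaks),
            all(c("center", "width", "share") %in% names(peaks)))
  if (any(peaks$width <= 0)) stop("peak widths must be positive", call. = FALSE)
  if (abs(sum(peaks$share) - 1) > 1e-9) {
    stop("peak area shares must sum to 1", call. = FALSE)
  }
  stopifnot(total_area > 0, total_volume > 0)
  structure(list(peaks = peaks, total_area = total_area,
                 total_volume = total_volume),
            class = "profile_spec")
}

#' Generate a sigma-profile from a peak specification
#'
#' Each Gaussian peak is discretised by exact bin-edge quadrature
#' (differences of the normal CDF), so the total surface area is
#' conserved to machine precision. A peak whose mass is not essentially
#' contained in the grid support is rejected rather than silently
#' truncated.
#'
#' @param spec a [profile_spec()].
#' @param grid sigma grid (default [default_sigma_grid()]).
#' @return a [sigma_profile()].
#' @export
generate_profile <- function(spec, grid = default_sigma_grid()) {
  stopifnot(inherits(spec, "profile_spec"))
  h <- .check_uniform_grid(grid)
  lo <- grid[1L] - h / 2
  hi <- grid[length(grid)] + h / 2
  edges <- c(grid - h / 2, hi)
  areas <- numeric(length(grid))
  for (i in seq_len(nrow(spec$peaks))) {
    p <- spec$peaks[i, ]
    captured <- stats::pnorm(hi, p$center, p$width) -
      stats::pnorm(lo, p$center, p$width)
    if (captured < 0.999) {
      stop(sprintf(
        "peak at sigma = %g (width %g) falls outside the grid support [%g, %g]",
        p$center, p$width, lo, hi), call. = FALSE)
    }
    cdf <- stats::pnorm(edges, p$center, p$width)
    areas <- areas + p$share * spec$total_area * diff(cdf) / captured
  }
  sigma_profile(grid, areas, cavity_area = spec$total_area,
                cavity_volume = spec$total_volume)
}

# Peak recipes for the hydrogen-bond characters used by the library
# generator. Shares/positions chosen so that the engine's excess enthalpy
# with the acceptor-type fixture drugs is negative for complements
# (donors meet the drug's free acceptors) and positive for clashes
# (a strongly self-associated zwitterion whose internal donor-acceptor
# network is diluted on mixing).
.hb_peak_recipes <- function() {
  list(
    complement_strong = data.frame(
      center = c(0.000, -0.0160),
      width = c(0.0040, 0.0018),
      share = c(0.94, 0.06)),
    complement_weak = data.frame(
      center = c(0.000, -0.0130),
      width = c(0.0040, 0.0018),
      share = c(0.98, 0.02)),
    clash = data.frame(
      center = c(0.000, -0.0190, 0.0190),
      width = c(0.0035, 0.0012, 0.0012),
      share = c(0.40, 0.30, 0.30)),
    neutral = data.frame(
      center = c(0.000),
      width = c(0.0045),
      share = c(1)))
}

#' Synthetic fixture drugs
#'
#' Two model drugs with mostly neutral surface and a distinct
#' basic-nitrogen acceptor peak at positive sigma, echoing the surface
#' character of poorly glass-forming lipophilic bases. Purely synthetic
#' constructions.
#'
#' @return named list of two [compound()]s, `drug_basic_A` and
#'   `drug_basic_B`.
#' @export
fixture_drugs <- function() {
  specA <- profile_spec(
    data.frame(center = c(0.000, 0.0140),
               width = c(0.0042, 0.0016),
               share = c(0.92, 0.08)),
    total_area = 320, total_volume = 390)
  specB <- profile_spec(
    data.frame(center = c(0.000, 0.0130),
               width = c(0.0040, 0.0016),
               share = c(0.90, 0.10)),
    total_area = 300, total_volume = 360)
  list(
    drug_basic_A = compound("drug_basic_A", generate_profile(specA),
                            molar_volume = 290, melting_point = 120,
                            state_flag = "solid", molecular_weight = 368),
    drug_basic_B = compound("drug_basic_B", generate_profile(specB),
                            molar_volume = 255, melting_point = 142,
                            state_flag = "solid", molecular_weight = 310))
}

#' Build a coformer compound from a library row
#'
#' Realises the sigma-profile implied by a candidate's hydrogen-bond
#' character and size metadata.
#'
#' @param row one row of a generated candidate library.
#' @return a [compound()].
#' @export
candidate_compound <- function(row) {
  recipe <- .hb_peak_recipes()[[row$hb_character]]
  if (is.null(recipe)) {
    stop("unknown hb_character '", row$hb_character, "'", call. = FALSE)
  }
  prof <- generate_profile(profile_spec(
    recipe,
    total_area = row$cavity_area_A2,
    total_volume = row$cavity_volume_A3))
  compound(row$name, prof,
           molar_volume = row$molar_volume_cm3mol,
           melting_point = if (row$state_flag %in% c("solid", "decomposes"))
             row$melting_point_C else NA_real_,
           state_flag = row$state_flag,
           molecular_weight = row$mw)
}

#' Generate a synthetic candidate coformer library with ground truth
#'
#' Emits `n` candidates spanning the design axes of the funnel: total
#' solubility parameters inside and outside a target ORSP, melting
#' behaviour below/within/above the process window (including liquid and
#' waxy additives), and hydrogen-bond characters complementary or
#' clashing with the acceptor-type fixture drugs. Each candidate carries
#' a designed excess enthalpy (its intended position on the map) and the
#' ground-truth table records ORSP membership, window position,
#' qualitative excess-enthalpy sign and the promise class implied by the
#' design.
#'
#' @param n number of candidates (default 34).
#' @param seed integer seed; the library is reproducible byte-for-byte.
#' @param orsp_range target ORSP `c(lower, upper)`, MPa^0.5.
#' @param window_range process window `c(t_low, t_high)`, degrees C.
#' @param threshold promising cutoff on the designed excess enthalpy,
#'   kcal/mol.
#' @return list with data frames `candidates` (the library CSV layout:
#'   `name`, `delta_total_MPa05`, `melting_point_C`, `state_flag`, `mw`,
#'   `molar_volume_cm3mol`, `cavity_area_A2`, `cavity_volume_A3`,
#'   `hb_character`, `designed_hex`) and `truth` (`name`, `orsp_member`,
#'   `window_position`, `hex_sign`, `truth_class`).
#' @export
#' @examples
#' lib <- generate_candidate_library(n = 10, seed = 7)
#' table(lib$truth$truth_class)
generate_candidate_library <- function(n = 34, seed = 1,
                                       orsp_range = c(14, 29),
                                       window_range = c(100, 225),
                                       threshold = -2) {
  stopifnot(n >= 1, diff(orsp_range) > 0, diff(window_range) > 0)
  with_seed(seed, {
    # cycle through design cells so every axis combination is covered
    orsp_cell <- rep_len(c("inside", "inside", "inside", "below", "above"), n)
    win_cell <- rep_len(c("inside", "inside", "below", "inside", "above",
                          "liquid", "inside", "waxy", "inside", "above"), n)
    hb_cell <- rep_len(c("complement_strong", "complement_weak", "clash",
                         "neutral", "complement_strong", "clash"), n)
    lo <- orsp_range[1L]; hi <- orsp_range[2L]
    delta <- ifelse(orsp_cell == "inside",
                    stats::runif(n, lo + 0.3, hi - 0.3),
                    ifelse(orsp_cell == "below",
                           stats::runif(n, max(5, lo - 6), lo - 0.5),
                           stats::runif(n, hi + 0.5, hi + 6)))
    state <- ifelse(win_cell == "liquid", "liquid",
                    ifelse(win_cell == "waxy", "waxy", "solid"))
    # a few high-melters decompose rather than melt
    decomp <- win_cell == "above" & stats::runif(n) < 0.4
    state[decomp] <- "decomposes"
    tm <- ifelse(win_cell == "below",
                 stats::runif(n, 40, window_range[1L] - 4),
                 ifelse(win_cell == "inside",
                        stats::runif(n, window_range[1L] + 4,
                                     window_range[2L] - 4),
                        stats::runif(n, window_range[2L] + 5,
                                     window_range[2L] + 110)))
    tm[state %in% c("liquid", "waxy")] <- NA_real_
    hex <- numeric(n)
    hex[hb_cell == "complement_strong"] <-
      stats::runif(sum(hb_cell == "complement_strong"), -5.5, threshold - 0.5)
    hex[hb_cell == "complement_weak"] <-
      stats::runif(sum(hb_cell == "complement_weak"), threshold + 0.4, -0.3)
    hex[hb_cell == "clash"] <- stats::runif(sum(hb_cell == "clash"), 0.2, 2.5)
    hex[hb_cell == "neutral"] <-
      stats::runif(sum(hb_cell == "neutral"), -0.15, 0.15)
    area <- round(stats::runif(n, 120, 260), 2)
    candidates <- data.frame(
      name = sprintf("cand_%02d_%s", seq_len(n), hb_cell),
      delta_total_MPa05 = round(delta, 2),
      melting_point_C = round(tm, 1),
      state_flag = state,
      mw = round(stats::runif(n, 90, 260), 1),
      molar_volume_cm3mol = round(stats::runif(n, 60, 180), 1),
      cavity_area_A2 = area,
      cavity_volume_A3 = round(area * stats::runif(n, 1.05, 1.25), 2),
      hb_character = hb_cell,
      designed_hex = round(hex, 3),
      stringsAsFactors = FALSE)
    truth_class <- vapply(seq_len(n), function(i) {
      if (state[i] %in% c("liquid", "waxy") ||
          (is.finite(tm[i]) && tm[i] < window_range[1L]))
        return("excluded_low_tm")
      if (is.finite(tm[i]) && tm[i] > window_range[2L])
        return("excluded_high_tm")
      if (candidates$designed_hex[i] <= threshold) "promising"
      else if (candidates$designed_hex[i] < 0) "possible"
      else "unfavorable"
    }, character(1L))
    truth <- data.frame(
      name = candidates$name,
      orsp_member = orsp_cell == "inside",
      window_position = win_cell,
      hex_sign = ifelse(grepl("^complement", hb_cell), "negative",
                        ifelse(hb_cell == "clash", "positive", "neutral")),
      truth_class = truth_class,
      stringsAsFactors = FALSE)
    list(candidates = candidates, truth = truth)
  })
}

#' Write a self-contained fixture directory
#'
#' Materialises a generated library on disk: `profiles/` with one
#' tabulated sigma-profile per candidate and per fixture drug,
#' `candidates.csv`, `solvents.csv` (the bundled reference solvent
#' table), `truth.csv`, and `params.txt` with the engine constants.
#'
#' @param dir destination directory (created if needed).
#' @param n,seed,orsp_range,window_range,threshold passed to
#'   [generate_candidate_library()].
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(dir, n = 34, seed = 1,
                              orsp_range = c(14, 29),
                              window_range = c(100, 225), threshold = -2) {
  lib <- generate_candidate_library(n, seed, orsp_range, window_range,
                                    threshold)
  dir.create(file.path(dir, "profiles"), recursive = TRUE,
             showWarnings = FALSE)
  cand <- lib$candidates
  cand$profile_path <- file.path("profiles", paste0(cand$name, ".sig"))
  for (i in seq_len(nrow(cand))) {
    cc <- candidate_compound(cand[i, ])
    write_sigma_profile(cc$profile, file.path(dir, cand$profile_path[i]))
  }
  drugs <- fixture_drugs()
  for (d in drugs) {
    write_sigma_profile(d$profile,
                        file.path(dir, "profiles", paste0(d$name, ".sig")))
  }
  utils::write.csv(cand, file.path(dir, "candidates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(lib$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  solv <- reference_solvents()
  utils::write.csv(solv, file.path(dir, "solvents.csv"),
                   row.names = FALSE, quote = FALSE)
  write_cosmo_parameters(cosmo_parameters(), file.path(dir, "params.txt"))
  invisible(dir)
}

#' Read a candidate library CSV
#'
#' @param path CSV with at least `name` and `delta_total_MPa05` columns
#'   (see [generate_candidate_library()] for the full layout).
#' @return data frame.
#' @export
read_candidate_library <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "delta_total_MPa05") %in% names(df))) {
    stop("candidate library needs columns `name` and `delta_total_MPa05`",
         call. = FALSE)
  }
  df
}
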