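# End-to-end screening: ORSP preselection -> excess enthalpy per
# surviving candidate -> process-window assessment -> ranking -> report.

#' Configuration of a screening run
#'
#' Bundles every knob of the funnel with its default. All defaults are
#' echoed verbatim in the report for auditability.
#'
#' @param drug a [compound()] with a sigma-profile (the engine needs it
#'   for excess enthalpies).
#' @param drug_delta total solubility parameter of the drug, MPa^0.5.
#' @param polymer_name polymer label.
#' @param polymer_delta total solubility parameter of the polymer,
#'   MPa^0.5.
#' @param width_rule `"broad"` (half-width 10, the default screening
#'   rule) or `"restrictive"` (half-width 7).
#' @param window a [process_window()].
#' @param threshold promising cutoff on excess enthalpy, kcal/mol.
#' @param ratio drug:coformer mole fractions for the enthalpy state.
#' @param temperature_C enthalpy evaluation temperature, degrees C.
#' @param params engine [cosmo_parameters()].
#' @param seed integer seed recorded in the report.
#' @return object of class `screen_config`.
#' @export
screen_config <- function(drug, drug_delta, polymer_name = "HPC",
                          polymer_delta = 24,
                          width_rule = c("broad", "restrictive"),
                          window = process_window(),
                          threshold = -2,
                          ratio = c(0.5, 0.5),
                          temperature_C = 25,
                          params = cosmo_parameters(),
                          seed = 1L) {
  stopifnot(inherits(drug, "compound"), is.numeric(drug_delta),
            is.numeric(polymer_delta), inherits(window, "process_window"),
            celsius_to_kelvin(temperature_C) > 0)
  width_rule <- match.arg(width_rule)
  structure(
    list(drug = drug, drug_delta = drug_delta,
         polymer_name = polymer_name, polymer_delta = polymer_delta,
         width_rule = width_rule,
         width = if (width_rule == "broad") 10 else 7,
         window = window, threshold = threshold, ratio = ratio,
         temperature_C = temperature_C, params = params,
         seed = as.integer(seed)),
    class = "screen_config")
}

#' Run the full coformer screen
#'
#' Executes the funnel: ORSP filter on total solubility parameters,
#' excess enthalpy (equimolar, at the configured temperature) for every
#' surviving candidate that carries a sigma-profile, process-window
#' assessment, and ranking. A candidate failing any stage is marked with
#' its reason and the run continues; a candidate without a profile passes
#' the ORSP stage but is reported `hex_unavailable` and is never
#' classified promising.
#'
#' @param config a [screen_config()].
#' @param candidates candidate library data frame (see
#'   [generate_candidate_library()] / [read_candidate_library()]). If it
#'   carries `hb_character` + cavity columns, profiles are realised with
#'   [candidate_compound()]; if it carries `profile_path`, profiles are
#'   read relative to `base_dir`.
#' @param base_dir directory against which `profile_path` is resolved.
#' @return object of class `coformer_screen` with the per-candidate
#'   results table, the ORSP used, and the configuration.
#' @export
run_screen <- function(config, candidates, base_dir = ".") {
  stopifnot(inherits(config, "screen_config"), is.data.frame(candidates))
  iv <- orsp(config$drug_delta, config$polymer_delta, config$width,
             drug_name = config$drug$name,
             polymer_name = config$polymer_name)
  n <- nrow(candidates)
  res <- data.frame(
    name = if (n) candidates$name else character(0),
    delta_total_MPa05 = if (n) candidates$delta_total_MPa05 else numeric(0),
    fate = character(n),
    h_ex = rep(NA_real_, n),
    melting_point_C = if ("melting_point_C" %in% names(candidates) && n)
      candidates$melting_point_C else rep(NA_real_, n),
    state_flag = if ("state_flag" %in% names(candidates) && n)
      candidates$state_flag else rep(NA_character_, n),
    promise_class = rep(NA_character_, n),
    rank = rep(NA_integer_, n),
    stringsAsFactors = FALSE)
  part <- filter_candidates(candidates, iv)
  inside <- part$inside$name
  res$fate[res$name %in% part$outside$name] <- "outside_orsp"
  res$fate[res$name %in% part$unscored$name] <- "unscored_no_delta"
  T_K <- celsius_to_kelvin(config$temperature_C)
  for (nm in inside) {
    i <- which(res$name == nm)
    row <- candidates[candidates$name == nm, , drop = FALSE]
    comp <- tryCatch(.realise_candidate(row, base_dir),
                     error = function(e) e)
    if (inherits(comp, "error")) {
      res$fate[i] <- if (grepl("no sigma-profile source", conditionMessage(comp)))
        "hex_unavailable" else paste0("failed: ", conditionMessage(comp))
      next
    }
    hx <- tryCatch(
      excess_enthalpy(config$drug, comp, config$ratio, T_K, config$params),
      error = function(e) e)
    if (inherits(hx, "error")) {
      res$fate[i] <- paste0("failed: ", conditionMessage(hx))
      next
    }
    res$h_ex[i] <- hx
    res$fate[i] <- "assessed"
  }
  ok <- res$fate == "assessed"
  if (any(ok)) {
    ass <- assess_candidates(
      data.frame(name = res$name[ok], h_ex = res$h_ex[ok],
                 melting_point_C = res$melting_point_C[ok],
                 state_flag = res$state_flag[ok],
                 stringsAsFactors = FALSE),
      window = config$window, threshold = config$threshold)
    ranked <- rank_candidates(ass)
    m <- match(res$name, ranked$name)
    res$promise_class <- ranked$promise_class[m]
    res$rank <- ranked$rank[m]
  }
  o <- order(!ok, res$rank, res$name, na.last = TRUE)
  res <- res[o, , drop = FALSE]
  rownames(res) <- NULL
  structure(list(results = res, orsp = iv, config = config,
                 n_candidates = n),
            class = "coformer_screen")
}

# Resolve a candidate row to a compound with a sigma-profile.
.realise_candidate <- function(row, base_dir) {
  if ("hb_character" %in% names(row) && !is.na(row$hb_character) &&
      nzchar(row$hb_character)) {
    return(candidate_compound(row))
  }
  if ("profile_path" %in% names(row) && !is.na(row$profile_path) &&
      nzchar(row$profile_path)) {
    prof <- read_sigma_profile(file.path(base_dir, row$profile_path))
    return(compound(row$name, prof,
                    molar_volume = row$molar_volume_cm3mol,
                    melting_point = if (row$state_flag %in%
                                        c("solid", "decomposes"))
                      row$melting_point_C else NA_real_,
                    state_flag = row$state_flag,
                    molecular_weight = row$mw))
  }
  stop("no sigma-profile source for candidate '", row$name, "'",
       call. = FALSE)
}

#' @export
print.coformer_screen <- function(x, ...) {
  cat("coformer screen: ", x$n_candidates, " candidates for drug '",
      x$config$drug$name, "' in polymer ", x$config$polymer_name, "\n",
      sep = "")
  print(x$orsp)
  tab <- table(factor(x$results$fate))
  cat("  fates: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  top <- x$results[!is.na(x$results$rank) & x$results$rank <= 5, ,
                   drop = FALSE]
  if (nrow(top)) {
    cat("  top ranked:\n")
    print(top[, c("name", "h_ex", "melting_point_C", "promise_class",
                  "rank")], row.names = FALSE)
  } else {
    cat("  nothing ranked (no candidate survived to assessment)\n")
  }
  invisible(x)
}

#' @export
summary.coformer_screen <- function(object, ...) {
  res <- object$results
  structure(
    list(screen = object,
         class_counts = table(factor(res$promise_class,
                                     levels = .PROMISE_CLASSES)),
         n_promising = sum(res$promise_class == "promising", na.rm = TRUE),
         n_failed = sum(grepl("^failed", res$fate))),
    class = "summary.coformer_screen")
}

#' @export
print.summary.coformer_screen <- function(x, ...) {
  print(x$screen)
  cat("  promise classes among assessed candidates:\n")
  print(x$class_counts)
  if (x$n_failed) cat("  stage failures:", x$n_failed, "\n")
  invisible(x)
}

#' Plot a screening result as the coformer map
#'
#' @param x a [run_screen()] result.
#' @param ... unused.
#' @export
plot.coformer_screen <- function(x, ...) {
  res <- x$results[!is.na(x$results$promise_class), , drop = FALSE]
  plot_coformer_map(
    data.frame(name = res$name, h_ex = res$h_ex,
               melting_point = res$melting_point_C,
               promise_class = res$promise_class,
               stringsAsFactors = FALSE),
    window = x$config$window, threshold = x$config$threshold)
}

#' @export
as.data.frame.coformer_screen <- function(x, ...) x$results

#' Write a screening report bundle
#'
#' Emits `results.csv` (machine-readable, deterministic for a fixed
#' configuration and seed), `map.csv` for the assessed candidates, and
#' `report.txt`, a human-readable account listing every candidate's fate
#' and every default used, with a provenance block (package version,
#' parameter-set version and checksum, seed).
#'
#' @param screen a [run_screen()] result.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(screen, dir) {
  stopifnot(inherits(screen, "coformer_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- screen$results
  out <- res
  out$h_ex <- ifelse(is.na(out$h_ex), "", sprintf("%.6f", out$h_ex))
  utils::write.csv(out, file.path(dir, "results.csv"),
                   row.names = FALSE, quote = FALSE)
  ass <- res[res$fate == "assessed", , drop = FALSE]
  export_map(
    data.frame(name = ass$name, h_ex = ass$h_ex,
               melting_point = ass$melting_point_C,
               promise_class = ass$promise_class,
               stringsAsFactors = FALSE),
    file.path(dir, "map.csv"), window = screen$config$window)
  cfg <- screen$config
  ptmp <- file.path(dir, "params.txt")
  write_cosmo_parameters(cfg$params, ptmp)
  lines <- c(
    "coformer screening report",
    "=========================",
    "",
    sprintf("drug: %s (delta_total %g MPa^0.5)", cfg$drug$name,
            cfg$drug_delta),
    sprintf("polymer: %s (delta_total %g MPa^0.5)", cfg$polymer_name,
            cfg$polymer_delta),
    sprintf("ORSP rule: %s (half-width %g MPa^0.5)", cfg$width_rule,
            cfg$width),
    if (screen$orsp$empty) "ORSP: empty" else
      sprintf("ORSP: %g - %g MPa^0.5", screen$orsp$lower, screen$orsp$upper),
    sprintf("process window: [%g, %g] C (%s)", cfg$window$t_low,
            cfg$window$t_high, cfg$window$polymer_name),
    sprintf("promising threshold: %g kcal/mol", cfg$threshold),
    sprintf("enthalpy state: mole fractions %s at %g C",
            paste(cfg$ratio, collapse = ":"), cfg$temperature_C),
    "",
    "provenance:",
    sprintf("  package version: %s",
            as.character(utils::packageVersion("cosmoform"))),
    sprintf("  engine parameters: %s (md5 %s)", cfg$params$version,
            parameter_checksum(ptmp)),
    sprintf("  seed: %d", cfg$seed),
    "",
    sprintf("candidates screened: %d", screen$n_candidates),
    if (screen$n_candidates == 0L)
      "warning: nothing screened (empty candidate set)",
    "",
    "per-candidate fates:",
    sprintf("  %-28s %-18s %-10s %s", res$name, res$fate,
            ifelse(is.na(res$h_ex), "-", sprintf("%.3f", res$h_ex)),
            ifelse(is.na(res$promise_class), "-", res$promise_class)))
  writeLines(lines[!vapply(lines, is.null, logical(1L))],
             file.path(dir, "report.txt"))
  invisible(dir)
}
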