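# Mapping candidates on the (melting point, H_ex) plane against the hot
# melt extrusion process window, classifying and ranking them.
#
# Rationale of the rules: liquid or waxy additives are hard to dose into
# an extruder barrel; additives melting above the window would stay as
# suspended particles with only surface contact to the drug; among the
# processable ones, more negative excess enthalpy signals stronger
# specific drug-coformer interaction and better amorphization prospects.

.PROMISE_CLASSES <- c("promising", "possible", "unfavorable",
                      "excluded_low_tm", "excluded_high_tm")

#' Hot melt extrusion process temperature window
#'
#' @param t_low lower limit, degrees C (polymer processability floor,
#'   e.g. glass-transition-informed).
#' @param t_high upper limit, degrees C (conservatively below polymer
#'   decomposition).
#' @param polymer_name label.
#' @return object of class `process_window` (closed at both bounds).
#' @export
#' @examples
#' process_window() # the HPC default, 100-225 C
process_window <- function(t_low = 100, t_high = 225, polymer_name = "HPC") {
  stopifnot(is.numeric(t_low), is.numeric(t_high))
  if (!(t_low < t_high)) {
    stop("`t_low` must be below `t_high`", call. = FALSE)
  }
  structure(list(t_low = t_low, t_high = t_high, polymer_name = polymer_name),
            class = "process_window")
}

#' @export
print.process_window <- function(x, ...) {
  cat(sprintf("process window for %s: [%g, %g] C (closed bounds)\n",
              x$polymer_name, x$t_low, x$t_high))
  invisible(x)
}

#' Registered polymer process windows
#'
#' Small registry of extrusion windows by polymer; currently
#' hydroxypropyl cellulose. Additional polymers can be addressed by
#' constructing a [process_window()] directly.
#'
#' @param polymer polymer name.
#' @return a [process_window()].
#' @export
polymer_window <- function(polymer = "HPC") {
  registry <- list(HPC = c(100, 225))
  if (!polymer %in% names(registry)) {
    stop("no registered process window for polymer '", polymer,
         "'; construct one with process_window()", call. = FALSE)
  }
  w <- registry[[polymer]]
  process_window(w[1L], w[2L], polymer_name = polymer)
}

#' Assess one coformer candidate against the process window
#'
#' Decision logic of the melting-point versus excess-enthalpy map:
#' \itemize{
#'   \item `excluded_low_tm` — liquid or waxy state, or melting point
#'     below the window;
#'   \item `excluded_high_tm` — melting (or decomposition) point above
#'     the window;
#'   \item otherwise `promising` if `h_ex <= threshold`, `possible` if
#'     `threshold < h_ex < 0`, `unfavorable` if `h_ex >= 0`.
#' }
#' Window bounds are closed; compounds that decompose are placed at their
#' decomposition temperature on the melting-point axis.
#'
#' @param name candidate identifier.
#' @param h_ex excess enthalpy at the screening state (equimolar, 25 C),
#'   kcal/mol.
#' @param melting_point melting or decomposition temperature, degrees C;
#'   may be `NA` for liquid/waxy candidates.
#' @param state_flag one of `"solid"`, `"liquid"`, `"waxy"`,
#'   `"decomposes"`.
#' @param window a [process_window()].
#' @param threshold promising-class cutoff on `h_ex`, kcal/mol
#'   (default -2).
#' @return one-row data frame: `name`, `h_ex`, `melting_point`,
#'   `state_flag`, `in_window`, `promise_class`.
#' @export
#' @examples
#' assess_coformer("malic_like", -3, 130, "solid", process_window())
assess_coformer <- function(name, h_ex, melting_point, state_flag,
                            window = process_window(), threshold = -2) {
  stopifnot(inherits(window, "process_window"))
  state_flag <- match.arg(state_flag, .STATE_FLAGS)
  has_tm <- length(melting_point) == 1L && is.finite(melting_point)
  if (!has_tm && !state_flag %in% c("liquid", "waxy")) {
    stop("candidate '", name,
         "' has neither a melting point nor a liquid/waxy state flag",
         call. = FALSE)
  }
  if (!is.finite(h_ex)) {
    stop("candidate '", name, "' has no excess enthalpy; assess() needs h_ex",
         call. = FALSE)
  }
  if (state_flag %in% c("liquid", "waxy") ||
      (has_tm && melting_point < window$t_low)) {
    cls <- "excluded_low_tm"; in_window <- FALSE
  } else if (melting_point > window$t_high) {
    cls <- "excluded_high_tm"; in_window <- FALSE
  } else {
    in_window <- TRUE
    cls <- if (h_ex <= threshold) "promising"
           else if (h_ex < 0) "possible"
           else "unfavorable"
  }
  out <- data.frame(name = name, h_ex = h_ex,
                    melting_point = if (has_tm) melting_point else NA_real_,
                    state_flag = state_flag,
                    in_window = in_window, promise_class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "context") <- list(t_low = window$t_low, t_high = window$t_high,
                               threshold = threshold)
  out
}

#' Assess a table of candidates
#'
#' Row-wise [assess_coformer()] over a candidate table with `h_ex`
#' values.
#'
#' @param candidates data frame with columns `name`, `h_ex`,
#'   `melting_point_C`, `state_flag`.
#' @param window a [process_window()].
#' @param threshold promising cutoff, kcal/mol.
#' @return data frame of assessments (one row per candidate) carrying the
#'   shared context as an attribute.
#' @export
assess_candidates <- function(candidates, window = process_window(),
                              threshold = -2) {
  if (nrow(candidates) == 0L) {
    out <- data.frame(name = character(0), h_ex = numeric(0),
                      melting_point = numeric(0), state_flag = character(0),
                      in_window = logical(0), promise_class = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "context") <- list(t_low = window$t_low, t_high = window$t_high,
                                 threshold = threshold)
    return(out)
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    assess_coformer(candidates$name[i], candidates$h_ex[i],
                    candidates$melting_point_C[i], candidates$state_flag[i],
                    window, threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "context") <- list(t_low = window$t_low, t_high = window$t_high,
                               threshold = threshold)
  out
}

#' Rank assessed candidates
#'
#' Non-excluded candidates are ordered by excess enthalpy ascending (most
#' negative, i.e. most strongly interacting, first); ties broken by lower
#' melting point, then by name. Excluded candidates are appended
#' unranked. All assessments must come from one window/threshold
#' context.
#'
#' @param assessments one or more assessment rows (from
#'   [assess_coformer()]/[assess_candidates()], rbind-compatible).
#' @return the assessments with a `rank` column (a permutation of
#'   `1..n` over non-excluded candidates, `NA` for excluded ones),
#'   ordered ranked-first.
#' @export
rank_candidates <- function(assessments) {
  if (is.list(assessments) && !is.data.frame(assessments)) {
    ctxs <- lapply(assessments, attr, "context")
    if (length(unique(vapply(ctxs, function(x)
      paste(unlist(x), collapse = "|"), character(1L)))) > 1L) {
      stop("assessments come from different window/threshold contexts",
           call. = FALSE)
    }
    ctx <- ctxs[[1L]]
    assessments <- do.call(rbind, assessments)
    attr(assessments, "context") <- ctx
  }
  stopifnot(is.data.frame(assessments))
  excluded <- grepl("^excluded", assessments$promise_class)
  ranked <- assessments[!excluded, , drop = FALSE]
  rest <- assessments[excluded, , drop = FALSE]
  if (nrow(ranked)) {
    o <- order(ranked$h_ex, ranked$melting_point, ranked$name)
    ranked <- ranked[o, , drop = FALSE]
    ranked$rank <- seq_len(nrow(ranked))
  } else {
    ranked$rank <- integer(0)
  }
  if (nrow(rest)) rest$rank <- NA_integer_ else rest$rank <- integer(0)
  out <- rbind(ranked, rest)
  rownames(out) <- NULL
  attr(out, "context") <- attr(assessments, "context")
  out
}

#' Export the coformer map
#'
#' Writes the map dataset as CSV (`name`, `melting_point_C`,
#' `h_ex_kcalmol`, `promise_class`) and optionally draws the
#' melting-point versus excess-enthalpy scatter with the process window
#' as two dashed vertical limits.
#'
#' @param assessments assessment table (see [assess_candidates()]).
#' @param path CSV destination.
#' @param window a [process_window()] for the figure limits.
#' @param plot_file optional figure destination (`.pdf` or `.png`); if
#'   `NULL`, no figure is produced unless `draw = TRUE`.
#' @param draw draw on the active graphics device instead of a file.
#' @return `path`, invisibly.
#' @export
export_map <- function(assessments, path, window = process_window(),
                       plot_file = NULL, draw = FALSE) {
  df <- data.frame(name = assessments$name,
                   melting_point_C = assessments$melting_point,
                   h_ex_kcalmol = assessments$h_ex,
                   promise_class = assessments$promise_class,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(plot_file) || draw) {
    if (!is.null(plot_file)) {
      ext <- tolower(tools::file_ext(plot_file))
      if (ext == "png") grDevices::png(plot_file, width = 900, height = 700)
      else grDevices::pdf(plot_file, width = 8, height = 6)
      on.exit(grDevices::dev.off())
    }
    plot_coformer_map(assessments, window)
  }
  invisible(path)
}

#' Draw the coformer map
#'
#' @param assessments assessment table.
#' @param window a [process_window()].
#' @param threshold promising cutoff drawn as a horizontal guide.
#' @export
plot_coformer_map <- function(assessments, window = process_window(),
                              threshold = -2) {
  cls <- factor(assessments$promise_class, levels = .PROMISE_CLASSES)
  pal <- c(promising = "#1f78b4", possible = "#33a02c",
           unfavorable = "#e31a1c", excluded_low_tm = "grey60",
           excluded_high_tm = "grey30")
  tm <- assessments$melting_point
  hx <- assessments$h_ex
  if (!length(tm) || all(!is.finite(tm))) {
    graphics::plot(NA, xlim = c(window$t_low - 60, window$t_high + 60),
                   ylim = c(-5, 2),
                   xlab = "melting / decomposition temperature (C)",
                   ylab = "excess enthalpy H_ex (kcal/mol)")
  } else {
    graphics::plot(tm, hx, pch = 19, col = pal[as.character(cls)],
                   xlim = range(c(tm, window$t_low - 20, window$t_high + 20),
                                na.rm = TRUE),
                   xlab = "melting / decomposition temperature (C)",
                   ylab = "excess enthalpy H_ex (kcal/mol)")
    graphics::text(tm, hx, labels = assessments$name, pos = 3, cex = 0.6)
  }
  graphics::abline(v = c(window$t_low, window$t_high), lty = 2)
  graphics::abline(h = c(0, threshold), lty = 3, col = "grey50")
  graphics::legend("topright", legend = levels(cls), col = pal, pch = 19,
                   cex = 0.7, bty = "n")
  invisible(assessments)
}
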