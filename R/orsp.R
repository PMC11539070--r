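# Overlap range of solubility parameter (ORSP): the preselection stage of
# the funnel. A drug-excipient pair with total solubility parameters
# differing by more than 10 MPa^0.5 is expected immiscible; within
# 7 MPa^0.5, fully miscible. The ORSP is the intersection of the
# drug +/- w and polymer +/- w intervals, and a coformer candidate must
# fall inside it.

#' Solubility-parameter interval of one component
#'
#' The closed interval `[delta_total - width, delta_total + width]`.
#'
#' @param delta_total total (Hildebrand) solubility parameter, MPa^0.5.
#' @param width half-width in MPa^0.5; 10 is the broad (miscibility-limit)
#'   rule, 7 the restrictive (full-miscibility) rule.
#' @return numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' component_interval(19, 10) # 9..29
component_interval <- function(delta_total, width) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0) {
    stop("`width` must be a single positive number", call. = FALSE)
  }
  stopifnot(is.numeric(delta_total), length(delta_total) == 1L,
            is.finite(delta_total))
  c(lower = delta_total - width, upper = delta_total + width)
}

#' Overlap range of solubility parameter
#'
#' Intersection of the drug and polymer component intervals. The overlap
#' is empty exactly when the two totals differ by more than twice the
#' half-width. Symmetric in drug and polymer.
#'
#' @param drug_delta,polymer_delta total solubility parameters, MPa^0.5.
#' @param width interval half-width, MPa^0.5 (default: the broad rule, 10).
#' @param drug_name,polymer_name labels carried into the result.
#' @return object of class `orsp_interval` with fields `lower`, `upper`,
#'   `empty`, `width`, `width_rule`, `drug_name`, `polymer_name`.
#' @export
#' @examples
#' orsp(19, 24, 10) # 14..29
#' orsp(19, 24, 7)  # 17..26
orsp <- function(drug_delta, polymer_delta, width = 10,
                 drug_name = "drug", polymer_name = "polymer") {
  a <- component_interval(drug_delta, width)
  b <- component_interval(polymer_delta, width)
  lower <- max(a[["lower"]], b[["lower"]])
  upper <- min(a[["upper"]], b[["upper"]])
  empty <- lower > upper
  structure(
    list(lower = if (empty) NA_real_ else lower,
         upper = if (empty) NA_real_ else upper,
         empty = empty, width = width,
         width_rule = if (width == 7) "restrictive" else
                      if (width == 10) "broad" else "custom",
         drug_name = drug_name, polymer_name = polymer_name),
    class = "orsp_interval")
}

#' @export
print.orsp_interval <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("ORSP %s / %s (+/- %g MPa^0.5): empty (no overlap)\n",
                x$drug_name, x$polymer_name, x$width))
  } else {
    cat(sprintf("ORSP %s / %s (+/- %g MPa^0.5, %s rule): %g - %g MPa^0.5\n",
                x$drug_name, x$polymer_name, x$width, x$width_rule,
                x$lower, x$upper))
  }
  invisible(x)
}

#' Partition coformer candidates by ORSP membership
#'
#' Bounds are inclusive: a candidate exactly on a bound is inside. Every
#' candidate lands in exactly one of three partitions; candidates without
#' a total solubility parameter are reported as `unscored`, never
#' silently dropped.
#'
#' @param candidates data frame with at least `name` and
#'   `delta_total_MPa05` columns (the candidate-library CSV layout).
#' @param interval an [orsp()] result.
#' @return list with data frames `inside`, `outside` and `unscored`; the
#'   first two carry a `margin` column, the distance to the nearest bound
#'   (inside: distance to exiting; outside: distance to entering).
#' @export
filter_candidates <- function(candidates, interval) {
  stopifnot(inherits(interval, "orsp_interval"), is.data.frame(candidates))
  if (!all(c("name", "delta_total_MPa05") %in% names(candidates))) {
    stop("candidate table needs columns `name` and `delta_total_MPa05`",
         call. = FALSE)
  }
  d <- candidates$delta_total_MPa05
  unscored_idx <- !is.finite(d)
  if (interval$empty) {
    inside_idx <- rep(FALSE, nrow(candidates))
  } else {
    inside_idx <- !unscored_idx & d >= interval$lower & d <= interval$upper
  }
  outside_idx <- !unscored_idx & !inside_idx
  margin_of <- function(idx) {
    if (interval$empty) return(rep(NA_real_, sum(idx)))
    x <- d[idx]
    pmin(abs(x - interval$lower), abs(x - interval$upper))
  }
  inside <- candidates[inside_idx, , drop = FALSE]
  outside <- candidates[outside_idx, , drop = FALSE]
  if (nrow(inside)) inside$margin <- margin_of(inside_idx)
  if (nrow(outside)) outside$margin <- margin_of(outside_idx)
  list(inside = inside, outside = outside,
       unscored = candidates[unscored_idx, , drop = FALSE])
}
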