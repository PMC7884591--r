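#' Tidy a calibration result
#'
#' A calibration result is already tabular; `tidy()` returns it as a plain
#' tibble with the per-query score shift added.
#'
#' @param x A `dockcal_calibration` object.
#' @param ... Unused.
#' @return A tibble with one row per query compound.
#' @method tidy dockcal_calibration
#' @export
tidy.dockcal_calibration <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(shift = .data$calibrated_score - .data$original_score)
}

#' One-row summary of a calibration run
#'
#' @param x A `dockcal_calibration` object.
#' @param ... Unused.
#' @return A one-row tibble: number of queries, fallback count, mean absolute
#'   score shift among calibrated queries, and the configuration used.
#' @method glance dockcal_calibration
#' @export
glance.dockcal_calibration <- function(x, ...) {
  cfg <- attr(x, "config")
  shifted <- abs(x$calibrated_score - x$original_score)[!x$fallback]
  tibble::tibble(
    n_queries = nrow(x),
    n_fallback = sum(x$fallback),
    mean_abs_shift = if (length(shifted)) mean(shifted) else NA_real_,
    p = cfg$p,
    tc_lower = cfg$tc_lower,
    tc_upper = cfg$tc_upper %||% NA_real_
  )
}

#' Tidy a benchmark: the long per-repeat metric table
#'
#' @param x A `dockcal_benchmark` object.
#' @param ... Unused.
#' @return Tibble with columns `repeat_index`, `fingerprint`, `p`,
#'   `tc_lower`, `tc_upper`, `metric`, `phase`, `value`, `degenerate`.
#' @method tidy dockcal_benchmark
#' @export
tidy.dockcal_benchmark <- function(x, ...) {
  x$results
}

#' Aggregated benchmark summary
#'
#' @param x A `dockcal_benchmark` object.
#' @param ... Unused.
#' @return Tibble with per grid cell, metric and phase: mean over repeats,
#'   95% CI half-width, and the calibrated-minus-original delta.
#' @method glance dockcal_benchmark
#' @export
glance.dockcal_benchmark <- function(x, ...) {
  x$summary
}

#' @export
print.dockcal_calibration <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<dockcal_calibration> ", nrow(x), " query(ies), CSE = S^", cfg$p,
      ", ", sum(x$fallback), " fallback(s)\n", sep = "")
  NextMethod()
}
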