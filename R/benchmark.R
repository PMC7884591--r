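#' Specification for repeated reference/validation splits
#'
#' Describes how a compound set is resampled for benchmarking: an optional
#' Ki-stratified draw that balances the affinity distribution, followed by
#' repeated random 4:1 reference/validation splits. The four affinity strata
#' are bounded at 10 nM, 1 uM and 100 uM, with at most `per_level_cap`
#' compounds drawn per stratum. Each repeat derives its own child seed from
#' the master seed, so the whole procedure is reproducible bit for bit.
#'
#' @param ratio Reference (training) fraction of each split, default 0.8.
#' @param n_repeats Number of random splits, default 10.
#' @param seed Master RNG seed.
#' @param strat_levels_nM Increasing Ki boundaries (nM) defining the strata;
#'   default `c(10, 1000, 1e5)`.
#' @param per_level_cap Maximum compounds retained per stratum, default 300.
#' @return A `split_spec` object.
#' @export
split_spec <- function(ratio = 0.8, n_repeats = 10L, seed = 1L,
                       strat_levels_nM = c(10, 1000, 1e5),
                       per_level_cap = 300L) {
  if (ratio <= 0 || ratio >= 1) {
    abort("ratio must lie strictly between 0 and 1", class = "dockcal_config_error")
  }
  if (n_repeats < 1) abort("n_repeats must be >= 1", class = "dockcal_config_error")
  if (is.unsorted(strat_levels_nM, strictly = TRUE)) {
    abort("strat_levels_nM must be strictly increasing", class = "dockcal_config_error")
  }
  structure(
    list(ratio = ratio, n_repeats = as.integer(n_repeats),
         seed = as.integer(seed), strat_levels_nM = strat_levels_nM,
         per_level_cap = as.integer(per_level_cap)),
    class = "split_spec"
  )
}

# Lehmer-style mix: independent, reproducible child streams per repeat,
# always below 2^31.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index) %% 2147483647)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Stratified sample of compounds by affinity level
#'
#' Assigns each compound to one of the affinity strata defined by
#' `spec$strat_levels_nM` and draws at most `spec$per_level_cap` compounds per
#' stratum uniformly without replacement (all of them when a stratum is
#' smaller than the cap). Balancing the strata keeps weak and potent binders
#' both represented in the benchmark.
#'
#' @param data Data frame with a `ki_nM` column.
#' @param spec A [split_spec()].
#' @param seed RNG seed for the draw (defaults to `spec$seed`).
#' @return The sampled tibble, in original row order.
#' @export
stratified_sample <- function(data, spec = split_spec(), seed = spec$seed) {
  stopifnot(is.data.frame(data), "ki_nM" %in% names(data))
  if (nrow(data) == 0L) {
    abort("cannot sample from an empty compound set", class = "dockcal_data_error")
  }
  level <- findInterval(data$ki_nM, spec$strat_levels_nM)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(data)), level), function(idx) {
      if (length(idx) <= spec$per_level_cap) idx
      else sample(idx, spec$per_level_cap)
    }), use.names = FALSE)
  })
  tibble::as_tibble(data[sort(keep), , drop = FALSE])
}

#' Split compounds into reference and validation sets
#'
#' One random 4:1 (by default) partition; the RNG stream is derived from the
#' master seed and the repeat index, so each repeat is a fresh but
#' reproducible split.
#'
#' @param data Data frame of compounds (n >= 5).
#' @param spec A [split_spec()].
#' @param repeat_index Which repeat this split belongs to (1-based).
#' @return A list with tibbles `reference` and `validation`; together they
#'   partition `data`.
#' @export
split_reference_validation <- function(data, spec = split_spec(),
                                       repeat_index = 1L) {
  stopifnot(is.data.frame(data))
  n <- nrow(data)
  if (n < 5L) {
    abort("need at least 5 compounds to split 4:1", class = "dockcal_data_error")
  }
  n_ref <- round(spec$ratio * n)
  idx <- with_seed(child_seed(spec$seed, repeat_index), sample(n, n_ref))
  list(
    reference = tibble::as_tibble(data[sort(idx), , drop = FALSE]),
    validation = tibble::as_tibble(data[-sort(idx), , drop = FALSE])
  )
}

#' Grid of calibration settings to sweep
#'
#' Full crossing of fingerprint types, CSE exponents and Tc ranges. `NA`
#' for `tc_upper` means no upper bound (focus-library scenario).
#'
#' @param fingerprint Fingerprint types (`"FP2"`, `"FP3"`, `"FP4"`,
#'   `"MACCS"`).
#' @param p CSE exponents.
#' @param tc_lower,tc_upper Tanimoto bounds (scalars or vectors crossed with
#'   the rest).
#' @return A tibble with one row per grid cell.
#' @export
calibration_grid <- function(fingerprint = "FP2", p = 4L, tc_lower = 0,
                             tc_upper = NA_real_) {
  tidyr::expand_grid(fingerprint = fingerprint, p = as.integer(p),
                     tc_lower = tc_lower, tc_upper = tc_upper)
}

#' Run the repeated-split calibration benchmark
#'
#' The full evaluation protocol: for each repeat, the compound set is split
#' into reference and validation sets; for every grid cell the validation
#' docking scores are calibrated against the references and the scoring
#' (RMSE, MAE), ranking (R-squared, PI) and screening (AUC, EF) metrics are
#' computed before and after calibration. Per-metric means and 95% confidence
#' intervals are aggregated over the repeats, together with the
#' calibrated-minus-original deltas (dRMSE, dMAE, dR2, dPI, ...).
#'
#' Fingerprints and the full similarity matrix are computed once per
#' fingerprint type; the per-repeat work is pure indexing, so the sweep is
#' cheap even for several grid cells.
#'
#' @param compounds Tibble with columns `id`, `docking_score`, affinity
#'   (`ki_nM` or `delta_g_kcal`), and structures: either a `molecule`
#'   list-column (from [read_molecules()]) or a `smiles` column.
#' @param grid A [calibration_grid()].
#' @param spec A [split_spec()].
#' @param ef_fractions Hit fractions for the enrichment factors.
#' @param activity_cutoff_nM Active/inactive cutoff (nM) for the screening
#'   metrics.
#' @param resample_strata If `TRUE`, the stratified draw is repeated per
#'   repeat; by default only the reference/validation split is redrawn.
#' @param ci One of `"normal"` (mean ± 1.96 sd/sqrt(r)) or `"t"` (Student-t
#'   quantile).
#' @param config_defaults A [calibration_config()] supplying the parameters
#'   not swept by the grid (min references, degenerate-score epsilon).
#' @return A `dockcal_benchmark` object: list with `results` (tidy long
#'   tibble: repeat, fingerprint, p, tc_lower, tc_upper, metric, phase,
#'   value), `summary` (per cell and metric: mean, CI and delta), `spec` and
#'   `grid`. Grid cells in which every calibration fell back are marked
#'   degenerate in the summary.
#' @export
run_benchmark <- function(compounds, grid = calibration_grid(),
                          spec = split_spec(), ef_fractions = c(0.1, 0.4),
                          activity_cutoff_nM = 100, resample_strata = FALSE,
                          ci = c("normal", "t"),
                          config_defaults = calibration_config()) {
  ci <- match.arg(ci)
  stopifnot(is.data.frame(compounds), is.data.frame(grid))
  compounds <- prepare_benchmark_compounds(compounds, activity_cutoff_nM)
  if (nrow(compounds) < 5L) {
    abort("too few compounds after preparation", class = "dockcal_data_error")
  }
  have_classes <- length(unique(compounds$is_active)) == 2L

  # one similarity matrix per fingerprint type, over all compounds
  sim_by_fp <- lapply(
    setNames(nm = unique(grid$fingerprint)),
    function(fp) {
      fps <- compute_fingerprints(compounds, fp)
      tanimoto_matrix(fps, fps)
    }
  )

  results <- purrr::map_dfr(seq_len(spec$n_repeats), function(r) {
    dat <- if (resample_strata && "ki_nM" %in% names(compounds)) {
      stratified_sample(compounds, spec, seed = child_seed(spec$seed, 10000L + r))
    } else compounds
    sets <- split_reference_validation(dat, spec, r)
    val <- sets$validation
    ref <- sets$reference
    before <- metrics_long(val$docking_score, val, ef_fractions, have_classes)
    purrr::pmap_dfr(grid, function(fingerprint, p, tc_lower, tc_upper) {
      cfg <- calibration_config(
        p = p, tc_lower = tc_lower,
        tc_upper = if (is.na(tc_upper)) NULL else tc_upper,
        min_references = config_defaults$min_references,
        degenerate_score_epsilon = config_defaults$degenerate_score_epsilon
      )
      s <- sim_by_fp[[fingerprint]][val$id, ref$id, drop = FALSE]
      cal <- suppressMessages(calibrate_scores(val, ref, cfg, similarities = s))
      after <- metrics_long(cal$calibrated_score, val, ef_fractions, have_classes)
      dplyr::bind_rows(
        dplyr::mutate(before, phase = "original"),
        dplyr::mutate(after, phase = "calibrated",
                      degenerate = all(cal$fallback))
      ) |>
        dplyr::mutate(repeat_index = r, fingerprint = fingerprint, p = p,
                      tc_lower = tc_lower, tc_upper = tc_upper)
    })
  })
  results <- results |>
    dplyr::mutate(degenerate = dplyr::coalesce(.data$degenerate, FALSE)) |>
    dplyr::select("repeat_index", "fingerprint", "p", "tc_lower", "tc_upper",
                  "metric", "phase", "value", "degenerate")

  summary <- summarise_benchmark(results, spec$n_repeats, ci)
  structure(list(results = results, summary = summary, spec = spec,
                 grid = grid, ci = ci),
            class = "dockcal_benchmark")
}

prepare_benchmark_compounds <- function(compounds, activity_cutoff_nM) {
  stopifnot(all(c("id", "docking_score") %in% names(compounds)))
  compounds <- tibble::as_tibble(compounds)
  compounds$id <- as.character(compounds$id)
  if (!"delta_g_kcal" %in% names(compounds)) {
    if (!"ki_nM" %in% names(compounds)) {
      abort("compounds need ki_nM or delta_g_kcal", class = "dockcal_data_error")
    }
    compounds$delta_g_kcal <- ki_to_delta_g(compounds$ki_nM)
  }
  if (!"is_active" %in% names(compounds)) {
    ki <- if ("ki_nM" %in% names(compounds)) compounds$ki_nM
          else delta_g_to_ki(compounds$delta_g_kcal)
    compounds$is_active <- label_activity(ki, activity_cutoff_nM)
  }
  if (!"molecule" %in% names(compounds)) {
    if (!"smiles" %in% names(compounds)) {
      abort("compounds need a molecule or smiles column", class = "dockcal_data_error")
    }
    parsed <- parse_smiles(compounds$smiles, compounds$id)
    if (length(parsed$ok) < nrow(compounds)) {
      warn(paste0("dropping ", nrow(compounds) - length(parsed$ok),
                  " unparseable structure(s)"))
    }
    compounds <- compounds[parsed$ok, , drop = FALSE]
    compounds$molecule <- parsed$mols
  }
  compounds
}

metrics_long <- function(predicted, val, ef_fractions, have_classes) {
  # a split may leave the validation set single-class; screening metrics are
  # then undefined for that repeat and reported NA
  use_labels <- have_classes && length(unique(val$is_active)) == 2L
  d <- tibble::tibble(p = predicted, e = val$delta_g_kcal, a = val$is_active)
  m <- if (use_labels) {
    score_metrics(d, p, e, active = a, ef_fractions = ef_fractions)
  } else {
    score_metrics(d, p, e, ef_fractions = ef_fractions)
  }
  m |>
    dplyr::select(-"n") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "metric",
                        values_to = "value")
}

summarise_benchmark <- function(results, n_repeats, ci) {
  half_width <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2L) return(NA_real_)
    q <- if (ci == "t") qt(0.975, length(v) - 1L) else qnorm(0.975)
    q * sd(v) / sqrt(length(v))
  }
  wide <- results |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      ci95 = half_width(.data$value),
      degenerate = any(.data$degenerate),
      .by = c("fingerprint", "p", "tc_lower", "tc_upper", "metric", "phase")
    )
  deltas <- wide |>
    dplyr::select(-"ci95", -"degenerate") |>
    tidyr::pivot_wider(names_from = "phase", values_from = "mean") |>
    dplyr::mutate(delta = .data$calibrated - .data$original)
  dplyr::left_join(
    wide, dplyr::select(deltas, -"calibrated", -"original"),
    by = c("fingerprint", "p", "tc_lower", "tc_upper", "metric")
  )
}

#' @export
print.dockcal_benchmark <- function(x, ...) {
  cat("<dockcal_benchmark> ", x$spec$n_repeats, " repeats, ",
      nrow(x$grid), " grid cell(s)\n", sep = "")
  print(glance(x), ...)
  invisible(x)
}
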