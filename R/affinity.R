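#' Convert an inhibition constant to binding free energy
#'
#' Converts Ki or Kd (nanomolar) to the binding free energy
#' \eqn{\Delta G = RT \ln K_i} with the constant in molar units, R = 8.314
#' J mol\eqn{^{-1}} K\eqn{^{-1}} and T = 298.15 K, reported in kcal/mol.
#' Any sub-molar constant therefore maps to a negative energy (a 100 nM binder
#' is about \eqn{-9.55} kcal/mol), matching the docking-score sign convention
#' in which more negative means stronger binding.
#'
#' @param ki_nM Positive Ki/Kd values in nM. Vectorised.
#' @return Binding free energies in kcal/mol.
#' @examples
#' ki_to_delta_g(100)    # ~ -9.55
#' ki_to_delta_g(1e9)    # 1 M -> 0
#' @export
ki_to_delta_g <- function(ki_nM) {
  if (any(!is.finite(ki_nM)) || any(ki_nM <= 0)) {
    abort("Ki/Kd values must be positive and finite (nM)",
          class = "dockcal_data_error")
  }
  RT_KCAL * log(ki_nM * 1e-9)
}

#' Inverse of [ki_to_delta_g()]: free energy (kcal/mol) back to Ki in nM
#' @param delta_g_kcal Binding free energies in kcal/mol.
#' @return Ki/Kd values in nM.
#' @export
delta_g_to_ki <- function(delta_g_kcal) {
  exp(delta_g_kcal / RT_KCAL) * 1e9
}

#' Average replicate Ki measurements
#'
#' When a compound carries several Ki values from different assays, the
#' arithmetic mean of the Ki values (on the nM scale, not of pKi) is used as
#' the compound's affinity.
#'
#' @param values_nM Non-empty vector of positive Ki/Kd values in nM.
#' @return The mean Ki in nM.
#' @export
aggregate_ki <- function(values_nM) {
  if (length(values_nM) == 0L) {
    abort("cannot aggregate an empty set of Ki values", class = "dockcal_data_error")
  }
  if (any(values_nM <= 0)) {
    abort("Ki values must be positive", class = "dockcal_data_error")
  }
  mean(values_nM)
}

#' Label compounds active by an affinity cutoff
#'
#' Actives are compounds with aggregated Ki/Kd strictly below the cutoff;
#' a compound sitting exactly on the cutoff is inactive. The 100 nM default is
#' deliberately tighter than the common 10 uM convention so that active and
#' inactive sets stay comparable in size on potency-rich reference sets.
#'
#' @param ki_nM Aggregated Ki/Kd values in nM.
#' @param cutoff_nM Activity cutoff in nM (default 100).
#' @return Logical vector, `TRUE` for active.
#' @export
label_activity <- function(ki_nM, cutoff_nM = 100) {
  ki_nM < cutoff_nM
}

#' Read and aggregate an affinity table
#'
#' Reads a CSV/TSV with header `id,ki_nM` (repeated ids allowed; replicates
#' are averaged with [aggregate_ki()]) or `id,delta_g_kcal`. Returns one row
#' per compound with both the Ki and free-energy representations plus the
#' activity label.
#'
#' @param path Path to the table.
#' @param cutoff_nM Activity cutoff passed to [label_activity()].
#' @return Tibble with columns `id`, `ki_nM`, `delta_g_kcal`, `is_active`.
#' @export
read_affinities <- function(path, cutoff_nM = 100) {
  if (!file.exists(path)) {
    abort(paste0("affinity table not found: ", path), class = "dockcal_io_error")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- read.csv(path, sep = sep, strip.white = TRUE)
  aggregate_affinities(df, cutoff_nM = cutoff_nM)
}

#' Aggregate an affinity data frame to one record per compound
#'
#' @param data Data frame with `id` and either `ki_nM` (repeated ids allowed)
#'   or `delta_g_kcal`.
#' @param cutoff_nM Activity cutoff in nM.
#' @return Tibble with columns `id`, `ki_nM`, `delta_g_kcal`, `is_active`,
#'   in first-appearance order of `id`.
#' @export
aggregate_affinities <- function(data, cutoff_nM = 100) {
  stopifnot(is.data.frame(data), "id" %in% names(data))
  if ("ki_nM" %in% names(data)) {
    out <- data |>
      dplyr::mutate(id = as.character(.data$id)) |>
      dplyr::summarise(ki_nM = aggregate_ki(.data$ki_nM),
                       .by = "id") |>
      dplyr::mutate(delta_g_kcal = ki_to_delta_g(.data$ki_nM))
  } else if ("delta_g_kcal" %in% names(data)) {
    out <- data |>
      dplyr::mutate(id = as.character(.data$id)) |>
      dplyr::summarise(delta_g_kcal = mean(.data$delta_g_kcal), .by = "id") |>
      dplyr::mutate(ki_nM = delta_g_to_ki(.data$delta_g_kcal))
  } else {
    abort("affinity data needs a ki_nM or delta_g_kcal column",
          class = "dockcal_data_error")
  }
  out |>
    dplyr::mutate(is_active = label_activity(.data$ki_nM, cutoff_nM)) |>
    dplyr::select("id", "ki_nM", "delta_g_kcal", "is_active") |>
    tibble::as_tibble()
}

#' Drop weak binders from an affinity table
#'
#' Removes compounds whose experimental binding free energy is above (less
#' negative than) the cutoff, the filter used before benchmarking so that
#' near-non-binders do not dominate the error statistics. The conventional
#' cutoffs are -4 kcal/mol (Glide-style scores) and -5 kcal/mol (Vina-style
#' scores). Order is preserved and the number of removals is reported.
#'
#' @param data Data frame with a `delta_g_kcal` column.
#' @param cutoff_kcal Retention threshold in kcal/mol (default -4); rows with
#'   `delta_g_kcal <= cutoff_kcal` are kept.
#' @return The filtered tibble.
#' @export
filter_weak_binders <- function(data, cutoff_kcal = -4) {
  stopifnot(is.data.frame(data), "delta_g_kcal" %in% names(data))
  keep <- data$delta_g_kcal <= cutoff_kcal
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    inform(paste0("removed ", n_removed, " weak binder(s) with ΔG > ",
                  cutoff_kcal, " kcal/mol"))
  }
  tibble::as_tibble(data[keep, , drop = FALSE])
}
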