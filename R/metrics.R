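#' Root-mean-square error between predicted and experimental energies
#'
#' @param predicted,experimental Equal-length numeric vectors (kcal/mol).
#' @return RMSE in kcal/mol.
#' @export
rmse <- function(predicted, experimental) {
  check_paired(predicted, experimental)
  sqrt(mean((predicted - experimental)^2))
}

#' Mean absolute error between predicted and experimental energies
#'
#' @inheritParams rmse
#' @return MAE in kcal/mol.
#' @export
mae <- function(predicted, experimental) {
  check_paired(predicted, experimental)
  mean(abs(predicted - experimental))
}

#' Squared Pearson correlation
#'
#' @inheritParams rmse
#' @return R-squared in \[0, 1\]; direction of the correlation is ignored.
#' @export
pearson_r2 <- function(predicted, experimental) {
  check_paired(predicted, experimental, min_n = 3L)
  if (sd(predicted) == 0) {
    abort("predicted values are constant; correlation undefined",
          class = "dockcal_data_error")
  }
  if (sd(experimental) == 0) {
    abort("experimental values are constant; correlation undefined",
          class = "dockcal_data_error")
  }
  cor(predicted, experimental)^2
}

#' Predictive index (Pearlman–Charifson)
#'
#' A pairwise rank-agreement statistic in which each compound pair is weighted
#' by its experimental affinity difference, so getting the potent/weak pairs
#' in the right order matters more than shuffling near-equipotent compounds:
#' \deqn{PI = \frac{\sum_{j>i} w_{ij} c_{ij}}{\sum_{j>i} w_{ij}}} with
#' \eqn{w_{ij} = |E_j - E_i|} and \eqn{c_{ij} = \pm 1} as the predicted pair
#' order agrees/disagrees with experiment (0 for a predicted tie). 1 is a
#' perfect ranking, -1 a fully inverted one.
#'
#' @inheritParams rmse
#' @return PI in \[-1, 1\].
#' @examples
#' predictive_index(c(-9, -5, -7), c(-9, -7, -5))
#' @export
predictive_index <- function(predicted, experimental) {
  check_paired(predicted, experimental, min_n = 2L)
  de <- outer(experimental, experimental, `-`)
  dp <- outer(predicted, predicted, `-`)
  up <- upper.tri(de)
  w <- abs(de[up])
  if (sum(w) == 0) {
    abort("all experimental values are equal; PI undefined",
          class = "dockcal_data_error")
  }
  concord <- sign(de[up] * dp[up])   # 0 where predicted (or experimental) tied
  sum(w * concord) / sum(w)
}

#' Enrichment factor at a hit fraction
#'
#' Ranks compounds by predicted score (ascending: more negative is better),
#' takes the top `ceiling(fraction * n)` and compares the active rate there to
#' the overall active rate. Random ranking gives 1 in expectation; the maximum
#' is `1/fraction` (capped by the number of actives). Score ties are broken by
#' input order (stable sort); a warning is issued when tied scores straddle
#' the cutoff, since the EF then depends on that arbitrary order.
#'
#' @inheritParams rmse
#' @param active Logical vector of activity labels.
#' @param fraction Hit fraction in (0, 1\].
#' @param dialect `"count"` (default): EF = (actives in top / m) / (actives /
#'   n) with m = `ceiling(fraction * n)`. `"fraction"`: EF = (fraction of all
#'   actives retrieved) / `fraction`; the two differ only through the rounding
#'   of m.
#' @return The enrichment factor (non-negative).
#' @examples
#' enrichment_factor(c(-10, -9, -3, -2, -1), c(TRUE, TRUE, FALSE, FALSE, FALSE),
#'                   fraction = 0.4)
#' @export
enrichment_factor <- function(predicted, active, fraction,
                              dialect = c("count", "fraction")) {
  dialect <- match.arg(dialect)
  check_paired(predicted, active)
  stopifnot(is.logical(active))
  if (!sum(active)) {
    abort("no active compounds; EF undefined", class = "dockcal_data_error")
  }
  if (fraction <= 0 || fraction > 1) {
    abort("fraction must lie in (0, 1]", class = "dockcal_config_error")
  }
  n <- length(predicted)
  m <- ceiling(fraction * n)
  ord <- order(predicted)              # stable: ties keep input order
  if (m < n && predicted[ord[m]] == predicted[ord[m + 1L]]) {
    warn("tied scores straddle the EF cutoff; ties broken by input order")
  }
  top_actives <- sum(active[ord[seq_len(m)]])
  switch(dialect,
    count = (top_actives / m) / (sum(active) / n),
    fraction = (top_actives / sum(active)) / fraction
  )
}

#' ROC AUC for active/inactive discrimination by score
#'
#' The probability that a randomly chosen active scores better (more negative)
#' than a randomly chosen inactive, with ties counting one half — the
#' Mann–Whitney rank statistic, identical to trapezoidal integration of the
#' ROC curve.
#'
#' @inheritParams enrichment_factor
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(predicted, active) {
  check_paired(predicted, active)
  stopifnot(is.logical(active))
  n_act <- sum(active)
  n_inact <- sum(!active)
  if (n_act == 0L || n_inact == 0L) {
    abort("both actives and inactives are required for AUC",
          class = "dockcal_data_error")
  }
  r <- rank(-predicted)                 # higher rank = better (more negative)
  (sum(r[active]) - n_act * (n_act + 1) / 2) / (n_act * n_inact)
}

check_paired <- function(a, b, min_n = 1L) {
  if (length(a) != length(b)) {
    abort("paired vectors have different lengths", class = "dockcal_data_error")
  }
  if (length(a) < min_n) {
    abort(paste0("at least ", min_n, " paired observations required"),
          class = "dockcal_data_error")
  }
  invisible(NULL)
}

#' All scoring, ranking and screening metrics in one row
#'
#' Computes RMSE and MAE (scoring power), R-squared and the predictive index
#' (ranking power), and — when activity labels are available — ROC AUC and
#' enrichment factors (screening power) for a set of predicted vs experimental
#' binding energies.
#'
#' @param data Data frame holding the columns referenced below.
#' @param predicted,experimental Columns of predicted and experimental
#'   energies (tidy-eval; kcal/mol).
#' @param active Optional column of logical activity labels; when absent the
#'   screening metrics are `NA`.
#' @param ef_fractions Hit fractions for the enrichment factors (default 10%
#'   and 40%).
#' @return A one-row tibble: `n`, `rmse`, `mae`, `r2`, `pi`, `auc` and one
#'   `ef_<percent>` column per fraction.
#' @examples
#' d <- data.frame(pred = c(-9, -8, -5, -4), expt = c(-10, -7, -6, -4),
#'                 act = c(TRUE, TRUE, FALSE, FALSE))
#' score_metrics(d, pred, expt, act)
#' @export
score_metrics <- function(data, predicted, experimental, active = NULL,
                          ef_fractions = c(0.1, 0.4)) {
  p <- dplyr::pull(data, {{ predicted }})
  e <- dplyr::pull(data, {{ experimental }})
  a <- if (rlang::quo_is_null(rlang::enquo(active))) NULL
       else dplyr::pull(data, {{ active }})
  out <- tibble::tibble(
    n = length(p),
    rmse = rmse(p, e),
    mae = mae(p, e),
    r2 = pearson_r2(p, e),
    pi = predictive_index(p, e)
  )
  ef_names <- paste0("ef_", as.character(round(ef_fractions * 100, 6)))
  if (is.null(a)) {
    out$auc <- NA_real_
    for (nm in ef_names) out[[nm]] <- NA_real_
  } else {
    out$auc <- roc_auc(p, a)
    for (k in seq_along(ef_fractions)) {
      out[[ef_names[k]]] <- enrichment_factor(p, a, ef_fractions[k])
    }
  }
  out
}
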