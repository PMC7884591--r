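#' Configuration for similarity-weighted score calibration
#'
#' Bundles the tunable parameters of the hybrid scoring function. `p` is the
#' exponent of the compound similarity effect (CSE) function \eqn{S^p}: larger
#' p concentrates weight on the most similar references, with `p = 4` the
#' recommended balance between the docking score and the similarity signal
#' (values above 4 are allowed but flagged). `tc_lower` and `tc_upper` bound
#' the Tanimoto similarities a reference may contribute at: a lower bound
#' alone models a focus library (lead optimisation, similar references
#' available); adding an upper bound models a diverse library (lead
#' identification, near-neighbours excluded). The lower bound is inclusive,
#' the upper bound exclusive.
#'
#' @param p Integer CSE exponent, >= 1 (default 4; warning above 4).
#' @param tc_lower Inclusive lower Tanimoto bound in \[0, 1\] (default 0).
#' @param tc_upper Exclusive upper Tanimoto bound in (0, 1\], or `NULL` for
#'   none.
#' @param min_references Minimum number of references that must survive the
#'   Tc filter for calibration to proceed (default 1); below it the query
#'   falls back to its original score.
#' @param degenerate_score_epsilon References with docking score >=
#'   `-degenerate_score_epsilon` kcal/mol are excluded before calibration: the
#'   experimental/docked ratio blows up near zero and flips sign for positive
#'   scores (default 0.1).
#' @return A `calibration_config` object.
#' @export
calibration_config <- function(p = 4L, tc_lower = 0, tc_upper = NULL,
                               min_references = 1L,
                               degenerate_score_epsilon = 0.1) {
  if (!is.numeric(p) || length(p) != 1L || p < 1 || p != round(p)) {
    abort("p must be a single integer >= 1", class = "dockcal_config_error")
  }
  if (p > 4) {
    warn(paste0("p = ", p, " exceeds the recommended maximum of 4; ",
                "calibration approaches a nearest-neighbour rule"))
  }
  if (tc_lower < 0 || tc_lower > 1) {
    abort("tc_lower must lie in [0, 1]", class = "dockcal_config_error")
  }
  if (!is.null(tc_upper)) {
    if (tc_upper <= 0 || tc_upper > 1) {
      abort("tc_upper must lie in (0, 1]", class = "dockcal_config_error")
    }
    if (tc_lower >= tc_upper) {
      abort("tc_lower must be below tc_upper", class = "dockcal_config_error")
    }
  }
  if (min_references < 1) {
    abort("min_references must be >= 1", class = "dockcal_config_error")
  }
  if (degenerate_score_epsilon <= 0) {
    abort("degenerate_score_epsilon must be positive", class = "dockcal_config_error")
  }
  structure(
    list(p = as.integer(p), tc_lower = tc_lower, tc_upper = tc_upper,
         min_references = as.integer(min_references),
         degenerate_score_epsilon = degenerate_score_epsilon),
    class = "calibration_config"
  )
}

#' @export
print.calibration_config <- function(x, ...) {
  upper <- if (is.null(x$tc_upper)) "none" else format(x$tc_upper)
  cat("<calibration_config> CSE = S^", x$p,
      ", Tc in [", format(x$tc_lower), ", ", upper, ")",
      ", min refs ", x$min_references, "\n", sep = "")
  invisible(x)
}

#' Calibrate query docking scores against reference ligands
#'
#' The hybrid scoring function: each query's docking score \eqn{DS_j^0} is
#' multiplied by a similarity-weighted mean of the reference ratios between
#' experimental binding free energy and docking score,
#' \deqn{DS_j = DS_j^0 \frac{1}{\omega} \sum_{i \ne j} S_{ij}^p
#'       \frac{\Delta G_i}{DS_i}, \qquad \omega = \sum_{i \ne j} S_{ij}^p,}
#' where \eqn{S_{ij}} is the Tanimoto similarity between query j and reference
#' i. References are filtered to `tc_lower <= S < tc_upper` first; a reference
#' sharing the query's id is always excluded (a distinct compound with
#' similarity 1 still contributes). When no reference survives — fewer than
#' `min_references`, or all surviving weights are zero — the query keeps its
#' original score and is flagged `fallback`; calibration degrades gracefully
#' rather than erroring on sparse reference sets.
#'
#' @param queries Data frame with columns `id` and `docking_score` (kcal/mol).
#' @param references Data frame with columns `id`, `docking_score` and
#'   `delta_g_kcal` (both kcal/mol, both expected negative).
#' @param config A [calibration_config()].
#' @param similarities Query-by-reference similarity matrix (rows in query
#'   order, columns in reference order). If `NULL`, both inputs must carry the
#'   fingerprint columns produced by [compute_fingerprints()] (joinable via
#'   their `bits` list-column) and similarities are computed with
#'   [tanimoto_matrix()].
#' @return A `dockcal_calibration` tibble with one row per query: `id`,
#'   `original_score`, `calibrated_score`, `omega` (sum of surviving CSE
#'   weights), `n_contributing` (references surviving the Tc filter) and
#'   `fallback`.
#' @examples
#' refs <- data.frame(id = c("r1", "r2"), docking_score = c(-8, -10),
#'                    delta_g_kcal = c(-7, -8))
#' qry <- data.frame(id = "q", docking_score = -9)
#' calibrate_scores(qry, refs, calibration_config(p = 4),
#'                  similarities = matrix(c(0.9, 0.5), nrow = 1))
#' @export
calibrate_scores <- function(queries, references, config = calibration_config(),
                             similarities = NULL) {
  stopifnot(inherits(config, "calibration_config"))
  queries <- validate_score_tbl(queries, "queries")
  references <- validate_score_tbl(references, "references", need_dg = TRUE)
  if (nrow(references) == 0L) {
    abort("reference set is empty", class = "dockcal_data_error")
  }

  # degenerate-score policy: near-zero or positive reference scores make the
  # ratio dG/DS unstable, so they never contribute
  degenerate <- references$docking_score >= -config$degenerate_score_epsilon
  if (any(degenerate)) {
    inform(paste0("excluding ", sum(degenerate),
                  " reference(s) with degenerate docking score (>= ",
                  -config$degenerate_score_epsilon, " kcal/mol)"))
  }

  if (is.null(similarities)) {
    if (!all(c("bits", "fp_type", "nbits") %in% names(queries)) ||
        !all(c("bits", "fp_type", "nbits") %in% names(references))) {
      abort(paste0("no similarity matrix given and inputs carry no ",
                   "fingerprint columns (bits, fp_type, nbits)"),
            class = "dockcal_data_error")
    }
    similarities <- tanimoto_matrix(queries, references)
  } else {
    similarities <- rbind(similarities)
    if (nrow(similarities) != nrow(queries) ||
        ncol(similarities) != nrow(references)) {
      abort("similarity matrix dimensions do not match queries x references",
            class = "dockcal_data_error")
    }
  }

  s <- similarities
  # self-exclusion by id, and the degenerate-score policy, as hard masks
  excluded <- outer(queries$id, references$id, `==`) |
    matrix(degenerate, nrow = nrow(queries), ncol = nrow(references), byrow = TRUE)
  in_range <- s >= config$tc_lower
  if (!is.null(config$tc_upper)) in_range <- in_range & s < config$tc_upper
  contributing <- in_range & !excluded

  w <- (s ^ config$p) * contributing
  omega <- rowSums(w)
  n_contributing <- rowSums(contributing)
  ratio <- references$delta_g_kcal / references$docking_score
  correction <- as.vector(w %*% ratio) / ifelse(omega > 0, omega, 1)

  fallback <- n_contributing < config$min_references | omega == 0
  if (any(fallback)) {
    inform(paste0(sum(fallback), " of ", nrow(queries),
                  " query(ies) fell back to the original score"))
  }

  out <- tibble::tibble(
    id = queries$id,
    original_score = queries$docking_score,
    calibrated_score = ifelse(fallback, queries$docking_score,
                              queries$docking_score * correction),
    omega = ifelse(fallback & omega == 0, 0, omega),
    n_contributing = as.integer(n_contributing),
    fallback = fallback
  )
  structure(out, config = config,
            class = c("dockcal_calibration", class(out)))
}

#' Calibrate a single query compound
#'
#' Convenience wrapper around [calibrate_scores()] for one query; accepts the
#' similarity row as a plain vector. See [calibrate_scores()] for the model.
#'
#' @param query A one-row data frame or named list with `id` and
#'   `docking_score`.
#' @param references As in [calibrate_scores()].
#' @param config A [calibration_config()].
#' @param similarities Numeric vector of similarities to each reference, or
#'   `NULL` to compute from fingerprints.
#' @return A one-row `dockcal_calibration` tibble.
#' @examples
#' refs <- data.frame(id = c("r1", "r2"), docking_score = c(-8, -10),
#'                    delta_g_kcal = c(-7, -8))
#' calibrate_one(list(id = "q", docking_score = -9), refs,
#'               similarities = c(0.9, 0.5))$calibrated_score
#' @export
calibrate_one <- function(query, references, config = calibration_config(),
                          similarities = NULL) {
  if (!is.data.frame(query)) query <- tibble::as_tibble(query[!sapply(query, is.null)])
  if (nrow(query) != 1L) {
    abort("query must be a single compound", class = "dockcal_data_error")
  }
  if (!is.null(similarities) && is.null(dim(similarities))) {
    similarities <- matrix(similarities, nrow = 1L)
  }
  calibrate_scores(query, references, config, similarities)
}

validate_score_tbl <- function(data, arg, need_dg = FALSE) {
  if (!is.data.frame(data) || !all(c("id", "docking_score") %in% names(data))) {
    abort(paste0(arg, " must be a data frame with columns id, docking_score"),
          class = "dockcal_data_error")
  }
  if (need_dg && !"delta_g_kcal" %in% names(data)) {
    abort(paste0(arg, " must carry a delta_g_kcal column ",
                 "(use aggregate_affinities()/ki_to_delta_g())"),
          class = "dockcal_data_error")
  }
  data <- tibble::as_tibble(data)
  data$id <- as.character(data$id)
  data
}

#' Determine the diverse-library upper Tanimoto bound
#'
#' For the diverse-library scenario the upper Tc bound is taken from the
#' similarity between the test compounds and a general-purpose screening
#' library: all pairwise test-by-screening similarities are pooled and the
#' bound is the smallest Tc such that more than half of the pooled
#' similarities lie below it, i.e. the pooled median. The full pooled
#' distribution is attached so alternative summaries can be computed.
#'
#' @param test_fps Fingerprint table of the test compounds.
#' @param screening_fps Fingerprint table of the screening library.
#' @return The upper bound in \[0, 1\], with the pooled similarities in
#'   attribute `"similarities"`.
#' @export
determine_tc_upper_bound <- function(test_fps, screening_fps) {
  s <- tanimoto_matrix(test_fps, screening_fps)
  pooled <- as.vector(s)
  bound <- median(pooled)
  inform(paste0("Tc upper bound ", signif(bound, 4), " from ", length(pooled),
                " pooled similarities (min ", signif(min(pooled), 3),
                ", max ", signif(max(pooled), 3), ")"))
  structure(bound, similarities = pooled)
}
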