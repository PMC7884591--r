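# Independent brute-force oracles: deliberately plain loops, no shared code
# with the implementation paths they check.

oracle_tanimoto <- function(a, b) {
  x <- 0L; y <- 0L; z <- 0L
  for (k in seq_along(a)) {
    if (a[k]) x <- x + 1L
    if (b[k]) y <- y + 1L
    if (a[k] && b[k]) z <- z + 1L
  }
  if (x + y == 0L) return(1)
  z / (x + y - z)
}

# Double-loop calibration: queries x references, with Tc filtering,
# self-exclusion and the degenerate-score policy applied literally.
oracle_calibrate <- function(queries, refs, p, tc_lower = 0, tc_upper = NULL,
                             min_references = 1, eps = 0.1, sims) {
  out <- data.frame(id = queries$id, calibrated = NA_real_,
                    omega = NA_real_, n = NA_integer_, fallback = NA)
  for (j in seq_len(nrow(queries))) {
    num <- 0; om <- 0; n_contrib <- 0L
    for (i in seq_len(nrow(refs))) {
      if (refs$id[i] == queries$id[j]) next
      if (refs$docking_score[i] >= -eps) next
      s <- sims[j, i]
      if (s < tc_lower) next
      if (!is.null(tc_upper) && s >= tc_upper) next
      n_contrib <- n_contrib + 1L
      w <- s^p
      om <- om + w
      num <- num + w * refs$delta_g_kcal[i] / refs$docking_score[i]
    }
    if (n_contrib < min_references || om == 0) {
      out$calibrated[j] <- queries$docking_score[j]
      out$omega[j] <- om
      out$fallback[j] <- TRUE
    } else {
      out$calibrated[j] <- queries$docking_score[j] * num / om
      out$omega[j] <- om
      out$fallback[j] <- FALSE
    }
    out$n[j] <- n_contrib
  }
  out
}

oracle_pi <- function(predicted, experimental) {
  num <- 0; den <- 0
  n <- length(predicted)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- abs(experimental[j] - experimental[i])
      dp <- predicted[j] - predicted[i]
      de <- experimental[j] - experimental[i]
      c_ij <- if (dp == 0 || de == 0) 0 else if (de / dp > 0) 1 else -1
      num <- num + w * c_ij
      den <- den + w
    }
  }
  num / den
}

oracle_auc <- function(predicted, active) {
  act <- predicted[active]
  inact <- predicted[!active]
  total <- 0
  for (a in act) {
    for (b in inact) {
      total <- total + if (a < b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(act) * length(inact))
}

random_fp_tbl <- function(n, nbits = 64, density = 0.3, prefix = "m") {
  bits <- lapply(seq_len(n), function(i) runif(nbits) < density)
  tibble::tibble(
    id = paste0(prefix, seq_len(n)),
    fp_type = "EXTERNAL",
    nbits = as.integer(nbits),
    bits = bits
  )
}

# two-reference worked configuration used across calibration tests
worked_refs <- function() {
  data.frame(id = c("ref1", "ref2"), docking_score = c(-8, -10),
             delta_g_kcal = c(-7, -8))
}

worked_query <- function() list(id = "q1", docking_score = -9)

local_smiles_file <- function(lines, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".smi", .local_envir = env)
  writeLines(lines, path)
  path
}
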