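test_that("the two-reference worked configuration calibrates to -7.82", {
  res <- calibrate_one(worked_query(), worked_refs(), calibration_config(p = 4),
                       similarities = c(0.9, 0.5))
  hand <- -9 * (0.9^4 * (-7 / -8) + 0.5^4 * (-8 / -10)) / (0.9^4 + 0.5^4)
  expect_equal(res$calibrated_score, hand)
  expect_equal(round(res$calibrated_score, 2), -7.82)
  expect_equal(res$omega, 0.9^4 + 0.5^4)
  expect_equal(res$n_contributing, 2L)
  expect_false(res$fallback)
})

test_that("the worked configuration at p = 1 matches a hand evaluation", {
  res <- calibrate_one(worked_query(), worked_refs(), calibration_config(p = 1),
                       similarities = c(0.9, 0.5))
  expect_equal(res$calibrated_score, -9 * (0.9 * 0.875 + 0.5 * 0.8) / 1.4)
  expect_equal(round(res$calibrated_score, 3), -7.634)
})

test_that("a single reference with matching score and energy is a fixed point", {
  refs <- data.frame(id = "r", docking_score = -6.5, delta_g_kcal = -6.5)
  for (s in c(0.2, 0.7, 1)) {
    res <- calibrate_one(list(id = "q", docking_score = -9), refs,
                         similarities = s)
    expect_identical(res$calibrated_score, -9)
    expect_false(res$fallback)
  }
})

test_that("single-reference calibration is DS0 * dG/DS independent of similarity", {
  refs <- data.frame(id = "r", docking_score = -8, delta_g_kcal = -6)
  for (s in c(0.1, 0.5, 0.9)) {
    res <- calibrate_one(list(id = "q", docking_score = -10), refs,
                         calibration_config(p = 3), similarities = s)
    expect_equal(res$calibrated_score, -10 * (-6 / -8))
  }
})

test_that("batch calibration equals the brute-force double-loop oracle", {
  withr::with_seed(101, {
    for (trial in 1:25) {
      nq <- sample(1:8, 1)
      nr <- sample(2:30, 1)
      queries <- tibble::tibble(id = paste0("q", seq_len(nq)),
                                docking_score = -runif(nq, 2, 14))
      refs <- tibble::tibble(id = paste0("r", seq_len(nr)),
                             docking_score = -runif(nr, 2, 14),
                             delta_g_kcal = -runif(nr, 2, 14))
      sims <- matrix(runif(nq * nr), nq, nr)
      tc_upper <- sample(c(NA, 0.9), 1)
      cfg <- calibration_config(p = sample(1:4, 1),
                                tc_lower = runif(1, 0, 0.4),
                                tc_upper = if (is.na(tc_upper)) NULL else tc_upper)
      got <- suppressMessages(calibrate_scores(queries, refs, cfg, sims))
      want <- oracle_calibrate(queries, refs, cfg$p, cfg$tc_lower, cfg$tc_upper,
                               sims = sims)
      expect_equal(got$calibrated_score, want$calibrated)
      expect_equal(got$omega, want$omega)
      expect_equal(got$n_contributing, want$n)
      expect_equal(got$fallback, want$fallback)
    }
  })
})

test_that("a batch of one equals calibrate_one and order never matters", {
  withr::with_seed(5, {
    refs <- tibble::tibble(id = paste0("r", 1:10),
                           docking_score = -runif(10, 3, 12),
                           delta_g_kcal = -runif(10, 3, 12))
    sims <- runif(10)
    one <- calibrate_one(list(id = "q", docking_score = -9), refs,
                         similarities = sims)
    batch <- calibrate_scores(tibble::tibble(id = "q", docking_score = -9),
                              refs, similarities = matrix(sims, 1))
    expect_equal(tibble::as_tibble(one), tibble::as_tibble(batch))
    perm <- sample(10)
    shuffled <- calibrate_one(list(id = "q", docking_score = -9), refs[perm, ],
                              similarities = sims[perm])
    expect_equal(shuffled$calibrated_score, one$calibrated_score)
    expect_equal(shuffled$omega, one$omega)
  })
})

test_that("normalized weights sum to one and the correction is convex", {
  withr::with_seed(8, {
    for (trial in 1:20) {
      nr <- sample(3:40, 1)
      refs <- tibble::tibble(id = paste0("r", seq_len(nr)),
                             docking_score = -runif(nr, 2, 14),
                             delta_g_kcal = -runif(nr, 2, 14))
      sims <- runif(nr, 0.05, 1)
      cfg <- calibration_config(p = sample(1:4, 1))
      res <- calibrate_one(list(id = "q", docking_score = -9), refs, cfg,
                           similarities = sims)
      w <- sims^cfg$p
      expect_equal(sum(w / res$omega), 1, tolerance = 1e-12)
      ratio <- refs$delta_g_kcal / refs$docking_score
      corr <- res$calibrated_score / -9
      expect_gte(corr, min(ratio) - 1e-12)
      expect_lte(corr, max(ratio) + 1e-12)
    }
  })
})

test_that("large p approaches the nearest-neighbour limit", {
  refs <- tibble::tibble(id = c("near", "far1", "far2"),
                         docking_score = c(-8, -11, -6),
                         delta_g_kcal = c(-5, -9, -7))
  sims <- c(0.9, 0.6, 0.5)
  res <- suppressWarnings(
    calibrate_one(list(id = "q", docking_score = -10), refs,
                  calibration_config(p = 50), similarities = sims)
  )
  expect_equal(res$calibrated_score, -10 * (-5 / -8), tolerance = 1e-6)
})

test_that("raising tc_lower never increases the contributing count", {
  withr::with_seed(21, {
    refs <- tibble::tibble(id = paste0("r", 1:30),
                           docking_score = -runif(30, 3, 12),
                           delta_g_kcal = -runif(30, 3, 12))
    sims <- runif(30)
    counts <- vapply(seq(0, 1, by = 0.1), function(lo) {
      suppressMessages(
        calibrate_one(list(id = "q", docking_score = -9), refs,
                      calibration_config(tc_lower = lo),
                      similarities = sims)$n_contributing
      )
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("Tc bounds are inclusive below and exclusive above", {
  refs <- tibble::tibble(id = c("at_lower", "at_upper"),
                         docking_score = c(-8, -8), delta_g_kcal = c(-4, -12))
  res <- calibrate_one(list(id = "q", docking_score = -9), refs,
                       calibration_config(tc_lower = 0.3, tc_upper = 0.6),
                       similarities = c(0.3, 0.6))
  expect_equal(res$n_contributing, 1L)   # 0.3 kept, 0.6 excluded
  expect_equal(res$calibrated_score, -9 * (-4 / -8))
})

test_that("self-id references are excluded but Tc = 1 twins contribute", {
  refs <- tibble::tibble(id = c("q", "twin"), docking_score = c(-2, -8),
                         delta_g_kcal = c(-1, -6))
  res <- calibrate_one(list(id = "q", docking_score = -9), refs,
                       similarities = c(1, 1))
  expect_equal(res$n_contributing, 1L)
  expect_equal(res$calibrated_score, -9 * (-6 / -8))
})

test_that("degenerate reference scores are policed, query scores are not", {
  refs <- tibble::tibble(id = c("bad", "good"), docking_score = c(-0.05, -8),
                         delta_g_kcal = c(-5, -6))
  expect_message(
    res <- calibrate_one(list(id = "q", docking_score = -9), refs,
                         similarities = c(0.9, 0.5)),
    "degenerate"
  )
  expect_equal(res$n_contributing, 1L)
  pos_query <- suppressMessages(
    calibrate_one(list(id = "q", docking_score = 2), refs,
                  similarities = c(0.9, 0.5))
  )
  expect_equal(pos_query$calibrated_score, 2 * (-6 / -8))
})

test_that("empty or exhausted reference sets fall back or error as contracted", {
  refs <- worked_refs()
  expect_error(
    calibrate_one(worked_query(), refs[0, ], similarities = numeric(0)),
    class = "dockcal_data_error"
  )
  res <- suppressMessages(
    calibrate_one(worked_query(), refs,
                  calibration_config(tc_lower = 0.99),
                  similarities = c(0.5, 0.4))
  )
  expect_true(res$fallback)
  expect_identical(res$calibrated_score, res$original_score)
  expect_equal(res$n_contributing, 0L)
  batch <- suppressMessages(
    calibrate_scores(tibble::tibble(id = c("a", "b"), docking_score = c(-7, -8)),
                     refs, calibration_config(tc_lower = 0.99),
                     similarities = matrix(0.1, 2, 2))
  )
  expect_true(all(batch$fallback))
})

test_that("configuration invariants are enforced", {
  expect_error(calibration_config(p = 0), class = "dockcal_config_error")
  expect_error(calibration_config(p = 2.5), class = "dockcal_config_error")
  expect_warning(calibration_config(p = 6), "recommended maximum")
  expect_error(calibration_config(tc_lower = 0.8, tc_upper = 0.5),
               class = "dockcal_config_error")
  expect_error(calibration_config(degenerate_score_epsilon = 0),
               class = "dockcal_config_error")
})

test_that("the diverse-library upper bound is the pooled similarity median", {
  one <- tibble::tibble(id = "t", fp_type = "EXTERNAL", nbits = 8L,
                        bits = list(rep(TRUE, 8)))
  expect_message(b1 <- determine_tc_upper_bound(one, one), "upper bound")
  expect_equal(as.numeric(b1), 1)

  test_fps <- tibble::tibble(id = c("t1", "t2"), fp_type = "EXTERNAL",
                             nbits = 8L,
                             bits = list(c(rep(TRUE, 4), rep(FALSE, 4)),
                                         c(rep(FALSE, 4), rep(TRUE, 4))))
  disjoint <- tibble::tibble(id = "s", fp_type = "EXTERNAL", nbits = 8L,
                             bits = list(rep(FALSE, 8)))
  # all-zero screening vector: similarity 0 against any nonzero fingerprint
  screen <- tibble::tibble(id = c("s1", "s2"), fp_type = "EXTERNAL", nbits = 8L,
                           bits = list(c(TRUE, rep(FALSE, 7)),
                                       c(rep(FALSE, 7), TRUE)))
  b <- suppressMessages(determine_tc_upper_bound(test_fps, screen))
  pooled <- sort(attr(b, "similarities"))
  expect_equal(as.numeric(b), median(pooled))
  expect_length(pooled, 4L)
})

test_that("pooled median follows the declared even-count convention", {
  # {0.1, 0.2, 0.3, 0.4} -> 0.25
  expect_equal(median(c(0.1, 0.2, 0.3, 0.4)), 0.25)
  fps_a <- tibble::tibble(id = c("a1", "a2"), fp_type = "EXTERNAL", nbits = 20L,
                          bits = list(c(rep(TRUE, 10), rep(FALSE, 10)),
                                      c(rep(FALSE, 10), rep(TRUE, 10))))
  fps_b <- tibble::tibble(id = c("b1", "b2"), fp_type = "EXTERNAL", nbits = 20L,
                          bits = list(rep(c(TRUE, FALSE), 10),
                                      rep(c(FALSE, TRUE), 10)))
  b <- suppressMessages(determine_tc_upper_bound(fps_a, fps_b))
  expect_equal(as.numeric(b), median(attr(b, "similarities")))
})
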