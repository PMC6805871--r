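test_that("welch one-sided p-values agree with stats::t.test", {
  set.seed(1)
  for (rep in 1:25) {
    x <- rnorm(sample(3:8, 1), mean = runif(1, -2, 2))
    y <- rnorm(sample(3:8, 1))
    expect_equal(
      stochcal:::welch_p_greater(x, y),
      t.test(x, y, alternative = "greater")$p.value,
      tolerance = 1e-12
    )
  }
})

test_that("TOST declares equivalence for identical stable samples and rejects shifts", {
  v <- c(10.0, 10.1, 9.9, 10.05, 9.95)
  expect_true(tost_cell(v, v, epsilon = 0.5, alpha = 0.05))
  # both one-sided tests verified directly against t.test
  expect_lte(t.test(v, v - 0.5, alternative = "greater")$p.value, 0.05)
  expect_lte(t.test(v + 0.5, v, alternative = "greater")$p.value, 0.05)
  # shift far beyond the margin
  expect_false(tost_cell(v, v + 10, epsilon = 0.5))
  # zero margin can never establish equivalence
  expect_false(tost_cell(v, v, epsilon = 0))
  expect_error(tost_cell(c(1), c(1, 2), epsilon = 1), "m >= 2")
})

test_that("DUT pair counts follow the 0.5-tie convention and sum to mn", {
  expect_equal(dut_counts(c(3, 5), 4), c(U_exp = 1, U_sims = 1))
  expect_equal(dut_counts(4, 4), c(U_exp = 0.5, U_sims = 0.5))
  expect_equal(dut_counts(c(5, 6), c(1, 2)), c(U_exp = 4, U_sims = 0))
  set.seed(2)
  for (rep in 1:30) {
    e <- sample(0:5, sample(2:6, 1), replace = TRUE)
    s <- sample(0:5, sample(2:6, 1), replace = TRUE)
    u <- dut_counts(e, s)
    expect_equal(unname(sum(u)), length(e) * length(s))
    # independent pair enumeration
    ue <- 0
    for (i in seq_along(e)) for (j in seq_along(s)) {
      ue <- ue + (e[i] > s[j]) + 0.5 * (e[i] == s[j])
    }
    expect_equal(unname(u["U_exp"]), ue)
  }
})

test_that("one-sided U-test p-values agree with stats::wilcox.test", {
  set.seed(3)
  for (rep in 1:20) {
    # tie-free: exact route
    x <- rnorm(sample(4:10, 1))
    y <- rnorm(sample(4:10, 1), mean = runif(1, -1, 1))
    for (alt in c("greater", "less")) {
      expect_equal(
        stochcal:::u_test_p(x, y, alt),
        wilcox.test(x, y, alternative = alt, exact = TRUE)$p.value,
        tolerance = 1e-12
      )
    }
    # tied integer samples: normal approximation with corrections
    xi <- sample(0:4, 12, replace = TRUE)
    yi <- sample(0:4, 15, replace = TRUE)
    for (alt in c("greater", "less")) {
      expect_equal(
        stochcal:::u_test_p(xi, yi, alt),
        suppressWarnings(
          wilcox.test(xi, yi, alternative = alt, exact = FALSE, correct = TRUE)$p.value
        ),
        tolerance = 1e-12
      )
    }
  }
})

test_that("DUT verdicts separate equivalent from shifted samples", {
  v <- c(10, 11, 9, 10.5, 9.5, 10.2, 9.8, 10.1, 9.9, 10.0)
  eps <- sd(v)
  # direct evaluation of both one-sided U tests at the chosen rule
  p_lo <- stochcal:::u_test_p(v, v - eps, "greater")
  p_hi <- stochcal:::u_test_p(v, v + eps, "less")
  expect_identical(dut_cell(v, v, eps), p_lo <= 0.05 && p_hi <= 0.05)
  expect_true(dut_cell(v, v, eps))
  expect_false(dut_cell(v, v + 100, epsilon = eps))
})

test_that("WMWET port reproduces the reference transcription on fixed vectors", {
  pairs <- list(
    list(exp = c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19),
         sim = c(2, 4, 6, 8, 10, 12, 14, 16, 18, 20)),
    list(exp = c(0.1, 0.9, 1.7, 2.2, 3.3, 4.1),
         sim = c(0.4, 1.2, 1.9, 2.8, 3.6, 4.4)),
    list(exp = c(10.2, 11.7, 9.3, 10.9, 12.4, 8.8, 11.1),
         sim = c(10.5, 9.9, 11.3, 10.1, 12.0, 9.6, 10.8)),
    list(exp = c(5.1, 5.9, 6.3, 7.2, 8.4),
         sim = c(9.5, 10.2, 11.7, 12.3, 13.1)),      # full separation
    list(exp = c(3.05, 3.62, 2.41, 3.98, 2.77, 3.33),
         sim = c(2.95, 3.48, 2.62, 3.81, 3.07, 3.29)),
    list(exp = 1:8 + 0.01 * (1:8)^2,
         sim = rev(1:8) + 0.015 * (1:8)^2)
  )
  for (band in list(c(0.19, 0.76), c(0.3, 0.7))) {
    for (p in pairs) {
      expect_identical(
        wmwet_cell(p$exp, p$sim, band = band, alpha = 0.05),
        wellek_reference_verdict(p$exp, p$sim, band[1], band[2], alpha = 0.05),
        label = paste("band", band[1], band[2])
      )
    }
  }
})

test_that("WMWET extremes: full separation fails, constant equality passes", {
  expect_false(wmwet_cell(1:5, 11:15))           # pi_hat = 1
  expect_true(wmwet_cell(rep(4, 5), rep(4, 6)))  # degenerate, pi_hat = 0.5
})

test_that("rejection matrix covers every cell and counts failures", {
  d <- make_data(3, c(1, 2, 3), c("A", "B"), function(r, t, v) 10 * v + t + r / 10)
  s <- data_as_sims(make_data(3, c(1, 2, 3), c("A", "B"),
                              function(r, t, v) 10 * v + t + r / 7))
  st <- equivalence_settings("TOST", range = 50)  # generous absolute margin
  mat <- rejection_matrix(d, s, st)
  expect_identical(nrow(mat), 6L)
  expect_true(all(mat$equivalent))
  expect_identical(equivalence_score(mat), 0L)

  far <- data_as_sims(make_data(3, c(1, 2, 3), c("A", "B"),
                                function(r, t, v) 1000 + r))
  st2 <- equivalence_settings("TOST", range = 0.5)
  mat2 <- rejection_matrix(d, far, st2)
  expect_identical(equivalence_score(mat2), 6L)
})

test_that("rejection matrix verdicts are invariant to observable order", {
  d <- make_data(3, c(1, 2), c("A", "B"), function(r, t, v) v * 5 + r + t)
  s <- make_sims(3, c(1, 2), c("A", "B"), function(r, t, v) v * 5 + r / 2 + t)
  st <- equivalence_settings("DUT", range = "1sd")
  mat <- rejection_matrix(d, s, st)
  flipped <- as_experiment_data(dplyr::arrange(tibble::as_tibble(d),
                                               dplyr::desc(observable)))
  sf <- as_sim_ensemble(dplyr::arrange(tibble::as_tibble(s),
                                       dplyr::desc(observable)))
  mat2 <- rejection_matrix(flipped, sf, st)
  key1 <- mat[order(mat$observable, mat$time), ]$equivalent
  key2 <- mat2[order(mat2$observable, mat2$time), ]$equivalent
  expect_identical(key1, key2)
})

test_that("widening the margin never increases the equivalence score", {
  set.seed(9)
  d <- make_data(5, c(1, 2, 3), "A", function(r, t, v) 20 + 3 * t + rnorm(1, 0, 2))
  s <- make_sims(5, c(1, 2, 3), "A", function(r, t, v) 21 + 3 * t + rnorm(1, 0, 2))
  scores <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(epsilon) {
    mat <- rejection_matrix(d, s, equivalence_settings("TOST", range = epsilon))
    as.numeric(equivalence_score(mat))
  }, numeric(1))
  expect_true(all(diff(scores) <= 0))
  dscores <- vapply(c(0, 0.5, 1, 2, 4, 8, 16), function(epsilon) {
    mat <- rejection_matrix(d, s, equivalence_settings("DUT", range = epsilon))
    as.numeric(equivalence_score(mat))
  }, numeric(1))
  expect_true(all(diff(dscores) <= 0))
})

test_that("verdicts are invariant under a common translation of both samples", {
  set.seed(10)
  e <- rnorm(6, 10)
  s <- rnorm(6, 10.5)
  for (shift in c(-20, 3, 111)) {
    expect_identical(tost_cell(e, s, 1), tost_cell(e + shift, s + shift, 1))
    expect_identical(dut_cell(e, s, 1), dut_cell(e + shift, s + shift, 1))
    expect_identical(wmwet_cell(e, s), wmwet_cell(e + shift, s + shift))
  }
})

test_that("untestable cells are counted as failed with a warning", {
  d <- make_data(1, c(1, 2), "A", function(r, t, v) t)  # single replicate
  s <- make_sims(3, c(1, 2), "A", function(r, t, v) t + r / 10)
  st <- equivalence_settings("TOST", range = "1sd")
  expect_warning(mat <- rejection_matrix(d, s, st), "untestable")
  expect_identical(equivalence_score(mat), 2L)
  expect_true(all(!mat$testable))
})
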