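test_that("population initialisation respects bounds, law and seed", {
  specs <- param_spec("k", 1e-2, 1e2, "log_uniform")
  pop <- initialize_population(specs, 10000, seed = 5)
  expect_true(all(pop$k >= 1e-2 & pop$k <= 1e2))
  # log10 of draws uniform on [-2, 2]
  ks <- ks.test(log10(pop$k), "punif", -2, 2)
  expect_gt(ks$p.value, 0.01)
  expect_identical(pop, initialize_population(specs, 10000, seed = 5))
  expect_error(initialize_population(specs, 0, seed = 1), "pop_size")
  expect_error(param_spec("k", -1, 2, "log_uniform"), "log_uniform")
  expect_error(param_spec("k", 3, 2), "lower < upper")
})

test_that("inverse-rank probabilities match the closed form", {
  expect_equal(inverse_rank_probabilities(1), 1)
  expect_equal(inverse_rank_probabilities(2), c(2 / 3, 1 / 3))
  p <- inverse_rank_probabilities(100)
  expect_equal(sum(p), 1)
  expect_equal(round(100 * p[1], 2), 19.28)
  expect_equal(round(100 * p[2], 2), 9.64)
})

test_that("parent selection follows the strategy's distribution", {
  ranked <- 101:200   # ids in rank order
  # strategy 1, elite 1: always self-recombination of the best
  withr::with_seed(1, {
    for (k in 1:10) expect_identical(select_parents(ranked, 1, elite = 1), c(101L, 101L))
  })
  # strategy 1, elite 10: uniform over the elite
  draws <- withr::with_seed(2, {
    replicate(50000, select_parents(ranked, 1, elite = 10))
  })
  freq <- tabulate(match(as.vector(draws), ranked), nbins = 100) / (2 * 50000)
  se <- sqrt(0.1 * 0.9 / (2 * 50000))
  expect_true(all(abs(freq[1:10] - 0.1) < 3.5 * se))
  expect_true(all(freq[11:100] == 0))
  # strategy 2: distinct parents, first-rank marginal 19.28%
  draws2 <- withr::with_seed(3, {
    replicate(50000, select_parents(ranked, 2))
  })
  expect_true(all(draws2[1, ] != draws2[2, ]))
  f1 <- mean(draws2[1, ] == 101)
  se1 <- sqrt(0.1928 * (1 - 0.1928) / 50000)
  expect_lt(abs(f1 - 0.1928), 3 * se1)
  expect_error(select_parents(101, 2), "at least 2")
})

test_that("crossover produces the documented gene mixtures", {
  a <- c(1, 2, 3, 4)
  b <- c(10, 20, 30, 40)
  kids <- withr::with_seed(4, replicate(200, crossover(a, b, "single_point")))
  # every child is a prefix of a followed by a suffix of b
  for (j in seq_len(ncol(kids))) {
    child <- kids[, j]
    k <- sum(child %in% a)
    expect_identical(child, c(a[seq_len(k)], b[(k + 1):4][seq_len(4 - k)]))
    expect_true(k >= 1 && k <= 3)
  }
  # identical parents are a fixed point for both modes
  expect_identical(withr::with_seed(5, crossover(a, a, "single_point")), a)
  expect_identical(withr::with_seed(5, crossover(a, a, "multi_point")), a)
  # multi-point picks each gene from parent a half the time
  kids2 <- withr::with_seed(6, replicate(10000, crossover(a, b, "multi_point")))
  from_a <- rowMeans(kids2 == a)
  se <- sqrt(0.25 / 10000)
  expect_true(all(abs(from_a - 0.5) < 3.5 * se))
})

test_that("mutation respects probability, bounds and the sampling law", {
  specs <- param_spec("k", 1e-2, 1e2, "log_uniform")
  x <- c(k = 1)
  expect_identical(withr::with_seed(7, mutate_params(x, specs, "redraw", prob = 0)), x)
  # factor mutation stays within +-10% before clipping
  specs2 <- param_spec("k", 1e-6, 1e6, "log_uniform")
  muts <- withr::with_seed(8, {
    replicate(2000, mutate_params(c(k = 1), specs2, "factor", prob = 1, halfwidth = 0.1))
  })
  expect_true(all(muts >= 0.9 & muts <= 1.1))
  # redraw at prob 1 reproduces the initialisation distribution
  redraws <- withr::with_seed(9, {
    replicate(10000, mutate_params(c(k = 1), specs, "redraw", prob = 1))
  })
  ks <- ks.test(log10(redraws), "punif", -2, 2)
  expect_gt(ks$p.value, 0.01)
  # factor mutation clips at the bounds
  specs3 <- param_spec("k", 0.5, 1.04)
  muts3 <- withr::with_seed(10, {
    replicate(500, mutate_params(c(k = 1), specs3, "factor", prob = 1, halfwidth = 0.1))
  })
  expect_true(all(muts3 <= 1.04))
})

test_that("ranking is ascending with deterministic id tie-breaks and Inf last", {
  r <- rank_population(cbind(c(3, 1, 2)))
  expect_identical(r$id, c(2L, 3L, 1L))
  r2 <- rank_population(cbind(c(1, 1, 2)), ids = c(9L, 4L, 1L))
  expect_identical(r2$id, c(4L, 9L, 1L))  # tie broken by lower id
  r3 <- rank_population(cbind(c(Inf, 1, Inf)))
  expect_identical(r3$id[1], 2L)
  expect_identical(sort(r3$rank), 1:3)
})

test_that("calibration with a deterministic backend converges and is reproducible", {
  data <- mock_data(a0 = 5)
  cfg <- tiny_ga_config(objectives = "SDA", strategy = 1, iterations = 6, seed = 3)
  cal1 <- calibrate(data, mock_specs(), cfg, mock_backend())
  cal2 <- calibrate(data, mock_specs(), cfg, mock_backend())
  expect_identical(cal1$history, cal2$history)
  # running best is non-increasing (asserted internally too)
  best <- cal1$per_iter$best
  expect_true(all(diff(best) <= 0))
  # population size conserved every iteration
  sizes <- table(cal1$history$iteration)
  expect_true(all(sizes == cfg$pop_size))
  # the optimum a0 = 5 is approached
  expect_lt(abs(cal1$best$params[["a"]] - 5), 0.5)
  # all visited parameters within bounds
  expect_true(all(cal1$history$a >= 0.1 & cal1$history$a <= 10))
})

test_that("elitism caches fitness so the best never degrades with zero mutation", {
  data <- mock_data(a0 = 5)
  cfg <- tiny_ga_config(objectives = "SDA", strategy = 1, iterations = 8,
                        mutation = list(mode = "redraw", prob = 0), seed = 21)
  cal <- calibrate(data, mock_specs(), cfg, mock_backend())
  expect_true(all(diff(cal$per_iter$best) <= 0))
})

test_that("strategies 2 and 3 run and keep the population within bounds", {
  data <- mock_data(a0 = 2)
  for (strat in 2:3) {
    cfg <- tiny_ga_config(objectives = "ADA", strategy = strat, iterations = 4,
                          seed = 30 + strat)
    cal <- calibrate(data, mock_specs(), cfg, mock_backend())
    expect_true(all(cal$history$a >= 0.1 & cal$history$a <= 10))
    expect_equal(max(cal$history$iteration), 4)
  }
})

test_that("a failing backend yields sentinel fitness without killing the run", {
  data <- mock_data(a0 = 5)
  flaky <- function(params, n_sims, times, seed) {
    if (params[["a"]] > 5) stop("boom")
    mock_backend()(params, n_sims, times, seed)
  }
  cfg <- tiny_ga_config(objectives = "SDA", strategy = 1, iterations = 3, seed = 12)
  cal <- calibrate(data, mock_specs(), cfg, flaky)
  expect_true(any(!is.finite(cal$history$SDA)))
  expect_true(is.finite(cal$best$fitness))
  # sentinels rank strictly after finite fitness
  h <- cal$history[cal$history$iteration == 1, ]
  expect_true(max(h$rank[is.finite(h$SDA)]) < min(h$rank[!is.finite(h$SDA)]))
})

test_that("fractional error normalises by the first iteration", {
  expect_equal(fractional_error(c(4, 2, 1))$fractional_error, c(1, 0.5, 0.25))
  expect_equal(fractional_error(c(7, 7, 7))$fractional_error, rep(1, 3))
  expect_error(fractional_error(c(0, 1)), class = "stochcal_error_degenerate")
  data <- mock_data(a0 = 5)
  cfg <- tiny_ga_config(objectives = "SDA", iterations = 3, seed = 2)
  fe <- fractional_error(calibrate(data, mock_specs(), cfg, mock_backend()))
  expect_equal(fe$fractional_error[fe$iteration == 1], 1)
})

test_that("smoke recovery: continuous objectives find the rates to order of magnitude", {
  net <- aguilera_network()
  truth <- aguilera_true_rates()
  d <- generate_synthetic_dataset(net, 10, seed = 404)
  specs <- param_specs_around(truth)
  cfg <- ga_config(objectives = "SDA", strategy = 1, pop_size = 30, elite = 6,
                   iterations = 12, n_sims = 5, seed = 404)
  cal <- calibrate(d, specs, cfg, builtin_backend(net))
  ratio <- cal$best$params[names(truth)] / truth
  expect_true(all(ratio > 0.1 & ratio < 10))
})

test_that("tidiers and plots expose the calibration result", {
  data <- mock_data(a0 = 5)
  cfg <- tiny_ga_config(objectives = c("SDA", "ADA"), iterations = 3, seed = 8)
  cal <- calibrate(data, mock_specs(), cfg, mock_backend())
  td <- tidy(cal)
  expect_true(all(c("iteration", "id", "rank", "a", "SDA", "ADA") %in% names(td)))
  g <- glance(cal)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("fitness_SDA", "fitness_ADA", "a") %in% names(g)))
  expect_s3_class(autoplot(cal), "ggplot")
})
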