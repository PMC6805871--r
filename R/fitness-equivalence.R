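#' Settings for the iterative equivalence tests
#'
#' The equivalence margin for TOST/DUT is either a multiple of the per-cell
#' experimental standard deviation (`range = "1sd"`, `"2sd"`, ...) or an
#' absolute value (`range = 0.5`). Wellek's test instead uses a probability
#' band around 1/2 within which `P(sim > exp)` must lie.
#'
#' @param test `"TOST"`, `"DUT"` or `"WMWET"`.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @param range Equivalence range for TOST/DUT: a string `"<k>sd"` for a
#'   k-standard-deviation symmetric margin (default one SD) or a non-negative
#'   number for an absolute margin.
#' @param band Length-2 probability band `(p_lo, p_hi)` for WMWET with
#'   `0 < p_lo < 0.5 < p_hi < 1`; default `c(0.19, 0.76)`.
#' @param range_scope For SD-based margins, the pool the standard deviation is
#'   computed from: `"cell"` (default) uses the cell's own experimental
#'   replicates, so the margin is the replicate dispersion at that time point;
#'   `"observable"` uses all experimental values of the cell's observable
#'   across replicates and time points, so the margin reflects the dynamic
#'   range of that variable. The per-cell margin is strict when replicates
#'   are few (it barely exceeds the sampling noise of the two cell means);
#'   the trade-off is discussed in the methods vignette.
#' @return A list of class `equivalence_settings`.
#' @export
equivalence_settings <- function(test = c("TOST", "DUT", "WMWET"), alpha = 0.05,
                                 range = "1sd", band = c(0.19, 0.76),
                                 range_scope = c("cell", "observable")) {
  range_scope <- match.arg(range_scope)
  test <- match.arg(test)
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_validation("alpha must be in (0, 1)")
  }
  if (is.character(range)) {
    if (!grepl("^[0-9.]+sd$", range)) stop_validation("range string must look like '1sd'")
    k <- as.numeric(sub("sd$", "", range))
    range_mode <- "sd_multiple"
  } else {
    if (!is_scalar_number(range) || range < 0) stop_validation("absolute range must be >= 0")
    k <- range
    range_mode <- "absolute"
  }
  if (length(band) != 2 || band[1] <= 0 || band[1] >= 0.5 ||
      band[2] <= 0.5 || band[2] >= 1) {
    stop_validation("band must satisfy 0 < p_lo < 0.5 < p_hi < 1")
  }
  structure(list(test = test, alpha = alpha, range_mode = range_mode,
                 range_value = k, band = band, range_scope = range_scope),
            class = "equivalence_settings")
}

# one-sided Welch p-value for the alternative mean(x) > mean(y);
# a zero-variance pair degenerates to certainty about the sign of the shift
welch_p_greater <- function(x, y) {
  m <- length(x)
  n <- length(y)
  vx <- stats::var(x)
  vy <- stats::var(y)
  d <- mean(x) - mean(y)
  se2 <- vx / m + vy / n
  if (se2 == 0) {
    return(if (d > 0) 0 else if (d < 0) 1 else 0.5)
  }
  tt <- d / sqrt(se2)
  df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
  pt(tt, df, lower.tail = FALSE)
}

#' Two one-sided t-tests (TOST) on one data cell
#'
#' Shifts the simulated values left and right by the equivalence margin and
#' asks, with unpaired one-sided Welch t-tests, whether the left-shifted
#' distribution is statistically smaller than the data and the right-shifted
#' one statistically larger. Equivalence is declared only when both one-sided
#' tests reject their null at level `alpha` — i.e. the mean difference is
#' bounded inside `(-epsilon, epsilon)` with confidence.
#'
#' @param exp Numeric vector of `m >= 2` experimental values.
#' @param sim Numeric vector of `n >= 2` simulated values.
#' @param epsilon Non-negative equivalence margin (same units as the data).
#' @param alpha Significance level.
#' @return `TRUE` if equivalence is established.
#' @examples
#' tost_cell(exp = c(10, 10.1, 9.9), sim = c(10.05, 9.95, 10), epsilon = 0.5)
#' @export
tost_cell <- function(exp, sim, epsilon, alpha = 0.05) {
  if (length(exp) < 2 || length(sim) < 2) {
    stop_validation("TOST needs m >= 2 and n >= 2 (dispersion required)")
  }
  if (!is_scalar_number(epsilon) || epsilon < 0) stop_validation("epsilon must be >= 0")
  p_lower <- welch_p_greater(exp, sim - epsilon)   # evidence: sim - eps < exp
  p_upper <- welch_p_greater(sim + epsilon, exp)   # evidence: sim + eps > exp
  isTRUE(p_lower <= alpha && p_upper <= alpha)
}

# pairwise count with the 0.5-per-tie convention
u_stat <- function(x, y) {
  d <- outer(x, y, "-")
  sum(d > 0) + 0.5 * sum(d == 0)
}

#' Mann-Whitney pair counts for the double U-test
#'
#' Counts over all `m * n` pairs how often an experimental value exceeds a
#' (shifted) simulated value, ties counting one half. The two counts always
#' satisfy `U_exp + U_sims = m * n`.
#'
#' @param exp Numeric vector of experimental values.
#' @param shifted_sim Numeric vector of margin-shifted simulated values.
#' @return Named numeric vector `c(U_exp, U_sims)`.
#' @examples
#' dut_counts(c(3, 5), 4)
#' @export
dut_counts <- function(exp, shifted_sim) {
  u <- u_stat(exp, shifted_sim)
  c(U_exp = u, U_sims = length(exp) * length(shifted_sim) - u)
}

# one-sided Mann-Whitney p-value; exact null via pwilcox when tie-free and
# mn <= 400, otherwise normal approximation with tie + continuity correction
u_test_p <- function(x, y, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  m <- length(x)
  n <- length(y)
  u <- u_stat(x, y)
  ties <- anyDuplicated(c(x, y)) > 0
  if (!ties && m * n <= 400) {
    if (alternative == "greater") {
      pwilcox(u - 1, m, n, lower.tail = FALSE)
    } else {
      pwilcox(u, m, n)
    }
  } else {
    tab <- table(c(x, y))
    tiesum <- sum(tab^3 - tab)
    mu <- m * n / 2
    sig <- sqrt((m * n / 12) * ((m + n + 1) - tiesum / ((m + n) * (m + n - 1))))
    if (sig == 0) return(0.5)
    if (alternative == "greater") {
      pnorm((u - mu - 0.5) / sig, lower.tail = FALSE)
    } else {
      pnorm((u - mu + 0.5) / sig)
    }
  }
}

#' Double Mann-Whitney U-test (DUT) on one data cell
#'
#' The nonparametric analogue of [tost_cell()]: the simulated values are
#' shifted left and right by the margin and compared with the unaltered data
#' by one-sided Mann-Whitney U-tests. Equivalence requires the data to be
#' stochastically greater than the left-shifted simulations and stochastically
#' smaller than the right-shifted ones, both significantly at level `alpha`.
#'
#' @inheritParams tost_cell
#' @return `TRUE` if equivalence is established.
#' @export
dut_cell <- function(exp, sim, epsilon, alpha = 0.05) {
  if (length(exp) < 2 || length(sim) < 2) {
    stop_validation("DUT needs m >= 2 and n >= 2")
  }
  if (!is_scalar_number(epsilon) || epsilon < 0) stop_validation("epsilon must be >= 0")
  p_lower <- u_test_p(exp, sim - epsilon, "greater")
  p_upper <- u_test_p(exp, sim + epsilon, "less")
  isTRUE(p_lower <= alpha && p_upper <= alpha)
}

#' Wellek's Mann-Whitney equivalence test (WMWET) on one data cell
#'
#' Tests whether `pi = P(sim > exp)` lies inside the band `(p_lo, p_hi)`
#' around 1/2. The U-statistic estimate `pi_hat` (ties counting one half) is
#' standardised by the estimated U-statistic standard error built from the
#' pair and triple concordance estimators, and equivalence is declared when
#' the standardised distance of `pi_hat` from the band centre falls below the
#' critical bound given by the `alpha`-quantile of the noncentral chi-squared
#' distribution with 1 df and noncentrality `((p_hi - p_lo) / (2 sigma))^2`.
#' A degenerate cell with zero estimated standard error is equivalent exactly
#' when `pi_hat` lies strictly inside the band.
#'
#' @inheritParams tost_cell
#' @param band Probability band `(p_lo, p_hi)`; see [equivalence_settings()].
#' @return `TRUE` if equivalence is established.
#' @export
wmwet_cell <- function(exp, sim, band = c(0.19, 0.76), alpha = 0.05) {
  if (length(exp) < 2 || length(sim) < 2) {
    stop_validation("WMWET needs m >= 2 and n >= 2")
  }
  x <- sim  # convention: pi = P(sim > exp)
  y <- exp
  nx <- length(x)
  ny <- length(y)

  gt <- function(a, b) (a > b) + 0.5 * (a == b)
  pi_hat <- mean(outer(x, y, gt))
  xmin <- combn(x, 2, min)
  ymax <- combn(y, 2, max)
  pi_xxy <- mean(outer(xmin, y, gt))   # P(min(X1, X2) > Y)
  pi_xyy <- mean(outer(x, ymax, gt))   # P(X > max(Y1, Y2))

  v <- (pi_hat - (nx + ny - 1) * pi_hat^2 +
        (nx - 1) * pi_xxy + (ny - 1) * pi_xyy) / (nx * ny)
  sig <- sqrt(max(v, 0))

  eps1 <- 0.5 - band[1]
  eps2 <- band[2] - 0.5
  if (sig == 0) {
    return(pi_hat > band[1] && pi_hat < band[2])
  }
  crit <- sqrt(qchisq(alpha, df = 1, ncp = ((eps1 + eps2) / (2 * sig))^2))
  isTRUE(abs((pi_hat - 0.5 + (eps2 - eps1) / 2) / sig) < crit)
}

cell_epsilon <- function(settings, exp_values, pool_values = NULL) {
  if (settings$range_mode == "absolute") return(settings$range_value)
  pool <- if (identical(settings$range_scope, "cell")) exp_values else {
    pool_values %||% exp_values
  }
  settings$range_value * sd(pool)
}

#' Build the rejection matrix of an iterative equivalence test
#'
#' Applies the configured equivalence test to every (observable, time point)
#' cell of an aligned data/simulation pair. A cell fails when equivalence is
#' not established; cells that cannot be tested (too few replicates for a
#' dispersion-based margin, or a degenerate configuration outside the decision
#' rules) are marked untestable and counted as failed, with a warning, so the
#' score's upper bound `V * T` always holds.
#'
#' @inheritParams fitness_cells
#' @param settings An [equivalence_settings()] object.
#' @return A tibble of class `rejection_matrix` with columns
#'   `(observable, time, equivalent, testable)`.
#' @export
rejection_matrix <- function(data, sims, settings) {
  data <- as_experiment_data(data)
  sims <- as_sim_ensemble(sims)
  check_aligned(data, sims)
  stopifnot(inherits(settings, "equivalence_settings"))
  earr <- ed_tensor(data)
  sarr <- se_tensor(sims)
  times <- attr(data, "times")
  obs <- attr(data, "observables")

  grid <- expand.grid(t = seq_along(times), v = seq_along(obs))
  verdict <- logical(nrow(grid))
  testable <- logical(nrow(grid))
  n_untestable <- 0L
  for (i in seq_len(nrow(grid))) {
    e <- earr[, grid$t[i], grid$v[i]]
    s <- sarr[, grid$t[i], grid$v[i]]
    pool <- as.vector(earr[, , grid$v[i]])
    res <- tryCatch({
      ok <- switch(settings$test,
        TOST = tost_cell(e, s, cell_epsilon(settings, e, pool), settings$alpha),
        DUT = dut_cell(e, s, cell_epsilon(settings, e, pool), settings$alpha),
        WMWET = wmwet_cell(e, s, settings$band, settings$alpha)
      )
      list(equivalent = ok, testable = TRUE)
    }, error = function(err) list(equivalent = FALSE, testable = FALSE))
    verdict[i] <- res$equivalent
    testable[i] <- res$testable
    if (!res$testable) n_untestable <- n_untestable + 1L
  }
  if (n_untestable > 0) {
    warn(paste0(n_untestable, " untestable cell(s) counted as failed"))
  }
  structure(
    tibble::tibble(observable = obs[grid$v], time = times[grid$t],
                   equivalent = verdict, testable = testable),
    test = settings$test, n_tests = nrow(grid),
    class = c("rejection_matrix", class(tibble::tibble()))
  )
}

#' Iterative equivalence score
#'
#' The count of cells in a rejection matrix where equivalence was not
#' established. A perfect model scores zero; a completely wrong model scores
#' the number of observables times the number of time points. Being a count,
#' the score is a discrete fitness function with known limits, suitable for
#' minimisation by the genetic algorithm.
#'
#' @param mat A [rejection_matrix()].
#' @return Integer score in `[0, V * T]`.
#' @export
equivalence_score <- function(mat) {
  stopifnot(inherits(mat, "rejection_matrix"))
  sum(!mat$equivalent)
}
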