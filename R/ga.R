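#' Declare free parameters and their search space
#'
#' Each calibrated rate is declared with bounds and a sampling law. The law
#' governs both population initialisation and redraw mutation: `"uniform"`
#' draws on `[lower, upper]`, `"log_uniform"` draws `10^U` with `U` uniform on
#' `[log10(lower), log10(upper)]` (requiring `lower > 0`), the usual choice
#' for rate constants whose plausible values span decades.
#'
#' @param name Parameter name.
#' @param lower,upper Bounds with `lower < upper`.
#' @param law `"uniform"` or `"log_uniform"`.
#' @return A one-row tibble; bind rows to build a full specification table.
#' @examples
#' specs <- dplyr::bind_rows(
#'   param_spec("k1", 1e-2, 1e2, "log_uniform"),
#'   param_spec("k2", 0, 1)
#' )
#' @export
param_spec <- function(name, lower, upper, law = c("uniform", "log_uniform")) {
  law <- match.arg(law)
  if (!is_scalar_number(lower) || !is_scalar_number(upper) || lower >= upper) {
    stop_validation("bounds must satisfy lower < upper")
  }
  if (law == "log_uniform" && lower <= 0) {
    stop_validation("log_uniform requires lower > 0")
  }
  tibble::tibble(name = name, lower = lower, upper = upper, law = law)
}

validate_specs <- function(specs) {
  specs <- tibble::as_tibble(specs)
  need <- c("name", "lower", "upper", "law")
  if (!all(need %in% names(specs))) {
    stop_validation("specs must have columns name, lower, upper, law")
  }
  if (nrow(specs) < 1) stop_validation("at least one parameter spec required")
  if (anyDuplicated(specs$name) > 0) stop_validation("duplicate parameter names")
  for (i in seq_len(nrow(specs))) {
    param_spec(specs$name[i], specs$lower[i], specs$upper[i], specs$law[i])
  }
  specs
}

#' Convenience search space around a set of rates
#'
#' Log-uniform bounds spanning `factor` below to `factor` above each rate,
#' the package's default search space for parameter-recovery benchmarks.
#'
#' @param rates Named numeric vector of positive reference rates.
#' @param factor Multiplicative half-width of the search space (default 10,
#'   i.e. two decades per parameter).
#' @return A parameter-spec tibble (see [param_spec()]).
#' @export
param_specs_around <- function(rates, factor = 10) {
  if (any(rates <= 0)) stop_validation("rates must be positive")
  dplyr::bind_rows(lapply(names(rates), function(nm) {
    param_spec(nm, rates[[nm]] / factor, rates[[nm]] * factor, "log_uniform")
  }))
}

draw_matrix <- function(specs, k) {
  cols <- lapply(seq_len(nrow(specs)), function(i) {
    if (specs$law[i] == "log_uniform") {
      10^runif(k, log10(specs$lower[i]), log10(specs$upper[i]))
    } else {
      runif(k, specs$lower[i], specs$upper[i])
    }
  })
  mx <- do.call(cbind, cols)
  colnames(mx) <- specs$name
  mx
}

#' Initialise a GA population
#'
#' Draws `pop_size` independent parameter vectors from the sampling law of
#' each [param_spec()]. Deterministic given `seed`.
#'
#' @param specs Parameter-spec tibble.
#' @param pop_size Population size `P >= 1`.
#' @param seed Integer seed.
#' @return A tibble with column `id` and one column per parameter.
#' @export
initialize_population <- function(specs, pop_size, seed = 1) {
  specs <- validate_specs(specs)
  if (!is_scalar_number(pop_size) || pop_size < 1) {
    stop_validation("pop_size must be >= 1")
  }
  mx <- withr::with_seed(seed, draw_matrix(specs, pop_size))
  dplyr::bind_cols(tibble::tibble(id = seq_len(pop_size)), tibble::as_tibble(mx))
}

#' Inverse-rank selection probabilities
#'
#' Under inverse-rank parent selection the individual with rank `r_i` in a
#' population of `R` is selected with probability
#' `p_i = 1 / (r_i * sum_j 1/r_j)`, i.e. proportional to the reciprocal rank.
#' For `R = 100` the first two ranks get 19.28% and 9.64%.
#'
#' @param R Population size.
#' @return Numeric probability vector of length `R` summing to 1.
#' @examples
#' round(100 * inverse_rank_probabilities(100)[1:2], 2)
#' @export
inverse_rank_probabilities <- function(R) {
  if (!is_scalar_number(R) || R < 1) stop_validation("R must be >= 1")
  r <- seq_len(R)
  1 / (r * sum(1 / r))
}

#' Select two parents from a ranked population
#'
#' Strategy 1 draws both parents uniformly (with replacement, so
#' self-recombination is allowed) from the top-`elite` individuals.
#' Strategies 2 and 3 draw two distinct parents from the whole population with
#' [inverse_rank_probabilities()]. Uses the current RNG stream.
#'
#' @param ranked_ids Individual ids in rank order (best first).
#' @param strategy 1, 2 or 3.
#' @param elite Elite size (strategy 1 only).
#' @return Length-2 vector of parent ids.
#' @export
select_parents <- function(ranked_ids, strategy = 1, elite = 10) {
  R <- length(ranked_ids)
  if (R < 1) stop_validation("ranked_ids must be non-empty")
  if (strategy == 1) {
    e <- min(elite, R)
    ranked_ids[sample.int(e, 2, replace = TRUE)]
  } else {
    if (R < 2) stop_validation("inverse-rank selection needs at least 2 individuals")
    p <- inverse_rank_probabilities(R)
    ranked_ids[sample.int(R, 2, replace = FALSE, prob = p)]
  }
}

#' Recombine two parameter vectors
#'
#' `"single_point"` cuts at a uniform position `k` in `1..(d-1)` and takes the
#' first `k` genes from `a`, the rest from `b` (for `d = 1`, a fair coin picks
#' one parent). `"multi_point"` copies each gene independently from `a` or `b`
#' with probability one half. Uses the current RNG stream.
#'
#' @param a,b Numeric parameter vectors of equal length.
#' @param mode `"single_point"` or `"multi_point"`.
#' @return The child parameter vector.
#' @export
crossover <- function(a, b, mode = c("single_point", "multi_point")) {
  mode <- match.arg(mode)
  if (length(a) != length(b)) stop_validation("parents must share the parameter space")
  d <- length(a)
  if (mode == "single_point") {
    if (d == 1) return(if (runif(1) < 0.5) a else b)
    k <- sample.int(d - 1, 1)
    c(a[seq_len(k)], b[(k + 1):d])
  } else {
    pick <- runif(d) < 0.5
    ifelse(pick, a, b)
  }
}

#' Mutate a parameter vector
#'
#' `"redraw"` replaces each gene, independently with probability `prob`, by a
#' fresh draw from its sampling law. `"factor"` multiplies, with probability
#' `prob`, by a uniform factor in `[1 - halfwidth, 1 + halfwidth]` and clips
#' to the bounds. The mutation probability is applied per parameter. Uses the
#' current RNG stream.
#'
#' @param x Numeric parameter vector within bounds.
#' @param specs Parameter-spec tibble.
#' @param mode `"redraw"` or `"factor"`.
#' @param prob Per-parameter mutation probability.
#' @param halfwidth Half-width of the factor interval (default 0.10).
#' @return The mutated vector, still within bounds.
#' @export
mutate_params <- function(x, specs, mode = c("redraw", "factor"), prob,
                          halfwidth = 0.10) {
  mode <- match.arg(mode)
  d <- length(x)
  hit <- runif(d) < prob
  if (!any(hit)) return(x)
  if (mode == "redraw") {
    fresh <- draw_matrix(specs, 1)[1, ]
    x[hit] <- fresh[hit]
  } else {
    f <- runif(d, 1 - halfwidth, 1 + halfwidth)
    x[hit] <- x[hit] * f[hit]
    x <- pmin(pmax(x, specs$lower), specs$upper)
  }
  x
}

#' Rank a population on one or several objectives
#'
#' Single objective: ascending order of fitness (minimisation). Several
#' objectives: unweighted sum of per-objective ranks (see [sum_of_ranks()]).
#' Ties are always broken by individual id, making the ordering stable and
#' deterministic; `+Inf` sentinel fitnesses (failed simulations) rank last.
#'
#' @param fm Data frame or matrix of fitness values, individuals in rows,
#'   objectives in columns.
#' @param ids Individual ids (default row order).
#' @return A tibble `(id, score, rank)` sorted by rank, where `score` is the
#'   rank sum (equal to the per-objective rank for a single objective).
#' @export
rank_population <- function(fm, ids = NULL) {
  sum_of_ranks(fm, ids)
}

#' Genetic-algorithm configuration
#'
#' Bundles the population design, the search strategy, and the fitness
#' objectives. The three built-in strategies are:
#'
#' * Strategy 1 (elitist): the top-`elite` individuals and their cached
#'   simulations/fitness carry over unchanged; both parents are drawn
#'   uniformly from the elite (self-recombination allowed); single-point
#'   crossover; per-parameter redraw mutation with probability 0.30.
#' * Strategy 2 (non-elitist): two distinct parents drawn from the whole
#'   population with inverse-rank probabilities; single-point crossover;
#'   redraw mutation 0.30. Elitism is off by default but available.
#' * Strategy 3: as strategy 2 but multi-point crossover and factor mutation
#'   (probability 0.20, factor within ±10% of the old value).
#'
#' One objective id gives a single-objective GA; several give a
#' multi-objective GA ranked by unweighted rank sums.
#'
#' @param objectives Character vector from [objective_ids()] /
#'   [equivalence_ids()].
#' @param strategy 1, 2 or 3.
#' @param pop_size,elite,iterations,n_sims Population size `P`, elite size
#'   `E` (`1 <= E < P`), iteration count `G`, and stochastic simulations per
#'   candidate.
#' @param crossover,mutation Operator overrides; defaults follow the strategy.
#'   `mutation` is a list `list(mode =, prob =, halfwidth =)`.
#' @param elitism Logical; default `TRUE` for strategy 1, `FALSE` otherwise.
#' @param alpha,range,band,range_scope Equivalence-test settings (see
#'   [equivalence_settings()]).
#' @param seed Root seed; every stream used by the run derives from it.
#' @param workers Parallel simulation workers (see [dispatch()]).
#' @param max_events SSA event cap per simulation passed to builtin backends.
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(objectives = "SDA", strategy = 1, pop_size = 100,
                      elite = 10, iterations = 100, n_sims = 10,
                      crossover = NULL, mutation = NULL, elitism = NULL,
                      alpha = 0.05, range = "1sd", band = c(0.19, 0.76),
                      range_scope = "cell",
                      seed = 1, workers = 1, max_events = 2e7) {
  if (!strategy %in% 1:3) stop_validation("strategy must be 1, 2 or 3")
  ok <- c(objective_ids(), equivalence_ids())
  bad <- setdiff(objectives, ok)
  if (length(bad) > 0) {
    stop_validation(paste0("unknown objective(s): ", paste(bad, collapse = ", ")))
  }
  if (elite < 1 || elite >= pop_size) stop_validation("need 1 <= elite < pop_size")
  if (iterations < 1 || n_sims < 1) stop_validation("iterations and n_sims must be >= 1")
  crossover <- crossover %||% if (strategy == 3) "multi_point" else "single_point"
  mutation <- mutation %||% if (strategy == 3) {
    list(mode = "factor", prob = 0.20, halfwidth = 0.10)
  } else {
    list(mode = "redraw", prob = 0.30)
  }
  mutation$halfwidth <- mutation$halfwidth %||% 0.10
  elitism <- elitism %||% (strategy == 1)
  structure(list(
    objectives = objectives, strategy = strategy, pop_size = pop_size,
    elite = elite, iterations = iterations, n_sims = n_sims,
    crossover = crossover, mutation = mutation, elitism = elitism,
    alpha = alpha, range = range, band = band, range_scope = range_scope,
    seed = seed, workers = workers, max_events = max_events
  ), class = "ga_config")
}

# score one candidate's simulation tensor against the precomputed cells;
# a failed simulation carries the +Inf sentinel on every objective
score_candidate <- function(sarr, cells, objectives, settings) {
  if (is.null(sarr)) {
    return(setNames(rep(Inf, length(objectives)), objectives))
  }
  vals <- numeric(length(objectives))
  for (k in seq_along(objectives)) {
    ob <- objectives[k]
    if (ob %in% equivalence_ids()) {
      fails <- 0L
      for (cell in cells) {
        s <- sarr[, cell$t, cell$v]
        ok <- tryCatch(switch(ob,
          TOST = tost_cell(cell$e, s, cell$eps, settings$alpha),
          DUT = dut_cell(cell$e, s, cell$eps, settings$alpha),
          WMWET = wmwet_cell(cell$e, s, settings$band, settings$alpha)
        ), error = function(err) FALSE)
        if (!ok) fails <- fails + 1L
      }
      vals[k] <- fails
    } else {
      tot <- 0
      for (cell in cells) {
        tot <- tot + tryCatch(
          cell_objective(ob, cell$e, sarr[, cell$t, cell$v]),
          stochcal_error_degenerate = function(err) 0,  # skipped cell
          error = function(err) Inf
        )
      }
      vals[k] <- tot
    }
  }
  setNames(vals, objectives)
}

#' Calibrate a model against replicated experimental data
#'
#' Runs the genetic algorithm: the population of candidate parameter vectors
#' is simulated through `backend`, scored on the configured objectives
#' against `data`, ranked, and bred by selection, recombination and mutation
#' for `iterations` generations. Under elitism the elite's individuals and
#' their cached fitness carry over unchanged (elite simulations are never
#' repeated), which makes the running-best fitness non-increasing by
#' construction for single-objective runs — asserted on every such run. The
#' whole run is reproducible from `config$seed` and independent of the worker
#' count.
#'
#' @param data An [as_experiment_data()] tibble (or coercible data frame).
#' @param specs Parameter-spec tibble ([param_spec()]).
#' @param config A [ga_config()].
#' @param backend A simulator backend such as [builtin_backend()]: a function
#'   `(params, n_sims, times, seed)` returning an `n x T x V` array whose
#'   third dimension is named by the data's observables. A backend error for
#'   a candidate yields the `+Inf` sentinel fitness; the run continues.
#' @return An object of class `calibration` with elements `history`
#'   (per-iteration population tibble), `per_iter` (per-iteration best and
#'   elite-mean fitness), `best` (final top-ranked individual), `specs`,
#'   `config`. Use [tidy()], [glance()], [autoplot()] and
#'   [parameter_recovery()] on it.
#' @export
calibrate <- function(data, specs, config, backend) {
  data <- as_experiment_data(data)
  specs <- validate_specs(specs)
  stopifnot(inherits(config, "ga_config"))
  d <- nrow(specs)
  P <- config$pop_size
  E <- config$elite
  K <- length(config$objectives)
  times <- attr(data, "times")
  obs <- attr(data, "observables")

  eq_used <- any(config$objectives %in% equivalence_ids())
  settings <- equivalence_settings(
    test = if (eq_used) intersect(config$objectives, equivalence_ids())[1] else "TOST",
    alpha = config$alpha, range = config$range, band = config$band,
    range_scope = config$range_scope
  )

  earr <- ed_tensor(data)
  grid <- expand.grid(t = seq_along(times), v = seq_along(obs))
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    e <- earr[, grid$t[i], grid$v[i]]
    list(t = grid$t[i], v = grid$v[i], e = e,
         eps = cell_epsilon(settings, e, as.vector(earr[, , grid$v[i]])))
  })

  pop <- as.matrix(initialize_population(specs, P, derive_seed(config$seed, "init"))[specs$name])
  ids <- seq_len(P)
  next_id <- P + 1L
  fitness <- matrix(NA_real_, P, K, dimnames = list(NULL, config$objectives))

  history <- vector("list", config$iterations)
  per_iter <- vector("list", config$iterations)
  prev_best <- rep(Inf, K)
  obs_checked <- FALSE

  for (iter in seq_len(config$iterations)) {
    need <- which(!stats::complete.cases(fitness))
    if (length(need) > 0) {
      jobs <- lapply(need, function(i) {
        params <- setNames(pop[i, ], specs$name)
        sim_seed <- derive_seed(config$seed, "sim", ids[i])
        function() backend(params, config$n_sims, times, sim_seed)
      })
      results <- dispatch(jobs, workers = config$workers)
      for (j in seq_along(need)) {
        res <- results[[j]]
        sarr <- if (inherits(res, "dispatch_failure")) NULL else res
        if (!is.null(sarr) && !obs_checked) {
          if (!identical(dimnames(sarr)[[3]], obs)) {
            stop_align("backend observables do not match the experimental data")
          }
          obs_checked <- TRUE
        }
        fitness[need[j], ] <- score_candidate(sarr, cells, config$objectives, settings)
      }
    }
    if (all(!is.finite(fitness[, 1]))) {
      abort("all candidates failed simulation in one iteration; aborting calibration")
    }

    ranked <- rank_population(fitness, ids)
    ord <- match(ranked$id, ids)

    history[[iter]] <- dplyr::bind_cols(
      tibble::tibble(iteration = iter, id = ids[ord], rank = seq_len(P)),
      tibble::as_tibble(pop[ord, , drop = FALSE]),
      tibble::as_tibble(fitness[ord, , drop = FALSE])
    )
    elite_rows <- ord[seq_len(E)]
    per_iter[[iter]] <- tibble::tibble(
      iteration = iter,
      objective = config$objectives,
      best = unname(fitness[ord[1], ]),
      elite_mean = unname(colMeans(fitness[elite_rows, , drop = FALSE]))
    )

    if (config$elitism && K == 1) {
      # elitism with cached elite fitness makes this exact, not approximate
      if (fitness[ord[1], 1] > prev_best[1] + 1e-12) {
        abort("internal invariant violated: running-best fitness increased under elitism")
      }
      prev_best[1] <- fitness[ord[1], 1]
    }

    if (iter == config$iterations) break

    n_keep <- if (config$elitism) E else 0L
    n_off <- P - n_keep
    breed <- withr::with_seed(derive_seed(config$seed, "ops", iter), {
      kids <- matrix(NA_real_, n_off, d)
      for (k in seq_len(n_off)) {
        parents <- select_parents(ranked$id, config$strategy, E)
        pa <- pop[match(parents[1], ids), ]
        pb <- pop[match(parents[2], ids), ]
        child <- crossover(pa, pb, config$crossover)
        kids[k, ] <- mutate_params(child, specs, config$mutation$mode,
                                   config$mutation$prob, config$mutation$halfwidth)
      }
      kids
    })

    if (n_keep > 0) {
      keep_rows <- ord[seq_len(n_keep)]
      pop <- rbind(pop[keep_rows, , drop = FALSE], breed)
      fitness <- rbind(fitness[keep_rows, , drop = FALSE],
                       matrix(NA_real_, n_off, K))
      ids <- c(ids[keep_rows], seq.int(next_id, length.out = n_off))
    } else {
      pop <- breed
      fitness <- matrix(NA_real_, n_off, K, dimnames = list(NULL, config$objectives))
      ids <- seq.int(next_id, length.out = n_off)
    }
    colnames(fitness) <- config$objectives
    colnames(pop) <- specs$name
    next_id <- next_id + n_off
  }

  final <- history[[config$iterations]]
  best_row <- final[final$rank == 1, ]
  structure(list(
    history = dplyr::bind_rows(history),
    per_iter = dplyr::bind_rows(per_iter),
    best = list(
      id = best_row$id,
      params = setNames(as.numeric(best_row[1, specs$name]), specs$name),
      fitness = setNames(as.numeric(best_row[1, config$objectives]), config$objectives)
    ),
    specs = specs, config = config
  ), class = "calibration")
}

#' Fractional error of a convergence history
#'
#' Normalises a per-iteration elite mean fitness series by its value at the
#' first iteration, so convergence can be compared across objectives with
#' different scales. For a `calibration` object the series is taken from its
#' per-iteration elite means (one series per objective).
#'
#' @param x Numeric series, or a [calibrate()] result.
#' @return A tibble `(iteration, objective, fractional_error)`; for a bare
#'   numeric series the objective column is `"fitness"`.
#' @export
fractional_error <- function(x) {
  if (inherits(x, "calibration")) {
    out <- dplyr::group_by(x$per_iter, .data$objective)
    out <- dplyr::mutate(out, fractional_error = {
      if (.data$elite_mean[1] == 0) {
        stop_degenerate("first-iteration mean fitness is zero; fractional error undefined")
      }
      .data$elite_mean / .data$elite_mean[1]
    })
    return(dplyr::ungroup(out)[c("iteration", "objective", "fractional_error")])
  }
  if (length(x) < 1 || x[1] == 0) {
    stop_degenerate("first entry must be non-zero")
  }
  tibble::tibble(iteration = seq_along(x), objective = "fitness",
                 fractional_error = x / x[1])
}

#' Percent error of recovered parameters against known true rates
#'
#' @param result A [calibrate()] result.
#' @param truth Named numeric vector of true rates.
#' @return A tibble `(parameter, truth, estimate, percent_error)` where
#'   `percent_error = 100 * (estimate / truth - 1)`.
#' @export
parameter_recovery <- function(result, truth) {
  stopifnot(inherits(result, "calibration"))
  est <- result$best$params[names(truth)]
  tibble::tibble(
    parameter = names(truth),
    truth = as.numeric(truth),
    estimate = as.numeric(est),
    percent_error = 100 * (as.numeric(est) / as.numeric(truth) - 1)
  )
}
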