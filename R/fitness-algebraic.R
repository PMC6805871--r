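#' Supported fitness-function identifiers
#'
#' `objective_ids()` lists the nine algebraic objectives, `equivalence_ids()`
#' the three iterative equivalence tests; all twelve can be used (alone or
#' combined) to rank candidate models. Every objective is non-negative and
#' minimised; a perfect fit scores zero (where the objective is defined).
#'
#' @return Character vector of identifiers.
#' @export
objective_ids <- function() {
  c("SDA", "ADA", "PWSD", "APWSD", "NPWSD", "ANPWSD", "SSQ", "CHISQ", "MNSE")
}

#' @rdname objective_ids
#' @export
equivalence_ids <- function() c("TOST", "DUT", "WMWET")

#' Evaluate one algebraic objective on a single data cell
#'
#' A "cell" is one (observable, time point) combination: `m` experimental
#' replicate values against `n` simulated values. The nine objectives are
#'
#' * `SDA`   — squared difference of the two averages,
#' * `ADA`   — absolute difference of the two averages,
#' * `PWSD`  — mean pairwise squared deviation, `(1/mn) sum (exp_i - sim_j)^2`,
#' * `APWSD` — mean pairwise absolute deviation,
#' * `NPWSD` — pairwise squared deviation normalised by `exp_i`,
#' * `ANPWSD`— pairwise absolute deviation normalised by `exp_i`,
#' * `SSQ`   — raw pairwise sum of squares (no `1/mn`),
#' * `CHISQ` — pairwise sum of squares standardised by the replicate SD,
#' * `MNSE`  — pairwise sum of squares normalised by the replicate mean.
#'
#' `NPWSD`/`ANPWSD` terms with `exp_i = 0` are skipped and the `1/(mn)`
#' divisor reduced to the count of retained terms; a cell whose experimental
#' values are all zero contributes 0 with a warning. `CHISQ` requires a
#' positive replicate SD and `MNSE` a non-zero replicate mean.
#'
#' @param name One of [objective_ids()].
#' @param exp Numeric vector of `m >= 1` experimental values.
#' @param sim Numeric vector of `n >= 1` simulated values.
#' @return A non-negative scalar.
#' @examples
#' cell_objective("PWSD", exp = c(1, 3), sim = c(2, 2))
#' @export
cell_objective <- function(name, exp, sim) {
  if (!name %in% objective_ids()) {
    stop_validation(paste0("unknown objective '", name, "'"))
  }
  if (length(exp) < 1 || length(sim) < 1) stop_validation("m >= 1 and n >= 1 required")
  if (!all(is.finite(exp)) || !all(is.finite(sim))) {
    stop_validation("values must be finite")
  }
  m <- length(exp)
  n <- length(sim)
  dif <- outer(exp, sim, "-")
  switch(name,
    SDA = (mean(exp) - mean(sim))^2,
    ADA = abs(mean(exp) - mean(sim)),
    PWSD = sum(dif^2) / (m * n),
    APWSD = sum(abs(dif)) / (m * n),
    NPWSD = ,
    ANPWSD = {
      keep <- exp != 0
      if (!any(keep)) {
        warn("all experimental values zero; normalised pairwise cell contributes 0")
        return(0)
      }
      term <- dif[keep, , drop = FALSE] / exp[keep]
      if (name == "NPWSD") sum(term^2) / (sum(keep) * n) else sum(abs(term)) / (sum(keep) * n)
    },
    SSQ = sum(dif^2),
    CHISQ = {
      s <- sd(exp)
      if (m < 2 || !is.finite(s) || s == 0) {
        stop_degenerate("CHISQ requires a positive experimental standard deviation")
      }
      sum((dif / s)^2)
    },
    MNSE = {
      mb <- mean(exp)
      if (mb == 0) stop_degenerate("MNSE requires a non-zero experimental mean")
      sum((dif / mb)^2)
    }
  )
}

#' Per-cell fitness contributions
#'
#' Evaluates one or more objectives on every (observable, time point) cell of
#' an aligned data/simulation pair. Algebraic objectives contribute their cell
#' value; equivalence objectives contribute 1 for a cell whose equivalence
#' test failed and 0 otherwise, so that summing the column reproduces the
#' iterative equivalence score.
#'
#' @param data An [as_experiment_data()] tibble.
#' @param sims An [as_sim_ensemble()] tibble aligned to `data`.
#' @param objectives Character vector drawn from [objective_ids()] and
#'   [equivalence_ids()].
#' @param settings An [equivalence_settings()] list used by the equivalence
#'   objectives (defaults if `NULL`).
#' @return A tibble `(observable, time, objective, value)`.
#' @export
fitness_cells <- function(data, sims, objectives, settings = NULL) {
  data <- as_experiment_data(data)
  sims <- as_sim_ensemble(sims)
  check_aligned(data, sims)
  earr <- ed_tensor(data)
  sarr <- se_tensor(sims)
  times <- attr(data, "times")
  obs <- attr(data, "observables")

  rows <- list()
  for (ob in objectives) {
    if (ob %in% equivalence_ids()) {
      st <- settings %||% equivalence_settings(test = ob)
      st$test <- ob
      mat <- rejection_matrix(data, sims, st)
      rows[[ob]] <- tibble::tibble(
        observable = mat$observable, time = mat$time,
        objective = ob, value = as.numeric(!mat$equivalent)
      )
    } else {
      grid <- expand.grid(t = seq_along(times), v = seq_along(obs))
      val <- mapply(function(t, v) {
        tryCatch(cell_objective(ob, earr[, t, v], sarr[, t, v]),
                 stochcal_error_degenerate = function(e) NA_real_)
      }, grid$t, grid$v)
      if (anyNA(val)) {
        warn(paste0(sum(is.na(val)), " degenerate cell(s) skipped for ", ob,
                    " (contribute 0)"))
        val[is.na(val)] <- 0
      }
      rows[[ob]] <- tibble::tibble(
        observable = obs[grid$v], time = times[grid$t],
        objective = ob, value = val
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Aggregate fitness of a candidate's simulations against data
#'
#' Unweighted sum of the per-cell contributions over all observables and
#' time points (see [fitness_cells()]); for equivalence objectives this is the
#' iterative equivalence score (count of failed cells).
#'
#' @inheritParams fitness_cells
#' @return A tibble `(objective, value)` with one row per objective.
#' @examples
#' \donttest{
#' net <- aguilera_network()
#' data <- generate_synthetic_dataset(net, n_replicates = 3, seed = 1)
#' sims <- simulate_ensemble(net, n = 5, t_grid = seq(0, 200, by = 20), seed = 2)
#' fitness_score(data, sims, c("SDA", "PWSD"))
#' }
#' @export
fitness_score <- function(data, sims, objectives, settings = NULL) {
  cells <- fitness_cells(data, sims, objectives, settings)
  out <- dplyr::summarise(dplyr::group_by(cells, .data$objective),
                          value = sum(.data$value), .groups = "drop")
  out[match(objectives, out$objective), ]
}
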