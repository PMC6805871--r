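#' Leave-one-out jackknife over data units
#'
#' Repeats the full calibration once per left-out unit (a replicate or a time
#' point), each sub-run on the reduced dataset with its own derived seed. The
#' spread of the per-unit estimates measures how strongly each data unit
#' pulls the calibrated parameters. The default unit is the replicate, the
#' sampling unit inside every fitness function.
#'
#' @inheritParams calibrate
#' @param unit `"replicate"` or `"timepoint"`.
#' @return A tibble of class `jackknife_estimates` with columns
#'   `(unit, seed, parameter, estimate)`; a sub-calibration that fails
#'   entirely is recorded as `NA` with a warning.
#' @export
jackknife_calibrations <- function(data, specs, config, backend,
                                   unit = c("replicate", "timepoint")) {
  unit <- match.arg(unit)
  data <- as_experiment_data(data)
  specs <- validate_specs(specs)
  units <- if (unit == "replicate") attr(data, "replicates") else attr(data, "times")
  if (length(units) < 3) stop_validation("need at least 3 leave-out units")

  rows <- lapply(seq_along(units), function(i) {
    u <- units[i]
    reduced <- if (unit == "replicate") {
      data[data$replicate != u, , drop = FALSE]
    } else {
      data[data$time != u, , drop = FALSE]
    }
    sub_config <- config
    sub_config$seed <- derive_seed(config$seed, "jackknife", i)
    est <- tryCatch(
      calibrate(as_experiment_data(reduced), specs, sub_config, backend)$best$params,
      error = function(e) {
        warn(paste0("jackknife sub-calibration for unit ", format(u), " failed: ",
                    conditionMessage(e)))
        setNames(rep(NA_real_, nrow(specs)), specs$name)
      }
    )
    tibble::tibble(unit = u, seed = sub_config$seed,
                   parameter = names(est), estimate = as.numeric(est))
  })
  structure(dplyr::bind_rows(rows), unit = unit,
            class = c("jackknife_estimates", class(tibble::tibble())))
}

#' Bootstrap parameter uncertainty over repeated GA runs
#'
#' Runs `n_runs` calibrations, each on a dataset whose replicates are
#' resampled with replacement (size `m`) and with its own derived seed, plus
#' one baseline calibration on the full data for the point estimate. Per
#' parameter, a percentile interval at the requested level summarises the
#' run-to-run spread. With `n_runs` runs the percentile resolution is
#' `1/(n_runs + 1)`, which bounds the usable confidence level (20 runs allow
#' at most 90%); the report records this. GA noise can place the point
#' estimate outside the interval; the interval is not forced to contain it.
#'
#' @inheritParams calibrate
#' @param n_runs Number of bootstrap GA runs (`>= 2`).
#' @param level Confidence level for the percentile interval.
#' @return A list of class `uncertainty_report`: `point` (named vector),
#'   `estimates` tibble `(run, seed, parameter, estimate)`, `intervals`
#'   tibble `(parameter, lower, point, upper, level)`, `resolution`.
#' @export
bootstrap_calibrations <- function(data, specs, config, backend,
                                   n_runs = 20, level = 0.90) {
  data <- as_experiment_data(data)
  specs <- validate_specs(specs)
  if (n_runs < 2) stop_validation("n_runs must be >= 2 (no interval from one run)")
  resolution <- 1 / (n_runs + 1)
  if (level > 1 - 2 * resolution) {
    warn(paste0("level ", level, " exceeds the resolution of ", n_runs,
                " runs; intervals are extrapolated percentiles"))
  }
  reps <- attr(data, "replicates")
  m <- length(reps)

  base_config <- config
  base_config$seed <- derive_seed(config$seed, "bootstrap", 0)
  point <- calibrate(data, specs, base_config, backend)$best$params

  rows <- lapply(seq_len(n_runs), function(r) {
    run_seed <- derive_seed(config$seed, "bootstrap", r)
    draw <- withr::with_seed(derive_seed(run_seed, "resample"),
                             sample(reps, m, replace = TRUE))
    pieces <- lapply(seq_along(draw), function(k) {
      piece <- data[data$replicate == draw[k], , drop = FALSE]
      piece$replicate <- k
      piece
    })
    boot_data <- as_experiment_data(dplyr::bind_rows(pieces))
    sub_config <- config
    sub_config$seed <- run_seed
    est <- tryCatch(
      calibrate(boot_data, specs, sub_config, backend)$best$params,
      error = function(e) {
        warn(paste0("bootstrap run ", r, " failed: ", conditionMessage(e)))
        setNames(rep(NA_real_, nrow(specs)), specs$name)
      }
    )
    tibble::tibble(run = r, seed = run_seed,
                   parameter = names(est), estimate = as.numeric(est))
  })
  estimates <- dplyr::bind_rows(rows)

  report <- structure(
    list(point = point, estimates = estimates, intervals = NULL,
         resolution = resolution),
    class = "uncertainty_report"
  )
  report$intervals <- bootstrap_interval(report, level)
  report
}

#' Percentile interval at a given level from a bootstrap report
#'
#' Recomputes the per-parameter percentile interval from the stored run
#' estimates, so intervals at several levels can be compared; intervals are
#' nested in the level by construction of the quantile function.
#'
#' @param report An `uncertainty_report` from [bootstrap_calibrations()].
#' @param level Confidence level.
#' @return A tibble `(parameter, lower, point, upper, level)`.
#' @export
bootstrap_interval <- function(report, level = 0.90) {
  stopifnot(inherits(report, "uncertainty_report"))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- dplyr::summarise(
    dplyr::group_by(report$estimates, .data$parameter),
    lower = quantile(.data$estimate, probs[1], na.rm = TRUE, names = FALSE),
    upper = quantile(.data$estimate, probs[2], na.rm = TRUE, names = FALSE),
    .groups = "drop"
  )
  out$point <- as.numeric(report$point[out$parameter])
  out$level <- level
  out[c("parameter", "lower", "point", "upper", "level")]
}
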