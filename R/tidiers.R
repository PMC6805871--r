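#' Tidy a calibration result
#'
#' Returns the full per-iteration population history: one row per individual
#' per iteration with its parameters, per-objective fitness and rank.
#'
#' @param x A [calibrate()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.calibration <- function(x, ...) {
  x$history
}

#' One-row summary of a calibration
#'
#' @param x A [calibrate()] result.
#' @param ... Unused.
#' @return A one-row tibble with the run design, the best individual's id and
#'   fitness per objective, and its parameter estimates.
#' @export
glance.calibration <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(
      strategy = x$config$strategy,
      pop_size = x$config$pop_size,
      iterations = x$config$iterations,
      n_sims = x$config$n_sims,
      seed = x$config$seed,
      best_id = x$best$id
    ),
    tibble::as_tibble(as.list(setNames(
      x$best$fitness, paste0("fitness_", names(x$best$fitness))
    ))),
    tibble::as_tibble(as.list(x$best$params))
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat("<calibration>", x$config$iterations, "iterations, population",
      x$config$pop_size, "\n")
  cat("objectives:", paste(x$config$objectives, collapse = ", "),
      "| strategy", x$config$strategy, "\n")
  cat("best individual", x$best$id, "with fitness",
      paste(sprintf("%s = %g", names(x$best$fitness), x$best$fitness),
            collapse = ", "), "\n")
  print(tibble::as_tibble(as.list(x$best$params)))
  invisible(x)
}

#' Convergence plot of a calibration
#'
#' Best and elite-mean fitness per iteration, one panel per objective.
#'
#' @param object A [calibrate()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.calibration <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_iter, c("best", "elite_mean"),
                              names_to = "series", values_to = "fitness")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$fitness,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$objective), scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "fitness (minimised)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Tile plot of a rejection matrix
#'
#' @param object A [rejection_matrix()].
#' @param ... Unused.
#' @return A ggplot object; failed cells (equivalence not established) are
#'   highlighted.
#' @export
autoplot.rejection_matrix <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$status <- ifelse(!df$testable, "untestable",
                      ifelse(df$equivalent, "equivalent", "rejected"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$time), y = .data$observable,
                                   fill = .data$status)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(equivalent = "#4daf4a",
                                          rejected = "#e41a1c",
                                          untestable = "grey70")) +
    ggplot2::labs(x = "time", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Tidy bootstrap uncertainty estimates
#'
#' @param x An `uncertainty_report` from [bootstrap_calibrations()].
#' @param ... Unused.
#' @return The per-run estimates tibble.
#' @export
tidy.uncertainty_report <- function(x, ...) {
  x$estimates
}

#' One-row-per-parameter summary of an uncertainty report
#'
#' @param x An `uncertainty_report`.
#' @param ... Unused.
#' @return The intervals tibble `(parameter, lower, point, upper, level)`.
#' @export
glance.uncertainty_report <- function(x, ...) {
  x$intervals
}

#' Interval plot of bootstrap parameter uncertainty
#'
#' @param object An `uncertainty_report`.
#' @param ... Unused.
#' @return A ggplot object with one percentile interval and point estimate
#'   per parameter (log scale, as rates usually span decades).
#' @export
autoplot.uncertainty_report <- function(object, ...) {
  ggplot2::ggplot(object$intervals,
                  ggplot2::aes(x = .data$parameter, y = .data$point)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower, ymax = .data$upper)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}
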