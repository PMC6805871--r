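#' Validate a replicated experimental time series
#'
#' An `experiment_data` object is a long tibble with columns `replicate`,
#' `time`, `observable`, `value` holding `m` replicated measurements of `V`
#' observables on a common grid of `T` time points. It is the experimental
#' side of every fitness computation: the fitness functions compare the `m`
#' replicate values of each (observable, time) cell against the `n` simulated
#' values of the same cell.
#'
#' Invariants enforced: the grid is complete (every replicate measured at
#' every time for every observable, exactly once), times are strictly
#' increasing, and all values are finite and non-negative.
#'
#' @param df A data frame with columns `replicate`, `time`, `observable`,
#'   `value`.
#' @return A tibble of class `experiment_data` with attributes `observables`
#'   (order of first appearance), `times` (sorted) and `replicates`.
#' @examples
#' df <- tidyr::expand_grid(replicate = 1:2, time = c(0, 1, 2), observable = "A")
#' df$value <- seq_len(nrow(df))
#' as_experiment_data(df)
#' @export
as_experiment_data <- function(df) {
  # always rebuild: subsetting can leave stale grid attributes behind
  df <- tibble::as_tibble(as.data.frame(df))
  need <- c("replicate", "time", "observable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_validation(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  df <- df[need]
  if (!is.numeric(df$time) || !is.numeric(df$value)) {
    stop_validation("'time' and 'value' must be numeric")
  }
  if (anyNA(df) || !all(is.finite(df$value))) {
    stop_validation("missing or non-finite cells are not allowed")
  }
  if (any(df$value < 0)) stop_validation("abundances must be non-negative")

  obs <- unique(df$observable)
  if (anyDuplicated(obs) > 0) stop_validation("duplicate observable names")
  times <- sort(unique(df$time))
  reps <- sort(unique(df$replicate))

  key <- paste(df$replicate, df$time, df$observable, sep = "\r")
  if (anyDuplicated(key) > 0) {
    stop_validation("duplicate (replicate, time, observable) measurement")
  }
  if (nrow(df) != length(reps) * length(times) * length(obs)) {
    stop_validation("incomplete grid: every replicate must cover every (time, observable)")
  }

  structure(df,
    observables = obs, times = times, replicates = reps,
    class = c("experiment_data", class(tibble::tibble()))
  )
}

#' Validate an ensemble of simulated trajectories
#'
#' The simulation-side counterpart of [as_experiment_data()]: a long tibble
#' with columns `run`, `time`, `observable`, `value` holding `n` stochastic
#' simulation runs of one candidate model, sampled on the experimental time
#' grid.
#'
#' @param df A data frame with columns `run`, `time`, `observable`, `value`.
#' @return A tibble of class `sim_ensemble` with attributes `observables`,
#'   `times` and `runs`.
#' @export
as_sim_ensemble <- function(df) {
  df <- tibble::as_tibble(as.data.frame(df))
  need <- c("run", "time", "observable", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_validation(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  df <- df[need]
  if (anyNA(df) || !all(is.finite(df$value))) {
    stop_validation("missing or non-finite cells are not allowed")
  }
  if (any(df$value < 0)) stop_validation("simulated abundances must be non-negative")
  obs <- unique(df$observable)
  times <- sort(unique(df$time))
  runs <- sort(unique(df$run))
  if (nrow(df) != length(runs) * length(times) * length(obs)) {
    stop_validation("incomplete grid: every run must cover every (time, observable)")
  }
  structure(df,
    observables = obs, times = times, runs = runs,
    class = c("sim_ensemble", class(tibble::tibble()))
  )
}

# long tibble -> (unit, time, observable) tensor; unit is replicate or run
td_tensor <- function(df, unit_col) {
  obs <- attr(df, "observables")
  times <- attr(df, "times")
  units <- sort(unique(df[[unit_col]]))
  o <- order(
    match(df$observable, obs),
    match(df$time, times),
    match(df[[unit_col]], units)
  )
  array(df$value[o],
    dim = c(length(units), length(times), length(obs)),
    dimnames = list(NULL, format(times, trim = TRUE), obs)
  )
}

ed_tensor <- function(data) td_tensor(as_experiment_data(data), "replicate")
se_tensor <- function(sims) td_tensor(as_sim_ensemble(sims), "run")

# tensor (n, T, V) -> sim_ensemble tibble
se_from_tensor <- function(arr, times, observables) {
  n <- dim(arr)[1]
  as_sim_ensemble(tibble::tibble(
    run = rep(seq_len(n), times = length(times) * length(observables)),
    time = rep(rep(times, each = n), times = length(observables)),
    observable = rep(observables, each = n * length(times)),
    value = as.vector(arr)
  ))
}

check_aligned <- function(data, sims) {
  if (!identical(attr(data, "observables"), attr(sims, "observables")) ||
      !isTRUE(all.equal(attr(data, "times"), attr(sims, "times")))) {
    stop_align("experimental data and simulations are not aligned (observables/times differ)")
  }
  invisible(TRUE)
}

#' Align a simulation ensemble to a target time grid
#'
#' Selects, for every target time, the trajectory sample whose time matches it
#' within `tol`. No interpolation is ever performed: every returned value is
#' one of the input samples. Simulator backends are required to emit the
#' experimental time points, so a target time with no matching sample is an
#' error, not an interpolation request.
#'
#' @param sims A [as_sim_ensemble()] tibble (or coercible data frame).
#' @param target_times Numeric vector of times to keep.
#' @param tol Absolute time tolerance for matching (default `1e-9`).
#' @return A `sim_ensemble` restricted to `target_times` (relabelled to the
#'   exact target values).
#' @export
align_to_times <- function(sims, target_times, tol = 1e-9) {
  sims <- as_sim_ensemble(sims)
  have <- attr(sims, "times")
  idx <- vapply(target_times, function(tt) {
    d <- abs(have - tt)
    i <- which.min(d)
    if (d[i] <= tol) i else NA_integer_
  }, integer(1))
  if (anyNA(idx)) {
    bad <- target_times[is.na(idx)]
    stop_align(paste0(
      "no trajectory sample within tol for target time(s): ",
      paste(format(bad), collapse = ", ")
    ))
  }
  matched <- have[idx]
  keep <- sims$time %in% matched
  out <- sims[keep, , drop = FALSE]
  out$time <- target_times[match(out$time, matched)]
  as_sim_ensemble(out)
}

#' Read a replicated experimental table
#'
#' Two dialects are supported. `"long"` files carry a `replicate` column, the
#' time column, and one column per observable. `"stacked"` files carry only
#' the time column plus observable columns, with the blocks of consecutive
#' rows belonging to successive replicates (each block repeats the same
#' strictly increasing time grid).
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param dialect `"long"` or `"stacked"`.
#' @param time_col Name of the time column (default `"time"`).
#' @param sep Field separator; defaults to `","` for `.csv`, tab otherwise.
#' @return An [as_experiment_data()] tibble.
#' @export
read_experimental_table <- function(path, dialect = c("long", "stacked"),
                                    time_col = "time", sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_parse(paste0("file not found: ", path))
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- read.delim(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
  if (!time_col %in% names(raw)) {
    stop_parse(paste0("missing time column '", time_col, "'"))
  }

  if (dialect == "long") {
    if (!"replicate" %in% names(raw)) stop_parse("long dialect requires a 'replicate' column")
    obs_cols <- setdiff(names(raw), c("replicate", time_col))
  } else {
    obs_cols <- setdiff(names(raw), time_col)
  }
  if (length(obs_cols) == 0) stop_parse("no observable columns found")
  for (cc in c(time_col, obs_cols)) {
    if (!is.numeric(raw[[cc]])) {
      stop_parse(paste0("non-numeric values in column '", cc, "'"))
    }
    if (anyNA(raw[[cc]])) {
      stop_parse(paste0("missing cell(s) in column '", cc, "', row(s) ",
                        paste(which(is.na(raw[[cc]])), collapse = ", ")))
    }
  }

  tt <- raw[[time_col]]
  if (dialect == "long") {
    key <- paste(raw$replicate, tt, sep = "\r")
    if (anyDuplicated(key) > 0) {
      stop_parse(paste0("duplicate (replicate, time) pair at row ",
                        which(duplicated(key))[1]))
    }
    for (r in unique(raw$replicate)) {
      tr <- tt[raw$replicate == r]
      if (any(diff(tr) <= 0)) {
        stop_parse(paste0("time column not strictly increasing within replicate ", r))
      }
    }
    replicate <- raw$replicate
  } else {
    starts <- c(1L, which(diff(tt) <= 0) + 1L)
    if (any(tt[starts[-1]] != tt[1])) {
      stop_parse("non-monotone time column (decrease without returning to the first grid time)")
    }
    block_id <- findInterval(seq_along(tt), starts)
    grid <- tt[block_id == 1L]
    if (any(diff(grid) <= 0)) stop_parse("time column not strictly increasing")
    for (b in unique(block_id)) {
      if (!identical(tt[block_id == b], grid)) {
        stop_parse(paste0("replicate block ", b, " does not repeat the time grid"))
      }
    }
    replicate <- block_id
  }

  long <- tidyr::pivot_longer(
    dplyr::mutate(raw[c(time_col, obs_cols)], replicate = replicate),
    cols = dplyr::all_of(obs_cols),
    names_to = "observable", values_to = "value"
  )
  names(long)[names(long) == time_col] <- "time"
  as_experiment_data(long[c("replicate", "time", "observable", "value")])
}

#' Write a replicated experimental table
#'
#' Inverse of [read_experimental_table()]. Values are written with 17
#' significant digits so a write-then-read round trip is bit exact.
#'
#' @param data An [as_experiment_data()] tibble.
#' @param path Output path.
#' @param dialect `"long"` or `"stacked"`.
#' @param sep Field separator; defaults to `","` for `.csv`, tab otherwise.
#' @return `path`, invisibly.
#' @export
write_experimental_table <- function(data, path, dialect = c("long", "stacked"),
                                     sep = NULL) {
  dialect <- match.arg(dialect)
  data <- as_experiment_data(data)
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  wide <- tidyr::pivot_wider(data, names_from = "observable", values_from = "value")
  wide <- dplyr::arrange(wide, .data$replicate, .data$time)
  if (dialect == "stacked") wide$replicate <- NULL
  num <- vapply(wide, is.numeric, logical(1)) & names(wide) != "replicate"
  wide[num] <- lapply(wide[num], function(x) sprintf("%.17g", x))
  write.table(wide, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
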