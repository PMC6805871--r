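#' Scan a model template for free-parameter placeholders
#'
#' Free parameters in an external simulator's model file are annotated with
#' placeholders of the form `__FREE__<name>`; the grammar is
#' simulator-language-agnostic, so any text-based model format can be
#' calibrated.
#'
#' @param template Model text (single string or character vector of lines).
#' @return Character vector of unique placeholder names.
#' @export
scan_free_parameters <- function(template) {
  text <- paste(template, collapse = "\n")
  m <- gregexpr("__FREE__([A-Za-z0-9_.]+)", text)[[1]]
  if (m[1] == -1) return(character(0))
  unique(sub("^__FREE__", "", regmatches(text, gregexpr("__FREE__[A-Za-z0-9_.]+", text))[[1]]))
}

#' Render a model template with a parameter assignment
#'
#' Substitutes every `__FREE__<name>` placeholder with the assigned value,
#' written in full-precision scientific notation (17 significant digits) so
#' the rendered model carries the exact binary value. No other bytes are
#' altered, and rendering is deterministic.
#'
#' @param template Model text with placeholders.
#' @param assignment Named numeric vector; names must exactly match the
#'   placeholder inventory (an unknown placeholder or an unused assignment is
#'   an error naming the offenders).
#' @return The rendered model text (single string).
#' @examples
#' render_model("rate 'k1' __FREE__k1", c(k1 = 0.03))
#' @export
render_model <- function(template, assignment) {
  text <- paste(template, collapse = "\n")
  found <- scan_free_parameters(text)
  missing <- setdiff(found, names(assignment))
  unused <- setdiff(names(assignment), found)
  if (length(missing) > 0 || length(unused) > 0) {
    stop_validation(paste0(
      "template/assignment mismatch",
      if (length(missing) > 0) paste0("; unassigned placeholder(s): ",
                                      paste(missing, collapse = ", ")) else "",
      if (length(unused) > 0) paste0("; unused assignment(s): ",
                                     paste(unused, collapse = ", ")) else ""
    ))
  }
  for (nm in found[order(-nchar(found))]) {
    text <- gsub(paste0("__FREE__", nm), sprintf("%.17e", assignment[[nm]]),
                 text, fixed = TRUE)
  }
  text
}

#' Parse a simulator output table
#'
#' Understands the three output dialects of the supported simulators:
#' `"gdat"` (whitespace-separated, header line starting with `#`, first
#' column time), `"kasim_csv"` (comma-separated with a quoted header, first
#' column the time tracker) and `"tsv"` (plain header plus time column).
#'
#' @param x Path to an output file, or the output text itself (anything
#'   containing a newline is treated as text).
#' @param dialect `"gdat"`, `"kasim_csv"` or `"tsv"`.
#' @return A tibble with a `time` column and one numeric column per
#'   observable.
#' @export
parse_sim_table <- function(x, dialect = c("gdat", "kasim_csv", "tsv")) {
  dialect <- match.arg(dialect)
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    strsplit(paste(x, collapse = "\n"), "\n")[[1]]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop_parse("output table needs a header and at least one row")

  split_row <- switch(dialect,
    gdat = function(l) strsplit(trimws(l), "[ \t]+")[[1]],
    kasim_csv = function(l) gsub("^\"|\"$", "", trimws(strsplit(l, ",")[[1]])),
    tsv = function(l) strsplit(l, "\t")[[1]]
  )
  header <- split_row(if (dialect == "gdat") sub("^#\\s*", "", lines[1]) else lines[1])
  if (length(header) < 2) stop_parse("header must name a time column and at least one observable")

  body <- lines[-1]
  rows <- lapply(seq_along(body), function(i) {
    f <- split_row(body[i])
    if (length(f) != length(header)) {
      stop_parse(paste0("line ", i + 1, ": expected ", length(header),
                        " fields, found ", length(f)))
    }
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) stop_parse(paste0("line ", i + 1, ": non-numeric value"))
    v
  })
  mx <- do.call(rbind, rows)
  colnames(mx) <- c("time", header[-1])
  tibble::as_tibble(as.data.frame(mx))
}

#' Dispatch a batch of simulation jobs
#'
#' Executes a list of zero-argument job closures and returns their results in
#' batch order regardless of completion order. `workers = 1` is exactly
#' serial execution; with more workers the jobs are forked with
#' `parallel::mclapply`. Because every job carries its own pre-assigned seed,
#' results are bit-identical for any worker count. A failing job yields a
#' `dispatch_failure` object in its slot (its candidate gets the sentinel
#' fitness) and the batch continues, unless `fail_fast`.
#'
#' @param jobs List of functions of no arguments.
#' @param workers Number of workers (`>= 1`).
#' @param fail_fast Abort on the first failing job instead of recording it.
#' @return List of results, `length(jobs)` long, in batch order.
#' @export
dispatch <- function(jobs, workers = 1, fail_fast = FALSE) {
  if (workers < 1) stop_validation("workers must be >= 1")
  run_one <- function(job) {
    tryCatch(job(), error = function(e) {
      structure(list(message = conditionMessage(e)), class = "dispatch_failure")
    })
  }
  results <- if (workers == 1) {
    lapply(jobs, run_one)
  } else {
    parallel::mclapply(jobs, run_one, mc.cores = workers, mc.preschedule = TRUE)
  }
  if (fail_fast) {
    bad <- which(vapply(results, inherits, logical(1), "dispatch_failure"))
    if (length(bad) > 0) {
      abort(paste0("job ", bad[1], " failed: ", results[[bad[1]]]$message))
    }
  }
  results
}

#' Built-in SSA simulator backend
#'
#' Wraps the exact Gillespie simulator as a calibration backend: given a
#' candidate parameter vector it simulates `n_sims` independent trajectories
#' of the network at those rates and returns the `(n, T, V)` tensor aligned
#' to the requested times. Per-run seeds are derived from the job seed, so
#' results do not depend on scheduling.
#'
#' @param net A [reaction_network()] whose parameter names include every
#'   calibrated parameter.
#' @param observables Species to report (default: all species).
#' @param max_events SSA event cap per run; a candidate whose dynamics
#'   explode beyond the cap fails and receives the sentinel fitness.
#' @return A backend function `(params, n_sims, times, seed)` for
#'   [calibrate()].
#' @export
builtin_backend <- function(net, observables = NULL, max_events = 2e7) {
  force(net)
  force(observables)
  force(max_events)
  function(params, n_sims, times, seed) {
    candidate <- set_parameters(net, params)
    simulate_ensemble_tensor(candidate, n_sims, times, seed,
                             observables = observables, max_events = max_events)
  }
}

#' External command-line simulator backend
#'
#' Adapter contract for external stochastic simulators: the model template's
#' placeholders are rendered with the candidate parameters
#' ([render_model()]), the command template's `{model}`, `{seed}` and
#' `{output}` slots are filled per run, the command is executed, and its
#' output table is parsed with the configured dialect and aligned to the
#' experimental times ([align_to_times()]).
#'
#' @param command Command template containing `{model}`, `{seed}` and
#'   `{output}` slots.
#' @param model_template Model text with `__FREE__` placeholders.
#' @param dialect Output dialect for [parse_sim_table()].
#' @param observables Observable columns to report (default: all parsed
#'   columns).
#' @param tol Time-alignment tolerance.
#' @return A backend function `(params, n_sims, times, seed)`.
#' @export
command_backend <- function(command, model_template,
                            dialect = c("gdat", "kasim_csv", "tsv"),
                            observables = NULL, tol = 1e-9) {
  dialect <- match.arg(dialect)
  for (slot in c("{model}", "{seed}", "{output}")) {
    if (!grepl(slot, command, fixed = TRUE)) {
      stop_validation(paste0("command template lacks the ", slot, " slot"))
    }
  }
  function(params, n_sims, times, seed) {
    model_path <- tempfile(fileext = ".model")
    writeLines(render_model(model_template, params), model_path)
    on.exit(unlink(model_path), add = TRUE)
    runs <- lapply(seq_len(n_sims), function(j) {
      out_path <- tempfile(fileext = ".out")
      on.exit(unlink(out_path), add = TRUE)
      cmd <- command
      cmd <- gsub("{model}", model_path, cmd, fixed = TRUE)
      cmd <- gsub("{seed}", as.character(derive_seed(seed, "run", j)), cmd, fixed = TRUE)
      cmd <- gsub("{output}", out_path, cmd, fixed = TRUE)
      status <- system(cmd, ignore.stdout = TRUE, ignore.stderr = TRUE)
      if (status != 0) abort(paste0("simulator command failed (exit ", status, ")"))
      parse_sim_table(out_path, dialect)
    })
    cols <- observables %||% setdiff(names(runs[[1]]), "time")
    arr <- array(NA_real_, dim = c(n_sims, length(times), length(cols)),
                 dimnames = list(NULL, format(times, trim = TRUE), cols))
    for (j in seq_len(n_sims)) {
      tab <- runs[[j]]
      idx <- vapply(times, function(tt) {
        dd <- abs(tab$time - tt)
        i <- which.min(dd)
        if (dd[i] <= tol) i else NA_integer_
      }, integer(1))
      if (anyNA(idx)) {
        stop_align(paste0("simulator output lacks requested time(s): ",
                          paste(format(times[is.na(idx)]), collapse = ", ")))
      }
      arr[j, , ] <- as.matrix(tab[idx, cols, drop = FALSE])
    }
    arr
  }
}

#' SLURM submission-script stub
#'
#' Documented adapter interface for cluster dispatch: generates a SLURM batch
#' script that would submit one array task per simulation job. The package
#' never executes the script itself (local dispatch uses [dispatch()]); the
#' function exists so cluster users can wire the same job batch into their
#' scheduler.
#'
#' @param commands Character vector of shell commands, one per job.
#' @param job_name,partition,time Standard SLURM header fields.
#' @return The script text (single string).
#' @export
slurm_script <- function(commands, job_name = "stochcal",
                         partition = "general", time = "01:00:00") {
  paste(c(
    "#!/bin/bash",
    paste0("#SBATCH --job-name=", job_name),
    paste0("#SBATCH --partition=", partition),
    paste0("#SBATCH --time=", time),
    paste0("#SBATCH --array=1-", length(commands)),
    "case $SLURM_ARRAY_TASK_ID in",
    vapply(seq_along(commands), function(i) {
      paste0(i, ") ", commands[i], " ;;")
    }, character(1)),
    "esac"
  ), collapse = "\n")
}
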