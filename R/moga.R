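#' Multi-objective combination by unweighted rank sums
#'
#' Each objective column is ranked ascending (minimisation, ties sharing the
#' minimum "competition" rank) and an individual's combined score is the
#' unweighted sum of its per-objective ranks. The final ordering is ascending
#' by combined score with ties broken by id, so it is deterministic and, for
#' a single objective, identical to that objective's own ranking. Because it
#' only uses ranks, the ordering is invariant to any strictly monotone
#' transform of any single objective.
#'
#' @param fm Matrix or data frame of fitness values (individuals x
#'   objectives); `+Inf` sentinels are allowed and rank last.
#' @param ids Individual ids (default `1..nrow`).
#' @return A tibble `(id, score, rank)` sorted by rank.
#' @examples
#' sum_of_ranks(rbind(c(1, 9), c(2, 2), c(3, 1)))
#' @export
sum_of_ranks <- function(fm, ids = NULL) {
  fm <- as.matrix(fm)
  if (nrow(fm) == 0 || ncol(fm) == 0) stop_validation("empty fitness matrix")
  if (any(is.na(fm))) stop_validation("fitness matrix has missing entries")
  ids <- ids %||% seq_len(nrow(fm))
  ranks <- apply(fm, 2, function(x) rank(x, ties.method = "min"))
  ranks <- matrix(ranks, nrow = nrow(fm))
  score <- rowSums(ranks)
  o <- order(score, ids)
  tibble::tibble(id = ids[o], score = score[o], rank = seq_along(o))
}

#' Correlation between fitness objectives across a population
#'
#' Used to pick non-redundant objective sets for multi-objective runs: two
#' objectives whose values over the first-iteration population are highly
#' rank-correlated would steer the search identically, so one of them is
#' redundant.
#'
#' @param fm Matrix or data frame of fitness values (individuals x
#'   objectives), at least 3 individuals.
#' @param method `"pearson"`, `"spearman"` or `"kendall"`.
#' @return Symmetric correlation matrix with unit diagonal; columns with zero
#'   variance yield `NA` entries with a warning.
#' @export
objective_correlation <- function(fm, method = c("pearson", "spearman", "kendall")) {
  method <- match.arg(method)
  fm <- as.matrix(fm)
  if (nrow(fm) < 3) stop_validation("need at least 3 individuals")
  if (!all(is.finite(fm))) stop_validation("fitness values must be finite")
  sds <- apply(fm, 2, sd)
  out <- suppressWarnings(cor(fm, method = method))
  if (any(sds == 0)) {
    warn(paste0("zero-variance objective column(s): ",
                paste(colnames(fm)[sds == 0], collapse = ", "),
                "; correlations reported as NA"))
    out[sds == 0, ] <- NA_real_
    out[, sds == 0] <- NA_real_
  }
  diag(out) <- 1
  out
}

#' Preset multi-objective bundles
#'
#' Named low-redundancy objective combinations for multi-objective runs,
#' chosen by rank correlation of the objectives: a two-, three- and four-way
#' bundle mixing an algebraic error with the nonparametric equivalence score.
#'
#' @return Named list of objective-id vectors.
#' @export
objective_bundles <- function() {
  list(
    chisq_wmwet = c("CHISQ", "WMWET"),
    anpwsd_wmwet_pwsd = c("ANPWSD", "WMWET", "PWSD"),
    chisq_wmwet_sda_npwsd = c("CHISQ", "WMWET", "SDA", "NPWSD")
  )
}
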