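#' Define a mass-action reaction network
#'
#' A reaction network is the input of the built-in exact stochastic simulator:
#' integer-valued species counts evolving by mass-action reactions under the
#' chemical master equation. Propensities follow the stochastic mass-action
#' convention, rate times the falling factorial of each reactant count.
#'
#' @param species Named integer vector of initial counts.
#' @param reactions List of reactions, each created by [reaction()].
#' @param parameters Named numeric vector of non-negative rate constants; every
#'   reaction's `rate` name must resolve here.
#' @return A list of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   species = c(X = 100),
#'   reactions = list(reaction(c(X = 1), c(), "k")),
#'   parameters = c(k = 0.1)
#' )
#' @export
reaction_network <- function(species, reactions, parameters) {
  if (is.null(names(species)) || any(names(species) == "")) {
    stop_validation("species must be a named vector of initial counts")
  }
  if (any(species < 0) || any(species != round(species))) {
    stop_validation("initial counts must be non-negative integers")
  }
  if (any(parameters < 0) || anyNA(parameters)) {
    stop_validation("rate parameters must be non-negative")
  }
  for (rx in reactions) {
    if (!identical(class(rx), "stochcal_reaction")) {
      stop_validation("reactions must be built with reaction()")
    }
    unknown <- setdiff(c(names(rx$reactants), names(rx$products)), names(species))
    if (length(unknown) > 0) {
      stop_validation(paste0("unknown species in reaction: ", paste(unknown, collapse = ", ")))
    }
    if (!rx$rate %in% names(parameters)) {
      stop_validation(paste0("rate parameter '", rx$rate, "' does not resolve"))
    }
  }
  structure(
    list(species = species, reactions = reactions, parameters = parameters),
    class = "reaction_network"
  )
}

#' @rdname reaction_network
#' @param reactants,products Named non-negative integer stoichiometry vectors
#'   (possibly empty for zero-order synthesis or pure degradation).
#' @param rate Name of the rate parameter.
#' @export
reaction <- function(reactants, products, rate) {
  for (side in list(reactants, products)) {
    if (length(side) > 0 && (any(side < 0) || any(side != round(side)))) {
      stop_validation("stoichiometries must be non-negative integers")
    }
  }
  structure(list(reactants = reactants, products = products, rate = rate),
            class = "stochcal_reaction")
}

#' Replace rate parameter values in a network
#'
#' @param net A [reaction_network()].
#' @param params Named numeric vector; names must be existing parameters.
#' @return The network with the given rates replaced.
#' @export
set_parameters <- function(net, params) {
  unknown <- setdiff(names(params), names(net$parameters))
  if (length(unknown) > 0) {
    stop_validation(paste0("unknown parameter(s): ", paste(unknown, collapse = ", ")))
  }
  if (any(params < 0) || anyNA(params)) stop_validation("rates must be non-negative")
  net$parameters[names(params)] <- params
  net
}

net_matrices <- function(net) {
  sp <- names(net$species)
  nr <- length(net$reactions)
  re <- matrix(0L, nr, length(sp))
  pr <- matrix(0L, nr, length(sp))
  rates <- numeric(nr)
  for (i in seq_len(nr)) {
    rx <- net$reactions[[i]]
    re[i, match(names(rx$reactants), sp)] <- as.integer(rx$reactants)
    pr[i, match(names(rx$products), sp)] <- as.integer(rx$products)
    rates[i] <- net$parameters[[rx$rate]]
  }
  list(reactants = re, products = pr, rates = rates, species = sp)
}

#' Simulate one exact SSA trajectory
#'
#' Draws a single realisation of the network's chemical master equation with
#' the Gillespie direct method and records the state at each grid time.
#' Deterministic given `(net, t_grid, seed)`.
#'
#' @param net A [reaction_network()].
#' @param t_grid Non-decreasing numeric time grid starting at or after 0.
#' @param seed Integer seed for the simulator's own RNG stream.
#' @param max_events Safety cap on the number of reaction events (guards
#'   against runaway parameter sets during calibration).
#' @return A tibble of class `ssa_trajectory` with column `time` and one
#'   integer-valued column per species; the seed is kept as an attribute.
#' @export
simulate_ssa <- function(net, t_grid, seed, max_events = 2e7) {
  if (length(t_grid) == 0) stop_validation("t_grid must be non-empty")
  if (any(diff(t_grid) < 0) || t_grid[1] < 0) {
    stop_validation("t_grid must be non-decreasing and start at time >= 0")
  }
  nm <- net_matrices(net)
  counts <- ssa_direct_cpp(
    as.numeric(net$species), nm$reactants, nm$products, nm$rates,
    as.numeric(t_grid), as.numeric(seed), max_events
  )
  colnames(counts) <- nm$species
  out <- tibble::as_tibble(as.data.frame(counts))
  out <- dplyr::bind_cols(tibble::tibble(time = as.numeric(t_grid)), out)
  structure(out, seed = as.integer(seed),
            class = c("ssa_trajectory", class(tibble::tibble())))
}

# n independent runs -> tensor (n, T, V); observables default to all species
simulate_ensemble_tensor <- function(net, n, t_grid, seed,
                                     observables = NULL, max_events = 2e7) {
  nm <- net_matrices(net)
  observables <- observables %||% nm$species
  ov <- match(observables, nm$species)
  if (anyNA(ov)) stop_validation("observables must be network species")
  arr <- array(NA_real_, dim = c(n, length(t_grid), length(observables)),
               dimnames = list(NULL, format(t_grid, trim = TRUE), observables))
  for (j in seq_len(n)) {
    counts <- ssa_direct_cpp(
      as.numeric(net$species), nm$reactants, nm$products, nm$rates,
      as.numeric(t_grid), as.numeric(derive_seed(seed, "run", j)), max_events
    )
    arr[j, , ] <- counts[, ov, drop = FALSE]
  }
  arr
}

#' Simulate an ensemble of SSA trajectories
#'
#' @inheritParams simulate_ssa
#' @param n Number of independent runs; each gets its own derived seed, so job
#'   order cannot change results.
#' @param observables Species to report (default: all).
#' @return A [as_sim_ensemble()] tibble with `n` runs.
#' @export
simulate_ensemble <- function(net, n, t_grid, seed, observables = NULL,
                              max_events = 2e7) {
  arr <- simulate_ensemble_tensor(net, n, t_grid, seed, observables, max_events)
  se_from_tensor(arr, as.numeric(t_grid), dimnames(arr)[[3]])
}

#' The two-species gene-expression benchmark network
#'
#' A four-reaction birth-death cascade describing the synthesis and
#' degradation of an mRNA and its encoded protein: `0 -> mRNA` (zero order,
#' rate `r1_v`), `mRNA -> 0` (`r2_k1`), `mRNA -> mRNA + Protein` (`r3_k1`),
#' and `Protein -> 0` (`r4_k1`). The returned network is preloaded with the
#' benchmark's known "true" rates `(r1_v = 5, r2_k1 = 0.03, r3_k1 = 0.1,
#' r4_k1 = 0.03)`, under which the stationary means are
#' `E[mRNA] = r1_v / r2_k1 = 166.67` and
#' `E[Protein] = r1_v * r3_k1 / (r2_k1 * r4_k1) = 555.56`.
#' Calibrations that re-estimate all four rates from synthetic data generated
#' at the true values are the package's standard parameter-recovery benchmark.
#'
#' @param initial Named integer vector of initial counts
#'   (default `c(mRNA = 0, Protein = 0)`).
#' @return A [reaction_network()].
#' @export
aguilera_network <- function(initial = c(mRNA = 0, Protein = 0)) {
  reaction_network(
    species = initial,
    reactions = list(
      reaction(c(), c(mRNA = 1), "r1_v"),
      reaction(c(mRNA = 1), c(), "r2_k1"),
      reaction(c(mRNA = 1), c(mRNA = 1, Protein = 1), "r3_k1"),
      reaction(c(Protein = 1), c(), "r4_k1")
    ),
    parameters = c(r1_v = 5, r2_k1 = 0.03, r3_k1 = 0.1, r4_k1 = 0.03)
  )
}

#' True rates of the gene-expression benchmark
#' @return Named numeric vector `(r1_v = 5, r2_k1 = 0.03, r3_k1 = 0.1, r4_k1 = 0.03)`.
#' @export
aguilera_true_rates <- function() {
  c(r1_v = 5, r2_k1 = 0.03, r3_k1 = 0.1, r4_k1 = 0.03)
}

#' Generate a synthetic replicated dataset from a network
#'
#' Runs `n_replicates` independent SSA realisations at the network's current
#' rates and packages them as experimental data, mimicking the design of
#' parameter-recovery studies where replicated stochastic simulations at known
#' "true" rates stand in for measurements. The default time grid
#' `0, 20, ..., 200` spans both the transient and the near-stationary regime
#' of the gene-expression benchmark so that all four rates are identifiable.
#'
#' @inheritParams simulate_ensemble
#' @param n_replicates Number of synthetic replicates.
#' @return An [as_experiment_data()] tibble of shape
#'   `(n_replicates, length(t_grid), V)`.
#' @export
generate_synthetic_dataset <- function(net, n_replicates, t_grid = seq(0, 200, by = 20),
                                       seed = 1, observables = NULL,
                                       max_events = 2e7) {
  if (n_replicates < 1) stop_validation("n_replicates must be >= 1")
  arr <- simulate_ensemble_tensor(net, n_replicates, t_grid, derive_seed(seed, "data"),
                                  observables, max_events)
  sims <- se_from_tensor(arr, as.numeric(t_grid), dimnames(arr)[[3]])
  names(sims)[names(sims) == "run"] <- "replicate"
  as_experiment_data(sims)
}

#' Read or write a reaction network as YAML
#'
#' Declarative plain-text network exchange format with top-level keys
#' `species` (name: initial count), `parameters` (name: rate) and `reactions`
#' (list of `{reactants:, products:, rate:}` maps).
#'
#' @param path File path.
#' @return `read_network_yaml()` returns a [reaction_network()];
#'   `write_network_yaml()` returns `path` invisibly.
#' @export
read_network_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  reactions <- lapply(y$reactions, function(rx) {
    reaction(unlist(rx$reactants) %||% c(), unlist(rx$products) %||% c(), rx$rate)
  })
  reaction_network(unlist(y$species), reactions, unlist(y$parameters))
}

#' @rdname read_network_yaml
#' @param net A [reaction_network()].
#' @export
write_network_yaml <- function(net, path) {
  y <- list(
    species = as.list(net$species),
    parameters = as.list(net$parameters),
    reactions = lapply(net$reactions, function(rx) {
      list(reactants = as.list(rx$reactants), products = as.list(rx$products),
           rate = rx$rate)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
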