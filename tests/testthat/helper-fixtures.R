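# shared fixtures, all generated in code

# complete long tibble for m replicates, times tt, observables obs;
# values from a deterministic function f(replicate, time, observable index)
make_data <- function(m, tt, obs, f) {
  df <- tidyr::expand_grid(replicate = seq_len(m), time = tt, observable = obs)
  df$value <- mapply(f, df$replicate, df$time, match(df$observable, obs))
  as_experiment_data(df)
}

make_sims <- function(n, tt, obs, f) {
  df <- tidyr::expand_grid(run = seq_len(n), time = tt, observable = obs)
  df$value <- mapply(f, df$run, df$time, match(df$observable, obs))
  as_sim_ensemble(df)
}

# turn an experiment_data into a same-valued sim ensemble
data_as_sims <- function(data) {
  df <- tibble::as_tibble(data)
  names(df)[names(df) == "replicate"] <- "run"
  as_sim_ensemble(df)
}

# deterministic mock backend: every run/ replicate value is a * time for the
# single free parameter a, so SDA over a dataset built at a = a0 is a smooth
# quadratic in a with unique optimum a0
mock_backend <- function(observables = "A") {
  function(params, n_sims, times, seed) {
    a <- params[["a"]]
    arr <- array(rep(a * times, each = n_sims),
                 dim = c(n_sims, length(times), length(observables)),
                 dimnames = list(NULL, format(times, trim = TRUE), observables))
    arr
  }
}

mock_data <- function(a0 = 5, tt = 1:5, m = 2) {
  make_data(m, tt, "A", function(r, t, v) a0 * t)
}

mock_specs <- function() param_spec("a", 0.1, 10, "uniform")

tiny_ga_config <- function(...) {
  args <- list(pop_size = 8, elite = 2, iterations = 4, n_sims = 2)
  user <- list(...)
  args[names(user)] <- user
  do.call(ga_config, args)
}

# pure decay network X -> 0 at rate k, X0 initial copies
decay_network <- function(k = 0.1, X0 = 100) {
  reaction_network(
    species = c(X = X0),
    reactions = list(reaction(c(X = 1), c(), "k")),
    parameters = c(k = k)
  )
}
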