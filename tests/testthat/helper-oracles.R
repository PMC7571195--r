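# Independent reference implementations (naive scalar loops) and small
# fixture builders used across the suite.

# Assemble a reservoir_net by hand from explicit coordinates and edges.
make_test_net <- function(coords, edges, input_map, params = reservoir_params()) {
  structure(list(coords = coords, input_map = input_map, edges = edges,
                 params = params, n = nrow(coords), features = NULL,
                 n_per_feature = NULL, trained = TRUE),
            class = "reservoir_net")
}

# Random small network with forced-input neurons and random spike trains.
random_small_net <- function(seed, max_neurons = 20L, n_steps = 200L) {
  set.seed(seed)
  n <- sample(3:max_neurons, 1)
  n_in <- sample(1:max(1, n %/% 3), 1)
  coords <- matrix(runif(3 * n, 0, 50), n, 3)
  n_e <- sample(1:(3 * n), 1)
  pre <- sample(n, n_e, replace = TRUE)
  post <- sample(n, n_e, replace = TRUE)
  keep <- pre != post & !duplicated(paste(pre, post))
  pre <- pre[keep]; post <- post[keep]
  edges <- data.frame(pre = pre, post = post,
                      weight = runif(length(pre), -0.3, 0.6),
                      is_input_edge = FALSE, dist = 1)
  params <- reservoir_params(firing_threshold = 0.5,
                             leak_per_step = sample(c(0.002, 0.02), 1),
                             refractory_steps = sample(0:3, 1), seed = seed)
  input_map <- sample(n, n_in)
  names(input_map) <- paste0("in", seq_len(n_in))
  raster <- matrix(rbinom(n_in * n_steps, 1, 0.15), n_in, n_steps)
  list(net = make_test_net(coords, edges, input_map, params), raster = raster)
}

# Naive per-neuron LIF simulation: scalar accumulation over incoming edges,
# no vectorisation shared with the implementation under test.
naive_propagate <- function(net, raster) {
  n <- net$n
  n_steps <- ncol(raster)
  inputs <- as.integer(net$input_map)
  in_edges <- lapply(seq_len(n), function(j) which(net$edges$post == j))
  psp <- rep(0, n); refr <- rep(0L, n); fired_prev <- rep(FALSE, n)
  out <- matrix(FALSE, n, n_steps)
  for (t in seq_len(n_steps)) {
    fired <- rep(FALSE, n)
    for (j in seq_len(n)) {
      k <- match(j, inputs)
      if (!is.na(k)) { fired[j] <- raster[k, t] > 0; next }
      if (refr[j] > 0L) { refr[j] <- refr[j] - 1L; next }
      arr <- 0
      for (e in in_edges[[j]])
        if (fired_prev[net$edges$pre[e]]) arr <- arr + net$edges$weight[e]
      psp[j] <- max(0, psp[j] - net$params$leak_per_step) + arr
      if (psp[j] >= net$params$firing_threshold) {
        fired[j] <- TRUE; psp[j] <- 0; refr[j] <- net$params$refractory_steps
      }
    }
    out[, t] <- fired
    fired_prev <- fired
  }
  out
}

# Firing matrix (n x n_steps) from a propagate() spike record.
record_to_matrix <- function(record, n) {
  m <- matrix(FALSE, n, record$n_steps)
  for (j in seq_len(n))
    if (length(record$firings[[j]])) m[j, record$firings[[j]] + 1L] <- TRUE
  m
}

# Hand-stepped single-neuron LIF trace: one neuron, fixed synaptic weights,
# explicit arrival trains (list of arrival step indices per synapse).
naive_lif_trace <- function(weights, arrival_steps, n_steps, params) {
  psp_trace <- numeric(n_steps)
  spikes <- integer(0)
  psp <- 0; refr <- 0L
  for (t in seq_len(n_steps)) {
    arr <- sum(weights[vapply(arrival_steps, function(s) t %in% s, logical(1))])
    if (refr > 0L) {
      refr <- refr - 1L
    } else {
      psp <- max(0, psp - params$leak_per_step) + arr
      if (psp >= params$firing_threshold) {
        spikes <- c(spikes, t)
        psp <- 0
        refr <- params$refractory_steps
      }
    }
    psp_trace[t] <- psp
  }
  list(psp = psp_trace, spikes = spikes)
}

# Per-step replay of the deSNN drift rule for one synapse.
replay_drift <- function(rank, firing_steps, horizon, params) {
  if (length(firing_steps) == 0L) return(0)
  w <- params$alpha * params$mod^rank
  first <- firing_steps[1L]
  if (first + 1L <= horizon - 1L)
    for (t in seq.int(first + 1L, horizon - 1L))
      w <- w + if (t %in% firing_steps) params$drift else -params$drift
  w
}

# Sort-based equal-count binning oracle: bin index per value given pooled
# sample, lower-tie convention, 5 bins.
oracle_bin_counts <- function(pooled, boundaries) {
  bins <- 1L + vapply(pooled, function(v) sum(v > boundaries), integer(1))
  tabulate(bins, nbins = length(boundaries) + 1L)
}

tiny_synth <- function(n_subjects = 3, trials = 4, effect = 2, seed = 7,
                       ...) {
  generate_dataset(synth_config(n_subjects = n_subjects,
                                trials_per_subject = trials,
                                effect_size = effect, seed = seed, ...))
}

# Small reservoir for fast pipeline tests: fewer neurons, same physics.
small_reservoir_params <- function(seed = 1L)
  reservoir_params(grid_dims = c(7L, 7L, 5L), seed = seed)
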