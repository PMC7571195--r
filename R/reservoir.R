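# 3D spiking reservoir: spatially embedded LIF neurons with small-world
# connectivity, driven by input spike rasters and trained online with
# spike-timing-dependent plasticity.

#' Reservoir parameters
#'
#' @param grid_dims Integer vector of neuron counts per axis; default
#'   `c(11, 11, 7)` giving 847 neurons.
#' @param grid_spacing Distance between adjacent grid neurons (distance
#'   units; default 10).
#' @param small_world_radius Maximum connection length `r` (default 25, i.e.
#'   up to two grid steps away).
#' @param excitatory_fraction Fraction of recurrent (non-input) connections
#'   with positive weight (default 0.8, enforced exactly up to rounding).
#' @param input_weight_multiplier Weight multiplier for connections incident
#'   to input neurons (default 2; such connections are always positive).
#' @param connect_prob_scale `p0` in the inverse-distance connection
#'   probability `p(d) = min(1, p0 * grid_spacing / d)` (default 0.15).
#' @param firing_threshold PSP firing threshold (potential units; default 0.5).
#' @param leak_per_step Constant PSP leak per time step (default 0.002).
#' @param refractory_steps Absolute refractory period in time steps
#'   (default 1).
#' @param stdp_learning_rate STDP learning rate `LR` (default 0.001).
#' @param seed Integer seed making reservoir construction deterministic.
#' @return An object of class `reservoir_params`.
#' @export
reservoir_params <- function(grid_dims = c(11L, 11L, 7L), grid_spacing = 10,
                             small_world_radius = 25,
                             excitatory_fraction = 0.8,
                             input_weight_multiplier = 2,
                             connect_prob_scale = 0.15,
                             firing_threshold = 0.5, leak_per_step = 0.002,
                             refractory_steps = 1L,
                             stdp_learning_rate = 0.001, seed = 1L) {
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1))
  check_number(grid_spacing, "grid_spacing", lower = 0, strict_lower = TRUE)
  check_number(small_world_radius, "small_world_radius", lower = 0)
  check_number(excitatory_fraction, "excitatory_fraction", 0, 1)
  check_number(input_weight_multiplier, "input_weight_multiplier", lower = 0)
  check_number(connect_prob_scale, "connect_prob_scale", 0, 1)
  check_number(firing_threshold, "firing_threshold", lower = 0,
               strict_lower = TRUE)
  check_number(leak_per_step, "leak_per_step", lower = 0)
  check_number(refractory_steps, "refractory_steps", lower = 0)
  check_number(stdp_learning_rate, "stdp_learning_rate", lower = 0)
  structure(list(grid_dims = as.integer(grid_dims),
                 grid_spacing = grid_spacing,
                 small_world_radius = small_world_radius,
                 excitatory_fraction = excitatory_fraction,
                 input_weight_multiplier = input_weight_multiplier,
                 connect_prob_scale = connect_prob_scale,
                 firing_threshold = firing_threshold,
                 leak_per_step = leak_per_step,
                 refractory_steps = as.integer(refractory_steps),
                 stdp_learning_rate = stdp_learning_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "reservoir_params")
}

# Grid coordinates centred on the origin at the given spacing, so the
# default 11 x 11 x 7 grid spans x, y in [-50, 50] and z in [-30, 30] and
# the three input layers sit exactly at z = -30, 0, +30.
grid_coordinates <- function(dims, spacing) {
  ax <- lapply(dims, function(n) (seq_len(n) - (n + 1) / 2) * spacing)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  as.matrix(g)
}

# Place the input populations as lines of adjacent neurons: facial features
# split over the bottom (z min) and top (z max) layers, peripheral features
# on the middle layer. Within a line, neurons n1..n5 occupy adjacent y
# positions; lines are spread over distinct x columns.
place_input_neurons <- function(coords, dims, spacing, features, n_per_feature) {
  facial <- intersect(features, facial_features())
  periph <- intersect(features, peripheral_features())
  nz <- dims[3]
  z_vals <- sort(unique(coords[, 3]))
  layers <- list()
  if (length(facial)) {
    half <- ceiling(length(facial) / 2)
    layers[[length(layers) + 1L]] <- list(f = facial[seq_len(half)],
                                          z = z_vals[1])
    if (length(facial) > half)
      layers[[length(layers) + 1L]] <- list(f = facial[(half + 1):length(facial)],
                                            z = z_vals[nz])
  }
  if (length(periph))
    layers[[length(layers) + 1L]] <- list(f = periph,
                                          z = z_vals[(nz + 1) %/% 2])
  x_vals <- sort(unique(coords[, 1]))
  y_vals <- sort(unique(coords[, 2]))
  y_line <- y_vals[seq.int(max(1L, (dims[2] - n_per_feature) %/% 2 + 1L),
                           length.out = n_per_feature)]
  input_map <- integer(0)
  nm <- character(0)
  for (lay in layers) {
    nf <- length(lay$f)
    x_idx <- round(seq(1, dims[1], length.out = nf + 2))[2:(nf + 1)]
    if (nf >= dims[1] - 1) x_idx <- seq_len(nf)
    if (anyDuplicated(x_idx)) x_idx <- seq_len(nf)
    for (j in seq_len(nf)) {
      for (k in seq_len(n_per_feature)) {
        idx <- which(coords[, 1] == x_vals[x_idx[j]] &
                       coords[, 2] == y_line[k] & coords[, 3] == lay$z)
        stopifnot(length(idx) == 1L)
        input_map <- c(input_map, idx)
        nm <- c(nm, paste0(lay$f[j], "_n", k))
      }
    }
  }
  names(input_map) <- nm
  ord <- as.vector(t(outer(features, seq_len(n_per_feature),
                           function(f, n) paste0(f, "_n", n))))
  input_map[ord]
}

#' Build a 3D small-world spiking reservoir
#'
#' Neurons occupy a regular grid; candidate neuron pairs within
#' `small_world_radius` are connected with probability decreasing in
#' distance, one random direction per pair, weight `u / d` (`u` uniform on
#' (0, 1], `d` the Euclidean distance). Among recurrent connections exactly
#' `excitatory_fraction` (rounded) are positive; connections incident to an
#' input neuron are always positive with doubled weight. The input
#' populations are embedded as lines of five adjacent neurons on the bottom,
#' middle and top grid layers.
#'
#' @param params A [reservoir_params()].
#' @param features Feature subset driving the reservoir (default all 16,
#'   giving 80 input neurons).
#' @param n_per_feature Population size per feature (default 5).
#' @return An object of class `reservoir_net` with `coords` (n x 3),
#'   `input_map` (named grid indices of the input rows), `edges` (data frame
#'   `pre`, `post`, `weight`, `is_input_edge`, `dist`), `params`, `n`, and a
#'   `trained` flag.
#' @export
build_reservoir <- function(params = reservoir_params(),
                            features = valence_features(),
                            n_per_feature = 5L) {
  stopifnot(inherits(params, "reservoir_params"))
  coords <- grid_coordinates(params$grid_dims, params$grid_spacing)
  n <- nrow(coords)
  input_map <- place_input_neurons(coords, params$grid_dims,
                                   params$grid_spacing, features,
                                   n_per_feature)
  is_input <- logical(n); is_input[input_map] <- TRUE
  with_seed(params$seed, {
    d2 <- as.matrix(stats::dist(coords))
    cand <- which(upper.tri(d2) & d2 > 0 & d2 <= params$small_world_radius,
                  arr.ind = TRUE)
    if (nrow(cand) == 0L || params$small_world_radius <= 0) {
      edges <- data.frame(pre = integer(0), post = integer(0),
                          weight = numeric(0), is_input_edge = logical(0),
                          dist = numeric(0))
    } else {
      d <- d2[cand]
      p <- pmin(1, params$connect_prob_scale * params$grid_spacing / d)
      keep <- stats::runif(length(p)) < p
      a <- cand[keep, 1]; b <- cand[keep, 2]; d <- d[keep]
      flip <- stats::runif(length(a)) < 0.5
      pre <- ifelse(flip, b, a); post <- ifelse(flip, a, b)
      u <- 1 - stats::runif(length(pre))       # uniform on (0, 1]
      w <- u / d
      inp <- is_input[pre] | is_input[post]
      n_rec <- sum(!inp)
      n_pos <- round(params$excitatory_fraction * n_rec)
      sign_vec <- rep(1, length(w))
      rec_idx <- which(!inp)
      neg_idx <- rec_idx[sample.int(length(rec_idx), n_rec - n_pos)]
      sign_vec[neg_idx] <- -1
      w <- w * sign_vec
      w[inp] <- abs(w[inp]) * params$input_weight_multiplier
      edges <- data.frame(pre = pre, post = post, weight = w,
                          is_input_edge = inp, dist = d)
    }
    structure(list(coords = coords, input_map = input_map, edges = edges,
                   params = params, n = n, features = features,
                   n_per_feature = as.integer(n_per_feature),
                   trained = FALSE),
              class = "reservoir_net")
  })
}

#' @export
print.reservoir_net <- function(x, ...) {
  cat(sprintf("<reservoir_net> %d neurons (%s grid), %d input neurons, %d connections%s\n",
              x$n, paste(x$params$grid_dims, collapse = "x"),
              length(x$input_map), nrow(x$edges),
              if (x$trained) ", STDP-trained" else ""))
  invisible(x)
}

#' One synchronous LIF update step
#'
#' For each non-refractory neuron the PSP leaks by `leak_per_step` (floored
#' at 0) and integrates the weighted spikes that arrived this step; if the
#' PSP reaches the firing threshold the neuron fires and its PSP resets to 0
#' with `refractory_steps` of refractoriness, during which arriving spikes
#' are ignored.
#'
#' @param states List with numeric `psp` and integer `refractory` vectors.
#' @param arriving Numeric vector of summed synaptic input per neuron.
#' @param params A [reservoir_params()].
#' @return List with updated `states` and logical vector `fired`.
#' @export
lif_step <- function(states, arriving, params) {
  psp <- states$psp
  refr <- states$refractory
  active <- refr <= 0L
  psp[active] <- pmax(0, psp[active] - params$leak_per_step) +
    arriving[active]
  fired <- active & psp >= params$firing_threshold
  psp[fired] <- 0
  refr[fired] <- params$refractory_steps
  refr[!active] <- refr[!active] - 1L
  list(states = list(psp = psp, refractory = refr), fired = fired)
}

# Compact edge-indexed view used by the propagation loop.
edge_arrays <- function(net) {
  e <- net$edges
  list(pre = e$pre, post = e$post, w = e$weight, n_e = nrow(e))
}

#' Propagate an input raster through the reservoir
#'
#' Runs the synchronous simulation for one trial: at each time step the
#' input neurons fire exactly their raster rows (their own PSP dynamics are
#' bypassed), spikes emitted at step `t` are delivered along each outgoing
#' connection at step `t + 1`, and every other neuron follows the LIF
#' dynamics of [lif_step()]. With `plasticity = TRUE` the connection weights
#' are updated online by nearest-spike STDP (see [stdp_delta()]): when a
#' neuron fires, each incoming connection whose presynaptic neuron has
#' already spiked is potentiated by `stdp_delta(t_post - t_pre_last)`, and
#' each outgoing connection whose postsynaptic neuron has already spiked is
#' depressed by `stdp_delta(t_post_last - t_pre)`.
#'
#' @param net A [build_reservoir()] network.
#' @param raster A `spike_raster` whose rows match `net$input_map`.
#' @param plasticity Apply STDP updates online (weights persist in the
#'   returned net).
#' @return List with `record` (a `spike_record`: per-neuron firing steps
#'   `firings`, `first_spike` step per neuron (`NA` if silent), per-edge
#'   `transmitted` spike counts, `fire_counts`, `n_steps`) and `net` (with
#'   updated weights when `plasticity = TRUE`).
#' @export
propagate <- function(net, raster, plasticity = FALSE) {
  stopifnot(inherits(net, "reservoir_net"))
  if (nrow(raster) != length(net$input_map))
    stop_invalid("raster has %d rows but the net has %d input neurons",
                 nrow(raster), length(net$input_map))
  n <- net$n
  n_steps <- ncol(raster)
  ea <- edge_arrays(net)
  w <- ea$w
  lr <- net$params$stdp_learning_rate
  input_idx <- as.integer(net$input_map)
  is_input <- logical(n); is_input[input_idx] <- TRUE
  psp <- numeric(n); refr <- integer(n)
  last_spike <- rep(NA_integer_, n)
  fired_prev <- logical(n)
  fired_by_step <- vector("list", n_steps)
  leak <- net$params$leak_per_step
  thr <- net$params$firing_threshold
  refr_steps <- net$params$refractory_steps
  pre <- ea$pre; post <- ea$post

  for (t in seq_len(n_steps)) {          # step index t-1 (0-based)
    arriving <- numeric(n)
    if (any(fired_prev)) {
      sel <- fired_prev[pre]
      if (any(sel)) {
        s <- rowsum(w[sel], post[sel])
        arriving[as.integer(rownames(s))] <- s
      }
    }
    active <- refr <= 0L & !is_input
    psp[active] <- pmax(0, psp[active] - leak) + arriving[active]
    fired <- active & psp >= thr
    psp[fired] <- 0
    refr[fired] <- refr_steps
    slow <- !active & !is_input
    refr[slow] <- refr[slow] - 1L
    fired[input_idx] <- raster[, t] > 0

    if (plasticity && any(fired)) {
      step0 <- t - 1L
      # potentiate incoming edges of firing neurons whose pre spiked earlier
      sel_in <- fired[post] & !is.na(last_spike[pre]) & !fired[pre]
      if (any(sel_in))
        w[sel_in] <- w[sel_in] + lr / (step0 - last_spike[pre[sel_in]] + 1)
      # depress outgoing edges of firing neurons whose post spiked earlier
      sel_out <- fired[pre] & !is.na(last_spike[post]) & !fired[post]
      if (any(sel_out))
        w[sel_out] <- w[sel_out] - lr / (step0 - last_spike[post[sel_out]] + 1)
      # simultaneous pre/post firing: dt = 0, no change (sgn(0) = 0)
    }
    if (any(fired)) {
      idx <- which(fired)
      fired_by_step[[t]] <- idx
      last_spike[idx] <- t - 1L
    }
    fired_prev <- fired
  }

  fire_counts <- integer(n)
  ev_n <- unlist(fired_by_step, use.names = FALSE)
  if (length(ev_n)) {
    tab <- tabulate(ev_n, nbins = n)
    fire_counts <- tab
  }
  ev_t <- rep.int(seq_len(n_steps) - 1L,
                  vapply(fired_by_step, length, integer(1)))
  firings <- split(ev_t, factor(ev_n, levels = seq_len(n)))
  first_spike <- rep(NA_integer_, n)
  if (length(ev_n))
    first_spike <- vapply(firings, function(v)
      if (length(v)) v[1L] else NA_integer_, integer(1))
  record <- structure(list(firings = firings, first_spike = first_spike,
                           fire_counts = fire_counts,
                           transmitted = fire_counts[pre],
                           n_steps = n_steps),
                      class = "spike_record")
  if (plasticity) net$edges$weight <- w
  list(record = record, net = net)
}

#' STDP weight change for a post-minus-pre spike-time difference
#'
#' `delta_w = sgn(dt) * LR / (|dt| + 1)`: a connection is strengthened when
#' the postsynaptic spike follows the presynaptic one (`dt > 0`) and
#' weakened otherwise, with magnitude decaying hyperbolically in the time
#' difference; simultaneous spikes (`dt = 0`) produce no change.
#'
#' @param dt Integer vector of `t_post - t_pre` (time steps).
#' @param lr Learning rate (default 0.001).
#' @return Numeric vector of weight changes.
#' @export
stdp_delta <- function(dt, lr = 0.001) {
  sign(dt) * lr / (abs(dt) + 1)
}

#' Unsupervised STDP training over a set of rasters
#'
#' Propagates each raster once, in the given order, with plasticity on.
#' Neuron states reset between trials; connection weights persist and carry
#' the learned spatio-temporal structure.
#'
#' @param net A [build_reservoir()] network.
#' @param rasters List of `spike_raster` objects.
#' @param shuffle Shuffle the trial order (seeded by `seed`) before training.
#' @param seed Seed used when `shuffle = TRUE`.
#' @return The network with updated weights and `trained = TRUE`.
#' @export
train_unsupervised <- function(net, rasters, shuffle = FALSE, seed = NULL) {
  stopifnot(inherits(net, "reservoir_net"))
  if (shuffle)
    rasters <- with_seed(seed, sample(rasters))
  for (r in rasters)
    net <- propagate(net, r, plasticity = TRUE)$net
  net$trained <- TRUE
  net
}

#' Spike-communication clusters around the input neurons
#'
#' Propagates a set of (single-class) rasters through the trained network
#' with plasticity off, accumulates how many spikes each connection
#' transmitted, and assigns every reservoir neuron to the input neuron
#' reachable from it along the directed path that maximises the minimum
#' transmitted count (widest path). Bottleneck ties are broken by the
#' Euclidean-nearest input; neurons with no positive-communication path stay
#' unassigned. Larger clusters mark input populations whose activity
#' dominated reservoir communication for that class.
#'
#' @param net A trained [reservoir_net] (a warning is issued if untrained).
#' @param rasters List of `spike_raster` objects, all of one class.
#' @return Named integer vector: cluster size per input neuron plus an
#'   `unassigned` count; sizes sum to the reservoir size.
#' @export
spike_communication_clusters <- function(net, rasters) {
  stopifnot(inherits(net, "reservoir_net"))
  if (!net$trained)
    warning("reservoir has not been STDP-trained; clusters reflect the initial wiring")
  n <- net$n
  caps <- numeric(nrow(net$edges))
  for (r in rasters)
    caps <- caps + propagate(net, r, plasticity = FALSE)$record$transmitted
  pre <- net$edges$pre; post <- net$edges$post
  inputs <- as.integer(net$input_map)
  out_edges <- split(seq_along(pre), factor(pre, levels = seq_len(n)))

  bott <- rep(-Inf, n); owner <- rep(NA_integer_, n)
  bott[inputs] <- Inf; owner[inputs] <- seq_along(inputs)
  # distance of every neuron to every input neuron, for tie-breaking
  d_inp <- as.matrix(stats::dist(net$coords))[, inputs, drop = FALSE]
  visited <- logical(n)
  repeat {
    u <- which.max(ifelse(visited, -Inf, bott))
    if (!length(u) || bott[u] <= 0 || visited[u]) break
    visited[u] <- TRUE
    for (e in out_edges[[u]]) {
      v <- post[e]
      if (visited[v]) next
      nb <- min(bott[u], caps[e])
      if (nb > bott[v] ||
          (nb == bott[v] && !is.na(owner[v]) && nb > 0 &&
           d_inp[v, owner[u]] < d_inp[v, owner[v]])) {
        bott[v] <- nb
        owner[v] <- owner[u]
      }
    }
    if (all(visited | bott <= 0)) break
  }
  assigned <- !is.na(owner) & bott > 0
  sizes <- tabulate(owner[assigned], nbins = length(inputs))
  names(sizes) <- names(net$input_map)
  c(sizes, unassigned = n - sum(sizes))
}
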