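test_that("the default reservoir has 847 neurons, 80 inputs, bounded edges", {
  net <- build_reservoir(reservoir_params(seed = 4))
  expect_identical(net$n, 847L)
  expect_length(net$input_map, 80L)
  expect_false(anyDuplicated(net$input_map) > 0)
  # grid spans x,y in [-50,50], z in [-30,30]; input layers at z -30/0/30
  expect_equal(range(net$coords[, 1]), c(-50, 50))
  expect_equal(range(net$coords[, 3]), c(-30, 30))
  z_in <- net$coords[net$input_map, 3]
  expect_setequal(unique(z_in), c(-30, 0, 30))
  expect_equal(unname(z_in[names(net$input_map) == "hrv_n1"]), 0)
  e <- net$edges
  expect_true(all(e$pre != e$post))
  expect_false(anyDuplicated(paste(e$pre, e$post)) > 0)
  expect_true(all(e$dist <= 25 + 1e-9))
  expect_true(all(e$weight[e$is_input_edge] > 0))
})

test_that("the excitatory split among recurrent edges is exact by construction", {
  for (s in 1:3) {
    net <- build_reservoir(reservoir_params(seed = s))
    rec <- net$edges$weight[!net$edges$is_input_edge]
    expect_identical(sum(rec > 0), as.integer(round(0.8 * length(rec))))
  }
})

test_that("reservoir construction is deterministic given the seed", {
  n1 <- build_reservoir(reservoir_params(seed = 11))
  n2 <- build_reservoir(reservoir_params(seed = 11))
  expect_identical(n1, n2)
  n3 <- build_reservoir(reservoir_params(seed = 12))
  expect_false(identical(n1$edges, n3$edges))
})

test_that("a zero radius yields no connections", {
  net <- build_reservoir(reservoir_params(small_world_radius = 0, seed = 1))
  expect_identical(nrow(net$edges), 0L)
})

test_that("a suprathreshold arriving spike fires the neuron and resets it", {
  p <- reservoir_params()
  st <- list(psp = c(0, 0), refractory = c(0L, 0L))
  out <- lif_step(st, arriving = c(0, 0.6), p)
  expect_identical(which(out$fired), 2L)
  expect_equal(out$states$psp[2], 0)
  expect_identical(out$states$refractory[2], 1L)
  # zero input forever: psp stays 0
  st <- list(psp = c(0, 0), refractory = c(0L, 0L))
  for (i in 1:10) st <- lif_step(st, c(0, 0), p)$states
  expect_equal(st$psp, c(0, 0))
})

test_that("the LIF trace matches a hand-stepped oracle on a 3-synapse neuron", {
  # three synapses (weights 0.1, 0.1, 0.35), leak 0.02/step, threshold 0.5,
  # refractory 3 steps, driven by constructed arrival trains
  p <- reservoir_params(leak_per_step = 0.02, refractory_steps = 3L)
  w <- c(0.1, 0.1, 0.35)
  arrivals <- list(c(2, 4, 6, 8, 10, 14, 18, 22), c(3, 6, 9, 12, 18, 21),
                   c(5, 12, 19, 23))
  oracle <- naive_lif_trace(w, arrivals, 25L, p)
  st <- list(psp = 0, refractory = 0L)
  psp_trace <- numeric(25); spikes <- integer(0)
  for (t in 1:25) {
    arr <- sum(w[vapply(arrivals, function(s) t %in% s, logical(1))])
    out <- lif_step(st, arr, p)
    st <- out$states
    psp_trace[t] <- st$psp
    if (out$fired) spikes <- c(spikes, t)
  }
  expect_equal(psp_trace, oracle$psp)
  expect_identical(spikes, oracle$spikes)
  expect_gt(length(spikes), 0)              # the drive does cross threshold
  expect_true(all(diff(spikes) > p$refractory_steps))
})

test_that("vectorised propagation matches the naive per-neuron reference", {
  for (s in 1:30) {
    fx <- random_small_net(seed = 1000 + s, n_steps = 120L)
    got <- record_to_matrix(propagate(fx$net, fx$raster)$record, fx$net$n)
    want <- naive_propagate(fx$net, fx$raster)
    expect_identical(got, want, label = sprintf("net seed %d", 1000 + s))
  }
})

test_that("no neuron fires on consecutive steps when refractory >= 1", {
  for (s in 1:5) {
    fx <- random_small_net(seed = 600 + s, n_steps = 150L)
    fx$net$params$refractory_steps <- 1L
    rec <- propagate(fx$net, fx$raster)$record
    non_input <- setdiff(seq_len(fx$net$n), fx$net$input_map)
    for (j in non_input)
      if (length(rec$firings[[j]]) > 1)
        expect_true(all(diff(rec$firings[[j]]) >= 2))
  }
})

test_that("the STDP law is antisymmetric, decaying and bounded", {
  dt <- -50:50
  dw <- stdp_delta(dt, lr = 0.001)
  expect_equal(stdp_delta(1, 0.001), 0.0005)
  expect_equal(stdp_delta(0, 0.001), 0)
  expect_equal(stdp_delta(-9, 0.001), -0.0001)
  expect_equal(dw, -stdp_delta(-dt, 0.001))
  pos <- dw[dt > 0]
  expect_true(all(diff(pos) < 0))              # strictly decaying magnitude
  expect_true(all(abs(dw) <= 0.001))
})

test_that("a single causal pre-post pair changes exactly one edge by LR/3", {
  coords <- matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE)
  edges <- data.frame(pre = 1L, post = 2L, weight = 0.2,
                      is_input_edge = TRUE, dist = 10)
  net <- make_test_net(coords, edges, input_map = c(a_n1 = 1L, b_n1 = 2L))
  raster <- matrix(0L, 2, 10)
  raster[1, 4] <- 1L  # pre fires at step 3 (0-based)
  raster[2, 6] <- 1L  # post fires at step 5
  out <- propagate(net, raster, plasticity = TRUE)
  expect_equal(out$net$edges$weight, 0.2 + 0.001 / 3)
  # all-empty rasters leave weights unchanged
  out0 <- propagate(net, matrix(0L, 2, 10), plasticity = TRUE)
  expect_equal(out0$net$edges$weight, 0.2)
  # anti-causal order depresses instead
  raster2 <- matrix(0L, 2, 10)
  raster2[1, 6] <- 1L; raster2[2, 4] <- 1L
  out2 <- propagate(net, raster2, plasticity = TRUE)
  expect_equal(out2$net$edges$weight, 0.2 - 0.001 / 3)
})

test_that("per-update STDP magnitude never exceeds the learning rate", {
  trials <- tiny_synth(seed = 5)
  bank <- fit_receptive_fields(trials)
  net <- build_reservoir(small_reservoir_params(seed = 2))
  w0 <- net$edges$weight
  net1 <- propagate(net, encode_trial(trials[[1]], bank),
                    plasticity = TRUE)$net
  rec <- propagate(net, encode_trial(trials[[1]], bank))$record
  n_fire <- sum(rec$fire_counts)
  expect_true(all(abs(net1$edges$weight - w0) <= 0.001 * n_fire))
  expect_gt(sum(net1$edges$weight != w0), 0)
})

test_that("propagation records firings and per-edge transmitted counts", {
  trials <- tiny_synth(seed = 6)
  bank <- fit_receptive_fields(trials)
  net <- build_reservoir(small_reservoir_params(seed = 3))
  raster <- encode_trial(trials[[1]], bank)
  out <- propagate(net, raster)
  rec <- out$record
  # input neurons fire exactly their raster rows
  for (i in seq_along(net$input_map)) {
    want <- which(raster[i, ] > 0) - 1L
    expect_identical(rec$firings[[net$input_map[i]]], want)
  }
  # conservation: transmitted count = presynaptic firing count per edge
  expect_identical(rec$transmitted, rec$fire_counts[net$edges$pre])
  # all-zero raster propagates nothing
  rec0 <- propagate(net, raster * 0L)$record
  expect_equal(sum(rec0$fire_counts), 0)
  # determinism
  expect_identical(propagate(net, raster)$record, rec)
  expect_error(propagate(net, raster[1:10, ]), "80")
})

test_that("unsupervised training updates weights and flags the net trained", {
  trials <- tiny_synth(seed = 8)
  bank <- fit_receptive_fields(trials)
  rasters <- lapply(trials, encode_trial, bank = bank)
  net <- build_reservoir(small_reservoir_params(seed = 5))
  trained <- train_unsupervised(net, rasters)
  expect_true(trained$trained)
  expect_gt(sum(trained$edges$weight != net$edges$weight), 0)
  expect_identical(trained$edges[, c("pre", "post", "dist")],
                   net$edges[, c("pre", "post", "dist")])
  # geometry is untouched by training: lengths still within the radius
  expect_true(all(trained$edges$dist <= net$params$small_world_radius + 1e-9))
  # deterministic: same inputs, same result
  expect_identical(train_unsupervised(net, rasters), trained)
})

test_that("with no activity every communication cluster is its input alone", {
  net <- build_reservoir(small_reservoir_params(seed = 6))
  net$trained <- TRUE
  trials <- tiny_synth(seed = 9)
  bank <- fit_receptive_fields(trials)
  empty <- encode_trial(trials[[1]], bank) * 0L
  sizes <- spike_communication_clusters(net, list(empty))
  expect_equal(sum(sizes), net$n)                     # partition
  expect_true(all(sizes[names(net$input_map)] == 1))  # each input by itself
  expect_equal(unname(sizes["unassigned"]), net$n - 80L)
})

test_that("clusters partition the reservoir and grow with activity", {
  trials <- tiny_synth(seed = 10, effect = 3)
  bank <- fit_receptive_fields(trials)
  rasters <- lapply(trials, encode_trial, bank = bank)
  net <- train_unsupervised(build_reservoir(small_reservoir_params(seed = 7)),
                            rasters)
  sizes <- spike_communication_clusters(net, rasters)
  expect_equal(sum(sizes), net$n)
  expect_true(all(sizes[names(net$input_map)] >= 1))
  expect_lt(unname(sizes["unassigned"]), net$n - 80L)
  expect_warning(
    spike_communication_clusters(build_reservoir(small_reservoir_params(seed = 7)),
                                 rasters[1]),
    "trained")
})
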