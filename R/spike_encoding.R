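# Population spike encoding: each feature drives a small population of
# neurons whose receptive-field ranges are equal-count (quantile) partitions
# of the pooled feature distribution; at each of the 64 window samples
# exactly one neuron of the population spikes, and zeros are interleaved so
# each train is 129 steps long.

#' Fit equal-count receptive fields for every feature
#'
#' For each feature the values of all supplied trials are pooled and split
#' into `per_feature_neurons` ranges holding an equal share of the pooled
#' values (within one, for distinct values). The boundaries are midpoints
#' between the flanking order statistics. A feature whose boundaries are not
#' strictly ascending (e.g. all values identical) is flagged degenerate; its
#' encoder then routes every value to the middle neuron.
#'
#' @param trials List of [labeled_trial()] objects.
#' @param per_feature_neurons Population size per feature (default 5).
#' @param features Feature subset to fit (default all 16).
#' @return A `receptive_field_bank`: list with `boundaries` (matrix, one row
#'   per feature, `per_feature_neurons - 1` columns), `degenerate` flags,
#'   `n_neurons`, and a `fitted_on` descriptor of the contributing trials.
#' @export
fit_receptive_fields <- function(trials, per_feature_neurons = 5L,
                                 features = valence_features()) {
  if (length(trials) == 0L) stop_invalid("cannot fit receptive fields on an empty trial list")
  m <- as.integer(per_feature_neurons)
  stopifnot(m >= 2L)
  boundaries <- matrix(NA_real_, length(features), m - 1L,
                       dimnames = list(features, NULL))
  degenerate <- logical(length(features)); names(degenerate) <- features
  for (f in features) {
    pooled <- sort(unlist(lapply(trials, function(tr) tr$features[f, ])))
    n <- length(pooled)
    ranks <- floor(seq_len(m - 1L) * n / m + 0.5)
    ranks <- pmin(pmax(ranks, 1L), n)
    b <- (pooled[ranks] + pooled[pmin(ranks + 1L, n)]) / 2
    if (any(diff(b) <= 0) || n < m) {
      degenerate[f] <- TRUE
    }
    boundaries[f, ] <- b
  }
  structure(list(boundaries = boundaries, degenerate = degenerate,
                 n_neurons = m,
                 fitted_on = sprintf("%d trials (%s)", length(trials),
                                     paste(unique(vapply(trials, `[[`,
                                                         "", "subject_id")),
                                           collapse = ","))),
            class = "receptive_field_bank")
}

#' @export
print.receptive_field_bank <- function(x, ...) {
  cat(sprintf("<receptive_field_bank> %d features x %d neurons, fitted on %s\n",
              nrow(x$boundaries), x$n_neurons, x$fitted_on))
  invisible(x)
}

# Map values to population neuron indices (1 = lowest range). Ties at a
# boundary go to the lower range; degenerate features use the middle neuron.
assign_neuron <- function(values, boundaries, degenerate, n_neurons) {
  if (degenerate) return(rep(ceiling(n_neurons / 2), length(values)))
  1L + colSums(outer(boundaries, values, FUN = "<"))
}

#' Encode one 64-sample feature series as a population spike block
#'
#' Sample `k` (`k = 0..63`) produces a single spike at time step `2k + 1` on
#' the neuron whose receptive-field range contains the value; all other
#' entries are zero, giving a `n_neurons x 129` binary block (zeros
#' interleaved between spike opportunities, step 0 silent).
#'
#' @param series Numeric vector of length 64.
#' @param bank A fitted `receptive_field_bank`.
#' @param feature Feature name selecting the bank row.
#' @return Binary `n_neurons x 129` matrix.
#' @export
encode_feature <- function(series, bank, feature) {
  stopifnot(inherits(bank, "receptive_field_bank"))
  if (length(series) != 64L)
    stop_invalid("series must have length 64 (got %d)", length(series))
  if (!feature %in% rownames(bank$boundaries))
    stop_invalid("bank has no receptive fields for feature `%s`", feature)
  neuron <- assign_neuron(series, bank$boundaries[feature, ],
                          bank$degenerate[[feature]], bank$n_neurons)
  n_steps <- 2L * length(series) + 1L
  block <- matrix(0L, bank$n_neurons, n_steps)
  block[cbind(neuron, 2L * seq_along(series))] <- 1L  # step 2k+1, 1-based col
  block
}

#' Encode a trial as an input spike raster
#'
#' Stacks the per-feature population blocks in canonical feature order into
#' one binary raster of `5 * n_features` input rows by 129 time steps.
#'
#' @param trial A [labeled_trial()].
#' @param bank A fitted `receptive_field_bank`.
#' @param features Feature subset (default all 16, giving 80 rows).
#' @return A `spike_raster`: binary matrix with row names like `f10_n5` and
#'   attributes `features` and `label`.
#' @export
encode_trial <- function(trial, bank, features = rownames(bank$boundaries)) {
  stopifnot(inherits(trial, "labeled_trial"))
  missing_f <- setdiff(features, rownames(bank$boundaries))
  if (length(missing_f))
    stop_invalid("bank not fitted for feature(s): %s",
                 paste(missing_f, collapse = ", "))
  blocks <- lapply(features, function(f)
    encode_feature(trial$features[f, ], bank, f))
  raster <- do.call(rbind, blocks)
  rownames(raster) <- as.vector(t(outer(features, seq_len(bank$n_neurons),
                                        function(f, n) paste0(f, "_n", n))))
  structure(raster, features = features, label = trial$label,
            class = c("spike_raster", class(raster)))
}
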