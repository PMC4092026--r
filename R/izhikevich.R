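#' Izhikevich neuron parameter presets
#'
#' The two-variable simple model: `dv/dt = 0.04 v^2 + 5 v + 140 - u + I`,
#' `du/dt = a (b v - u)`, with reset `v <- c`, `u <- u + d` whenever `v`
#' reaches the 30 mV spike peak. Excitatory neurons use the regular-spiking
#' preset (a = 0.02, b = 0.2, c = -65, d = 8) and inhibitory neurons the
#' fast-spiking preset (a = 0.1, b = 0.2, c = -65, d = 2).
#'
#' @param type `"excitatory"` or `"inhibitory"`.
#' @return Named list with elements `a`, `b`, `c`, `d`.
#' @export
izhikevich_preset <- function(type = c("excitatory", "inhibitory")) {
  switch(match.arg(type),
         excitatory = list(a = 0.02, b = 0.2, c = -65, d = 8),
         inhibitory = list(a = 0.1, b = 0.2, c = -65, d = 2))
}

#' Advance one Izhikevich neuron by one Euler step
#'
#' @param state List with `v` (membrane potential, mV), `u` (recovery
#'   variable) and `fired` (logical).
#' @param params Preset from [izhikevich_preset()].
#' @param input_current Injected current I for this step.
#' @param dt Step size in ms (> 0; default 1).
#' @return Updated state; `fired` is `TRUE` iff the neuron spiked this step,
#'   in which case `v` has been reset to `params$c`.
#' @export
step_neuron <- function(state, params, input_current, dt = 1) {
  stopifnot(dt > 0)
  v <- state$v
  u <- state$u
  if (!is.finite(v) || !is.finite(u))
    stop("non-finite neuron state", call. = FALSE)
  v <- v + dt * (0.04 * v^2 + 5 * v + 140 - u + input_current)
  u <- u + dt * params$a * (params$b * state$v - u)
  fired <- v >= 30
  if (fired) {
    v <- params$c
    u <- u + params$d
  }
  list(v = v, u = u, fired = fired)
}

#' Random input projection
#'
#' Maps each input feature to a fixed random subset of reservoir neurons;
#' every feature fans out to `ceiling(fanout * n_nodes)` distinct neurons.
#'
#' @param n_features Number of input features.
#' @param n_nodes Reservoir size.
#' @param fanout Fraction of the reservoir each feature projects to
#'   (default 0.3).
#' @param seed Integer seed.
#' @return List of integer neuron-index vectors, one per feature.
#' @export
make_input_projection <- function(n_features, n_nodes, fanout = 0.3,
                                  seed = 1L) {
  local_rng(seed)
  k <- ceiling(fanout * n_nodes)
  lapply(seq_len(n_features), function(f) sort(sample.int(n_nodes, k)))
}

#' Simulate the reservoir's response to one input sample
#'
#' Runs the spiking reservoir for `duration` ms of Euler integration at step
#' `dt`. Input features (already normalised to `[0, 1]`) are scaled by
#' `input_scale` and injected as current into their projected neurons; each
#' input frame is held for `duration / n_frames` ms. Synapses are static
#' delta impulses without delay: a spike in neuron `j` at step `t` injects
#' current `W[i, j]` into neuron `i` at step `t + 1`.
#'
#' @param topology A weighted `weighted_topology`.
#' @param input_frames Numeric `frames x features` matrix in `[0, 1]`.
#' @param projection Projection from [make_input_projection()] (one entry per
#'   feature).
#' @param duration Simulation length in ms (default 150).
#' @param dt Euler step in ms (default 1).
#' @param input_scale Input current scaling factor (default 20).
#' @return A `spike_train_set`: list of per-neuron spike-time vectors (ms,
#'   strictly increasing), with attributes `duration` and `n_nodes`.
#' @export
simulate_sample <- function(topology, input_frames, projection,
                            duration = 150, dt = 1, input_scale = 20) {
  stopifnot(inherits(topology, "weighted_topology"), topology$weighted)
  n <- topology$n_nodes
  W <- topology$weights
  input_frames <- as.matrix(input_frames)
  n_frames <- nrow(input_frames)
  stopifnot(ncol(input_frames) == length(projection))

  # per-step injected current from the (held) input frames
  n_steps <- as.integer(round(duration / dt))
  frame_of_step <- pmin(ceiling(seq_len(n_steps) * n_frames / n_steps),
                        n_frames)
  drive <- matrix(0, n, n_frames)
  for (f in seq_along(projection)) {
    drive[projection[[f]], ] <- drive[projection[[f]], ] +
      rep(input_scale * input_frames[, f], each = length(projection[[f]]))
  }

  exc <- topology$excitatory
  a <- ifelse(exc, 0.02, 0.1)
  b <- 0.2
  cc <- rep(-65, n)
  d <- ifelse(exc, 8, 2)

  v <- rep(-65, n)
  u <- b * v
  fired_prev <- logical(n)
  spikes <- vector("list", n_steps)

  for (t in seq_len(n_steps)) {
    I <- drive[, frame_of_step[t]]
    if (any(fired_prev)) {
      I <- I + rowSums(W[, fired_prev, drop = FALSE])
    }
    v_new <- v + dt * (0.04 * v * v + 5 * v + 140 - u + I)
    u <- u + dt * a * (b * v - u)
    if (!all(is.finite(v_new)))
      stop(sprintf("non-finite membrane potential at step %d", t),
           call. = FALSE)
    fired <- v_new >= 30
    v_new[fired] <- cc[fired]
    u[fired] <- u[fired] + d[fired]
    v <- v_new
    spikes[[t]] <- which(fired)
    fired_prev <- fired
  }

  out <- vector("list", n)
  for (i in seq_len(n)) out[[i]] <- numeric(0)
  times <- rep(seq_len(n_steps) * dt, lengths(spikes))
  ids <- unlist(spikes, use.names = FALSE)
  if (length(ids)) {
    split_times <- split(times, factor(ids, levels = seq_len(n)))
    out <- lapply(split_times, as.numeric)
  }
  structure(out, duration = duration, n_nodes = n, class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d neurons, %d spikes in %g ms\n",
              attr(x, "n_nodes"), sum(lengths(x)), attr(x, "duration")))
  invisible(x)
}

#' Low-pass filter spike trains into a reservoir state vector
#'
#' Each neuron's spike train is convolved with a causal exponential kernel
#' and read out at the end of the sample window:
#' `x_i = sum_k exp(-(duration - t_k) / tau)`. A silent neuron contributes 0;
#' a spike exactly at `duration` contributes 1.
#'
#' @param spikes A `spike_train_set`.
#' @param tau Filter time constant in ms (> 0; default 30).
#' @param duration Sample window length in ms; defaults to the spike set's.
#' @return Numeric state vector of length `n_nodes` (all entries >= 0).
#' @export
filter_spike_trains <- function(spikes, tau = 30,
                                duration = attr(spikes, "duration")) {
  stopifnot(tau > 0)
  vapply(spikes, function(ts) {
    if (!length(ts)) return(0)
    sum(exp(-(duration - ts) / tau))
  }, double(1))
}

#' Export spike trains as two-column delimited text
#'
#' @param spikes A `spike_train_set`.
#' @param path Output path; columns `neuron`, `time_ms`.
#' @return `path`, invisibly.
#' @export
write_spike_trains <- function(spikes, path) {
  df <- data.frame(neuron = rep(seq_along(spikes), lengths(spikes)),
                   time_ms = unlist(spikes, use.names = FALSE))
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
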