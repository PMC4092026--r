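# Small builders shared across test files. Everything is generated in code;
# no binary fixtures.

tiny_topology <- function(n = 6, p = 0.5, seed = 42, weighted = TRUE) {
  topo <- generate_uniform(n, p, seed)
  if (weighted) topo <- assign_weights(topo, seed = seed + 1) else topo
}

# A hand-specified two-neuron topology: one synapse 1 -> 2 with weight w.
two_neuron_topology <- function(w = 10, exc = c(TRUE, TRUE)) {
  topo <- generate_uniform(2, 0, seed = 1)
  topo$excitatory <- exc
  topo$weights <- matrix(c(0, w, 0, 0), 2, 2)  # entry [2,1] = synapse 1 -> 2
  topo$weighted <- TRUE
  topo
}

# spike_train_set from a plain list of spike-time vectors
make_spikes <- function(times, duration = 150) {
  structure(times, duration = duration, n_nodes = length(times),
            class = "spike_train_set")
}

# labelled random state fixture for metric tests
random_states <- function(L = 10, N = 20, C = 3, seed = 1) {
  set.seed(seed)
  list(states = matrix(rnorm(L * N), L, N),
       labels = sample(rep(seq_len(C), length.out = N)))
}
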