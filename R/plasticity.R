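#' Synaptic plasticity rules
#'
#' Three unsupervised rules adapt the reservoir weights during a pre-training
#' phase (with a static no-op control): the rate-based BCM rule with a sliding
#' modification threshold, and spike-timing-dependent plasticity (STDP) with
#' either a bi-phasic or a tri-phasic learning window. All rules update the
#' signed weight and clamp it to the Dale-sign-preserving range: excitatory
#' synapses to `[0, 10]`, inhibitory to `[-10, 0]`. The zero pattern of the
#' topology is never changed.
#'
#' @name plasticity
NULL

#' STDP parameters
#'
#' Bi-phasic window (two decaying exponentials):
#' `A_plus * exp(-dt / tau_plus)` for `dt > 0` (in-order pairs, potentiation)
#' and `-A_minus * exp(dt / tau_minus)` for `dt < 0` (out-of-order pairs,
#' depression), where `dt` is post minus pre spike time. A simultaneous pair
#' (`dt = 0`) contributes nothing.
#'
#' Tri-phasic window (difference of two Gaussians centred at `tri_center`):
#' `tri_a_plus * exp(-(dt - tri_center)^2 / tri_den_plus) -
#'  tri_a_minus * exp(-(dt - tri_center)^2 / tri_den_minus)`,
#' a narrow potentiating bump for closely in-order pairs flanked by
#' depression on both sides (uncorrelated and late activity), the window
#' shape reported between hippocampal areas CA3 and CA1.
#'
#' @param A_plus,A_minus Bi-phasic amplitudes (> 0).
#' @param tau_plus,tau_minus Bi-phasic time constants in ms (> 0).
#' @param tri_a_plus,tri_a_minus Tri-phasic amplitudes (> 0).
#' @param tri_center Centre of the tri-phasic window in ms.
#' @param tri_den_plus,tri_den_minus Gaussian width denominators (ms^2) of the
#'   potentiating and depressing lobes.
#' @param horizon Pairing horizon in ms: spike pairs farther apart are
#'   ignored.
#' @return Named list of STDP parameters.
#' @export
stdp_params <- function(A_plus = 0.05, A_minus = 0.055,
                        tau_plus = 20, tau_minus = 20,
                        tri_a_plus = 0.25, tri_a_minus = 0.1,
                        tri_center = 15,
                        tri_den_plus = 200, tri_den_minus = 2000,
                        horizon = 50) {
  stopifnot(A_plus > 0, A_minus > 0, tau_plus > 0, tau_minus > 0,
            tri_a_plus > 0, tri_a_minus > 0,
            tri_den_plus > 0, tri_den_minus > 0, horizon > 0)
  as.list(environment())
}

#' @describeIn plasticity Bi-phasic STDP learning window; `delta_t` is the
#'   post-minus-pre spike delay in ms (vectorised).
#' @param delta_t Spike delay(s), ms.
#' @param params From [stdp_params()].
#' @export
stdp_biphasic_window <- function(delta_t, params = stdp_params()) {
  ifelse(delta_t > 0, params$A_plus * exp(-delta_t / params$tau_plus),
         ifelse(delta_t < 0, -params$A_minus * exp(delta_t / params$tau_minus),
                0))
}

#' @describeIn plasticity Tri-phasic STDP learning window (vectorised).
#' @export
stdp_triphasic_window <- function(delta_t, params = stdp_params()) {
  z2 <- (delta_t - params$tri_center)^2
  params$tri_a_plus * exp(-z2 / params$tri_den_plus) -
    params$tri_a_minus * exp(-z2 / params$tri_den_minus)
}

#' Apply an STDP window to all spike pairs of one simulated sample
#'
#' For every synapse `j -> i` with at least one presynaptic and one
#' postsynaptic spike, accumulates `window(t_post - t_pre)` over all spike
#' pairs within `params$horizon`, adds the summed change to the weight, and
#' clamps to the sign-preserving range.
#'
#' @param spikes A `spike_train_set` from [simulate_sample()].
#' @param topology A weighted `weighted_topology`.
#' @param window A window function such as [stdp_biphasic_window()] or
#'   [stdp_triphasic_window()].
#' @param params From [stdp_params()].
#' @return The topology with adapted, clamped weights.
#' @export
apply_stdp <- function(spikes, topology, window = stdp_biphasic_window,
                       params = stdp_params()) {
  n <- topology$n_nodes
  times <- unlist(spikes, use.names = FALSE)
  if (length(times)) {
    neuron <- rep(seq_len(n), lengths(spikes))
    # aggregate all spike pairs per ordered neuron pair by collapsing events
    # onto their (few) unique times: dW = C F C^T with C the neuron-by-time
    # spike-count matrix and F[a, b] = window(t_a - t_b), so that
    # dW[i, j] = sum over (post spike of i at t_a, pre spike of j at t_b)
    u <- sort(unique(times))
    C <- matrix(0, n, length(u))
    tab <- table(factor(neuron, levels = seq_len(n)),
                 factor(times, levels = u))
    C[] <- as.numeric(tab)
    dts <- outer(u, u, "-")  # [post time, pre time]
    F <- window(dts, params) * (abs(dts) <= params$horizon)
    dW <- C %*% F %*% t(C)
    mask <- topology$weights != 0
    topology$weights <- topology$weights + dW * mask
  }
  clamp_weights(topology)
}

#' Clamp weights to the Dale-sign-preserving range
#'
#' Excitatory synapses are clipped to `[0, 10]`, inhibitory to `[-10, 0]`;
#' a sign can never flip, and absent synapses stay absent.
#'
#' @param topology A weighted `weighted_topology`.
#' @param bound Clamp magnitude (default 10).
#' @return The clamped topology.
#' @export
clamp_weights <- function(topology, bound = 10) {
  W <- topology$weights
  exc <- topology$excitatory
  W[, exc] <- pmin(pmax(W[, exc, drop = FALSE], 0), bound)
  W[, !exc] <- pmin(pmax(W[, !exc, drop = FALSE], -bound), 0)
  topology$weights <- W
  topology
}

#' BCM plasticity state
#'
#' Running quantities of the rate-based BCM rule: the temporal average
#' `y_bar` of each neuron's postsynaptic activity (an exponential moving
#' average with the given horizon, in samples), the sliding modification
#' threshold `theta = y_bar^2 / y0` (floored at `theta_min` for numerical
#' safety), the desired activity level `y0`, the learning rate `eta`, and the
#' uniform weight-decay rate `epsilon`.
#'
#' @param n_nodes Reservoir size.
#' @param y0 Desired postsynaptic activity level in filtered-state units
#'   (default 1).
#' @param eta Learning rate (default 0.05).
#' @param epsilon Weight decay rate per update (default 0.1).
#' @param horizon Samples over which the activity average slides (default 10).
#' @param theta_min Lower floor for the threshold (default 0.05).
#' @return An object of class `bcm_state`.
#' @export
bcm_state <- function(n_nodes, y0 = 1, eta = 0.05, epsilon = 0.1,
                      horizon = 10, theta_min = 0.05) {
  stopifnot(y0 > 0, eta > 0, epsilon >= 0, horizon >= 1, theta_min > 0)
  structure(
    list(y_bar = rep(y0, n_nodes), y0 = y0, eta = eta, epsilon = epsilon,
         horizon = horizon, theta_min = theta_min),
    class = "bcm_state"
  )
}

bcm_theta <- function(state) {
  pmax(state$y_bar^2 / state$y0, state$theta_min)
}

#' One BCM update for a single synapse
#'
#' The weight change is the threshold-normalised Hebbian term minus uniform
#' decay:
#' `dw = eta * post * (post - theta) * pre / theta - epsilon * w`,
#' with `theta = y_bar^2 / y0` sliding with the temporal average of the
#' postsynaptic activity. Activity above threshold potentiates, below
#' threshold depresses, and the sliding threshold regulates the postsynaptic
#' rate toward `y0`. The returned state carries the updated activity average.
#'
#' @param weight Current synaptic weight (scalar).
#' @param pre_activity,post_activity Non-negative rate estimates (filtered
#'   spike-train values).
#' @param state A length-1 [bcm_state()].
#' @param excitatory Is the presynaptic neuron excitatory? Sets the clamp
#'   range.
#' @return List with `weight` (updated, clamped) and `state`.
#' @export
bcm_update <- function(weight, pre_activity, post_activity, state,
                       excitatory = TRUE) {
  stopifnot(pre_activity >= 0, post_activity >= 0)
  theta <- bcm_theta(state)[1]
  dw <- state$eta * post_activity * (post_activity - theta) * pre_activity /
    theta - state$epsilon * weight
  w <- weight + dw
  w <- if (excitatory) min(max(w, 0), 10) else min(max(w, -10), 0)
  state$y_bar[1] <- state$y_bar[1] +
    (post_activity - state$y_bar[1]) / state$horizon
  list(weight = w, state = state)
}

#' One BCM update of the whole reservoir from a sample's activity
#'
#' Vectorised form of [bcm_update()] over every existing synapse, using the
#' sample's filtered state vector as both the pre- and postsynaptic rate
#' estimate, followed by clamping and an update of the sliding averages.
#'
#' @param topology A weighted `weighted_topology`.
#' @param activity Filtered state vector of the sample (length `n_nodes`).
#' @param state A [bcm_state()] of matching size.
#' @return List with `topology` (adapted) and `state` (updated averages).
#' @export
apply_bcm <- function(topology, activity, state) {
  W <- topology$weights
  theta <- bcm_theta(state)
  hebb <- state$eta * activity * (activity - theta) / theta  # per postsyn i
  mask <- W != 0
  dW <- outer(hebb, activity) * mask - state$epsilon * W
  topology$weights <- W + dW
  topology <- clamp_weights(topology)
  state$y_bar <- state$y_bar + (activity - state$y_bar) / state$horizon
  list(topology = topology, state = state)
}
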