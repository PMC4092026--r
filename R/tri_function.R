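#' Generate the tri-function switching benchmark signal
#'
#' Produces a univariate signal in which one of three generating functions is
#' active at any timestep: a sinusoid of a randomly drawn period, the chaotic
#' tent map, or a randomly drawn constant. At every step the active generator
#' is redrawn, uniformly among all three, with probability `switch_probability`
#' (so the rate of switches to a *different* generator is 2/3 of it). All
#' values lie in `[0, 1]`.
#'
#' Segment parameters are drawn at segment start: the sine period uniformly in
#' `[10, 50]` steps, the tent-map seed and the constant level uniformly in
#' `[0, 1]`. The tent map iterates `x <- 2 * min(x, 1 - x)`.
#'
#' @param n_steps Number of timesteps (>= 1).
#' @param switch_probability Per-step probability of redrawing the active
#'   generator, in (0, 1).
#' @param seed Integer seed; the same seed reproduces the signal exactly.
#' @return A tibble of class `tri_function_signal` with columns `step`,
#'   `value`, `generator` (factor with levels sine, tent, constant) and
#'   `segment` (counter that increments at every redraw of the generator).
#' @examples
#' sig <- generate_tri_function(500, 0.05, seed = 1)
#' table(sig$generator)
#' @export
generate_tri_function <- function(n_steps, switch_probability = 0.05, seed = 1L) {
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 1)
    stop("`n_steps` must be a positive integer", call. = FALSE)
  if (switch_probability <= 0 || switch_probability >= 1)
    stop("`switch_probability` must be in (0, 1)", call. = FALSE)
  n_steps <- as.integer(n_steps)
  gens <- c("sine", "tent", "constant")

  local_rng(seed)
  values <- numeric(n_steps)
  labels <- character(n_steps)
  segment_id <- integer(n_steps)

  draw_params <- function(g) {
    switch(g,
      sine     = list(period = stats::runif(1, 10, 50),
                      phase  = stats::runif(1, 0, 2 * pi)),
      tent     = list(x = stats::runif(1)),
      constant = list(level = stats::runif(1))
    )
  }

  g <- sample(gens, 1L)
  par <- draw_params(g)
  t_seg <- 0L
  seg <- 1L
  for (t in seq_len(n_steps)) {
    if (t > 1L && stats::runif(1) < switch_probability) {
      g <- sample(gens, 1L)
      par <- draw_params(g)
      t_seg <- 0L
      seg <- seg + 1L
    }
    values[t] <- switch(g,
      sine     = 0.5 + 0.5 * sin(2 * pi * t_seg / par$period + par$phase),
      tent     = { x <- par$x; par$x <- 2 * min(x, 1 - x); x },
      constant = par$level
    )
    labels[t] <- g
    segment_id[t] <- seg
    t_seg <- t_seg + 1L
  }

  out <- tibble::tibble(
    step = seq_len(n_steps),
    value = values,
    generator = factor(labels, levels = gens),
    segment = segment_id
  )
  attr(out, "switch_probability") <- switch_probability
  class(out) <- c("tri_function_signal", class(out))
  out
}

#' Cut a tri-function signal into labelled classification samples
#'
#' Consecutive non-overlapping windows of the signal become samples of a
#' [labelled sequence dataset][sequence_dataset]; each window's class is the
#' majority generator within it, ties broken in favour of the generator that
#' appears earliest in the window. Each sample is a `window_length x 1` matrix
#' (the signal is a single feature observed over time).
#'
#' @param signal A `tri_function_signal` tibble from [generate_tri_function()].
#' @param window_length Window size in steps (>= 1, <= signal length). Trailing
#'   steps that do not fill a window are dropped.
#' @return A `sequence_dataset` with `n_classes = 3` (1 = sine, 2 = tent,
#'   3 = constant).
#' @export
segment_signal <- function(signal, window_length = 15L) {
  stopifnot(inherits(signal, "tri_function_signal"))
  n <- nrow(signal)
  if (window_length < 1) stop("`window_length` must be >= 1", call. = FALSE)
  if (window_length > n)
    stop("`window_length` exceeds the signal length", call. = FALSE)
  n_win <- n %/% window_length
  samples <- vector("list", n_win)
  labels <- integer(n_win)
  gen <- as.integer(signal$generator)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * window_length + 1L):(w * window_length)
    samples[[w]] <- matrix(signal$value[idx], ncol = 1L,
                           dimnames = list(NULL, "signal"))
    labels[w] <- majority_label(gen[idx])
  }
  sequence_dataset(samples, labels, n_classes = 3L,
                   class_names = levels(signal$generator))
}

# majority vote; ties broken by earliest occurrence in the window
majority_label <- function(x) {
  counts <- tabulate(x, nbins = max(x))
  top <- which(counts == max(counts))
  if (length(top) == 1L) return(top)
  firsts <- vapply(top, function(k) match(k, x), integer(1))
  top[which.min(firsts)]
}
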