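#' Reservoir quality metrics
#'
#' Four measures of a reservoir computed from its state matrix (columns are
#' per-sample filtered state vectors), the corresponding inputs, and its
#' weight matrix: class separation, kernel quality, a Lyapunov exponent
#' estimate, and spectral radius. See the individual functions.
#'
#' @name reservoir_metrics
NULL

#' Class separation of labelled reservoir states
#'
#' The mean pairwise distance between distinct class centroids divided by the
#' mean within-class spread plus one:
#' \deqn{Sep = \frac{\frac{1}{C(C-1)}\sum_{m \ne n} \lVert c_m - c_n \rVert}
#'                  {1 + \frac{1}{C}\sum_m \rho_m}}
#' where `c_m` is the centroid (mean state vector) of class `m`, `C` the
#' number of classes, and `rho_m` the mean Euclidean distance of class `m`'s
#' states to `c_m`. The `+1` in the denominator prevents division by zero.
#' Larger values should make a linear readout's job easier. With a single
#' class the inter-class term is 0.
#'
#' @param states `L x N` state matrix (one column per sample).
#' @param labels Class labels, one per column; every class non-empty.
#' @return Non-negative scalar.
#' @export
class_separation <- function(states, labels) {
  states <- as.matrix(states)
  stopifnot(ncol(states) == length(labels))
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 1L) stop("need at least one class", call. = FALSE)
  centroids <- vapply(classes, function(cl) {
    rowMeans(states[, labels == cl, drop = FALSE])
  }, double(nrow(states)))
  inter <- 0
  if (C > 1L) {
    for (m in seq_len(C)) {
      for (n in seq_len(C)) {
        inter <- inter + sqrt(sum((centroids[, m] - centroids[, n])^2))
      }
    }
    inter <- inter / (C * (C - 1))
  }
  intra <- mean(vapply(seq_len(C), function(m) {
    cols <- which(labels == classes[m])
    mean(sqrt(colSums((states[, cols, drop = FALSE] - centroids[, m])^2)))
  }, double(1)))
  inter / (1 + intra)
}

#' Kernel quality (linear separation property)
#'
#' The numerical rank of the state matrix `M` whose columns are the reservoir
#' state vectors: the number of singular values exceeding
#' `tolerance * sigma_max` (by default the standard machine-epsilon-scaled
#' threshold `max(dim(M)) * eps`). Bounded by `min(L, N)`; a reservoir whose
#' states span all `L` dimensions attains the maximum, `L`.
#'
#' @param states `L x N` state matrix.
#' @param tolerance Relative singular-value threshold; `NULL` (default) uses
#'   `max(dim(states)) * .Machine$double.eps`.
#' @return Integer rank in `[0, min(L, N)]`.
#' @export
kernel_quality <- function(states, tolerance = NULL) {
  states <- as.matrix(states)
  sv <- svd(states, nu = 0, nv = 0)$d
  if (!length(sv) || max(sv) == 0) return(0L)
  if (is.null(tolerance)) tolerance <- max(dim(states)) * .Machine$double.eps
  sum(sv > tolerance * max(sv))
}

#' Lyapunov exponent estimate from paired input/state distances
#'
#' A proportional estimate of the chaoticity of the input-driven reservoir
#' dynamics: for each sample `j`, its nearest neighbour `j'` in input space is
#' found, and the log-ratio of state-space to input-space distance is
#' averaged,
#' \deqn{\lambda \propto \frac{k\,L}{N}\sum_j
#'       \ln\frac{\lVert x_j - x_{j'} \rVert}{\lVert u_j - u_{j'} \rVert}}
#' with `u_j` the frame-averaged input vector of sample `j` and the scale
#' `k * L` (default `k = 1`, `L` the reservoir dimension, following the
#' convention of scaling by the state dimension 135). The constant is
#' undetermined, so values are comparable only within this estimator. Pairs
#' with zero input distance, or zero state distance (log undefined), are
#' skipped.
#'
#' @param inputs `d x N` matrix of per-sample input vectors (frame averages).
#' @param states `L x N` matrix of the corresponding state vectors.
#' @param scale Multiplier applied to the mean log-ratio (default
#'   `nrow(states)`, the reservoir dimension).
#' @return Scalar estimate (0 if every pair was skipped).
#' @export
lyapunov_estimate <- function(inputs, states, scale = nrow(states)) {
  inputs <- as.matrix(inputs)
  states <- as.matrix(states)
  N <- ncol(inputs)
  stopifnot(ncol(states) == N, N >= 2)
  d_in <- as.matrix(stats::dist(t(inputs)))
  diag(d_in) <- Inf
  ratios <- numeric(0)
  for (j in seq_len(N)) {
    jn <- which.min(d_in[j, ])
    du <- d_in[j, jn]
    if (!is.finite(du) || du == 0) next
    dx <- sqrt(sum((states[, j] - states[, jn])^2))
    if (dx == 0) next
    ratios <- c(ratios, log(dx / du))
  }
  if (!length(ratios)) return(0)
  scale * mean(ratios)
}

#' Spectral radius of a reservoir weight matrix
#'
#' The largest absolute eigenvalue of the weight matrix. Spectral radius
#' below 1 is associated with fading memory, near 1 with edge-of-chaos
#' dynamics. If the eigenvalue routine fails numerically the metric is
#' recorded as 0 with `valid = FALSE`, mirroring how failed computations are
#' treated in grid summaries.
#'
#' @param topology A `weighted_topology`, or a square numeric matrix.
#' @return List with `value` (non-negative scalar) and `valid` (logical).
#' @export
spectral_radius <- function(topology) {
  W <- if (inherits(topology, "weighted_topology")) topology$weights
       else as.matrix(topology)
  stopifnot(nrow(W) == ncol(W))
  if (!all(is.finite(W)))
    stop("weight matrix has non-finite entries", call. = FALSE)
  ev <- tryCatch(eigen(W, only.values = TRUE)$values,
                 error = function(e) NULL)
  if (is.null(ev) || !all(is.finite(Mod(ev)))) {
    return(list(value = 0, valid = FALSE))
  }
  list(value = max(Mod(ev)), valid = TRUE)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over the standard correlation: errors on fewer
#' than two points or zero variance rather than returning `NA`.
#'
#' @param xs,ys Numeric vectors of equal length (>= 2).
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  if (length(xs) < 2L) stop("need at least two points", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("correlation undefined: zero variance", call. = FALSE)
  stats::cor(xs, ys)
}
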