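#' Reservoir connectivity
#'
#' A `weighted_topology` holds the directed, signed connectivity of the
#' reservoir: an `n x n` weight matrix `W` where entry `W[i, j]` is the
#' synapse from presynaptic neuron `j` to postsynaptic neuron `i` (0 means no
#' synapse), a per-node excitatory mask at the 4:1 excitatory:inhibitory
#' ratio, and, for the lattice model, integer 3-D grid positions. Outgoing
#' synapses of excitatory neurons are non-negative and of inhibitory neurons
#' non-positive (Dale's sign convention); no neuron connects to itself.
#'
#' Three generators produce the unweighted adjacency: [generate_uniform()]
#' (Erdos-Renyi: every ordered pair connected independently with probability
#' `p`), [generate_scale_free()] (Barabasi-Albert preferential attachment;
#' each undirected attachment becomes one directed synapse with a fair coin
#' deciding direction), and [generate_lattice()] (neurons on a 3-D grid,
#' ordered pair at Euclidean distance `D` connected with probability
#' `C * exp(-(D / lambda)^2)`). [assign_weights()] then draws signed Gaussian
#' weights.
#'
#' @name weighted_topology
NULL

new_topology <- function(adj, excitatory, model, positions = NULL) {
  n <- nrow(adj)
  structure(
    list(n_nodes = n, weights = adj, excitatory = excitatory,
         model = model, positions = positions, weighted = FALSE),
    class = "weighted_topology"
  )
}

#' @export
print.weighted_topology <- function(x, ...) {
  cat(sprintf(
    "<weighted_topology> %s, %d nodes (%d exc / %d inh), %d synapses%s\n",
    x$model, x$n_nodes, sum(x$excitatory), sum(!x$excitatory),
    sum(x$weights != 0), if (x$weighted) ", weighted" else " (adjacency only)"))
  invisible(x)
}

# 4:1 split: after a seeded shuffle of node indices the first ceil(0.8 n)
# are excitatory
excitatory_mask <- function(n) {
  mask <- logical(n)
  mask[sample.int(n)[seq_len(ceiling(0.8 * n))]] <- TRUE
  mask
}

#' @describeIn weighted_topology Erdos-Renyi directed adjacency.
#' @param n_nodes Number of neurons (default 135).
#' @param p Connection probability for each ordered non-self pair.
#' @param seed Integer seed.
#' @export
generate_uniform <- function(n_nodes = 135L, p = 0.1, seed = 1L) {
  if (p < 0 || p > 1) stop("`p` must be a probability", call. = FALSE)
  local_rng(seed)
  n <- as.integer(n_nodes)
  adj <- matrix(stats::runif(n * n) < p, n, n) * 1
  diag(adj) <- 0
  new_topology(adj, excitatory_mask(n), "uniform")
}

#' @describeIn weighted_topology Barabasi-Albert scale-free adjacency.
#' @param edges_per_new_node Attachments made by each newly added node
#'   (default 5).
#' @export
generate_scale_free <- function(n_nodes = 135L, edges_per_new_node = 5L,
                                seed = 1L) {
  m <- as.integer(edges_per_new_node)
  n <- as.integer(n_nodes)
  if (m < 1L || m >= n)
    stop("`edges_per_new_node` must be in [1, n_nodes)", call. = FALSE)
  local_rng(seed)
  g <- igraph::sample_pa(n, m = m, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  # a fair coin orients each undirected attachment
  flip <- stats::runif(nrow(el)) < 0.5
  from <- ifelse(flip, el[, 1], el[, 2])
  to <- ifelse(flip, el[, 2], el[, 1])
  adj <- matrix(0, n, n)
  adj[cbind(to, from)] <- 1  # row = post, column = pre
  diag(adj) <- 0
  new_topology(adj, excitatory_mask(n), "scale_free")
}

#' @describeIn weighted_topology Distance-dependent 3-D lattice adjacency.
#' @param grid_dims Three integers whose product is the node count
#'   (default `c(15, 3, 3)`).
#' @param lambda_param Length scale of the connection-probability falloff.
#' @param c_param Base connection probability at zero distance.
#' @export
generate_lattice <- function(grid_dims = c(15L, 3L, 3L), lambda_param = 2,
                             c_param = 0.3, seed = 1L) {
  stopifnot(length(grid_dims) == 3L, lambda_param > 0,
            c_param >= 0, c_param <= 1)
  local_rng(seed)
  n <- prod(grid_dims)
  pos <- as.matrix(expand.grid(x = seq_len(grid_dims[1]),
                               y = seq_len(grid_dims[2]),
                               z = seq_len(grid_dims[3])))
  d2 <- as.matrix(stats::dist(pos))^2
  prob <- c_param * exp(-d2 / lambda_param^2)
  adj <- matrix(stats::runif(n * n) < prob, n, n) * 1
  diag(adj) <- 0
  new_topology(adj, excitatory_mask(n), "lattice", positions = pos)
}

#' Draw signed Gaussian synaptic weights onto an adjacency
#'
#' Every existing synapse receives a weight drawn from the excitatory or the
#' inhibitory Gaussian according to its presynaptic neuron, then rectified so
#' excitatory weights are `>= 0` and inhibitory `<= 0`.
#'
#' @param topology A `weighted_topology` (adjacency stage).
#' @param exc_mean,exc_sd Excitatory weight distribution (default N(6, 2)).
#' @param inh_mean,inh_sd Inhibitory weight distribution (default N(-6, 2)).
#' @param seed Integer seed.
#' @return The topology with `weights` filled in and `weighted = TRUE`.
#' @export
assign_weights <- function(topology, exc_mean = 6, exc_sd = 2,
                           inh_mean = -6, inh_sd = 2, seed = 1L) {
  stopifnot(inherits(topology, "weighted_topology"))
  local_rng(seed)
  n <- topology$n_nodes
  adj <- topology$weights != 0
  w <- matrix(0, n, n)
  for (j in seq_len(n)) {
    syn <- which(adj[, j])
    if (!length(syn)) next
    if (topology$excitatory[j]) {
      w[syn, j] <- pmax(stats::rnorm(length(syn), exc_mean, exc_sd), 0)
    } else {
      w[syn, j] <- pmin(stats::rnorm(length(syn), inh_mean, inh_sd), 0)
    }
  }
  topology$weights <- w
  topology$weighted <- TRUE
  topology
}

#' Export / import a topology as an edge list
#'
#' Tab-separated columns `from`, `to`, `weight` with a commented provenance
#' header (`# model=... n_nodes=...`), plus one `# excitatory=` line encoding
#' the node signs.
#'
#' @param topology A `weighted_topology`.
#' @param path Output path.
#' @return `path` invisibly (write); a `weighted_topology` (read).
#' @export
write_topology <- function(topology, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# model=%s n_nodes=%d weighted=%s",
                     topology$model, topology$n_nodes, topology$weighted), con)
  writeLines(paste0("# excitatory=",
                    paste(as.integer(topology$excitatory), collapse = "")), con)
  idx <- which(topology$weights != 0, arr.ind = TRUE)
  df <- data.frame(from = idx[, 2], to = idx[, 1],
                   weight = topology$weights[idx])
  df <- df[order(df$from, df$to), ]
  writeLines("from\tto\tweight", con)
  writeLines(sprintf("%d\t%d\t%.17g", df$from, df$to, df$weight), con)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^# ", "", lines[1]), " ")[[1]]
  kv <- strsplit(hdr, "=")
  meta <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  exc <- as.logical(as.integer(strsplit(sub("^# excitatory=", "",
                                            lines[2]), "")[[1]]))
  n <- as.integer(meta[["n_nodes"]])
  body <- lines[-(1:3)]
  w <- matrix(0, n, n)
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, "\t"))
    w[cbind(as.integer(parts[, 2]), as.integer(parts[, 1]))] <-
      as.numeric(parts[, 3])
  }
  topo <- new_topology(w, exc, meta[["model"]])
  topo$weighted <- as.logical(meta[["weighted"]])
  topo
}
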