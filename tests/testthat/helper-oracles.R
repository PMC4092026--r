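# Independent brute-force metric transcriptions used as oracles across test
# files. Kept deliberately naive (explicit loops, no shared package code).

oracle_separation <- function(states, labels) {
  classes <- sort(unique(labels))
  C <- length(classes)
  cents <- list()
  for (m in seq_len(C)) {
    cols <- which(labels == classes[m])
    cents[[m]] <- apply(states[, cols, drop = FALSE], 1, mean)
  }
  inter <- 0
  for (m in 1:C) for (n in 1:C) {
    inter <- inter + sqrt(sum((cents[[m]] - cents[[n]])^2))
  }
  inter <- inter / (C * (C - 1))
  intra <- 0
  for (m in 1:C) {
    cols <- which(labels == classes[m])
    s <- 0
    for (j in cols) s <- s + sqrt(sum((states[, j] - cents[[m]])^2))
    intra <- intra + s / length(cols)
  }
  intra <- intra / C
  inter / (1 + intra)
}

oracle_lyapunov <- function(inputs, states, scale) {
  N <- ncol(inputs)
  logs <- c()
  for (j in 1:N) {
    best <- Inf; jn <- NA
    for (k in 1:N) {
      if (k == j) next
      d <- sqrt(sum((inputs[, j] - inputs[, k])^2))
      if (d < best) { best <- d; jn <- k }
    }
    if (best == 0) next
    dx <- sqrt(sum((states[, j] - states[, jn])^2))
    if (dx == 0) next
    logs <- c(logs, log(dx / best))
  }
  if (!length(logs)) return(0)
  scale * mean(logs)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

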