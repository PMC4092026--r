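#' Generate a surrogate nine-speaker vowel dataset
#'
#' Emulates the statistical shape of the classic nine-speaker Japanese-vowel
#' utterance data: 9 classes, 12 cepstrum-like features per frame, per-sample
#' frame counts drawn uniformly in `[7, 29]`, and default train/test sizes of
#' 270/370. Each class is a stationary first-order autoregressive Gaussian
#' process around a class-specific mean vector, so classes are separable but
#' overlapping. No audio is involved; only the shape statistics are emulated.
#'
#' The class structure (mean vectors on a sphere of radius
#' `class_separation`, and per-class AR coefficients spread over
#' 0.55-0.87) is drawn from `seed` and shared between the train and test sets.
#'
#' @param n_train,n_test Sample counts (each >= 9); every class appears.
#' @param seed Integer seed.
#' @param class_separation Radius of the sphere the class mean vectors are
#'   drawn on; larger values separate the classes more. Default 2.
#' @param noise_sd Innovation standard deviation of the AR process; 0 gives
#'   each class its deterministic mean trajectory. Default 1.
#' @return List with elements `train` and `test`, each a [sequence_dataset()].
#' @examples
#' d <- generate_surrogate_vowels(27, 18, seed = 1)
#' d$train
#' @export
generate_surrogate_vowels <- function(n_train = 270L, n_test = 370L, seed = 1L,
                                      class_separation = 2, noise_sd = 1) {
  if (n_train < 9L || n_test < 9L)
    stop("need at least one sample per class in each split", call. = FALSE)
  n_classes <- 9L
  n_feat <- 12L
  local_rng(seed)

  # fixed class structure shared by both splits
  mu <- matrix(stats::rnorm(n_classes * n_feat), n_classes, n_feat)
  mu <- mu / sqrt(rowSums(mu^2)) * class_separation
  ar <- 0.55 + 0.04 * (seq_len(n_classes) - 1L)

  draw_split <- function(n) {
    labels <- c(seq_len(n_classes),
                sample(n_classes, n - n_classes, replace = TRUE))
    labels <- sample(labels)  # shuffle order
    samples <- lapply(labels, function(cl) {
      nf <- sample(7:29, 1L)
      m <- matrix(0, nf, n_feat)
      x <- mu[cl, ]
      for (t in seq_len(nf)) {
        x <- mu[cl, ] + ar[cl] * (x - mu[cl, ]) +
          noise_sd * stats::rnorm(n_feat)
        m[t, ] <- x
      }
      colnames(m) <- paste0("f", seq_len(n_feat))
      m
    })
    sequence_dataset(samples, labels, n_classes = n_classes,
                     class_names = paste0("speaker", seq_len(n_classes)))
  }

  list(train = draw_split(n_train), test = draw_split(n_test))
}

#' Read the nine-speaker Japanese vowel files (UCI text dialect)
#'
#' Parses the whitespace-delimited `ae.train` / `ae.test` dialect: each line
#' holds 12 real-valued cepstrum coefficients for one frame; a blank line ends
#' an utterance. Utterances occur in speaker blocks; `train_blocks` /
#' `test_blocks` give the number of utterances per speaker (in order), which
#' maps blocks to class labels 1-9. The defaults are the published block sizes
#' (30 per speaker for training; 31, 35, 88, 44, 29, 24, 40, 50, 29 for
#' testing).
#'
#' @param train_path,test_path Paths to the two files.
#' @param train_blocks,test_blocks Integer vectors of utterances per speaker.
#' @return List with elements `train` and `test`, each a [sequence_dataset()].
#' @export
read_japanese_vowels <- function(train_path, test_path,
                                 train_blocks = rep(30L, 9L),
                                 test_blocks = c(31L, 35L, 88L, 44L, 29L,
                                                 24L, 40L, 50L, 29L)) {
  list(train = parse_vowel_file(train_path, train_blocks),
       test = parse_vowel_file(test_path, test_blocks))
}

parse_vowel_file <- function(path, blocks) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  samples <- list()
  frames <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "") {
      if (length(frames)) {
        samples[[length(samples) + 1L]] <- do.call(rbind, frames)
        frames <- list()
      }
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
    if (length(vals) != 12L || anyNA(vals))
      stop(sprintf("malformed frame at %s line %d: expected 12 numeric fields",
                   path, i), call. = FALSE)
    frames[[length(frames) + 1L]] <- vals
  }
  if (length(frames)) samples[[length(samples) + 1L]] <- do.call(rbind, frames)
  if (length(samples) != sum(blocks))
    stop(sprintf("%s: found %d utterances but speaker blocks sum to %d",
                 path, length(samples), sum(blocks)), call. = FALSE)
  labels <- rep(seq_along(blocks), times = blocks)
  sequence_dataset(samples, labels, n_classes = length(blocks),
                   class_names = paste0("speaker", seq_along(blocks)))
}
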