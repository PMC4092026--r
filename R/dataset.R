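#' Labelled multivariate sequence datasets
#'
#' The common container for both classification tasks: a list of samples, each
#' a `frames x features` numeric matrix, with one integer class label per
#' sample (labels run from 1 to `n_classes`). The feature count is constant
#' across samples; frame counts may vary.
#'
#' @param samples List of numeric matrices with identical column counts.
#' @param labels Integer class labels, one per sample, in `[1, n_classes]`.
#' @param n_classes Number of classes; defaults to `max(labels)`.
#' @param class_names Optional character vector of length `n_classes`.
#' @return An object of class `sequence_dataset`.
#' @export
sequence_dataset <- function(samples, labels, n_classes = max(labels),
                             class_names = NULL) {
  stopifnot(is.list(samples), length(samples) == length(labels))
  if (length(samples) == 0L) stop("dataset must contain samples", call. = FALSE)
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > n_classes))
    stop("labels must lie in [1, n_classes]", call. = FALSE)
  ncols <- vapply(samples, ncol, integer(1))
  if (length(unique(ncols)) != 1L)
    stop("all samples must have the same feature count", call. = FALSE)
  if (any(vapply(samples, nrow, integer(1)) < 1L))
    stop("every sample needs at least one frame", call. = FALSE)
  structure(
    list(samples = samples, labels = labels,
         n_classes = as.integer(n_classes),
         feature_count = ncols[[1]],
         class_names = class_names),
    class = "sequence_dataset"
  )
}

#' @export
print.sequence_dataset <- function(x, ...) {
  fr <- range(vapply(x$samples, nrow, integer(1)))
  cat(sprintf(
    "<sequence_dataset> %d samples, %d classes, %d features, %d-%d frames\n",
    length(x$samples), x$n_classes, x$feature_count, fr[1], fr[2]))
  invisible(x)
}

#' @export
length.sequence_dataset <- function(x) length(x$samples)

#' Flatten a sequence dataset to a tibble (one frame per row)
#'
#' @param x A `sequence_dataset`.
#' @param ... Unused.
#' @return Tibble with columns `sample_id`, `label`, `frame`, and one column
#'   per feature (`f1`, `f2`, ...).
#' @export
as_tibble.sequence_dataset <- function(x, ...) {
  purrr::map2_dfr(x$samples, seq_along(x$samples), function(m, i) {
    colnames(m) <- paste0("f", seq_len(ncol(m)))
    tibble::tibble(sample_id = i, label = x$labels[i],
                   frame = seq_len(nrow(m)),
                   tibble::as_tibble(m))
  })
}

#' Write / read a sequence dataset as delimited text
#'
#' The on-disk format is tab-separated with a header: columns `sample_id`,
#' `label`, `frame`, then `f1..fK`. [read_sequence_dataset()] inverts
#' [write_sequence_dataset()] exactly.
#'
#' @param dataset A `sequence_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly (write) or a `sequence_dataset` (read).
#' @export
write_sequence_dataset <- function(dataset, path) {
  readr::write_tsv(as_tibble.sequence_dataset(dataset), path)
  invisible(path)
}

#' @rdname write_sequence_dataset
#' @export
read_sequence_dataset <- function(path) {
  tb <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- unique(tb$sample_id)
  feat <- grep("^f[0-9]+$", names(tb), value = TRUE)
  samples <- lapply(ids, function(i) {
    as.matrix(tb[tb$sample_id == i, feat, drop = FALSE])
  })
  labels <- vapply(ids, function(i) tb$label[match(i, tb$sample_id)], double(1))
  sequence_dataset(samples, labels, n_classes = max(labels))
}

#' Min-max normalise features to [0, 1]
#'
#' Rescales every feature to `[0, 1]` using per-feature minima and maxima.
#' Statistics are computed from the dataset itself unless `stats` is supplied
#' (pass the training set's statistics when normalising test data); values
#' outside the training range are clipped to `[0, 1]`. A constant feature maps
#' to 0.5.
#'
#' @param dataset A `sequence_dataset` with finite features.
#' @param stats Optional statistics (the `"norm_stats"` attribute of a
#'   previously normalised dataset): a list with `min` and `max` vectors.
#' @return The normalised `sequence_dataset`, with attribute `norm_stats`.
#' @export
normalize_inputs <- function(dataset, stats = NULL) {
  stopifnot(inherits(dataset, "sequence_dataset"))
  all_frames <- do.call(rbind, dataset$samples)
  if (!all(is.finite(all_frames)))
    stop("features must be finite", call. = FALSE)
  if (is.null(stats)) {
    stats <- list(min = apply(all_frames, 2, min),
                  max = apply(all_frames, 2, max))
  }
  rng <- stats$max - stats$min
  const <- rng == 0
  dataset$samples <- lapply(dataset$samples, function(m) {
    out <- m
    for (j in seq_len(ncol(m))) {
      out[, j] <- if (const[j]) 0.5 else (m[, j] - stats$min[j]) / rng[j]
    }
    pmin(pmax(out, 0), 1)
  })
  attr(dataset, "norm_stats") <- stats
  dataset
}
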