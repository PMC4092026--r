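#' Configure the reservoir-metric experiment grid
#'
#' Describes the full study: for one task, every combination of plasticity
#' rule, connectivity model and random initialisation is run, yielding
#' `|rules| * |topologies| * n_seeds` reservoir runs (the default grid is
#' 4 x 3 x 10 = 120 runs). All module defaults can be overridden here.
#'
#' The benchmark task segments a freshly generated tri-function signal into
#' fixed windows; its default problem size (240 training and 120 test windows
#' of 15 steps) is a reduced-scale choice that keeps a full grid run in the
#' minutes range while leaving the per-run dynamics at full reservoir scale;
#' `benchmark` options scale it back up. The speaker task uses the surrogate
#' vowel generator at its published split sizes (270/370).
#'
#' @param task `"benchmark"` (tri-function signal) or `"speaker"` (surrogate
#'   vowels).
#' @param rules Subset of `"static"`, `"bcm"`, `"biphasic"`, `"triphasic"`.
#' @param topologies Subset of `"uniform"`, `"scale_free"`, `"lattice"`.
#' @param n_seeds Random reservoir initialisations per cell (default 10).
#' @param master_seed Seed from which all per-run seeds derive.
#' @param n_nodes Reservoir size (default 135).
#' @param benchmark,speaker Task-specific options (lists); see Details.
#' @param topology_opts,plasticity_opts,readout_opts,reservoir_opts Module
#'   option lists; unnamed entries keep their defaults.
#' @details
#' `benchmark`: `n_train`, `n_test` (window counts), `window_length`,
#' `switch_probability`. `speaker`: `n_train`, `n_test`, `class_separation`,
#' `noise_sd`. `topology_opts`: `p`, `edges_per_new_node`, `grid_dims`,
#' `lambda_param`, `c_param`, `exc_mean`, `exc_sd`, `inh_mean`, `inh_sd`.
#' `plasticity_opts`: `epochs`, `stdp` (a [stdp_params()] list), `bcm`
#' (arguments to [bcm_state()]). `readout_opts`: `epochs`, `learning_rate`.
#' `reservoir_opts`: `duration`, `dt`, `tau`, `input_scale`, `fanout`.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(task = c("benchmark", "speaker"),
                              rules = c("static", "bcm", "biphasic",
                                        "triphasic"),
                              topologies = c("uniform", "scale_free",
                                             "lattice"),
                              n_seeds = 10L, master_seed = 1L,
                              n_nodes = 135L,
                              benchmark = list(), speaker = list(),
                              topology_opts = list(),
                              plasticity_opts = list(),
                              readout_opts = list(),
                              reservoir_opts = list()) {
  task <- match.arg(task)
  rules <- match.arg(rules, several.ok = TRUE)
  topologies <- match.arg(topologies, several.ok = TRUE)
  cfg <- list(
    task = task, rules = rules, topologies = topologies,
    n_seeds = as.integer(n_seeds), master_seed = as.integer(master_seed),
    n_nodes = as.integer(n_nodes),
    benchmark = utils::modifyList(
      list(n_train = 240L, n_test = 120L, window_length = 15L,
           switch_probability = 0.05), benchmark),
    speaker = utils::modifyList(
      list(n_train = 270L, n_test = 370L, class_separation = 2,
           noise_sd = 1), speaker),
    topology_opts = utils::modifyList(
      list(p = 0.1, edges_per_new_node = 5L, grid_dims = c(15L, 3L, 3L),
           lambda_param = 2, c_param = 0.3,
           exc_mean = 6, exc_sd = 2, inh_mean = -6, inh_sd = 2),
      topology_opts),
    plasticity_opts = utils::modifyList(
      list(epochs = 1L, stdp = stdp_params(), bcm = list()),
      plasticity_opts),
    readout_opts = utils::modifyList(
      list(epochs = 20L, learning_rate = 0.001), readout_opts),
    reservoir_opts = utils::modifyList(
      list(duration = 150, dt = 1, tau = 30, input_scale = 20, fanout = 0.3),
      reservoir_opts)
  )
  structure(cfg, class = "experiment_config")
}

#' Generate and normalise one task's train/test data
#'
#' Benchmark: a tri-function signal of `(n_train + n_test) * window_length`
#' steps is generated, segmented, and split sequentially into train then test
#' windows (the seed is advanced until every class appears in the training
#' split). Speaker: the surrogate vowel generator at the configured sizes.
#' Both splits are min-max normalised with training-set statistics.
#'
#' @param config An [experiment_config()].
#' @param seed Data seed.
#' @return List with `train` and `test` [sequence_dataset()]s.
#' @export
prepare_task_data <- function(config, seed = config$master_seed) {
  if (config$task == "benchmark") {
    b <- config$benchmark
    n_steps <- (b$n_train + b$n_test) * b$window_length
    for (try in 0:20) {
      sig <- generate_tri_function(n_steps, b$switch_probability,
                                   seed = derive_seed(seed, try))
      ds <- segment_signal(sig, b$window_length)
      tr_idx <- seq_len(b$n_train)
      if (all(seq_len(3L) %in% ds$labels[tr_idx]) &&
          all(seq_len(3L) %in% ds$labels[-tr_idx])) break
    }
    train <- sequence_dataset(ds$samples[tr_idx], ds$labels[tr_idx],
                              n_classes = 3L, class_names = ds$class_names)
    test <- sequence_dataset(ds$samples[-tr_idx], ds$labels[-tr_idx],
                             n_classes = 3L, class_names = ds$class_names)
  } else {
    s <- config$speaker
    d <- generate_surrogate_vowels(s$n_train, s$n_test, seed = seed,
                                   class_separation = s$class_separation,
                                   noise_sd = s$noise_sd)
    train <- d$train
    test <- d$test
  }
  train <- normalize_inputs(train)
  test <- normalize_inputs(test, stats = attr(train, "norm_stats"))
  list(train = train, test = test)
}

make_topology <- function(model, config, seed) {
  t_opts <- config$topology_opts
  if (model == "lattice" && prod(t_opts$grid_dims) != config$n_nodes)
    stop(sprintf("lattice grid %s does not hold %d nodes",
                 paste(t_opts$grid_dims, collapse = "x"), config$n_nodes),
         call. = FALSE)
  topo <- switch(model,
    uniform = generate_uniform(config$n_nodes, t_opts$p, seed),
    scale_free = generate_scale_free(config$n_nodes,
                                     t_opts$edges_per_new_node, seed),
    lattice = generate_lattice(t_opts$grid_dims, t_opts$lambda_param,
                               t_opts$c_param, seed)
  )
  assign_weights(topo, t_opts$exc_mean, t_opts$exc_sd,
                 t_opts$inh_mean, t_opts$inh_sd,
                 seed = derive_seed(seed, 1L))
}

collect_states <- function(topology, dataset, projection, r_opts) {
  vapply(dataset$samples, function(frames) {
    spk <- simulate_sample(topology, frames, projection,
                           duration = r_opts$duration, dt = r_opts$dt,
                           input_scale = r_opts$input_scale)
    filter_spike_trains(spk, tau = r_opts$tau, duration = r_opts$duration)
  }, double(topology$n_nodes))
}

pretrain_plasticity <- function(topology, dataset, projection, rule, config) {
  p_opts <- config$plasticity_opts
  r_opts <- config$reservoir_opts
  if (rule == "static") return(topology)
  window <- switch(rule, biphasic = stdp_biphasic_window,
                   triphasic = stdp_triphasic_window, NULL)
  bcm <- if (rule == "bcm") {
    do.call(bcm_state, c(list(n_nodes = topology$n_nodes), p_opts$bcm))
  }
  for (ep in seq_len(p_opts$epochs)) {
    for (frames in dataset$samples) {
      spk <- simulate_sample(topology, frames, projection,
                             duration = r_opts$duration, dt = r_opts$dt,
                             input_scale = r_opts$input_scale)
      if (rule == "bcm") {
        x <- filter_spike_trains(spk, tau = r_opts$tau,
                                 duration = r_opts$duration)
        upd <- apply_bcm(topology, x, bcm)
        topology <- upd$topology
        bcm <- upd$state
      } else {
        topology <- apply_stdp(spk, topology, window, p_opts$stdp)
      }
    }
  }
  topology
}

#' Execute one reservoir run of the grid
#'
#' One reservoir initialisation: generate the topology, run the unsupervised
#' plasticity phase on the training data, collect filtered state vectors for
#' both splits, compute the four metrics (class separation, kernel quality,
#' Lyapunov estimate on frame-averaged training inputs, spectral radius of
#' the adapted weight matrix), then train the LMS readout and measure
#' accuracy. Fully deterministic given `run_seed`.
#'
#' @param config An [experiment_config()].
#' @param rule Plasticity rule for this run.
#' @param topology_model Connectivity model for this run.
#' @param run_seed Integer seed for this run.
#' @param data Optionally, pre-generated task data from
#'   [prepare_task_data()] (shared across a grid).
#' @return One-row tibble: run coordinates, the four metric values,
#'   `spectral_radius_valid`, and train/test accuracy.
#' @export
run_single <- function(config, rule, topology_model, run_seed, data = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  rule <- match.arg(rule, c("static", "bcm", "biphasic", "triphasic"))
  topology_model <- match.arg(topology_model,
                              c("uniform", "scale_free", "lattice"))
  if (is.null(data)) data <- prepare_task_data(config)
  r_opts <- config$reservoir_opts

  topo <- make_topology(topology_model, config, derive_seed(run_seed, 2L))
  projection <- make_input_projection(data$train$feature_count,
                                      config$n_nodes, r_opts$fanout,
                                      seed = derive_seed(run_seed, 3L))

  topo <- pretrain_plasticity(topo, data$train, projection, rule, config)

  states_train <- collect_states(topo, data$train, projection, r_opts)
  states_test <- collect_states(topo, data$test, projection, r_opts)

  sep <- class_separation(states_train, data$train$labels)
  kq <- kernel_quality(states_train)
  inputs_train <- vapply(data$train$samples, colMeans,
                         double(data$train$feature_count))
  inputs_train <- matrix(inputs_train, ncol = length(data$train$samples))
  lyap <- lyapunov_estimate(inputs_train, states_train)
  sr <- spectral_radius(topo)

  ro_opts <- config$readout_opts
  readout <- train_readout(states_train, data$train$labels,
                           n_classes = data$train$n_classes,
                           epochs = ro_opts$epochs,
                           learning_rate = ro_opts$learning_rate,
                           seed = derive_seed(run_seed, 4L))
  tibble::tibble(
    task = config$task, rule = rule, topology = topology_model,
    seed = as.integer(run_seed),
    separation = sep, kernel_quality = kq, lyapunov = lyap,
    spectral_radius = sr$value, spectral_radius_valid = sr$valid,
    train_accuracy = readout_accuracy(readout, states_train,
                                      data$train$labels),
    test_accuracy = readout_accuracy(readout, states_test,
                                     data$test$labels),
    error = NA_character_
  )
}

failed_record <- function(config, rule, topology_model, run_seed, msg) {
  tibble::tibble(
    task = config$task, rule = rule, topology = topology_model,
    seed = as.integer(run_seed),
    separation = NA_real_, kernel_quality = NA_integer_,
    lyapunov = NA_real_, spectral_radius = NA_real_,
    spectral_radius_valid = NA,
    train_accuracy = NA_real_, test_accuracy = NA_real_,
    error = msg
  )
}

#' Run the full experiment grid
#'
#' Executes every (rule, topology, seed) combination of the configuration on
#' one shared task dataset. Per-run seeds derive from the master seed by a
#' fixed counter scheme, so a grid is reproducible as a whole and any single
#' run is reproducible in isolation. A failing run is recorded with its error
#' message and the grid continues. If `checkpoint` names a file, each
#' completed record is appended to it as CSV and already-present runs are
#' skipped on re-invocation.
#'
#' @param config An [experiment_config()].
#' @param checkpoint Optional CSV path for incremental results.
#' @param progress Print one line per completed run?
#' @return A `reservoir_grid` tibble with one row per run (see
#'   [run_single()]), carrying the config as an attribute.
#' @export
run_grid <- function(config, checkpoint = NULL, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  data <- prepare_task_data(config)
  cells <- expand.grid(seed_idx = seq_len(config$n_seeds),
                       topology = config$topologies,
                       rule = config$rules,
                       stringsAsFactors = FALSE)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- readr::read_csv(checkpoint, show_col_types = FALSE,
                            progress = FALSE)
  }
  records <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    rule <- cells$rule[k]
    topol <- cells$topology[k]
    run_seed <- derive_seed(config$master_seed, k)
    if (!is.null(done) &&
        any(done$rule == rule & done$topology == topol &
            done$seed == run_seed)) {
      records[[k]] <- done[done$rule == rule & done$topology == topol &
                             done$seed == run_seed, ][1, ]
      next
    }
    rec <- tryCatch(
      run_single(config, rule, topol, run_seed, data = data),
      error = function(e) failed_record(config, rule, topol, run_seed,
                                        conditionMessage(e))
    )
    records[[k]] <- rec
    if (!is.null(checkpoint)) {
      readr::write_csv(rec, checkpoint, append = file.exists(checkpoint))
    }
    if (progress) {
      message(sprintf("[%d/%d] %s/%s seed=%d acc=%s", k, nrow(cells), rule,
                      topol, run_seed,
                      ifelse(is.na(rec$test_accuracy), "FAILED",
                             sprintf("%.3f", rec$test_accuracy))))
    }
  }
  out <- dplyr::bind_rows(records)
  attr(out, "config") <- config
  class(out) <- c("reservoir_grid", class(out))
  out
}

#' Box-plot summary statistics per grid cell
#'
#' For every (rule, topology) cell: median, quartiles and whisker range
#' (1.5 IQR convention) of each metric and of test accuracy — the numbers a
#' box-and-whisker plot of the grid would display. Runs with an invalid
#' spectral radius are excluded from that metric's summary (they are kept,
#' as zeros, in [correlate_metrics()]).
#'
#' @param records A `reservoir_grid` tibble.
#' @return Tibble with columns `rule`, `topology`, `quantity`, `n`, `median`,
#'   `q1`, `q3`, `whisker_low`, `whisker_high`.
#' @export
summarize_grid <- function(records) {
  ok <- records[is.na(records$error), ]
  long <- tidyr::pivot_longer(
    ok[, c("rule", "topology", "separation", "kernel_quality", "lyapunov",
           "spectral_radius", "spectral_radius_valid", "test_accuracy")],
    cols = c("separation", "kernel_quality", "lyapunov", "spectral_radius",
             "test_accuracy"),
    names_to = "quantity", values_to = "value")
  long <- dplyr::filter(long, .data$quantity != "spectral_radius" |
                          .data$spectral_radius_valid)
  dplyr::summarise(
    dplyr::group_by(long, .data$rule, .data$topology, .data$quantity),
    n = dplyr::n(),
    median = stats::median(.data$value),
    q1 = stats::quantile(.data$value, 0.25, names = FALSE),
    q3 = stats::quantile(.data$value, 0.75, names = FALSE),
    whisker_low = min(.data$value[.data$value >= q1 - 1.5 * (q3 - q1)]),
    whisker_high = max(.data$value[.data$value <= q3 + 1.5 * (q3 - q1)]),
    .groups = "drop")
}

#' Correlate each metric with test accuracy over a grid
#'
#' Pearson correlation of each of the four metrics against test accuracy
#' across all completed runs. Following the study's treatment, runs whose
#' spectral radius could not be computed enter that metric's correlation as
#' zeros (`r`); `r_valid_only` is the companion correlation over valid runs
#' only. A metric with zero variance is reported as `NA` with
#' `undefined = TRUE`.
#'
#' @param records A `reservoir_grid` tibble.
#' @return Tibble with columns `metric`, `r`, `r_valid_only`, `n`,
#'   `undefined`.
#' @export
correlate_metrics <- function(records) {
  ok <- records[is.na(records$error), ]
  if (nrow(ok) < 2L) stop("need at least two completed runs", call. = FALSE)
  acc <- ok$test_accuracy
  one <- function(vals, valid = NULL) {
    r <- tryCatch(pearson(vals, acc), error = function(e) NA_real_)
    rv <- if (is.null(valid)) r else {
      tryCatch(pearson(vals[valid], acc[valid]), error = function(e) NA_real_)
    }
    c(r = r, rv = rv)
  }
  rows <- list(
    separation = one(ok$separation),
    kernel_quality = one(as.numeric(ok$kernel_quality)),
    lyapunov = one(ok$lyapunov),
    spectral_radius = one(ifelse(ok$spectral_radius_valid,
                                 ok$spectral_radius, 0),
                          valid = ok$spectral_radius_valid)
  )
  r_all <- unname(vapply(rows, `[[`, double(1), "r"))
  tibble::tibble(
    metric = names(rows),
    r = r_all,
    r_valid_only = unname(vapply(rows, `[[`, double(1), "rv")),
    n = nrow(ok),
    undefined = is.na(r_all)
  )
}

#' @export
print.reservoir_grid <- function(x, ...) {
  cat(sprintf("<reservoir_grid> %d runs (%d failed), task=%s\n",
              nrow(x), sum(!is.na(x$error)),
              attr(x, "config")$task))
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-run records of a grid, one row per reservoir run
#'
#' @param x A `reservoir_grid`.
#' @param ... Unused.
#' @return The underlying tibble of run records.
#' @export
tidy.reservoir_grid <- function(x, ...) {
  out <- x
  attr(out, "config") <- NULL
  class(out) <- setdiff(class(out), "reservoir_grid")
  out
}

#' One-row summary of a grid: size, accuracy, metric-accuracy correlations
#'
#' @param x A `reservoir_grid`.
#' @param ... Unused.
#' @return One-row tibble with run counts, median accuracy and the Pearson
#'   correlation of each metric with test accuracy.
#' @export
glance.reservoir_grid <- function(x, ...) {
  corr <- correlate_metrics(x)
  ok <- x[is.na(x$error), ]
  tibble::tibble(
    task = attr(x, "config")$task,
    n_runs = nrow(x), n_failed = sum(!is.na(x$error)),
    median_accuracy = stats::median(ok$test_accuracy),
    r_separation = corr$r[corr$metric == "separation"],
    r_kernel_quality = corr$r[corr$metric == "kernel_quality"],
    r_lyapunov = corr$r[corr$metric == "lyapunov"],
    r_spectral_radius = corr$r[corr$metric == "spectral_radius"]
  )
}
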