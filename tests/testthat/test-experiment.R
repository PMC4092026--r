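# A reduced configuration shared by the experiment tests: 20-neuron
# reservoir, small surrogate speaker task, so a grid completes in seconds.
small_config <- function(rules = "static", topologies = "uniform",
                         n_seeds = 2L, master_seed = 7L) {
  experiment_config(
    task = "speaker", rules = rules, topologies = topologies,
    n_seeds = n_seeds, master_seed = master_seed, n_nodes = 20L,
    speaker = list(n_train = 36L, n_test = 27L),
    topology_opts = list(grid_dims = c(5L, 2L, 2L)),
    readout_opts = list(epochs = 10L)
  )
}

test_that("grid size and determinism follow the configuration", {
  cfg <- small_config(n_seeds = 3L)
  g1 <- run_grid(cfg)
  expect_equal(nrow(g1), 3L)  # 1 rule x 1 topology x 3 seeds
  expect_true(all(is.na(g1$error)))
  expect_true(all(g1$kernel_quality <= 20))
  expect_true(all(g1$test_accuracy >= 0 & g1$test_accuracy <= 1))

  g2 <- run_grid(cfg)
  expect_identical(tidy(g1), tidy(g2))
})

test_that("a single static run is bit-reproducible", {
  cfg <- small_config()
  data <- prepare_task_data(cfg)
  a <- run_single(cfg, "static", "uniform", 555, data = data)
  b <- run_single(cfg, "static", "uniform", 555, data = data)
  expect_identical(a, b)
})

test_that("reduced end-to-end pipeline beats chance on the speaker task", {
  # 20-neuron reservoir on a cleaner surrogate (wider class separation, less
  # frame noise): the pipeline must carry class signal end to end
  cfg <- experiment_config(
    task = "speaker", rules = "static", topologies = "uniform",
    n_seeds = 3L, master_seed = 7L, n_nodes = 20L,
    speaker = list(n_train = 54L, n_test = 54L, class_separation = 4,
                   noise_sd = 0.5),
    readout_opts = list(epochs = 10L)
  )
  g <- run_grid(cfg)
  expect_true(all(is.na(g$error)))
  expect_gt(mean(g$test_accuracy), 1 / 9)
})

test_that("failed runs are recorded and the grid continues", {
  cfg <- small_config(n_seeds = 2L)
  data <- prepare_task_data(cfg)
  # a lattice whose grid does not match n_nodes must fail cleanly
  cfg_bad <- small_config(topologies = c("uniform", "lattice"))
  cfg_bad$topology_opts$grid_dims <- c(3L, 3L, 3L)  # 27 != 20 nodes
  g <- run_grid(cfg_bad)
  expect_equal(nrow(g), 4L)
  expect_true(all(!is.na(g$error[g$topology == "lattice"])))
  expect_true(all(is.na(g$error[g$topology == "uniform"])))
})

test_that("checkpointing resumes without recomputation", {
  cfg <- small_config(n_seeds = 2L)
  path <- withr::local_tempfile(fileext = ".csv")
  g1 <- run_grid(cfg, checkpoint = path)
  expect_true(file.exists(path))
  before <- file.mtime(path)
  g2 <- run_grid(cfg, checkpoint = path)
  expect_equal(as.data.frame(g2[, 1:11]), as.data.frame(g1[, 1:11]),
               tolerance = 1e-12)
})

test_that("summaries match hand-computed box statistics", {
  rec <- tibble::tibble(
    task = "speaker", rule = "static", topology = "uniform",
    seed = 1:5,
    separation = c(1, 2, 3, 4, 100),
    kernel_quality = c(5L, 5L, 5L, 5L, 5L),
    lyapunov = 1:5 * 1.0,
    spectral_radius = c(1, 2, 3, 4, 5),
    spectral_radius_valid = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    train_accuracy = rep(1, 5),
    test_accuracy = c(0.2, 0.4, 0.6, 0.8, 1),
    error = NA_character_
  )
  s <- summarize_grid(rec)
  acc <- s[s$quantity == "test_accuracy", ]
  expect_equal(acc$median, 0.6)
  expect_equal(acc$q1, 0.4)
  expect_equal(acc$q3, 0.8)
  sep <- s[s$quantity == "separation", ]
  expect_equal(sep$median, 3)
  expect_equal(sep$whisker_high, 4)  # 100 lies beyond the 1.5 IQR whisker
  # invalid spectral radius is excluded from the distribution summary
  expect_equal(s$n[s$quantity == "spectral_radius"], 4L)
})

test_that("metric-accuracy correlations behave as Pearson should", {
  rec <- tibble::tibble(
    task = "speaker", rule = "static", topology = "uniform",
    seed = 1:6,
    separation = c(6, 5, 4, 3, 2, 1),
    kernel_quality = c(1L, 2L, 3L, 4L, 5L, 6L),
    lyapunov = c(1, 2, 3, 4, 5, 6),
    spectral_radius = c(2, 2, 2, 4, 4, 4),
    spectral_radius_valid = rep(TRUE, 6),
    train_accuracy = rep(1, 6),
    test_accuracy = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    error = NA_character_
  )
  corr <- correlate_metrics(rec)
  expect_equal(corr$r[corr$metric == "lyapunov"], 1)       # metric == accuracy
  expect_equal(corr$r[corr$metric == "separation"], -1)
  # permutation invariance
  corr_p <- correlate_metrics(rec[sample(6), ])
  expect_equal(dplyr::arrange(corr, metric), dplyr::arrange(corr_p, metric))

  # identical accuracies: undefined, flagged
  rec$test_accuracy <- rep(0.5, 6)
  corr0 <- correlate_metrics(rec)
  expect_true(all(corr0$undefined))
  expect_true(all(is.na(corr0$r)))
})

test_that("invalid spectral radii enter correlations as zero", {
  rec <- tibble::tibble(
    task = "speaker", rule = "static", topology = "uniform",
    seed = 1:4,
    separation = c(1, 2, 3, 4),
    kernel_quality = 1:4,
    lyapunov = c(1, 2, 3, 4),
    spectral_radius = c(10, 20, 30, 40),
    spectral_radius_valid = c(TRUE, TRUE, FALSE, FALSE),
    train_accuracy = rep(1, 4),
    test_accuracy = c(0.1, 0.2, 0.3, 0.4),
    error = NA_character_
  )
  corr <- correlate_metrics(rec)
  expect_equal(corr$r[corr$metric == "spectral_radius"],
               pearson(c(10, 20, 0, 0), rec$test_accuracy))
  expect_equal(corr$r_valid_only[corr$metric == "spectral_radius"],
               pearson(c(10, 20), c(0.1, 0.2)))
})

test_that("tidy, glance and the plots work on a small grid", {
  cfg <- small_config(rules = c("static", "bcm"), n_seeds = 2L)
  g <- run_grid(cfg)
  td <- tidy(g)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "reservoir_grid"))
  gl <- glance(g)
  expect_equal(gl$n_runs, 4L)
  expect_true(is.numeric(gl$r_lyapunov))
  expect_s3_class(autoplot(g), "ggplot")
  expect_s3_class(plot_metric_correlation(g), "ggplot")
  expect_s3_class(autoplot(generate_tri_function(300, 0.05, 1)), "ggplot")
})
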