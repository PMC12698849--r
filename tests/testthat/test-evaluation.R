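# Metrics, report serialization, the noise sweep, configs, and the CLI.

test_that("perfect predictions give a perfect report", {
  r <- compute_metrics(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L), 4L)
  expect_identical(r$accuracy, 1)
  expect_true(all(r$per_class$precision == 1))
  expect_true(all(r$per_class$recall == 1))
  expect_true(all(r$per_class$f1 == 1))
  expect_identical(nrow(r$per_class), 4L)
})

test_that("degenerate predictions match the hand-computed report", {
  r <- compute_metrics(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L), 2L)
  expect_identical(r$accuracy, 0.5)
  expect_identical(r$per_class$precision, c(0.5, 0))
  expect_identical(r$per_class$recall, c(1, 0))
  expect_equal(r$macro$f1, (2 / 3 + 0) / 2, tolerance = 1e-12)
  # cross-check against brute-force counting
  nm <- naive_metrics(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L), 2L)
  expect_equal(r$per_class$precision, unname(nm$per[, "p"]))
  expect_equal(r$per_class$recall, unname(nm$per[, "r"]))
  expect_equal(r$accuracy, nm$accuracy)
})

test_that("report identities hold on random label vectors", {
  for (seed in 1:5) {
    v <- withr::with_seed(seed, list(t = sample(0:3, 60, replace = TRUE),
                                     p = sample(0:3, 60, replace = TRUE)))
    r <- compute_metrics(v$t, v$p, 4L)
    expect_identical(sum(r$confusion), 60L)
    expect_identical(unname(rowSums(r$confusion)),
                     as.numeric(r$per_class$support))
    expect_equal(r$accuracy, sum(diag(r$confusion)) / 60)
    expect_equal(r$macro$precision, mean(r$per_class$precision))
    w <- r$per_class$support / 60
    expect_equal(r$weighted$f1, sum(w * r$per_class$f1))
    expect_true(all(unlist(r[c("macro", "weighted")]) >= 0))
    expect_true(all(unlist(r[c("macro", "weighted")]) <= 1))
    nm <- naive_metrics(v$t, v$p, 4L)
    expect_equal(r$per_class$f1, unname(nm$per[, "f"]))
  }
  expect_error(compute_metrics(c(0L, 1L), 0L, 2L), "length")
  expect_error(compute_metrics(c(0L, 4L), c(0L, 1L), 2L), "outside")
})

test_that("reports round-trip losslessly through JSON and CSV", {
  r <- compute_metrics(c(0L, 0L, 1L, 2L), c(0L, 1L, 1L, 2L), 3L)
  jpath <- withr::local_tempfile(fileext = ".json")
  write_report(r, jpath)
  back <- read_report(jpath)
  expect_equal(back$accuracy, r$accuracy)
  expect_equal(back$per_class$f1, r$per_class$f1)
  expect_equal(unname(as.matrix(back$confusion)), unname(r$confusion))

  df <- data.frame(family = "cauchy", scale = 1, seed = 1L,
                   model_accuracy = 0.9375, attack_accuracy = 0.25)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_report(df, cpath)
  back2 <- read_report(cpath)
  expect_identical(names(back2), names(df))
  expect_identical(back2$model_accuracy, df$model_accuracy)
  expect_error(write_report(df, "report.xlsx"), "extension")
  expect_error(read_report(withr::local_tempfile(fileext = ".json")),
               "no such")
})

test_that("attack results serialize with per-sample candidate MSEs", {
  fx <- small_trained_state()
  res <- run_attack(fx$state, fx$ds$test, n_samples = 5L, seed = 1L)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(res, path)
  back <- read_report(path)
  expect_equal(back$accuracy, res$accuracy)
  expect_equal(back$per_sample$mse_0, res$per_sample$mse_0)
})

test_that("the noise sweep emits one row per combination plus baselines", {
  ds <- small_dataset(6L)
  plan <- partition(ds$train, 2L, seed = 1L)
  cfg <- train_config(k = 2L, epochs = 1L, batch_size = 8L, seed = 1L)
  csv <- withr::local_tempfile(fileext = ".csv")
  sw <- run_noise_sweep(ds$train, plan, ds$test, cfg,
                        families = c("gaussian", "cauchy"),
                        scales = c(0.1, 10), seeds = 1:2, n_attack = 10L,
                        targets = "gradients", retrain = TRUE,
                        out_csv = csv)
  expect_identical(nrow(sw), 2L * (2L * 2L + 1L))
  expect_identical(sum(sw$family == "none"), 2L)
  expect_true(all(sw$attack_accuracy >= 0 & sw$attack_accuracy <= 1))
  flushed <- read_report(csv)
  expect_identical(nrow(flushed), nrow(sw))
  expect_identical(names(flushed), names(as.data.frame(sw)))
})

test_that("experiment configs resolve defaults and YAML overrides", {
  cfg <- read_experiment_config(NULL)
  expect_identical(cfg$train$k, 2L)
  expect_identical(cfg$data$n_per_class, 200L)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("train:", "  epochs: 3", "dp:", "  enabled: true",
               "  family: laplace"), path)
  cfg2 <- read_experiment_config(path)
  expect_identical(cfg2$train$epochs, 3L)
  expect_identical(cfg2$dp$family, "laplace")
  expect_identical(cfg2$train$k, 2L)  # untouched default
  tc <- config_train_config(cfg2)
  expect_s3_class(tc$dp, "noise_spec")
  expect_identical(tc$dp$family, "laplace")
  expect_error(read_experiment_config("nope.yaml"), "not found")
})

test_that("the command-line interface trains and attacks from a config file", {
  cli <- system.file("exec", "splitfed-lab", package = "splitfedlab")
  if (cli == "")
    cli <- file.path(find.package("splitfedlab"), "exec", "splitfed-lab")
  expect_true(file.exists(cli))
  tmp <- withr::local_tempdir()
  cfgfile <- file.path(tmp, "cfg.yaml")
  writeLines(c("data:", "  n_per_class: 8", "  image_size: 16",
               "train:", "  epochs: 1", "  batch_size: 16",
               "attack:", "  n_samples: 4"), cfgfile)
  out <- file.path(tmp, "run")
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript", c(cli, "train", "--config", cfgfile,
                                 "--out", out),
                    stdout = FALSE, stderr = FALSE)
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out, "checkpoint.json")))
  expect_true(file.exists(file.path(out, "metrics.json")))
  expect_true(file.exists(file.path(out, "history.csv")))
  rep_path <- file.path(tmp, "attack.json")
  status2 <- system2("Rscript", c(cli, "attack", "--checkpoint", out,
                                  "--config", cfgfile,
                                  "--out", rep_path),
                     stdout = FALSE, stderr = FALSE)
  expect_identical(status2, 0L)
  expect_gte(read_report(rep_path)$accuracy, 0)
})
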