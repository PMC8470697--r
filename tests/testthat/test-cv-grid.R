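make_tiny_dataset <- function(n_normal = 14, n_faulty = 14, effect = 3,
                              seed = 1) {
  cfg <- sim_config(roi_size = 16, n_bands = 4, n_normal = n_normal,
                    n_faulty = n_faulty, effect_size = effect,
                    blob_radius = c(3, 5), holdout_fraction = 0, seed = seed)
  simulate_dataset(cfg = cfg)
}

test_that("a memorizing classifier passes training folds but not noise holdout", {
  # interpolating ELM on pure noise: perfect on what it saw, chance beyond
  set.seed(101)
  n <- 60
  imgs <- array(rnorm(8 * 8 * n), c(8, 8, n))
  labels <- sample(c("normal", "faulty"), n, replace = TRUE)
  sp <- make_splits(labels, k = 2, holdout_fraction = 0.3, seed = 2)
  tr <- which(!sp$holdout); ho <- which(sp$holdout)
  m <- train_elm(image_set(imgs[, , tr], labels[tr]), h = 120, seed = 3)
  acc_train <- mean(predict(m, imgs[, , tr])$labels == labels[tr])
  acc_hold <- mean(predict(m, imgs[, , ho])$labels == labels[ho])
  expect_equal(acc_train, 1)
  # chance level: inside the exact binomial band around 0.5
  expect_gt(binom.test(round(acc_hold * length(ho)), length(ho), 0.5)$p.value,
            0.01)
})

test_that("cross_validate trains per fold and reports fold and holdout metrics", {
  cfg <- sim_config(roi_size = 16, n_bands = 4, n_normal = 50, n_faulty = 50,
                    effect_size = 5, blob_radius = c(4, 6),
                    holdout_fraction = 0, seed = 5)
  ds <- simulate_dataset(cfg = cfg)
  imgs <- fuse_dataset(ds, "pca")
  labels <- ds$manifest$label
  sp <- make_splits(labels, k = 3, holdout_fraction = 0.2, seed = 4)
  cv <- cross_validate(imgs, labels, "elm", sp,
                       config = list(h = 200, activation = "tribas", seed = 8))
  expect_length(cv$fold_metrics, 3)
  expect_true(all(is.finite(cv$cv_mean)))
  expect_s3_class(cv$holdout_metrics, "hsi_metrics")
  # strong signal: high out-of-fold accuracy
  expect_gt(cv$cv_mean[["accuracy"]], 0.85)
})

test_that("the smallest grid yields one complete record", {
  ds <- make_tiny_dataset(seed = 6)
  g <- run_grid(ds, fusions = "average", families = "elm",
                holdout_fraction = 0.25, seed = 3,
                model_args = list(elm = list(h = 50)))
  expect_equal(nrow(g$records), 1L)
  expect_true(is.finite(g$records$accuracy))
  expect_match(g$records$config_hash, "^[0-9a-f]+$")
})

test_that("the full 8x4 grid runs every cell with the expected methods", {
  ds <- make_tiny_dataset(seed = 7)
  micro <- list(
    cnn = list(epochs = 2),
    sae = list(hidden_sizes = c(12, 6), pretrain_epochs = 2,
               finetune_epochs = 3),
    dbn = list(hidden_sizes = c(12, 6), epochs = 1, finetune_epochs = 3,
               batch_size = 7),
    elm = list(h = 40))
  fargs <- list(dwt = list(levels = 2), sidwt = list(levels = 2),
                dtcwt = list(levels = 2), laplacian = list(T = 2))
  # micro-epoch cells may predict one class; their undefined F warnings
  # are expected behaviour, not failures
  g <- suppressWarnings(run_grid(ds, holdout_fraction = 0.25, seed = 9,
                                 fusion_args = fargs, model_args = micro))
  expect_equal(nrow(g$records), 32L)
  expect_setequal(unique(g$records$fusion), fusion_methods())
  expect_setequal(unique(g$records$family), classifier_families())
  expect_true(all(is.na(g$records$error)))
  expect_true(all(is.finite(g$records$accuracy)))
})

test_that("a poisoned cell fails alone while the others complete", {
  ds <- make_tiny_dataset(seed = 8)
  g <- run_grid(ds, fusions = c("average", "max"), families = c("elm"),
                holdout_fraction = 0.25, seed = 2,
                fusion_args = list(max = NULL),
                model_args = list(elm = list(h = 30)))
  expect_true(all(is.na(g$records$error)))

  g2 <- run_grid(ds, fusions = c("average", "pca"), families = "elm",
                 holdout_fraction = 0.25, seed = 2,
                 fusion_args = list(pca = list(d = 99)),   # poisoned: d > L
                 model_args = list(elm = list(h = 30)))
  expect_equal(sum(!is.na(g2$records$error)), 1L)
  expect_true(is.finite(g2$records$accuracy[g2$records$fusion == "average"]))
})

test_that("grid results are written as CSV and JSON", {
  ds <- make_tiny_dataset(seed = 10)
  g <- run_grid(ds, fusions = "min", families = "elm",
                holdout_fraction = 0.25, seed = 1,
                model_args = list(elm = list(h = 30)))
  csv <- file.path(tempdir(), "grid.csv"); js <- file.path(tempdir(), "grid.json")
  write_grid_results(g, csv, js)
  expect_equal(nrow(utils::read.csv(csv)), 1)
  parsed <- jsonlite::read_json(js)
  expect_equal(length(parsed$cells), 1)
  expect_equal(parsed$cells[[1]]$fusion, "min")
})
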