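# Experiment-grid runner: sweeps fusion-method x classifier-family cells
# over one dataset, with a single shared holdout split so cells are
# directly comparable, crash isolation per cell, and a rendered table in
# the AC/PR/R/K/F layout.

# polynomial rolling hash of a serialized object (stable config fingerprint)
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Fuse every ROI of a dataset with one method
#'
#' @param dataset an `hsi_dataset`.
#' @param method fusion method name, see [fusion_methods()].
#' @param ... method parameters forwarded to [fuse()].
#' @return An `h x w x n` array of fused images.
#' @export
fuse_dataset <- function(dataset, method, ...) {
  imgs <- lapply(dataset$patches, function(p) fuse(p$cube, method, ...)$values)
  array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
}

#' Run the fusion-by-classifier experiment grid
#'
#' For every selected (fusion, classifier) cell: fuse all ROIs (fusion is
#' fit-free), train on the non-holdout data and score the shared holdout
#' set; optionally also run k-fold cross-validation inside the training
#' portion. The holdout split is computed once per run and shared across
#' all cells. A failing cell is recorded as failed without aborting the
#' others.
#'
#' Classifier seeds are derived from the run seed and the family only, so
#' a family keeps the same initialization across fusion methods and
#' columns are comparable.
#'
#' @param dataset an `hsi_dataset` (e.g. from [simulate_dataset()]).
#' @param fusions subset of [fusion_methods()].
#' @param families subset of [classifier_families()].
#' @param folds cross-validation folds inside the training portion; 0
#'   skips CV and reports holdout metrics only (default 0).
#' @param holdout_fraction share of ROIs held out once for all cells.
#' @param seed run seed (splits and classifier seeds derive from it).
#' @param fusion_args named list: per-fusion-method argument lists.
#' @param model_args named list: per-family argument lists (epochs,
#'   sizes, ...).
#' @param verbose print per-cell progress lines.
#' @return An object of class `hsi_grid`: `records` data.frame (one row
#'   per cell: metrics, durations, seed, config hash, error for failed
#'   cells) and `details` (per-cell reports).
#' @export
run_grid <- function(dataset, fusions = fusion_methods(),
                     families = classifier_families(), folds = 0L,
                     holdout_fraction = 337 / 2112, seed = 1L,
                     fusion_args = list(), model_args = list(),
                     verbose = FALSE) {
  stopifnot(inherits(dataset, "hsi_dataset"))
  fusions <- match.arg(fusions, fusion_methods(), several.ok = TRUE)
  families <- match.arg(families, classifier_families(), several.ok = TRUE)
  labels <- dataset$manifest$label
  splits <- make_splits(labels, k = max(folds, 1L), holdout_fraction, seed)
  records <- list(); details <- list()
  for (fu in fusions) {
    fargs <- fusion_args[[fu]]
    imgs <- tryCatch(do.call(fuse_dataset, c(list(dataset, fu), fargs)),
                     error = function(e) e)
    if (inherits(imgs, "error")) {
      # a broken fusion config fails every cell of this method, not the run
      for (fa in families) {
        cell <- paste(fu, fa, sep = "_")
        if (verbose) message(cell, ": FAILED (", conditionMessage(imgs), ")")
        records[[cell]] <- data.frame(
          fusion = fu, family = fa, accuracy = NA_real_,
          precision = NA_real_, recall = NA_real_, kappa = NA_real_,
          f_measure = NA_real_, cv_accuracy = NA_real_,
          train_time = NA_real_, total_time = NA_real_,
          seed = seed + 1000L * match(fa, classifier_families()),
          config_hash = config_hash(list(fu, fargs, fa, model_args[[fa]], seed)),
          error = conditionMessage(imgs), stringsAsFactors = FALSE)
      }
      next
    }
    for (fa in families) {
      cell <- paste(fu, fa, sep = "_")
      margs <- model_args[[fa]]
      model_seed <- seed + 1000L * match(fa, classifier_families())
      cfg_h <- config_hash(list(fu, fargs, fa, margs, seed))
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        if (folds >= 2L) {
          cv <- do.call(cross_validate,
                        list(imgs, labels, fa, splits,
                             c(margs, list(seed = model_seed))))
        } else {
          tr <- which(!splits$holdout)
          model <- do.call(train_classifier,
                           c(list(image_set(imgs[, , tr, drop = FALSE],
                                            labels[tr]), fa),
                             margs, list(seed = model_seed)))
          ho <- which(splits$holdout)
          t1 <- proc.time()[["elapsed"]]
          pred <- predict(model, imgs[, , ho, drop = FALSE])
          cm <- confusion(labels[ho], pred$labels)
          cv <- list(holdout_metrics = metrics(cm), holdout_confusion = cm,
                     model = model, train_time = t1 - t0)
        }
        cv
      }, error = function(e) e)
      elapsed <- proc.time()[["elapsed"]] - t0
      if (inherits(res, "error")) {
        if (verbose) message(cell, ": FAILED (", conditionMessage(res), ")")
        records[[cell]] <- data.frame(
          fusion = fu, family = fa, accuracy = NA_real_,
          precision = NA_real_, recall = NA_real_, kappa = NA_real_,
          f_measure = NA_real_, cv_accuracy = NA_real_,
          train_time = NA_real_, total_time = elapsed, seed = model_seed,
          config_hash = cfg_h, error = conditionMessage(res),
          stringsAsFactors = FALSE)
      } else {
        hm <- res$holdout_metrics
        records[[cell]] <- data.frame(
          fusion = fu, family = fa, accuracy = hm$accuracy,
          precision = hm$precision, recall = hm$recall, kappa = hm$kappa,
          f_measure = hm$f_measure,
          cv_accuracy = if (!is.null(res$cv_mean))
            unname(res$cv_mean["accuracy"]) else NA_real_,
          train_time = if (!is.null(res$train_time)) res$train_time
            else NA_real_,
          total_time = elapsed, seed = model_seed, config_hash = cfg_h,
          error = NA_character_, stringsAsFactors = FALSE)
        details[[cell]] <- res
        if (verbose)
          message(sprintf("%s: AC %.3f (%.1fs)", cell, hm$accuracy, elapsed))
      }
    }
  }
  structure(list(records = do.call(rbind, c(records, make.row.names = FALSE)),
                 details = details, splits = splits, seed = seed,
                 folds = folds),
            class = "hsi_grid")
}

#' @export
print.hsi_grid <- function(x, ...) {
  r <- x$records
  cat("<hsi_grid>", nrow(r), "cells, seed", x$seed, "\n")
  for (fa in unique(r$family)) {
    cat("\n", toupper(fa), "  (values in %)\n", sep = "")
    sub <- r[r$family == fa, c("fusion", "accuracy", "precision", "recall",
                               "kappa", "f_measure")]
    sub[-1] <- lapply(sub[-1], function(v) sprintf("%.1f", 100 * v))
    names(sub) <- c("fusion", "AC", "PR", "R", "K", "F")
    print(sub, row.names = FALSE)
  }
  if (any(!is.na(r$error)))
    cat("\nfailed cells:", paste(r$fusion[!is.na(r$error)],
                                 r$family[!is.na(r$error)], sep = "_",
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Write grid results to CSV and JSON
#'
#' @param grid an [run_grid()] result.
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return `grid`, invisibly.
#' @export
write_grid_results <- function(grid, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(grid$records, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    recs <- grid$records
    out <- list(seed = grid$seed, folds = grid$folds,
                cells = lapply(seq_len(nrow(recs)), function(i)
                  as.list(recs[i, setdiff(names(recs), "error")])))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(grid)
}
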