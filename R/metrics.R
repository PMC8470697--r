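#' Two-class confusion matrix for seal classification
#'
#' Counts under the convention that a *normal* tray is the positive class:
#' `Tp` = normal predicted normal, `Tn` = faulty predicted faulty, `Fp` =
#' faulty predicted normal, `Fn` = normal predicted faulty.
#'
#' @param y_true,y_pred equal-length vectors of `"normal"`/`"faulty"`.
#' @param positive the positive class (default `"normal"`).
#' @return An object of class `hsi_confusion`: list with counts `Tp`,
#'   `Tn`, `Fp`, `Fn`.
#' @export
confusion <- function(y_true, y_pred, positive = "normal") {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 1L) stop("empty label vectors")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  pos_t <- y_true == positive; pos_p <- y_pred == positive
  structure(list(Tp = sum(pos_t & pos_p), Tn = sum(!pos_t & !pos_p),
                 Fp = sum(!pos_t & pos_p), Fn = sum(pos_t & !pos_p),
                 positive = positive),
            class = "hsi_confusion")
}

#' @export
print.hsi_confusion <- function(x, ...) {
  m <- matrix(c(x$Tp, x$Fn, x$Fp, x$Tn), 2, 2,
              dimnames = list(truth = c("normal", "faulty"),
                              predicted = c("normal", "faulty")))
  print(m)
  invisible(x)
}

#' Classification metric suite from a confusion matrix
#'
#' Computes accuracy `(Tp+Tn)/T`, recall `Tp/(Tp+Fn)`, precision
#' `Tp/(Tp+Fp)`, F-measure `2pr/(p+r)` and Cohen's kappa in its 2x2 closed
#' form `2(Tp*Tn - Fn*Fp) / ((Tp+Fp)(Tn+Fp) + (Tp+Fn)(Tn+Fn))`, which is
#' algebraically identical to the textbook `(p_o - p_e)/(1 - p_e)`.
#'
#' A metric whose denominator is zero is reported as `NA` with a warning,
#' never silently as 0. `as_printed = TRUE` switches precision and
#' F-measure to the literal source formulas `Tp/(Tn+Fp)` and
#' `2pr/(pr)` for audit purposes only (the latter is constant at 2
#' whenever `pr > 0`).
#'
#' @param cm an [confusion()] result.
#' @param as_printed evaluate the literal (typographical) precision and
#'   F-measure formulas instead of the standard ones.
#' @return An object of class `hsi_metrics`: list with `accuracy`,
#'   `precision`, `recall`, `f_measure`, `kappa` (fractions; kappa in
#'   [-1, 1]).
#' @export
metrics <- function(cm, as_printed = FALSE) {
  if (!inherits(cm, "hsi_confusion")) stop("expected an `hsi_confusion`")
  Tp <- cm$Tp; Tn <- cm$Tn; Fp <- cm$Fp; Fn <- cm$Fn
  Tt <- Tp + Tn + Fp + Fn
  safe_div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)"); NA_real_ }
    else num / den
  }
  acc <- safe_div(Tp + Tn, Tt, "accuracy")
  rec <- safe_div(Tp, Tp + Fn, "recall")
  prec <- if (as_printed) safe_div(Tp, Tn + Fp, "precision")
          else safe_div(Tp, Tp + Fp, "precision")
  fm <- if (is.na(prec) || is.na(rec)) NA_real_
  else if (as_printed) {
    if (prec * rec == 0) { warning("f_measure undefined"); NA_real_ }
    else 2 * (prec * rec) / (prec * rec)
  } else {
    if (prec + rec == 0) { warning("f_measure undefined"); NA_real_ }
    else 2 * prec * rec / (prec + rec)
  }
  kden <- (Tp + Fp) * (Tn + Fp) + (Tp + Fn) * (Tn + Fn)
  kap <- safe_div(2 * (Tp * Tn - Fn * Fp), kden, "kappa")
  structure(list(accuracy = acc, precision = prec, recall = rec,
                 f_measure = fm, kappa = kap, confusion = cm),
            class = "hsi_metrics")
}

#' @export
print.hsi_metrics <- function(x, ...) {
  v <- unlist(x[c("accuracy", "precision", "recall", "kappa", "f_measure")])
  cat(sprintf("AC %.1f%%  PR %.1f%%  R %.1f%%  K %.1f%%  F %.1f%%\n",
              100 * v[1], 100 * v[2], 100 * v[3], 100 * v[4], 100 * v[5]))
  invisible(x)
}

as_row <- function(m) {
  data.frame(accuracy = m$accuracy, precision = m$precision,
             recall = m$recall, kappa = m$kappa, f_measure = m$f_measure)
}

#' Stratified holdout + k-fold split plan
#'
#' First sets aside a label-stratified holdout fraction (the final
#' validation set), then partitions the remainder into `k` label-stratified
#' folds whose sizes differ by at most one. Seeded and reproducible.
#'
#' @param labels label vector for the whole dataset.
#' @param k number of folds (default 5).
#' @param holdout_fraction fraction kept out of cross-validation
#'   (default `337/2112`, the study's final-validation share).
#' @param seed RNG seed.
#' @return An object of class `hsi_splits`: list with `fold` (integer per
#'   example; `NA` for holdout), `holdout` (logical), `k`, `seed`.
#' @export
make_splits <- function(labels, k = 5L, holdout_fraction = 337 / 2112,
                        seed = 1L) {
  n <- length(labels)
  labels <- as.character(labels)
  if (k < 1L) stop("k must be >= 1")
  holdout <- logical(n)
  fold <- rep(NA_integer_, n)
  local_seed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nh <- round(length(idx) * holdout_fraction)
      hsel <- if (nh > 0) sample(idx, nh) else integer(0)
      holdout[hsel] <- TRUE
      rest <- sample(setdiff(idx, hsel))
      if (length(rest) < k && length(rest) > 0 && k > 1L)
        stop("k = ", k, " exceeds the training examples of class ", cl)
      fold[rest] <- rep_len(seq_len(k), length(rest))
    }
  })
  if (all(holdout)) stop("holdout fraction leaves no training data")
  structure(list(fold = fold, holdout = holdout, k = k, seed = seed),
            class = "hsi_splits")
}

#' Cross-validated evaluation of one fusion-classifier combination
#'
#' Fusion is fit-free and applied once per ROI; the classifier is trained
#' per fold on the remaining training folds only and scored on the held
#' fold; a final model trained on all non-holdout data is scored on the
#' untouched holdout.
#'
#' @param images `h x w x n` array of fused ROI images.
#' @param labels label vector.
#' @param family classifier family, see [train_classifier()].
#' @param splits an [make_splits()] plan for these labels.
#' @param config named list of family-specific training arguments.
#' @return List with `fold_metrics` (list of `hsi_metrics`), `cv_mean`
#'   (named numeric means over folds), `holdout_metrics`, and
#'   `holdout_confusion`.
#' @export
cross_validate <- function(images, labels, family, splits,
                           config = list()) {
  labels <- as.character(labels)
  if (!inherits(splits, "hsi_splits")) stop("expected `hsi_splits`")
  fold_metrics <- vector("list", splits$k)
  for (f in seq_len(splits$k)) {
    tr <- which(!splits$holdout & !is.na(splits$fold) & splits$fold != f)
    va <- which(!splits$holdout & !is.na(splits$fold) & splits$fold == f)
    if (!length(va)) next
    model <- do.call(train_classifier,
                     c(list(image_set(images[, , tr, drop = FALSE],
                                      labels[tr]), family), config))
    pred <- predict(model, images[, , va, drop = FALSE])
    fold_metrics[[f]] <- metrics(confusion(labels[va], pred$labels))
  }
  keep <- !vapply(fold_metrics, is.null, logical(1))
  rows <- do.call(rbind, lapply(fold_metrics[keep], as_row))
  cv_mean <- colMeans(rows, na.rm = TRUE)
  tr_all <- which(!splits$holdout)
  model <- do.call(train_classifier,
                   c(list(image_set(images[, , tr_all, drop = FALSE],
                                    labels[tr_all]), family), config))
  ho <- which(splits$holdout)
  holdout_metrics <- NULL; holdout_cm <- NULL
  if (length(ho)) {
    pred <- predict(model, images[, , ho, drop = FALSE])
    holdout_cm <- confusion(labels[ho], pred$labels)
    holdout_metrics <- metrics(holdout_cm)
  }
  list(fold_metrics = fold_metrics[keep], cv_mean = cv_mean,
       holdout_metrics = holdout_metrics, holdout_confusion = holdout_cm,
       model = model)
}
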