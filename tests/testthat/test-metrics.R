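test_that("confusion counts follow the positive-equals-normal convention", {
  y <- c("normal", "normal", "faulty", "faulty", "normal")
  cm <- confusion(y, y)
  expect_equal(c(cm$Tp, cm$Tn, cm$Fp, cm$Fn), c(3, 2, 0, 0))
  flip <- ifelse(y == "normal", "faulty", "normal")
  cm2 <- confusion(y, flip)
  expect_equal(c(cm2$Tp, cm2$Tn), c(0, 0))
  expect_error(confusion(y, y[-1]), "equal length")

  # explicit loop oracle on random labels
  set.seed(90)
  yt <- sample(c("normal", "faulty"), 50, replace = TRUE)
  yp <- sample(c("normal", "faulty"), 50, replace = TRUE)
  cm3 <- confusion(yt, yp)
  tp <- tn <- fp <- fn <- 0
  for (i in 1:50) {
    if (yt[i] == "normal" && yp[i] == "normal") tp <- tp + 1
    if (yt[i] == "faulty" && yp[i] == "faulty") tn <- tn + 1
    if (yt[i] == "faulty" && yp[i] == "normal") fp <- fp + 1
    if (yt[i] == "normal" && yp[i] == "faulty") fn <- fn + 1
  }
  expect_equal(c(cm3$Tp, cm3$Tn, cm3$Fp, cm3$Fn), c(tp, tn, fp, fn))
})

test_that("the metric suite reproduces the worked confusion example", {
  cm <- structure(list(Tp = 40, Tn = 45, Fp = 5, Fn = 10, positive = "normal"),
                  class = "hsi_confusion")
  m <- metrics(cm)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$precision, 40 / 45, tolerance = 1e-4)   # 0.8889
  expect_equal(m$recall, 0.80)
  expect_equal(m$f_measure, 0.8421, tolerance = 1e-4)
  expect_equal(m$kappa, 0.70)

  perfect <- metrics(confusion(rep(c("normal", "faulty"), each = 50),
                               rep(c("normal", "faulty"), each = 50)))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall",
                                "f_measure", "kappa")]),
               c(accuracy = 1, precision = 1, recall = 1, f_measure = 1,
                 kappa = 1))

  wrong <- structure(list(Tp = 0, Tn = 0, Fp = 10, Fn = 10, positive = "normal"),
                     class = "hsi_confusion")
  mw <- suppressWarnings(metrics(wrong))   # F-measure undefined here
  expect_equal(mw$accuracy, 0)
  expect_equal(mw$kappa, -1)
})

test_that("the closed-form kappa equals textbook Cohen's kappa", {
  set.seed(91)
  checked <- 0
  while (checked < 1000) {
    cts <- sample(0:40, 4, replace = TRUE)
    Tp <- cts[1]; Tn <- cts[2]; Fp <- cts[3]; Fn <- cts[4]
    Tt <- Tp + Tn + Fp + Fn
    kden <- (Tp + Fp) * (Tn + Fp) + (Tp + Fn) * (Tn + Fn)
    if (Tt == 0 || kden == 0) next
    po <- (Tp + Tn) / Tt
    pe <- ((Tp + Fp) * (Tp + Fn) + (Fn + Tn) * (Fp + Tn)) / Tt^2
    if (pe == 1) next
    cm <- structure(list(Tp = Tp, Tn = Tn, Fp = Fp, Fn = Fn,
                         positive = "normal"), class = "hsi_confusion")
    k <- suppressWarnings(metrics(cm))$kappa
    expect_equal(k, (po - pe) / (1 - pe), tolerance = 1e-12)
    checked <- checked + 1
  }
})

test_that("metrics are invariant to scaling all counts", {
  cm1 <- structure(list(Tp = 12, Tn = 9, Fp = 4, Fn = 3, positive = "normal"),
                   class = "hsi_confusion")
  cm5 <- structure(list(Tp = 60, Tn = 45, Fp = 20, Fn = 15, positive = "normal"),
                   class = "hsi_confusion")
  m1 <- metrics(cm1); m5 <- metrics(cm5)
  for (f in c("accuracy", "precision", "recall", "f_measure", "kappa"))
    expect_equal(m1[[f]], m5[[f]])
})

test_that("swapping the positive class swaps the error roles", {
  yt <- c(rep("normal", 6), rep("faulty", 4))
  yp <- c(rep("normal", 4), rep("faulty", 2), rep("faulty", 3), "normal")
  a <- confusion(yt, yp, positive = "normal")
  b <- confusion(yt, yp, positive = "faulty")
  expect_equal(a$Tp, b$Tn); expect_equal(a$Fp, b$Fn)
})

test_that("zero denominators give NA with a warning, and the literal audit
           formulas behave as printed", {
  none_pos <- structure(list(Tp = 0, Tn = 5, Fp = 0, Fn = 0,
                             positive = "normal"), class = "hsi_confusion")
  w <- testthat::capture_warnings(m <- metrics(none_pos))
  expect_true(any(grepl("recall undefined", w)))
  expect_true(is.na(m$recall))

  cm <- structure(list(Tp = 40, Tn = 45, Fp = 5, Fn = 10, positive = "normal"),
                  class = "hsi_confusion")
  lit <- metrics(cm, as_printed = TRUE)
  expect_equal(lit$precision, 40 / 50)   # Tp / (Tn + Fp)
  expect_equal(lit$f_measure, 2)         # 2pr/(pr) is constant
})
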