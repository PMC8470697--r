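# Synthetic seal-ROI generator. Emulates the statistical structure of the
# industrial NIR seal dataset: smooth class-dependent spectral signatures
# with per-class dispersion, a tray-edge background, one planted elliptical
# contamination blob per faulty ROI, additive sensor noise and a per-pixel
# multiplicative illumination factor. It makes no claim of radiometric
# realism; it exists so that every pipeline stage is testable end to end.

#' The eleven impurity classes of the seal-contamination study
#' @return Character vector of impurity names.
#' @export
impurity_classes <- function() {
  c("washers", "sugar", "flange", "plywood", "cork", "elastic rubber",
    "wood", "paper", "silver paper", "hair", "polarized plastic")
}

#' Configuration for the synthetic seal-ROI generator
#'
#' Defaults mirror the printed statistics of the reference dataset: 40x40
#' ROIs, 130 retained bands over 984.2-1631.0 nm, 1123 normal and 989
#' faulty ROIs (2112 total), with roughly a 337/2112 share tagged for
#' final validation.
#'
#' @param roi_size spatial ROI size in pixels (square).
#' @param n_bands number of spectral bands `L`.
#' @param wl_range wavelength span in nm (uniform axis).
#' @param n_normal,n_faulty class counts.
#' @param blob_radius range (pixels) for the elliptical blob semi-axes.
#' @param effect_size multiplier on the anomaly-vs-tray-edge spectral
#'   contrast; 0 removes all class signal.
#' @param noise_sd additive Gaussian noise scale, in units of the
#'   per-class dispersion curve (1 = one dispersion sd per band).
#' @param illum_sd sd of the per-pixel multiplicative illumination factor.
#' @param holdout_fraction share tagged `validation` in the manifest.
#' @param quantize_int16 emit as-acquired style int16 cubes.
#' @param seed master RNG seed.
#' @return A list of class `hsi_simconfig`.
#' @export
sim_config <- function(roi_size = 40L, n_bands = 130L,
                       wl_range = c(984.2, 1631.0),
                       n_normal = 1123L, n_faulty = 989L,
                       blob_radius = c(4, 10), effect_size = 1,
                       noise_sd = 1, illum_sd = 0.01,
                       holdout_fraction = 337 / 2112,
                       quantize_int16 = FALSE, seed = 1L) {
  stopifnot(roi_size >= 4, n_bands >= 4, n_normal >= 0, n_faulty >= 0,
            effect_size >= 0, noise_sd >= 0, illum_sd >= 0)
  structure(list(roi_size = as.integer(roi_size),
                 n_bands = as.integer(n_bands), wl_range = wl_range,
                 n_normal = as.integer(n_normal),
                 n_faulty = as.integer(n_faulty),
                 blob_radius = blob_radius, effect_size = effect_size,
                 noise_sd = noise_sd, illum_sd = illum_sd,
                 holdout_fraction = holdout_fraction,
                 quantize_int16 = quantize_int16, seed = seed),
            class = "hsi_simconfig")
}

# smooth curve as a sum of Gaussian bumps over normalized wavelength
gauss_bumps <- function(x, n_bumps, amp_range, signed = TRUE) {
  centers <- runif(n_bumps)
  widths <- runif(n_bumps, 0.08, 0.25)
  amps <- runif(n_bumps, amp_range[1], amp_range[2])
  if (signed) amps <- amps * sample(c(-1, 1), n_bumps, replace = TRUE)
  y <- numeric(length(x))
  for (i in seq_len(n_bumps))
    y <- y + amps[i] * exp(-(x - centers[i])^2 / (2 * widths[i]^2))
  y
}

#' Build the class spectral library
#'
#' Thirteen classes: `tray-edge`, `tray-center` and the eleven impurities.
#' Every class mean is the smooth tray-edge base curve plus
#' `effect_size` times a class-specific smooth contrast curve (so the
#' impurity-to-edge spectral distance is exactly linear in `effect_size`,
#' and all classes collapse onto the tray-edge mean at `effect_size = 0`).
#' Each class also carries a smooth, strictly positive dispersion curve.
#'
#' @param cfg an [sim_config()].
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return An object of class `hsi_speclib`: list with `wavelengths`,
#'   `classes` (named list of `mean`/`sd` vectors) and `effect_size`.
#' @export
make_library <- function(cfg = sim_config(), seed = cfg$seed) {
  L <- cfg$n_bands
  wl <- seq(cfg$wl_range[1], cfg$wl_range[2], length.out = L)
  x <- (wl - wl[1]) / (wl[L] - wl[1])
  cls <- c("tray-edge", "tray-center", impurity_classes())
  lib <- local_seed(seed, {
    base <- 0.45 + gauss_bumps(x, 4L, c(0.05, 0.2))
    out <- list()
    for (cl in cls) {
      delta <- if (cl == "tray-edge") numeric(L)
               else gauss_bumps(x, 3L, c(0.06, 0.15))
      disp <- 0.02 + abs(gauss_bumps(x, 2L, c(0.005, 0.02)))
      out[[cl]] <- list(mean = base + cfg$effect_size * delta, sd = disp)
    }
    out
  })
  structure(list(wavelengths = wl, classes = lib,
                 effect_size = cfg$effect_size, seed = seed),
            class = "hsi_speclib")
}

#' @export
print.hsi_speclib <- function(x, ...) {
  cat(sprintf("<hsi_speclib> %d classes, %d bands, effect_size = %g\n",
              length(x$classes), length(x$wavelengths), x$effect_size))
  invisible(x)
}

# elliptical blob mask fully inside a size x size patch
sample_blob_mask <- function(size, radius_range) {
  r1 <- runif(1, radius_range[1], radius_range[2])
  r2 <- runif(1, radius_range[1], radius_range[2])
  rmax <- max(r1, r2)
  if (2 * rmax + 2 > size)
    stop("blob of radius ", round(rmax, 1), " cannot fit in a ", size,
         "-pixel patch")
  theta <- runif(1, 0, pi)
  cx <- runif(1, 1 + rmax, size - rmax)
  cy <- runif(1, 1 + rmax, size - rmax)
  ix <- matrix(seq_len(size), size, size)
  iy <- matrix(seq_len(size), size, size, byrow = TRUE)
  dx <- ix - cx; dy <- iy - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / r1
  v <- (-dx * sin(theta) + dy * cos(theta)) / r2
  u^2 + v^2 <= 1
}

#' Simulate one labeled seal ROI
#'
#' Background pixels follow the tray-edge class: per-pixel spectrum =
#' illumination factor (Normal(1, `illum_sd`)) times the class mean, plus
#' per-band Gaussian noise with sd `noise_sd * dispersion`. A faulty ROI
#' additionally carries one contiguous elliptical blob (semi-axes drawn
#' from `cfg$blob_radius`, orientation and position uniform, fully inside
#' the patch) whose pixels follow the given anomaly class instead.
#'
#' @param lib an [make_library()] spectral library.
#' @param label `"normal"` or `"faulty"`.
#' @param anomaly_class impurity name; required iff `label = "faulty"`.
#' @param cfg an [sim_config()].
#' @param seed RNG seed for this patch.
#' @return An object of class `hsi_roi`: list with `cube` (an
#'   `hsi_cube`), `label`, `anomaly_class`, `source_id` and the planted
#'   `blob_mask` (NULL for normal ROIs).
#' @export
simulate_roi <- function(lib, label = c("normal", "faulty"),
                         anomaly_class = NULL, cfg = sim_config(),
                         seed = cfg$seed) {
  label <- match.arg(label)
  if (label == "faulty") {
    if (is.null(anomaly_class) || !anomaly_class %in% impurity_classes())
      stop("faulty ROIs need an `anomaly_class` from impurity_classes()")
  } else if (!is.null(anomaly_class))
    stop("normal ROIs must not carry an anomaly class")
  s <- cfg$roi_size; L <- length(lib$wavelengths)
  local_seed(seed, {
    mask <- if (label == "faulty")
      sample_blob_mask(s, cfg$blob_radius) else NULL
    flat <- matrix(0, s * s, L)
    bg <- lib$classes[["tray-edge"]]
    illum <- 1 + cfg$illum_sd * rnorm(s * s)
    flat <- outer(illum, bg$mean)
    if (cfg$noise_sd > 0)
      flat <- flat + matrix(rnorm(s * s * L), s * s, L) *
        matrix(cfg$noise_sd * bg$sd, s * s, L, byrow = TRUE)
    if (!is.null(mask) && any(mask)) {
      an <- lib$classes[[anomaly_class]]
      idx <- which(as.vector(mask))
      blob <- outer(illum[idx], an$mean)
      if (cfg$noise_sd > 0)
        blob <- blob + matrix(rnorm(length(idx) * L), length(idx), L) *
          matrix(cfg$noise_sd * an$sd, length(idx), L, byrow = TRUE)
      flat[idx, ] <- blob
    }
    values <- array(flat, c(s, s, L))
    cube <- if (cfg$quantize_int16)
      datacube(array(pmin(pmax(round(values * 10000), -32768), 32767),
                     c(s, s, L)), lib$wavelengths, "int16")
    else datacube(values, lib$wavelengths, "real")
    structure(list(cube = cube, label = label,
                   anomaly_class = anomaly_class,
                   source_id = paste0("sim-", seed), blob_mask = mask),
              class = "hsi_roi")
  })
}

#' Composition manifest of a synthetic dataset
#'
#' Deterministic plan of the dataset before any pixel is drawn: per-ROI
#' label, impurity class (faulty ROIs cycle uniformly over the eleven
#' impurities — per-impurity counts differ by at most one) and a
#' label-stratified `train`/`validation` split tag.
#'
#' @param cfg an [sim_config()].
#' @return A data.frame with columns `id`, `label`, `anomaly_class`,
#'   `split`, `seed`.
#' @export
dataset_composition <- function(cfg = sim_config()) {
  n <- cfg$n_normal + cfg$n_faulty
  labels <- c(rep("normal", cfg$n_normal), rep("faulty", cfg$n_faulty))
  anomaly <- c(rep(NA_character_, cfg$n_normal),
               rep_len(impurity_classes(), cfg$n_faulty))
  split <- rep("train", n)
  if (cfg$holdout_fraction > 0 && n > 0) {
    sp <- make_splits(labels, k = 1L,
                      holdout_fraction = cfg$holdout_fraction,
                      seed = cfg$seed)
    split[sp$holdout] <- "validation"
  }
  data.frame(id = sprintf("roi-%05d", seq_len(n)), label = labels,
             anomaly_class = anomaly, split = split,
             seed = cfg$seed + seq_len(n), stringsAsFactors = FALSE)
}

#' Simulate a full labeled seal dataset
#'
#' Draws every ROI of the [dataset_composition()] plan; each patch uses a
#' seed derived from the master seed, so the whole dataset is reproducible
#' byte for byte.
#'
#' @param lib an [make_library()]; defaults to the library built from
#'   `cfg`.
#' @param cfg an [sim_config()].
#' @return An object of class `hsi_dataset`: list with `patches` (list of
#'   `hsi_roi`) and `manifest` (the composition data.frame).
#' @export
simulate_dataset <- function(lib = NULL, cfg = sim_config()) {
  if (is.null(lib)) lib <- make_library(cfg)
  manifest <- dataset_composition(cfg)
  patches <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    simulate_roi(lib, r$label,
                 if (is.na(r$anomaly_class)) NULL else r$anomaly_class,
                 cfg, seed = r$seed)
  })
  structure(list(patches = patches, manifest = manifest, config = cfg),
            class = "hsi_dataset")
}

#' @export
print.hsi_dataset <- function(x, ...) {
  tab <- table(x$manifest$label)
  cat(sprintf("<hsi_dataset> %d ROIs (%d normal / %d faulty), %d tagged validation\n",
              nrow(x$manifest), tab[["normal"]], tab[["faulty"]],
              sum(x$manifest$split == "validation")))
  invisible(x)
}
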