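# Transform-domain fusion: decompose every band, select per coefficient
# the value of largest magnitude across bands (max-value scheme), invert.

# running per-coefficient selection; ties keep the earliest band
select_max_abs <- function(mats) {
  best <- mats[[1]]
  best_abs <- Mod(best)
  for (b in seq_along(mats)[-1]) {
    a <- Mod(mats[[b]])
    take <- a > best_abs
    best[take] <- mats[[b]][take]
    best_abs[take] <- a[take]
  }
  best
}

select_mean <- function(mats) Reduce(`+`, mats) / length(mats)

same_structure <- function(a, b) {
  identical(class(a), class(b)) &&
    identical(a$transform, b$transform) && identical(a$levels, b$levels) &&
    identical(a$family, b$family) && identical(a$dims, b$dims)
}

#' Max-value coefficient selection across per-band stacks
#'
#' Given one wavelet stack per spectral band (all structurally identical),
#' produces a single fused stack: at every coefficient position in every
#' subband, the coefficient of largest absolute value (largest complex
#' magnitude for the dual-tree transform) across the bands is kept, sign
#' and phase preserved. Ties take the lowest band index. The approximation
#' subband follows the same rule by default (`approx_rule = "max"`);
#' `approx_rule = "mean"` averages it instead.
#'
#' @param stacks list of `wavelet_stack` objects, one per band.
#' @param approx_rule `"max"` or `"mean"` for the approximation subband.
#' @return A fused `wavelet_stack`.
#' @export
max_value_select <- function(stacks, approx_rule = c("max", "mean")) {
  approx_rule <- match.arg(approx_rule)
  if (!length(stacks)) stop("no stacks supplied")
  if (!all(vapply(stacks, inherits, logical(1), "wavelet_stack")))
    stop("all elements must be `wavelet_stack` objects")
  for (s in stacks[-1])
    if (!same_structure(stacks[[1]], s))
      stop("stacks are structurally different (transform/levels/family/dims)")
  fused <- stacks[[1]]
  sel_approx <- if (approx_rule == "max") select_max_abs else select_mean
  is_dt <- fused$transform == "dtcwt"
  for (l in seq_len(fused$levels)) {
    for (or in names(fused$detail[[l]])) {
      if (is_dt) {
        for (pm in c("p", "m"))
          fused$detail[[l]][[or]][[pm]] <-
            select_max_abs(lapply(stacks, function(s) s$detail[[l]][[or]][[pm]]))
      } else {
        fused$detail[[l]][[or]] <-
          select_max_abs(lapply(stacks, function(s) s$detail[[l]][[or]]))
      }
    }
  }
  for (nm in names(fused$approx))
    fused$approx[[nm]] <- sel_approx(lapply(stacks, function(s) s$approx[[nm]]))
  fused
}

#' Transform-domain fusion of a datacube
#'
#' The four-step scheme: (1) take the `L` band images; (2) decompose each
#' with a multilevel wavelet transform (default three levels); (3) fuse
#' coefficients across bands with the max-value scheme; (4) inverse
#' transform the fused stack into the single fused image.
#'
#' @param cube an `hsi_cube`.
#' @param transform `"dwt"`, `"sidwt"` or `"dtcwt"`.
#' @param levels decomposition depth (default 3).
#' @param family filter family (default `"haar"` for dwt/sidwt, `"db4"`
#'   for dtcwt); see [wavelet_filters()].
#' @param approx_rule fusion rule for the approximation subband, see
#'   [max_value_select()].
#' @return An `hsi_fused` image.
#' @export
fuse_wavelet <- function(cube, transform = c("dwt", "sidwt", "dtcwt"),
                         levels = 3L, family = NULL,
                         approx_rule = c("max", "mean")) {
  assert_cube(cube)
  transform <- match.arg(transform)
  approx_rule <- match.arg(approx_rule)
  L <- dim(cube$values)[3]
  stacks <- lapply(seq_len(L), function(k)
    decompose_band(cube$values[, , k], transform, levels, family))
  fused <- max_value_select(stacks, approx_rule)
  fused_image(reconstruct_band(fused), transform,
              params = list(levels = levels, family = fused$family,
                            approx_rule = approx_rule))
}

#' Laplacian-pyramid fusion of a datacube
#'
#' Builds a Laplacian pyramid per band; at every pyramid level (including
#' the top Gaussian level) selects per coefficient the value of largest
#' absolute value across bands; reconstructs the fused pyramid by the
#' backward recurrence.
#'
#' @param cube an `hsi_cube`.
#' @param T number of Laplacian levels (default 3).
#' @param approx_rule fusion rule for the top Gaussian level: `"max"`
#'   (default) or `"mean"`.
#' @return An `hsi_fused` image.
#' @export
fuse_laplacian <- function(cube, T = 3L, approx_rule = c("max", "mean")) {
  assert_cube(cube)
  approx_rule <- match.arg(approx_rule)
  L <- dim(cube$values)[3]
  pyrs <- lapply(seq_len(L), function(k)
    build_laplacian_pyramid(cube$values[, , k], T))
  fused <- pyrs[[1]]
  for (t in seq_len(fused$T))
    fused$laplacian[[t]] <- select_max_abs(lapply(pyrs, function(p) p$laplacian[[t]]))
  fused$top <- if (approx_rule == "max")
    select_max_abs(lapply(pyrs, function(p) p$top))
  else select_mean(lapply(pyrs, function(p) p$top))
  fused_image(reconstruct_laplacian_pyramid(fused), "laplacian",
              params = list(T = T, approx_rule = approx_rule))
}
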