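#' Construct a hyperspectral datacube
#'
#' A datacube is an `M x N x L` intensity array: two spatial dimensions
#' (rows, columns) and one spectral dimension of `L` bands, each band
#' centred on a wavelength in nanometres. Values are either raw camera
#' counts (16-bit signed integers, as acquired by line-scan NIR cameras)
#' or normalized real reflectance.
#'
#' @param values numeric 3-D array, `M x N x L`.
#' @param wavelengths numeric vector of band centres in nm, strictly
#'   increasing, length `L`. Defaults to a uniform axis over
#'   984.2–1631.0 nm (the retained NIR range of the target camera).
#' @param dtype_origin `"int16"` for as-acquired integer data (values are
#'   checked against the signed 16-bit range) or `"real"` for normalized
#'   data.
#' @return An object of class `hsi_cube`: a list with elements `values`,
#'   `wavelengths`, `dtype_origin`.
#' @examples
#' cube <- datacube(array(rnorm(4 * 5 * 3), c(4, 5, 3)))
#' dim(cube)
#' @export
datacube <- function(values, wavelengths = NULL,
                     dtype_origin = c("real", "int16")) {
  dtype_origin <- match.arg(dtype_origin)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array (rows x cols x bands)")
  d <- dim(values)
  if (any(d < 1L)) stop("all cube dimensions must be >= 1")
  L <- d[3L]
  if (is.null(wavelengths))
    wavelengths <- default_wavelengths(L)
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != L)
    stop("length(wavelengths) must equal the number of bands (", L, ")")
  if (L > 1L && any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  storage.mode(values) <- "double"
  if (dtype_origin == "int16" &&
      (anyNA(values) || any(values < -32768 | values > 32767)))
    stop("int16 cube holds values outside the signed 16-bit range")
  structure(list(values = values, wavelengths = wavelengths,
                 dtype_origin = dtype_origin),
            class = "hsi_cube")
}

# Uniform axis over the retained NIR window; used for synthetic cubes.
default_wavelengths <- function(L) {
  if (L == 1L) return(1307.6)          # midpoint of the default window
  seq(984.2, 1631.0, length.out = L)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %d x %d pixels, %d bands (%.1f-%.1f nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$dtype_origin))
  invisible(x)
}

is_cube <- function(x) inherits(x, "hsi_cube")

assert_cube <- function(x) {
  if (!is_cube(x)) stop("expected an `hsi_cube` object")
  invisible(x)
}

#' Restrict a datacube to a wavelength interval
#'
#' Keeps the bands whose centre wavelength lies inside the closed interval
#' `keep_range` (inclusive at both ends); band order is preserved. The
#' default interval is the informative NIR window 984.2–1631.0 nm used when
#' trimming uninformative edge channels from the camera's full range.
#'
#' @param cube an `hsi_cube`.
#' @param keep_range length-2 numeric, closed interval in nm.
#' @return An `hsi_cube` with the retained bands.
#' @export
filter_bands <- function(cube, keep_range = c(984.2, 1631.0)) {
  assert_cube(cube)
  if (length(keep_range) != 2L || keep_range[1] > keep_range[2])
    stop("`keep_range` must be c(lo, hi) with lo <= hi")
  keep <- cube$wavelengths >= keep_range[1] & cube$wavelengths <= keep_range[2]
  if (!any(keep)) stop("no bands retained by keep_range")
  datacube(cube$values[, , keep, drop = FALSE],
           cube$wavelengths[keep], cube$dtype_origin)
}

#' Extract a rectangular region of interest
#'
#' Windows use 0-based row/column origins and a half-open convention:
#' the window covers rows `row0 .. row0 + h - 1` (0-based). The window must
#' lie fully inside the cube; there is no silent clipping.
#'
#' @param cube an `hsi_cube`.
#' @param row0,col0 0-based origin of the window.
#' @param h,w window height and width in pixels.
#' @return An `hsi_cube` of spatial size `h x w` sharing the wavelength axis.
#' @export
extract_roi <- function(cube, row0, col0, h, w) {
  assert_cube(cube)
  d <- dim(cube$values)
  if (row0 < 0 || col0 < 0 || h < 1 || w < 1 ||
      row0 + h > d[1] || col0 + w > d[2])
    stop("ROI window [", row0, ",", row0 + h, ") x [", col0, ",",
         col0 + w, ") is out of bounds for a ", d[1], " x ", d[2], " frame")
  datacube(cube$values[(row0 + 1):(row0 + h), (col0 + 1):(col0 + w), ,
                       drop = FALSE],
           cube$wavelengths, cube$dtype_origin)
}

#' Per-band mean and standard deviation over a pixel mask
#'
#' Summarises the spectral signature of an image region: for every band the
#' mean and the population standard deviation over the masked pixels. Used
#' to compare anomaly, tray-edge and tray-centre regions of a seal ROI.
#'
#' @param cube an `hsi_cube`.
#' @param mask logical `M x N` matrix selecting at least one pixel.
#' @param region_label free-text label stored with the signature.
#' @return An object of class `spectral_signature`: list with `mean`, `sd`
#'   (length-`L` vectors), `wavelengths`, `region_label`, `n_pixels`.
#' @export
spectral_signature <- function(cube, mask, region_label = "region") {
  assert_cube(cube)
  d <- dim(cube$values)
  if (!is.logical(mask) || !identical(dim(mask), d[1:2]))
    stop("`mask` must be a logical M x N matrix matching the cube")
  n <- sum(mask)
  if (n < 1L) stop("empty mask")
  flat <- matrix(cube$values, d[1] * d[2], d[3])[as.vector(mask), , drop = FALSE]
  mu <- colMeans(flat)
  # population (1/n) standard deviation
  sdv <- sqrt(colMeans(flat^2) - mu^2)
  sdv[sdv < 0 | is.nan(sdv)] <- 0
  structure(list(mean = mu, sd = sdv, wavelengths = cube$wavelengths,
                 region_label = region_label, n_pixels = n),
            class = "spectral_signature")
}

#' @export
print.spectral_signature <- function(x, ...) {
  cat(sprintf("<spectral_signature> '%s': %d pixels, %d bands, mean range [%.4g, %.4g]\n",
              x$region_label, x$n_pixels, length(x$mean),
              min(x$mean), max(x$mean)))
  invisible(x)
}

#' Rescale a datacube
#'
#' `minmax` maps the whole cube affinely onto `[0, 1]`; `zscore` centres to
#' zero mean and unit variance (population variance, whole cube); `none`
#' returns the cube unchanged. After `minmax`/`zscore` the cube is flagged
#' as normalized real data.
#'
#' @param cube an `hsi_cube`.
#' @param method one of `"minmax"`, `"zscore"`, `"none"`.
#' @return An `hsi_cube`.
#' @export
normalize_cube <- function(cube, method = c("minmax", "zscore", "none")) {
  assert_cube(cube)
  method <- match.arg(method)
  if (method == "none") return(cube)
  v <- cube$values
  if (method == "minmax") {
    rng <- range(v)
    if (rng[2] == rng[1]) stop("constant cube cannot be min-max normalized")
    v <- (v - rng[1]) / (rng[2] - rng[1])
  } else {
    mu <- mean(v)
    sdv <- sqrt(mean((v - mu)^2))
    if (sdv == 0) stop("constant cube cannot be z-scored")
    v <- (v - mu) / sdv
  }
  datacube(v, cube$wavelengths, "real")
}
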