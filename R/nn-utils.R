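# Shared numerical helpers for the classifier families. All stochastic
# draws flow through local_seed() so identical seed + config + data give
# bit-identical models.

# evaluate `code` under a temporary RNG state seeded with `seed`
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Activation functions for the extreme learning machine
#'
#' `sigmoid` 1/(1+exp(-x)); `tribas` (triangular basis) max(0, 1-|x|);
#' `sine` sin(x); `hardlim` (hard limit) 1 if x >= 0 else 0; `radbas`
#' (radial basis) exp(-x^2).
#'
#' @param name activation name.
#' @return The activation function.
#' @export
elm_activation <- function(name) {
  switch(name,
    sigmoid = sigmoid,
    tribas = function(x) pmax(1 - abs(x), 0),
    sine = sin,
    hardlim = function(x) (x >= 0) + 0,
    radbas = function(x) exp(-x^2),
    stop("unknown activation: ", name,
         " (use sigmoid, tribas, sine, hardlim or radbas)"))
}

#' Labeled set of fused seal images
#'
#' The unit fed to every classifier family: equal-sized 2-D images (fused
#' ROIs) with binary labels. `normal` is the positive class throughout.
#'
#' @param images 3-D array `h x w x n`, or list of equal-sized matrices.
#' @param labels character/factor vector of `"normal"` / `"faulty"`,
#'   length `n`.
#' @return An object of class `hsi_imageset`.
#' @export
image_set <- function(images, labels) {
  if (is.list(images)) {
    d <- dim(images[[1]])
    if (!all(vapply(images, function(m) identical(dim(m), d), logical(1))))
      stop("all images must share the same size")
    images <- array(unlist(images), c(d, length(images)))
  }
  if (length(dim(images)) != 3L) stop("`images` must be an h x w x n array")
  labels <- as.character(labels)
  if (length(labels) != dim(images)[3])
    stop("one label per image required")
  if (!all(labels %in% c("normal", "faulty")))
    stop("labels must be 'normal' or 'faulty'")
  structure(list(images = images, labels = labels), class = "hsi_imageset")
}

#' @export
print.hsi_imageset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<hsi_imageset> %d images of %d x %d (%d normal / %d faulty)\n",
              d[3], d[1], d[2], sum(x$labels == "normal"),
              sum(x$labels == "faulty")))
  invisible(x)
}

class_levels <- c("normal", "faulty")

check_trainable <- function(set) {
  if (!inherits(set, "hsi_imageset")) stop("expected an `hsi_imageset`")
  if (length(unique(set$labels)) < 2L)
    stop("training data must contain both classes")
  invisible(set)
}

# min-max each image to [0, 1] (constant images map to 0)
normalize_images <- function(images) {
  d <- dim(images)
  m <- matrix(images, d[1] * d[2], d[3])
  lo <- apply(m, 2, min); hi <- apply(m, 2, max)
  rng <- hi - lo; rng[rng == 0] <- 1
  array(sweep(sweep(m, 2, lo), 2, rng, "/"), d)
}

# rows = samples
flatten_images <- function(images) {
  d <- dim(images)
  t(matrix(images, d[1] * d[2], d[3]))
}

one_hot <- function(labels) {
  Y <- matrix(0, length(labels), 2L, dimnames = list(NULL, class_levels))
  Y[cbind(seq_along(labels), match(labels, class_levels))] <- 1
  Y
}

new_model <- function(family, params, cfg, input_dim, normalize) {
  structure(list(family = family, params = params, cfg = cfg,
                 input_dim = input_dim, normalize = normalize),
            class = c(paste0("hsi_model_", family), "hsi_model"))
}

#' @export
print.hsi_model <- function(x, ...) {
  cat(sprintf("<hsi_model> family = %s, input = %d x %d\n",
              x$family, x$input_dim[1], x$input_dim[2]))
  invisible(x)
}

model_input <- function(model, images) {
  if (is.list(images) || length(dim(images)) == 3L) {
    if (is.list(images)) images <- image_set(images,
                                             rep("normal", length(images)))$images
  } else stop("`images` must be an h x w x n array or list of matrices")
  if (!identical(dim(images)[1:2], model$input_dim))
    stop("image size ", dim(images)[1], " x ", dim(images)[2],
         " does not match the model's input shape ",
         model$input_dim[1], " x ", model$input_dim[2])
  if (model$normalize) images <- normalize_images(images)
  images
}
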