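#' Predict seal labels from a trained classifier
#'
#' @param object a trained `hsi_model` (any family).
#' @param images an `h x w x n` array, a list of matrices, or an
#'   [image_set()] (its labels are ignored).
#' @param ... unused.
#' @return A list with `labels` (character vector, `"normal"`/`"faulty"`)
#'   and `scores` (`n x 2` matrix; class probabilities summing to one per
#'   row for the softmax families cnn/sae/dbn, raw least-squares scores
#'   for elm).
#' @export
predict.hsi_model <- function(object, images, ...) {
  if (inherits(images, "hsi_imageset")) images <- images$images
  scores <- switch(object$family,
    elm = elm_scores(object, images),
    cnn = cnn_scores(object, images),
    sae = sae_scores(object, images),
    dbn = dbn_scores(object, images),
    stop("unknown model family: ", object$family))
  list(labels = class_levels[max.col(scores, ties.method = "first")],
       scores = scores)
}

#' Train any classifier family by name
#'
#' Thin dispatcher over [train_cnn()], [train_sae()], [train_dbn()] and
#' [train_elm()].
#'
#' @param data an [image_set()].
#' @param family `"cnn"`, `"sae"`, `"dbn"` or `"elm"`.
#' @param ... family-specific configuration.
#' @return An `hsi_model`.
#' @export
train_classifier <- function(data, family = c("cnn", "sae", "dbn", "elm"),
                             ...) {
  family <- match.arg(family)
  switch(family,
    cnn = train_cnn(data, ...),
    sae = train_sae(data, ...),
    dbn = train_dbn(data, ...),
    elm = train_elm(data, ...))
}

#' Names of the four classifier families
#' @return Character vector `c("cnn", "sae", "dbn", "elm")`.
#' @export
classifier_families <- function() c("cnn", "sae", "dbn", "elm")
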