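#' Per-pixel classification map
#'
#' Classifies every labelled pixel of a reduced cube with a trained model
#' and returns the prediction as a label map; background (label 0) pixels
#' stay 0.
#'
#' @param model a trained [sst_model] (or any model with a compatible
#'   `predict` method taking a [patch_set]).
#' @param reduced a [reduced_cube] whose band count matches the model.
#' @param labels a [label_map]; only its nonzero pixels are classified.
#' @param s patch window; defaults to the model's configured window.
#' @return a [label_map] of predicted classes.
#' @export
classification_map <- function(model, reduced, labels, s = NULL) {
  stopifnot(inherits(labels, "label_map"))
  if (is.null(s)) {
    s <- if (inherits(model, "sst_model")) model$config$s else model$s
  }
  b_model <- if (inherits(model, "sst_model")) model$config$b else model$b
  if (!is.null(b_model) && dim(reduced$values)[3] != b_model) {
    stop(sprintf("model expects %d bands but the cube has %d",
                 b_model, dim(reduced$values)[3]))
  }
  ps <- extract_patches(reduced, labels, s = s)
  pred <- predict(model, ps)
  out <- matrix(0L, nrow(labels$labels), ncol(labels$labels))
  out[ps$centers] <- as.integer(pred)
  label_map(out, labels$class_names)
}
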