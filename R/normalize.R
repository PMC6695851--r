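#' Min-max normalization to [-1, 1] fitted on training data
#'
#' Each feature's training minimum maps to -1 and maximum to +1, affinely in
#' between. Test values outside the training range extrapolate (they are not
#' clipped), so the transform is exactly affine everywhere.
#'
#' @param x numeric matrix or data.frame of training features
#'   (rows = subjects)
#' @return object of class `normalization_params` with per-feature `min`,
#'   `max`
#' @export
fit_normalizer <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop_domain("features must be numeric")
  mins <- apply(x, 2, min)
  maxs <- apply(x, 2, max)
  if (any(maxs <= mins))
    stop_domain("degenerate feature: a training column is constant")
  structure(list(min = mins, max = maxs), class = "normalization_params")
}

#' @rdname fit_normalizer
#' @param params a fitted `normalization_params`
#' @param newx features to transform (matrix, data.frame, or single row)
#' @return matrix of features scaled to the training [-1, 1] frame
#' @export
apply_normalizer <- function(params, newx) {
  stopifnot(inherits(params, "normalization_params"))
  newx <- if (is.null(dim(newx))) matrix(newx, nrow = 1) else as.matrix(newx)
  if (ncol(newx) != length(params$min))
    stop_domain("feature count mismatch with fitted normalizer")
  sweep(sweep(newx, 2, params$min), 2,
        (params$max - params$min) / 2, "/") - 1
}
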