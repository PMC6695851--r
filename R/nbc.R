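#' Gaussian naive Bayes classifier
#'
#' Each feature is modelled as class-conditionally Gaussian and independent
#' of the others; classification is by maximum a posteriori with priors
#' taken from the training class frequencies. A variance floor of 1e-9
#' guards degenerate features.
#'
#' @param train_x numeric training feature matrix
#' @param train_y labels ("positive"/"negative" or +1/-1)
#' @return object of class `nbc_model` (per-class means, variances, priors)
#' @export
nbc_fit <- function(train_x, train_y) {
  x <- as.matrix(train_x)
  y <- as_pm1(train_y)
  if (!all(c(1L, -1L) %in% y))
    stop_domain("both classes must be present in the training data")
  if (any(table(y) < 2))
    stop_domain("each class needs at least 2 training points")
  per_class <- lapply(c(pos = 1L, neg = -1L), function(cls) {
    xc <- x[y == cls, , drop = FALSE]
    list(mu = colMeans(xc),
         var = pmax(apply(xc, 2, stats::var), 1e-9),
         prior = nrow(xc) / nrow(x))
  })
  structure(per_class, class = "nbc_model")
}

# log p(class) + sum log N(x | mu, var) per class
.nbc_log_joint <- function(model, xrow) {
  vapply(model, function(cl) {
    log(cl$prior) + sum(stats::dnorm(xrow, cl$mu, sqrt(cl$var), log = TRUE))
  }, numeric(1))
}

#' @rdname nbc_fit
#' @param model a fitted `nbc_model`
#' @param test_x one test point (vector) or matrix of test points
#' @return `nbc_classify`: predicted labels (posterior ties go to positive);
#'   `nbc_posterior`: matrix of class posteriors (columns `pos`, `neg`)
#' @export
nbc_classify <- function(model, test_x) {
  post <- nbc_posterior(model, test_x)
  unname(ifelse(post[, "pos"] >= post[, "neg"], "positive", "negative"))
}

#' @rdname nbc_fit
#' @export
nbc_posterior <- function(model, test_x) {
  stopifnot(inherits(model, "nbc_model"))
  test_x <- if (is.null(dim(test_x))) matrix(test_x, nrow = 1) else as.matrix(test_x)
  out <- t(apply(test_x, 1, function(r) {
    lj <- .nbc_log_joint(model, r)
    w <- exp(lj - max(lj))
    w / sum(w)
  }))
  colnames(out) <- c("pos", "neg")
  out
}
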