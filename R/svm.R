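#' Radial basis kernel
#'
#' `exp(-||x_j - x_k||^2 / sigma)`: the scale parameter divides the squared
#' Euclidean distance directly (a reparameterization of the usual
#' gamma-form RBF with `gamma = 1/sigma`).
#'
#' @param x,z feature matrices (rows = points); `z` defaults to `x`
#' @param sigma kernel scale (> 0)
#' @return kernel matrix, `nrow(x)` by `nrow(z)`
#' @export
rbf_kernel <- function(x, z = x, sigma) {
  check_num(sigma, "sigma", positive = TRUE)
  x <- as.matrix(x); z <- as.matrix(z)
  d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * tcrossprod(x, z)
  exp(-pmax(d2, 0) / sigma)
}

#' Soft-margin RBF support vector machine
#'
#' Solves the box-constrained dual
#' \deqn{\max_\alpha \sum_j \alpha_j - \tfrac12 \sum_{j,k}
#'   \alpha_j\alpha_k y_j y_k G(x_j, x_k)}
#' subject to \eqn{\sum_j y_j\alpha_j = 0,\ 0 \le \alpha_j \le C^*},
#' by sequential minimal optimization. The decision rule is
#' `sign(sum_j alpha_j y_j G(x_j, x) + b)`.
#'
#' @param train_x training feature matrix
#' @param train_y labels ("positive"/"negative" or +1/-1), both classes
#'   present
#' @param C penalty for misclassification (> 0)
#' @param sigma RBF scale (> 0)
#' @param tol KKT violation tolerance of the solver
#' @param max_steps cap on SMO pair updates
#' @param best_effort return the (feasible) iterate when the step cap is
#'   hit instead of erroring; used during grid search, where an
#'   almost-converged solution ranks hyperparameters just as well
#' @return object of class `svm_model` holding support coefficients
#'   `alpha`, bias `b`, the training data, and solver diagnostics
#' @export
svm_fit <- function(train_x, train_y, C, sigma, tol = 1e-6,
                    max_steps = 1e7, best_effort = FALSE) {
  x <- as.matrix(train_x)
  y <- as_pm1(train_y)
  if (!all(c(1L, -1L) %in% y))
    stop_domain("both classes must be present in the training data")
  check_num(C, "C", positive = TRUE)
  K <- rbf_kernel(x, sigma = sigma)
  sol <- smo_solve(K, as.numeric(y), C, tol = tol, max_steps = max_steps)
  if (!isTRUE(sol$converged) && !best_effort)
    stop_domain("SMO did not converge (", sol$steps, " steps); ",
                "consider loosening tol or rescaling features")
  structure(list(x = x, y = y, alpha = as.numeric(sol$alpha), b = sol$b,
                 C = C, sigma = sigma, tol = tol, K = K,
                 steps = sol$steps, converged = sol$converged),
            class = "svm_model")
}

#' Decision values and labels for an SVM model
#'
#' @param model a fitted `svm_model`
#' @param test_x one point (vector) or a matrix of points
#' @return `svm_decision`: numeric decision values;
#'   `svm_classify`: predicted labels (0 decides positive)
#' @export
svm_decision <- function(model, test_x) {
  stopifnot(inherits(model, "svm_model"))
  test_x <- if (is.null(dim(test_x))) matrix(test_x, nrow = 1) else as.matrix(test_x)
  Kt <- rbf_kernel(model$x, test_x, model$sigma)
  as.numeric(crossprod(Kt, model$alpha * model$y)) + model$b
}

#' @rdname svm_decision
#' @export
svm_classify <- function(model, test_x) {
  label_of(ifelse(svm_decision(model, test_x) >= 0, 1L, -1L))
}

#' Dual objective and KKT diagnostics of a fitted SVM
#'
#' `svm_dual_objective` evaluates the dual at the returned multipliers.
#' `svm_kkt` reports the equality-constraint residual `|sum alpha_j y_j|`,
#' the box violation, and the worst complementary-slackness residual
#' `alpha_j * (y_j f(x_j) - 1 + zeta_j)` with
#' `zeta_j = max(0, 1 - y_j f(x_j))` and its mirror
#' `(C - alpha_j) * zeta_j`.
#'
#' @param model a fitted `svm_model`
#' @return `svm_dual_objective`: a scalar; `svm_kkt`: a named list
#' @export
svm_dual_objective <- function(model) {
  ay <- model$alpha * model$y
  sum(model$alpha) - 0.5 * drop(t(ay) %*% model$K %*% ay)
}

#' @rdname svm_dual_objective
#' @export
svm_kkt <- function(model) {
  f <- as.numeric(model$K %*% (model$alpha * model$y)) + model$b
  margin <- model$y * f
  zeta <- pmax(0, 1 - margin)
  list(equality = abs(sum(model$alpha * model$y)),
       box = max(0, max(-model$alpha), max(model$alpha - model$C)),
       comp_slack = max(abs(model$alpha * (margin - 1 + zeta))),
       comp_slack_upper = max(abs((model$C - model$alpha) * zeta)))
}

#' Grid search for the SVM penalty and kernel scale
#'
#' Inner stratified cross-validated accuracy on the training fold; ties are
#' broken towards the smaller penalty, then the larger kernel scale (the
#' smoother model). Default grids are powers of two spanning
#' 2^-5..2^15 (penalty) and 2^-5..2^10 (scale).
#'
#' @param train_x training features
#' @param train_y training labels
#' @param C_grid,sigma_grid candidate values
#' @param nfolds inner folds (default 5)
#' @param tol solver tolerance used during the search
#' @return list with `C`, `sigma`, `accuracy`
#' @export
svm_grid_search <- function(train_x, train_y,
                            C_grid = 2^seq(-5, 15, by = 2),
                            sigma_grid = 2^seq(-5, 10, by = 3),
                            nfolds = 5, tol = 1e-4) {
  x <- as.matrix(train_x)
  y <- as_pm1(train_y)
  if (length(C_grid) == 0 || length(sigma_grid) == 0)
    stop_domain("empty hyperparameter grid")
  folds <- make_folds(y, nfolds)
  best <- list(C = NA_real_, sigma = NA_real_, correct = -1L)
  for (C in sort(C_grid)) {
    for (sigma in sort(sigma_grid, decreasing = TRUE)) {
      correct <- 0L
      for (f in seq_len(nfolds)) {
        tr <- folds != f; te <- folds == f
        if (!any(te) || length(unique(y[tr])) < 2) next
        m <- svm_fit(x[tr, , drop = FALSE], y[tr], C, sigma, tol = tol,
                     max_steps = 2e4, best_effort = TRUE)
        correct <- correct + sum(as_pm1(svm_classify(m, x[te, , drop = FALSE])) == y[te])
      }
      if (correct > best$correct)  # scan order encodes the tie-breaks
        best <- list(C = C, sigma = sigma, correct = correct)
    }
  }
  list(C = best$C, sigma = best$sigma, accuracy = best$correct / length(y))
}
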