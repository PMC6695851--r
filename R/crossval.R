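#' Feature columns consumed by each screening task
#'
#' The stenosis task uses the five features of the optical/compliance
#' derivation; the flow task additionally uses heart rate.
#'
#' @param task `"dos"` or `"bfv"`
#' @return character vector of feature column names
#' @export
task_features <- function(task = c("dos", "bfv")) {
  task <- match.arg(task)
  base <- c("pi_max", "pi_min", "spo2", "sbp", "dbp")
  if (task == "bfv") c(base, "hr") else base
}

# fit the requested classifier on a (normalized) training fold and return a
# prediction closure; grids are re-searched inside this fold only
.fit_fold_classifier <- function(xtr, ytr, classifier) {
  method <- classifier$method
  if (method == "knn") {
    gs <- knn_grid_search(xtr, ytr,
                          k_grid = classifier$k_grid %||% c(1, 3, 5, 7, 9, 11))
    list(predict = function(xte) knn_classify(xtr, ytr, xte, gs$k),
         params = list(k = gs$k))
  } else if (method == "nbc") {
    model <- nbc_fit(xtr, ytr)
    list(predict = function(xte) nbc_classify(model, xte),
         params = list())
  } else if (method == "svm") {
    gs <- svm_grid_search(xtr, ytr,
                          C_grid = classifier$C_grid %||% 2^seq(-5, 15, by = 2),
                          sigma_grid = classifier$sigma_grid %||% 2^seq(-5, 10, by = 3))
    model <- svm_fit(xtr, ytr, gs$C, gs$sigma)
    list(predict = function(xte) svm_classify(model, xte),
         params = list(C = gs$C, sigma = gs$sigma))
  } else stop_domain("unknown classifier method: ", method)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified 10-fold subject-level cross-validation
#'
#' Subjects are shuffled under the seed, dealt into stratified
#' subject-disjoint folds, and each fold serves once as the test set.
#' Normalization and hyperparameter grid search are re-fitted inside each
#' training fold only, so no information leaks from test subjects. The
#' pooled matrix sums the per-fold test confusion matrices.
#'
#' @param subjects data.frame with the feature columns of [task_features()]
#'   and a `dos_label` / `bfv_label` column for the chosen task
#' @param task `"dos"` or `"bfv"`
#' @param classifier list with `method` ("knn", "nbc" or "svm") and optional
#'   grids (`k_grid`, `C_grid`, `sigma_grid`)
#' @param seed integer seed controlling the fold shuffle
#' @param nfolds number of folds (default 10)
#' @return object of class `cv_result`: `pooled` confusion matrix, `folds`
#'   (per-fold matrices), `params` (per-fold selected hyperparameters),
#'   `assignments` (fold id per subject, in input order)
#' @export
crossvalidate <- function(subjects, task = c("dos", "bfv"),
                          classifier = list(method = "svm"),
                          seed = 1L, nfolds = 10L) {
  task <- match.arg(task)
  feats <- task_features(task)
  labcol <- paste0(task, "_label")
  if (!all(c(feats, labcol) %in% names(subjects)))
    stop_domain("subject table lacks required columns for task ", task)
  n <- nrow(subjects)
  if (n < nfolds) stop_domain("need at least ", nfolds, " subjects")
  x <- as.matrix(subjects[, feats])
  y <- as_pm1(subjects[[labcol]])

  old <- .Random.seed_exists()
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  .restore_seed(old)

  folds_perm <- make_folds(y[perm], nfolds)
  folds <- integer(n)
  folds[perm] <- folds_perm

  fold_cms <- vector("list", nfolds)
  fold_params <- vector("list", nfolds)
  for (f in seq_len(nfolds)) {
    tr <- folds != f; te <- folds == f
    if (!any(te)) {
      fold_cms[[f]] <- confusion_matrix(0, 0, 0, 0)
      fold_params[[f]] <- list()
      next
    }
    norm <- fit_normalizer(x[tr, , drop = FALSE])
    xtr <- apply_normalizer(norm, x[tr, , drop = FALSE])
    xte <- apply_normalizer(norm, x[te, , drop = FALSE])
    fit <- .fit_fold_classifier(xtr, y[tr], classifier)
    pred <- fit$predict(xte)
    fold_cms[[f]] <- confusion_from_labels(y[te], pred)
    fold_params[[f]] <- fit$params
  }
  pooled <- Reduce(`+`, fold_cms)
  structure(list(pooled = pooled, folds = fold_cms, params = fold_params,
                 assignments = folds, task = task, seed = seed,
                 method = classifier$method),
            class = "cv_result")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV, task %s, classifier %s (seed %d)\n",
              length(x$folds), toupper(x$task), x$method, x$seed))
  print(x$pooled)
  invisible(x)
}
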