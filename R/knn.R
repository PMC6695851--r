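#' k-nearest-neighbour classification
#'
#' Majority vote among the `k` training points with smallest Euclidean
#' distance. Vote ties are broken towards the class with the smaller summed
#' neighbour distance, then towards the positive class; equal distances are
#' resolved by training-set order.
#'
#' @param train_x numeric matrix of training features (rows = subjects)
#' @param train_y labels, "positive"/"negative" (or +1/-1)
#' @param test_x one test point (vector) or a matrix of test points
#' @param k number of neighbours, `1 <= k <= nrow(train_x)`
#' @return character vector of predicted labels
#' @export
knn_classify <- function(train_x, train_y, test_x, k) {
  train_x <- as.matrix(train_x)
  if (nrow(train_x) == 0) stop_domain("empty training set")
  y <- as_pm1(train_y)
  k <- as.integer(k)
  if (k < 1 || k > nrow(train_x)) stop_domain("k must lie in [1, n_train]")
  test_x <- if (is.null(dim(test_x))) matrix(test_x, nrow = 1) else as.matrix(test_x)
  out <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- sqrt(rowSums(sweep(train_x, 2, test_x[i, ])^2))
    nb <- order(d)[seq_len(k)]         # order() is stable: ties to earlier rows
    votes_pos <- sum(y[nb] == 1)
    votes_neg <- k - votes_pos
    lab <- if (votes_pos != votes_neg) {
      if (votes_pos > votes_neg) 1 else -1
    } else {
      dp <- sum(d[nb][y[nb] == 1]); dn <- sum(d[nb][y[nb] == -1])
      if (dp < dn) 1 else if (dn < dp) -1 else 1
    }
    out[i] <- label_of(lab)
  }
  out
}

#' Grid search for the kNN neighbourhood size
#'
#' Inner 5-fold cross-validated accuracy on the training fold; ties return
#' the smallest `k`. The grid is restricted to odd values to avoid vote
#' ties.
#'
#' @param train_x training features
#' @param train_y training labels
#' @param k_grid candidate neighbourhood sizes (odd, >= 1)
#' @param nfolds inner folds (default 5)
#' @return list with `k` (selected) and `accuracy` (its inner-CV accuracy)
#' @export
knn_grid_search <- function(train_x, train_y, k_grid = c(1, 3, 5, 7, 9, 11),
                            nfolds = 5) {
  train_x <- as.matrix(train_x)
  y <- as_pm1(train_y)
  if (length(k_grid) == 0) stop_domain("empty k grid")
  if (any(k_grid %% 2 == 0)) stop_domain("k grid must contain odd values only")
  k_grid <- sort(unique(as.integer(k_grid)))
  folds <- make_folds(y, nfolds)
  best_k <- NA_integer_; best_correct <- -1L
  for (k in k_grid) {
    correct <- 0L
    for (f in seq_len(nfolds)) {
      tr <- folds != f; te <- folds == f
      if (!any(te) || sum(tr) < k) next
      pred <- knn_classify(train_x[tr, , drop = FALSE], y[tr],
                           train_x[te, , drop = FALSE], k)
      correct <- correct + sum(as_pm1(pred) == y[te])
    }
    if (correct > best_correct) { best_correct <- correct; best_k <- k }
  }
  list(k = best_k, accuracy = best_correct / length(y))
}
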