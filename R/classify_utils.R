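# Shared label and fold plumbing for the classifiers.

# labels -> +1/-1 ("positive" is +1)
as_pm1 <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop_domain("numeric labels must be +1/-1")
    return(as.integer(y))
  }
  y <- tolower(as.character(y))
  if (!all(y %in% c("positive", "negative")))
    stop_domain('labels must be "positive"/"negative" or +1/-1')
  ifelse(y == "positive", 1L, -1L)
}

label_of <- function(pm1) ifelse(pm1 == 1, "positive", "negative")

# Stratified fold assignment: within each class, members are dealt to folds
# cyclically in their current order. Deterministic; callers that want random
# folds shuffle the subject order first (under their seed).
make_folds <- function(y, nfolds) {
  y <- as_pm1(y)
  folds <- integer(length(y))
  at <- 0L  # continue the deal across classes so no fold is left empty
  for (cls in c(1L, -1L)) {
    idx <- which(y == cls)
    if (length(idx)) {
      folds[idx] <- (at + seq_along(idx) - 1L) %% nfolds + 1L
      at <- at + length(idx)
    }
  }
  folds
}
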