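# Model-accuracy measures shared by the item response model, the forest and
# the hybrid.

#' Area under the ROC curve
#'
#' Rank-based AUC with midranks for tied probabilities; equals the
#' trapezoidal area under the ROC curve and the concordance probability.
#'
#' @param y binary 0/1 vector with both classes present.
#' @param p probability (or any score) vector.
#' @return scalar in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0, 0, 1, 1), c(0.1, 0.6, 0.4, 0.9))  # 0.75
auc <- function(y, p) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_eirmrf("AUC undefined: only one class present", "value_error")
  }
  r <- rank(p)  # midranks for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between binary outcomes and predicted
#' probabilities; smaller is better.
#'
#' @param y binary 0/1 vector.
#' @param p probabilities in `[0, 1]`.
#' @return scalar in `[0, 1]`.
#' @export
brier <- function(y, p) {
  y <- as.numeric(y)
  stopifnot(length(y) == length(p))
  if (any(p < 0 | p > 1)) {
    stop_eirmrf("probabilities must lie in [0, 1]", "value_error")
  }
  mean((y - p)^2)
}

#' Bundle AUC and Brier score for a labelled model
#'
#' @param y binary outcomes.
#' @param p predicted probabilities.
#' @param model label for the row.
#' @return one-row data frame with `model`, `auc`, `brier`, `n`.
#' @export
accuracy_report <- function(y, p, model = "model") {
  data.frame(
    model = model, auc = auc(y, p), brier = brier(y, p), n = length(y),
    stringsAsFactors = FALSE
  )
}
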