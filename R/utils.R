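# Internal numeric helpers shared across the fitting and inference code.

# Quantile soft/hard thresholding of a weight vector. `lambda` is the
# proportion of entries to suppress: the threshold is the lambda-quantile of
# |w|; lambda = 0 leaves w untouched, lambda = 1 zeroes everything.
threshold_weights <- function(w, lambda, mode = c("soft", "hard")) {
  mode <- match.arg(mode)
  if (lambda < 0 || lambda > 1) {
    abort("`lambda` must lie in [0, 1].")
  }
  if (lambda == 0 || all(w == 0)) {
    return(w)
  }
  tau <- unname(quantile(abs(w), probs = lambda, type = 7))
  keep <- abs(w) > tau
  out <- numeric(length(w))
  if (mode == "soft") {
    out[keep] <- sign(w[keep]) * (abs(w[keep]) - tau)
  } else {
    out[keep] <- w[keep]
  }
  names(out) <- names(w)
  out
}

# Unit-normalize, leaving an all-zero vector alone.
unitize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm > 0) v / nrm else v
}

# F1 score for binary labels with class 1 positive. Returns 0 when class 1 is
# never predicted (or never present), so a degenerate classifier scores worst.
f1_score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (tp == 0) {
    return(0)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  2 * precision * recall / (precision + recall)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment of a vector of p-values. A thin
#' wrapper over [stats::p.adjust()] that tolerates empty input and validates
#' the domain.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] with no missing values.")
  }
  p.adjust(p, method = "BH")
}
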