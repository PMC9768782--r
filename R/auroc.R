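#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' Computed by the rank formula, which equals the pairwise concordance
#' (number of positive-negative pairs where the positive outscores the
#' negative, with ties credited 0.5) divided by `n_pos * n_neg`. Invariant
#' under strictly monotone transforms of the scores. A single-class label
#' vector is an error, never silently 0.5.
#'
#' @param scores numeric vector of real-valued scores.
#' @param labels 0/1 vector of the same length.
#' @return list of class `metric_value`: name, value, n_pos, n_neg,
#'   tie_count (number of score-tied positive-negative pairs).
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))$value  # 0.75
auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop_input("scores and labels must have equal length")
  if (anyNA(scores) || anyNA(labels) || any(!is.finite(scores)))
    stop_input("scores and labels must be finite")
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop_input("labels must be 0/1")
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos < 1 || n_neg < 1)
    stop_input("AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  value <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  tab <- table(scores, y)
  tie_count <- if (ncol(tab) == 2) sum(tab[, "1"] * tab[, "0"]) else 0
  structure(list(name = "auroc", value = value, n_pos = n_pos,
                 n_neg = n_neg, tie_count = as.integer(tie_count)),
            class = "metric_value")
}

#' @export
print.metric_value <- function(x, ...) {
  cat(sprintf("%s = %.4f (n_pos=%d, n_neg=%d, ties=%d)\n", x$name,
              x$value, x$n_pos, x$n_neg, x$tie_count))
  invisible(x)
}
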