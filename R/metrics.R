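# Rank-based AUC (Mann-Whitney) and macro averaging.

#' Rank-formula AUC
#'
#' Computes the area under the ROC curve by the rank formula
#' `AUC = (sum of positive ranks - M(M+1)/2) / (M * N)`, with ranks ascending
#' in score and midranks for ties, which makes the result exactly the
#' Mann-Whitney probability that a random positive outscores a random
#' negative (ties counted one half).
#'
#' @param scores Numeric vector of scores.
#' @param truth 0/1 vector of the same length.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  if (length(scores) != length(truth)) stopf("scores/truth length mismatch")
  if (!all(truth %in% c(0, 1))) stopf("truth must be 0/1")
  m <- sum(truth == 1)
  n <- sum(truth == 0)
  if (m == 0) stopf("AUC undefined: no positive samples")
  if (n == 0) stopf("AUC undefined: no negative samples")
  r <- rank(scores)  # midranks for ties
  (sum(r[truth == 1]) - m * (m + 1) / 2) / (m * n)
}

#' Macro-averaged AUC over classes
#'
#' Unweighted mean of per-class one-vs-rest [auc_rank()] over evaluable
#' classes.  A class whose truth column is all 0 or all 1 is excluded from
#' the average and reported in the `excluded` attribute (with a warning).
#'
#' @param scores n x C matrix of per-class scores.
#' @param truth n x C 0/1 matrix.
#' @return Macro-AUC (scalar) with attributes `per_class` (named per-class
#'   AUCs, `NA` for excluded classes) and `excluded` (column indices/names).
#' @export
macro_auc <- function(scores, truth) {
  scores <- as.matrix(scores)
  truth <- as.matrix(truth)
  if (!all(dim(scores) == dim(truth))) stopf("scores/truth dimension mismatch")
  C <- ncol(scores)
  per <- rep(NA_real_, C)
  names(per) <- colnames(scores)
  for (k in seq_len(C)) {
    pos <- sum(truth[, k] == 1)
    if (pos > 0 && pos < nrow(truth)) per[k] <- auc_rank(scores[, k], truth[, k])
  }
  excluded <- which(is.na(per))
  if (length(excluded) == C) stopf("no evaluable class: every class is degenerate")
  if (length(excluded) > 0) {
    warning(sprintf("%d degenerate class(es) excluded from macro-AUC: %s",
                    length(excluded),
                    paste(if (is.null(colnames(scores))) excluded
                          else colnames(scores)[excluded], collapse = ", ")),
            call. = FALSE)
  }
  out <- mean(per, na.rm = TRUE)
  attr(out, "per_class") <- per
  attr(out, "excluded") <- excluded
  out
}
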