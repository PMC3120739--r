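# ---- diagnostic calibration against a gold standard --------------------
#
# Samples carry a non-negative score (standardized RCN) and a binary gold
# standard label. The classification rule throughout is: score >= cutoff
# => test-positive. Accuracy is the Youden index, sensitivity + specificity
# - 1, the quantity maximized to select the ROC cutoff.

#' ROC curve over all distinct score thresholds
#'
#' Builds one operating point per distinct classification of the data under
#' the rule score >= cutoff. Interior cutoffs are reported at the midpoint
#' between adjacent distinct scores (a reproducible, dataset-independent
#' representation); the two boundary points are (cutoff 0: everything
#' positive, sensitivity 1, specificity 0) and (cutoff Inf: everything
#' negative, sensitivity 0, specificity 1). Points are ordered by cutoff.
#'
#' @param scores numeric vector of non-negative scores.
#' @param labels vector of gold-standard labels; \code{positive} gives the
#'   level treated as positive.
#' @param positive value of \code{labels} denoting a gold-standard positive
#'   (default \code{"positive"}; logical \code{TRUE} also works).
#' @return object of class \code{roc_curve}: list with \code{points}
#'   (data.frame cutoff, sensitivity, specificity), \code{n_pos},
#'   \code{n_neg}.
#' @export
roc_points <- function(scores, labels, positive = "positive") {
  stopifnot(length(scores) == length(labels))
  if (any(is.na(scores)) || any(is.na(labels))) {
    stop("scores and labels must not contain NA", call. = FALSE)
  }
  is_pos <- labels == positive
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  pos <- scores[is_pos]; neg <- scores[!is_pos]
  s <- sort(unique(scores))
  cutoffs <- c(0, if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2, Inf)
  sens <- vapply(cutoffs, function(c) mean(pos >= c), numeric(1L))
  spec <- vapply(cutoffs, function(c) mean(neg < c), numeric(1L))
  # cutoff 0 always classifies everything positive (scores are >= 0)
  structure(list(points = data.frame(cutoff = cutoffs, sensitivity = sens,
                                     specificity = spec),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d positives, %d negatives, %d points; AUC = %.4f\n",
              x$n_pos, x$n_neg, nrow(x$points), auc_trapezoid(x)))
  invisible(x)
}

#' Area under the ROC curve by the trapezoidal rule
#'
#' Integrates sensitivity over 1 - specificity; over the full threshold set
#' this equals the Mann-Whitney probability estimate
#' P(score_pos > score_neg) + 0.5 P(tie).
#'
#' @param roc a \code{\link{roc_points}} curve.
#' @return AUC in [0, 1].
#' @export
auc_trapezoid <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  fpr <- 1 - p$specificity
  o <- order(fpr, p$sensitivity)
  x <- fpr[o]; y <- p$sensitivity[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Youden-optimal cutoff of an ROC curve
#'
#' Selects the cutoff maximizing sensitivity + specificity - 1. Ties are
#' broken toward higher specificity, then toward the higher cutoff.
#'
#' @param roc a \code{\link{roc_points}} curve.
#' @return list with \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy} (the Youden index at the cutoff).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  p <- roc$points
  acc <- p$sensitivity + p$specificity - 1
  o <- order(-acc, -p$specificity, -p$cutoff)
  best <- p[o[1L], ]
  list(cutoff = best$cutoff, sensitivity = best$sensitivity,
       specificity = best$specificity,
       accuracy = accuracy_youden(best$sensitivity, best$specificity))
}

#' Diagnostic accuracy as the Youden index
#'
#' Accuracy is defined as sensitivity + specificity - 1.
#'
#' @param sensitivity,specificity fractions in [0, 1].
#' @return accuracy in [-1, 1].
#' @examples
#' accuracy_youden(0.705, 0.845)  # 0.550
#' accuracy_youden(0.591, 0.983)  # 0.574
#' @export
accuracy_youden <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1)) {
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  }
  sensitivity + specificity - 1
}

#' Cross-tabulate binary predictions against the gold standard
#'
#' Rows follow the gold standard (the "exposure"), columns the prediction:
#' \code{a} = gold-positive predicted positive, \code{b} = gold-positive
#' predicted negative, \code{c} = gold-negative predicted positive,
#' \code{d} = gold-negative predicted negative. Sensitivity is a/(a+b) and
#' specificity d/(c+d).
#'
#' @param predictions,truths equal-length logical vectors (or vectors
#'   matching \code{positive}).
#' @param positive value denoting a positive (default \code{TRUE}).
#' @return object of class \code{contingency_2x2}: list with integer
#'   \code{a}, \code{b}, \code{c}, \code{d}.
#' @export
two_by_two <- function(predictions, truths, positive = TRUE) {
  if (length(predictions) == 0L) stop("empty input", call. = FALSE)
  if (length(predictions) != length(truths)) {
    stop("predictions and truths must have equal length", call. = FALSE)
  }
  p <- predictions == positive
  t <- truths == positive
  contingency_2x2(sum(t & p), sum(t & !p), sum(!t & p), sum(!t & !p))
}

#' Construct a 2x2 contingency table
#'
#' @param a exposed (or gold-positive) with the outcome.
#' @param b exposed without the outcome.
#' @param c unexposed with the outcome.
#' @param d unexposed without the outcome.
#' @return object of class \code{contingency_2x2}.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(v < 0) || any(v != round(v))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(as.integer(v)), names = names(v), class = "contingency_2x2")
}

.as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$c, tab$b, tab$d), nrow = 2,
         dimnames = list(exposure = c("exposed", "unexposed"),
                         outcome = c("yes", "no")))
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  print(.as_matrix_2x2(x))
  invisible(x)
}

#' Odds ratio with a Woolf (log-normal) confidence interval
#'
#' Point estimate (a d)/(b c). The interval uses the Woolf log-normal
#' method, exp(log OR +/- z sqrt(1/a + 1/b + 1/c + 1/d)); this is a package
#' choice of method. Tables with a zero cell receive the Haldane-Anscombe
#' 0.5 correction in every cell (flagged) before both the estimate and the
#' interval are computed.
#'
#' @param table a \code{\link{contingency_2x2}}.
#' @param level confidence level (default 0.95).
#' @return list with \code{or}, \code{ci_low}, \code{ci_high},
#'   \code{corrected} (TRUE when Haldane-Anscombe applied), \code{level}.
#' @examples
#' odds_ratio_ci(contingency_2x2(6, 2, 6, 16))$or  # 8
#' @export
odds_ratio_ci <- function(table, level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  cells <- c(table$a, table$b, table$c, table$d)
  corrected <- any(cells == 0L)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1L] * cells[4L]) / (cells[2L] * cells[3L])
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       corrected = corrected, level = level)
}

#' Two-sided association test for a 2x2 table
#'
#' Pearson chi-square without continuity correction when every expected
#' count exceeds 5, otherwise the two-sided Fisher exact test. The
#' method actually used is returned with the p-value.
#'
#' @param table a \code{\link{contingency_2x2}}.
#' @return list with \code{p_value} and \code{method} ("chi-square" or
#'   "fisher").
#' @export
association_p <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- .as_matrix_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (all(expected > 5)) {
    p <- stats::chisq.test(m, correct = FALSE)$p.value
    list(p_value = p, method = "chi-square")
  } else {
    p <- stats::fisher.test(m, alternative = "two.sided")$p.value
    list(p_value = p, method = "fisher")
  }
}

#' Summarize diagnostic performance at the Youden-optimal cutoff
#'
#' Convenience wrapper: builds the ROC curve, finds the Youden cutoff,
#' classifies at it, and reports the 2x2 table, odds ratio and association
#' p-value alongside AUC.
#'
#' @inheritParams roc_points
#' @return list with \code{roc}, \code{auc}, \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{accuracy},
#'   \code{table}, \code{odds_ratio}, \code{association}.
#' @export
diagnostic_summary <- function(scores, labels, positive = "positive") {
  roc <- roc_points(scores, labels, positive = positive)
  best <- youden_cutoff(roc)
  pred <- scores >= best$cutoff
  tab <- two_by_two(pred, labels == positive)
  list(roc = roc, auc = auc_trapezoid(roc), cutoff = best$cutoff,
       sensitivity = best$sensitivity, specificity = best$specificity,
       accuracy = best$accuracy, table = tab,
       odds_ratio = odds_ratio_ci(tab), association = association_p(tab))
}
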