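#' Map a 1-8 self-assessment score to an easy/difficult label
#'
#' Questionnaire responses on the 8-point difficulty scale are dichotomised
#' at the midpoint: 1-4 is "easy", 5-8 is "difficult".
#'
#' @param score integer vector with values in 1..8.
#' @return character vector of labels.
#' @export
label_from_questionnaire <- function(score) {
  if (any(!is.finite(score)) || any(score < 1 | score > 8) ||
      any(score != round(score)))
    stop("questionnaire scores must be integers in 1..8")
  ifelse(score <= 4, "easy", "difficult")
}

#' Confusion counts for easy/difficult predictions
#'
#' "difficult" is the positive class: `tp` counts sessions predicted and
#' referenced difficult, `tn` both easy, `fp` predicted difficult but
#' referenced easy, `fn` predicted easy but referenced difficult.
#'
#' @param predictions,references character vectors of `"easy"` /
#'   `"difficult"` labels, equal length, non-empty.
#' @return object of class `cl_confusion` with fields `tp`, `tn`, `fp`, `fn`.
#' @export
confusion <- function(predictions, references) {
  if (length(predictions) != length(references))
    stop("predictions and references must have equal length")
  if (length(predictions) == 0L) stop("empty label vectors")
  ok <- c("easy", "difficult")
  if (!all(predictions %in% ok) || !all(references %in% ok))
    stop("labels must be 'easy' or 'difficult'")
  structure(list(
    tp = sum(predictions == "difficult" & references == "difficult"),
    tn = sum(predictions == "easy"      & references == "easy"),
    fp = sum(predictions == "difficult" & references == "easy"),
    fn = sum(predictions == "easy"      & references == "difficult")),
    class = "cl_confusion")
}

#' @export
print.cl_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(predicted = c("difficult", "easy"),
                              reference = c("difficult", "easy")))
  print(m)
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1 ("difficult" positive).  Ratios with
#' a zero denominator are reported as `NA` (absent), not 0.
#'
#' @param c a `cl_confusion`.
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics <- function(c) {
  stopifnot(inherits(c, "cl_confusion"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) stop("empty confusion counts")
  precision <- if (c$tp + c$fp > 0L) c$tp / (c$tp + c$fp) else NA_real_
  recall <- if (c$tp + c$fn > 0L) c$tp / (c$tp + c$fn) else NA_real_
  list(accuracy = (c$tp + c$tn) / total,
       precision = precision,
       recall = recall,
       f1 = f1_score(precision, recall))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR/(P+R)`; `NA` when either input is absent or both
#' are zero.
#'
#' @param precision,recall fractions in (0, 1).
#' @return F1 score.
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall) || precision + recall == 0)
    return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Paired-median accuracy criterion
#'
#' The fraction of subjects whose higher-load session median strictly
#' exceeds their lower-load session median (ties count as failures).
#'
#' @param medians_low,medians_high paired numeric vectors (one entry per
#'   subject), equal length.
#' @return fraction in (0, 1).
#' @export
median_accuracy_criterion <- function(medians_low, medians_high) {
  if (length(medians_low) != length(medians_high))
    stop("paired median vectors must have equal length")
  if (length(medians_low) == 0L) stop("empty input")
  mean(medians_high > medians_low)
}

#' Rank statistics between two CL samples
#'
#' Two-sample Wilcoxon rank-sum test with the normal-approximation z and
#' the effect size `r = |z| / sqrt(N)`, plus (when the inputs are paired,
#' i.e. equal length) the Spearman rank correlation with its two-sided p.
#' Both the raw rank-sum statistic and the z approximation are reported,
#' since published "W" values are variously one or the other.
#'
#' @param a,b numeric vectors.
#' @return list with `w` (Mann-Whitney U), `z`, `p`, `r`, and `spearman`
#'   (list with `rho`, `p`, or `NULL` for unpaired input; `NA` rho with a
#'   warning for degenerate constant input).
#' @export
rank_tests <- function(a, b) {
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  n1 <- length(a); n2 <- length(b)
  mu <- n1 * n2 / 2
  pooled <- c(a, b)
  ties <- table(pooled)
  sigma <- sqrt(n1 * n2 / 12 *
                  ((n1 + n2 + 1) - sum(ties^3 - ties) /
                     ((n1 + n2) * (n1 + n2 - 1))))
  z <- (unname(wt$statistic) - mu) / sigma
  res <- list(w = unname(wt$statistic), z = z, p = wt$p.value,
              r = abs(z) / sqrt(n1 + n2), spearman = NULL)
  if (n1 == n2) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant input; Spearman correlation undefined")
      res$spearman <- list(rho = NA_real_, p = NA_real_)
    } else {
      st <- suppressWarnings(stats::cor.test(a, b, method = "spearman"))
      res$spearman <- list(rho = unname(st$estimate), p = st$p.value)
    }
  }
  res
}

new_boot_result <- function(point, ci, level, n, p = NA_real_) {
  structure(list(point = point, ci_low = unname(ci[1L]),
                 ci_high = unname(ci[2L]), level = level,
                 n_resamples = n, p_two_tailed = p,
                 h0_rejected = !(0 >= ci[1L] && 0 <= ci[2L])),
            class = "cl_boot")
}

#' @export
print.cl_boot <- function(x, ...) {
  cat(sprintf("bootstrap: point %.4f, %.1f%% CI [%.4f, %.4f] (%d resamples)\n",
              x$point, 100 * x$level, x$ci_low, x$ci_high, x$n_resamples))
  if (!is.na(x$p_two_tailed))
    cat(sprintf("  two-tailed p = %.4f\n", x$p_two_tailed))
  cat("  H0 (zero in CI):", if (x$h0_rejected) "rejected" else "retained", "\n")
  invisible(x)
}

#' One-sample bootstrap test on a vector of differences
#'
#' Resamples `diffs` with replacement `n` times, takes the mean of each
#' resample, and reports the percentile confidence interval at `level`.
#' The null hypothesis of no effect is rejected when zero falls outside
#' the interval.
#'
#' @param diffs non-empty numeric vector (e.g. per-subject CL differences).
#' @param level confidence level in (0, 1), e.g. 0.99.
#' @param n number of resamples (default 10000).
#' @param seed RNG seed.
#' @return a `cl_boot` result.
#' @export
bootstrap_one_sample <- function(diffs, level = 0.99, n = 10000L, seed = 1L) {
  if (length(diffs) == 0L) stop("empty input")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  set.seed(seed)
  m <- length(diffs)
  means <- colMeans(matrix(diffs[sample.int(m, m * n, replace = TRUE)],
                           nrow = m))
  ci <- stats::quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2))
  new_boot_result(mean(diffs), ci, level, n)
}

#' Bootstrap confidence interval for a Spearman correlation
#'
#' Paired resampling of `(x, y)` with the Spearman rho computed per
#' resample; percentile CI at `level`.  The two-tailed p is the fraction
#' of the resampled distribution at least as extreme (in absolute value)
#' as the observed correlation -- note this follows the published
#' definition literally, which is conservative for a bootstrap
#' distribution centred on the observed value.
#'
#' @param x,y paired numeric vectors, length >= 5.
#' @param level confidence level (default 0.95).
#' @param n resamples (default 10000).
#' @param seed RNG seed.
#' @return a `cl_boot` result.
#' @export
bootstrap_correlation <- function(x, y, level = 0.95, n = 10000L, seed = 1L) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 5L) stop("need at least 5 pairs")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  set.seed(seed)
  m <- length(x)
  point <- stats::cor(x, y, method = "spearman")
  rhos <- vapply(seq_len(n), function(i) {
    idx <- sample.int(m, m, replace = TRUE)
    suppressWarnings(stats::cor(x[idx], y[idx], method = "spearman"))
  }, 0.0)
  rhos <- rhos[is.finite(rhos)]
  ci <- stats::quantile(rhos, c((1 - level) / 2, 1 - (1 - level) / 2))
  p <- mean(abs(rhos) >= abs(point))
  new_boot_result(point, ci, level, n, p = p)
}

#' Bootstrap confidence interval for a KL divergence
#'
#' Resamples both samples independently with replacement and recomputes
#' [kl_divergence()] per resample; percentile CI at `level`.  The null of
#' non-divergence is retained when zero lies within the interval.
#'
#' @param sample_a,sample_b non-empty numeric vectors; divergence is
#'   `D(A || B)`.
#' @param level confidence level (default 0.99).
#' @param n resamples (default 10000).
#' @param bins histogram bins (default 16).
#' @param seed RNG seed.
#' @return a `cl_boot` result.
#' @export
bootstrap_kl <- function(sample_a, sample_b, level = 0.99, n = 10000L,
                         bins = 16L, seed = 1L) {
  if (length(sample_a) == 0L || length(sample_b) == 0L) stop("empty input")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  set.seed(seed)
  na <- length(sample_a); nb <- length(sample_b)
  kls <- vapply(seq_len(n), function(i)
    kl_divergence(sample_a[sample.int(na, na, replace = TRUE)],
                  sample_b[sample.int(nb, nb, replace = TRUE)], bins),
    0.0)
  ci <- stats::quantile(kls, c((1 - level) / 2, 1 - (1 - level) / 2))
  new_boot_result(kl_divergence(sample_a, sample_b, bins), ci, level, n)
}
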