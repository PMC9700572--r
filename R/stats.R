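#' Mann-Whitney U test
#'
#' Two-tailed rank-sum comparison. With `n_a + n_b <= 20` and no ties the
#' p-value is exact by complete enumeration of rank assignments; otherwise
#' the normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param group_a,group_b numeric vectors, non-empty.
#' @return List with `U` (number of (a, b) pairs with a > b, ties counted
#'   1/2), `p_value`, and `method`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  group_a <- as.numeric(group_a)
  group_b <- as.numeric(group_b)
  na <- length(group_a)
  nb <- length(group_b)
  if (na == 0 || nb == 0) {
    abort_afd("both groups must be non-empty", "invalid_parameter")
  }
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  has_ties <- any(duplicated(pooled))
  if (na + nb <= 20 && !has_ties) {
    combos <- utils::combn(na + nb, na)
    rs <- colSums(matrix(r[combos], nrow = na))
    U_all <- rs - na * (na + 1) / 2
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    N <- na + nb
    tie_tab <- table(pooled)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- if (sigma2 == 0) 0 else {
      num <- U - mu
      (num - sign(num) * 0.5) / sqrt(sigma2)  # continuity correction
    }
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approximation"
  }
  list(U = U, p_value = p, method = method)
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return List with `r`, `p_value` (two-tailed, t transform with n - 2 df),
#'   and `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort_afd("x and y must have equal length", "invalid_parameter")
  }
  if (length(x) < 3) abort_afd("need at least 3 pairs", "invalid_parameter")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_afd("correlation is undefined for a constant vector",
              "degenerate_input")
  }
  r <- stats::cor(x, y)
  n <- length(x)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(r = r, p_value = p, n = n)
}

#' ROC analysis with Hanley-McNeil CI and Youden cutoff
#'
#' Convention: a higher score predicts the positive class. The AUC is the
#' concordance statistic (ties counted 1/2, equivalent to the trapezoidal
#' rule over the empirical ROC); its 95% CI uses the Hanley-McNeil standard
#' error, clipped to `[0, 1]`. The Youden cutoff is the observed score
#' maximising sensitivity + specificity - 1 under the rule
#' "positive if score >= cutoff", ties broken toward the smallest cutoff.
#'
#' @param scores numeric predictor values.
#' @param labels binary outcome (logical, or coercible 0/1), both classes
#'   present.
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity`, `specificity`, and the ROC `curve`
#'   (data frame `fpr`, `tpr`).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(labels)) {
    abort_afd("scores and binary labels must align", "invalid_parameter")
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort_afd("both label classes must be present", "invalid_parameter")
  }
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  cuts <- sort(unique(scores))
  sens <- vapply(cuts, function(cc) mean(scores[labels] >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(scores[!labels] < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]   # smallest cutoff among ties
  curve <- data.frame(fpr = c(1, 1 - spec, 0), tpr = c(1, sens, 0))
  structure(list(auc = auc,
                 ci_low = max(0, auc - 1.959964 * se),
                 ci_high = min(1, auc + 1.959964 * se),
                 cutoff = cuts[best], sensitivity = sens[best],
                 specificity = spec[best], curve = curve),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f (95%% CI %.3f-%.3f); Youden cutoff %.4f: sens %.1f%%, spec %.1f%%\n",
    x$auc, x$ci_low, x$ci_high, x$cutoff, 100 * x$sensitivity,
    100 * x$specificity))
  invisible(x)
}

#' Agreement between automatic and manual measurements
#'
#' Cronbach's alpha for the two-rater case and the intraclass correlation
#' for absolute agreement, two-way random effects, single measures
#' (ICC(A,1) in McGraw-Wong terms) with the F-based 95% confidence interval.
#' Absolute agreement penalises a systematic offset between methods, which a
#' consistency measure would not.
#'
#' @param auto,manual paired numeric vectors, length >= 3.
#' @return An object of class `agreement_result`: `cronbach_alpha`, `icc`,
#'   `icc_ci_low`, `icc_ci_high`, `n`.
#' @export
agreement <- function(auto, manual) {
  if (length(auto) != length(manual)) {
    abort_afd("auto and manual must be paired (equal length)",
              "invalid_parameter")
  }
  n <- length(auto)
  if (n < 3) abort_afd("need at least 3 pairs", "invalid_parameter")
  X <- cbind(auto, manual)
  k <- 2
  var_total <- stats::var(auto + manual)
  alpha <- if (var_total == 0) 1 else {
    k / (k - 1) * (1 - (stats::var(auto) + stats::var(manual)) / var_total)
  }
  gm <- mean(X)
  rowm <- rowMeans(X)
  colm <- colMeans(X)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  mse <- sum((X - outer(rowm, rep(1, k)) -
                outer(rep(1, n), colm) + gm)^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  # McGraw & Wong (1996) F-based CI for ICC(A,1)
  if (mse == 0 && msc == 0) {
    lo <- hi <- icc
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(0.975, n - 1, v)
    f_u <- stats::qf(0.975, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  }
  structure(list(cronbach_alpha = alpha, icc = icc, icc_ci_low = lo,
                 icc_ci_high = hi, n = n),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> alpha %.3f; ICC(A,1) %.3f (95%% CI %.3f-%.3f), n = %d\n",
    x$cronbach_alpha, x$icc, x$icc_ci_low, x$icc_ci_high, x$n))
  invisible(x)
}
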