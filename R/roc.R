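# Paired diagnostic-evaluation statistics: empirical ROC AUC
# (Mann-Whitney), the DeLong test for paired AUCs, unnormalized partial AUC
# over a specificity range with a stratified paired bootstrap comparison,
# sensitivity at fixed specificity, Spearman correlation with a bootstrap
# comparison of two correlations, and Benjamini-Hochberg correction.
#
# Direction convention: rim areas are smaller in disease, so the default
# score direction is "lower_is_case". Internally scores are oriented so
# that higher values indicate the case class.

.orient <- function(scores, direction) {
  if (direction == "lower_is_case") -as.double(scores) else as.double(scores)
}

.split_cc <- function(scores, labels, positive = "case") {
  case <- .as_case(labels, positive)
  if (!any(case) || !any(!case))
    stop("need at least one case and one control", call. = FALSE)
  list(cases = scores[case], controls = scores[!case])
}

.as_case <- function(labels, positive = "case") {
  if (is.logical(labels)) return(labels)
  labels == positive
}

# Mann-Whitney AUC, ties counted 1/2; scores already oriented
.auc_cc <- function(cases, controls) {
  m <- length(cases)
  n <- length(controls)
  r <- rank(c(cases, controls))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Empirical ROC area under the curve
#'
#' Mann-Whitney estimator: the fraction of case/control pairs ordered
#' correctly, ties counted one half.
#'
#' @param scores numeric scores, one per eye.
#' @param labels logical (`TRUE` = case) or character vector; character
#'   labels equal to `positive` are cases.
#' @param direction `"lower_is_case"` (default: smaller rim area indicates
#'   disease) or `"higher_is_case"`.
#' @param positive label treated as the case class when `labels` is
#'   character.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels, direction = c("lower_is_case", "higher_is_case"),
                    positive = "case") {
  direction <- match.arg(direction)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  cc <- .split_cc(.orient(scores, direction), labels, positive)
  .auc_cc(cc$cases, cc$controls)
}

# DeLong structural components for one oriented score vector
.delong_components <- function(cases, controls) {
  m <- length(cases)
  n <- length(controls)
  all_r <- rank(c(cases, controls))
  case_r <- rank(cases)
  ctrl_r <- rank(controls)
  v10 <- (all_r[seq_len(m)] - case_r) / n                 # per-case
  v01 <- 1 - (all_r[m + seq_len(n)] - ctrl_r) / m         # per-control
  list(auc = (sum(all_r[seq_len(m)]) - m * (m + 1) / 2) / (m * n),
       v10 = v10, v01 = v01)
}

#' DeLong test for two paired AUCs
#'
#' Compares the AUCs of two markers measured on the same eyes using the
#' DeLong (1988) structural-components covariance of the paired AUC
#' difference, with a two-sided normal p-value. A zero-variance difference
#' (e.g. identical markers) returns `z = 0`, `p = 1`.
#'
#' @param scores1,scores2 parallel numeric score vectors over the same eyes.
#' @param labels case/control labels (see [roc_auc()]).
#' @inheritParams roc_auc
#' @return List with `auc1`, `auc2`, `z`, `p`.
#' @export
delong_paired_test <- function(scores1, scores2, labels,
                               direction = c("lower_is_case", "higher_is_case"),
                               positive = "case") {
  direction <- match.arg(direction)
  if (length(scores1) != length(scores2) || length(scores1) != length(labels))
    stop("scores1, scores2 and labels must have equal length", call. = FALSE)
  case <- .as_case(labels, positive)
  if (!any(case) || !any(!case))
    stop("need at least one case and one control", call. = FALSE)
  s1 <- .orient(scores1, direction)
  s2 <- .orient(scores2, direction)
  c1 <- .delong_components(s1[case], s1[!case])
  c2 <- .delong_components(s2[case], s2[!case])
  m <- sum(case)
  n <- sum(!case)
  s10 <- stats::var(cbind(c1$v10, c2$v10))
  s01 <- stats::var(cbind(c1$v01, c2$v01))
  v <- (s10[1L, 1L] + s10[2L, 2L] - 2 * s10[1L, 2L]) / m +
       (s01[1L, 1L] + s01[2L, 2L] - 2 * s01[1L, 2L]) / n
  d <- c1$auc - c2$auc
  if (v <= 0 || (abs(d) < .Machine$double.eps && v < 1e-300)) {
    z <- 0
    p <- 1
  } else {
    z <- d / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  list(auc1 = c1$auc, auc2 = c2$auc, z = z, p = p)
}

# empirical ROC polyline vertices, oriented scores; returns fpr/tpr
# (including (0,0) and (1,1)); ties yield diagonal segments so that full
# trapezoidal area equals the Mann-Whitney AUC
.roc_points <- function(cases, controls) {
  m <- length(cases)
  n <- length(controls)
  s <- c(cases, controls)
  lab <- c(rep(1L, m), rep(0L, n))
  o <- order(s, decreasing = TRUE)
  s <- s[o]
  lab <- lab[o]
  tp <- cumsum(lab)
  fp <- cumsum(1L - lab)
  last <- c(s[-1L] != s[-length(s)], TRUE)  # last occurrence of each value
  list(fpr = c(0, fp[last] / n), tpr = c(0, tp[last] / m))
}

# trapezoidal integral of the ROC polyline over fpr in [x0, x1], with
# linear interpolation at the range endpoints; scores oriented
.pauc_cc <- function(cases, controls, x0, x1) {
  rp <- .roc_points(cases, controls)
  x <- rp$fpr
  y <- rp$tpr
  k <- length(x)
  a <- x[-k]; b <- x[-1L]
  ya <- y[-k]; yb <- y[-1L]
  w <- b - a
  keep <- w > 0 & b > x0 & a < x1
  if (!any(keep)) return(0)
  a <- a[keep]; b <- b[keep]; ya <- ya[keep]; yb <- yb[keep]
  w <- b - a
  lo <- pmax(a, x0)
  hi <- pmin(b, x1)
  ylo <- ya + (yb - ya) * (lo - a) / w
  yhi <- ya + (yb - ya) * (hi - a) / w
  sum((hi - lo) * (ylo + yhi) / 2)
}

#' Partial AUC over a specificity range
#'
#' Area under the empirical ROC curve restricted to specificity in
#' `[spec_lo, spec_hi]`, unnormalized: the maximum attainable value is
#' `spec_hi - spec_lo` (0.1 for the default range), matching the
#' magnitudes conventionally reported for the 1.0-0.9 specificity band.
#' Trapezoidal integration with linear interpolation at the range
#' endpoints; over the full range `[0, 1]` it equals the AUC.
#'
#' @inheritParams roc_auc
#' @param spec_lo,spec_hi specificity bounds, `0 <= spec_lo < spec_hi <= 1`.
#' @return Partial AUC in `[0, spec_hi - spec_lo]`.
#' @export
partial_auc <- function(scores, labels, spec_lo = 0.9, spec_hi = 1.0,
                        direction = c("lower_is_case", "higher_is_case"),
                        positive = "case") {
  direction <- match.arg(direction)
  if (!(spec_lo >= 0 && spec_lo < spec_hi && spec_hi <= 1))
    stop("need 0 <= spec_lo < spec_hi <= 1", call. = FALSE)
  cc <- .split_cc(.orient(scores, direction), labels, positive)
  .pauc_cc(cc$cases, cc$controls, 1 - spec_hi, 1 - spec_lo)
}

#' Stratified paired bootstrap comparison of two partial AUCs
#'
#' Cases and controls are resampled separately with replacement, keeping
#' the pairing of the two markers within each eye. The two-sided p-value is
#' the normal tail probability of the observed pAUC difference standardized
#' by the bootstrap standard deviation of the difference. Identical markers
#' give p = 1.
#'
#' @inheritParams delong_paired_test
#' @param spec_lo,spec_hi specificity range of the partial AUC.
#' @param B number of bootstrap resamples (>= 100).
#' @param seed integer seed; results are reproducible given the seed.
#' @return List with `pauc1`, `pauc2`, `p`, `B`.
#' @export
bootstrap_pauc_test <- function(scores1, scores2, labels,
                                spec_lo = 0.9, spec_hi = 1.0, B = 2000L,
                                seed = 1L,
                                direction = c("lower_is_case", "higher_is_case"),
                                positive = "case") {
  direction <- match.arg(direction)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  case <- .as_case(labels, positive)
  if (!any(case) || !any(!case))
    stop("need at least one case and one control", call. = FALSE)
  s1 <- .orient(scores1, direction)
  s2 <- .orient(scores2, direction)
  x0 <- 1 - spec_hi
  x1 <- 1 - spec_lo
  ca1 <- s1[case]; co1 <- s1[!case]
  ca2 <- s2[case]; co2 <- s2[!case]
  m <- length(ca1); n <- length(co1)
  obs <- .pauc_cc(ca1, co1, x0, x1) - .pauc_cc(ca2, co2, x0, x1)
  dstar <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ic <- sample.int(m, m, replace = TRUE)
      io <- sample.int(n, n, replace = TRUE)
      .pauc_cc(ca1[ic], co1[io], x0, x1) - .pauc_cc(ca2[ic], co2[io], x0, x1)
    }, numeric(1))
  })
  sdd <- stats::sd(dstar)
  p <- if (!is.finite(sdd) || sdd == 0) {
    if (abs(obs) < .Machine$double.eps) 1 else 0
  } else {
    2 * pnorm(-abs(obs / sdd))
  }
  list(pauc1 = .pauc_cc(ca1, co1, x0, x1),
       pauc2 = .pauc_cc(ca2, co2, x0, x1),
       p = p, B = as.integer(B))
}

#' Sensitivity at fixed specificity
#'
#' Uses the conservative step-function convention: the operating threshold
#' is the smallest cutoff whose empirical specificity is at least `spec`
#' (so the specificity constraint is always met exactly or exceeded), and
#' the sensitivity at that cutoff is returned.
#'
#' @inheritParams roc_auc
#' @param spec target specificity (e.g. 0.90 or 0.95).
#' @return Sensitivity in `[0, 1]`.
#' @export
sensitivity_at_specificity <- function(scores, labels, spec = 0.95,
                                       direction = c("lower_is_case", "higher_is_case"),
                                       positive = "case") {
  direction <- match.arg(direction)
  if (spec < 0 || spec > 1) stop("spec must be in [0, 1]", call. = FALSE)
  cc <- .split_cc(.orient(scores, direction), labels, positive)
  thr <- c(sort(unique(c(cc$cases, cc$controls))), Inf)
  for (c0 in thr) {
    if (mean(cc$controls < c0) >= spec) return(mean(cc$cases >= c0))
  }
  0
}

#' Spearman rank correlation
#'
#' Midrank-tie Spearman correlation (delegates to [stats::cor()]).
#' Constant input vectors are an error because the correlation is
#' undefined.
#'
#' @param x,y paired numeric vectors, `n >= 3`.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' Bootstrap comparison of two correlations with a common variable
#'
#' Tests whether `rho(x, y1)` differs from `rho(x, y2)` by resampling the
#' paired triples with replacement; the two-sided p-value standardizes the
#' observed difference by the bootstrap standard deviation.
#'
#' @param x common variable (e.g. visual-field mean deviation).
#' @param y1,y2 the two competing markers, paired with `x`.
#' @param B bootstrap resamples (>= 100).
#' @param seed integer seed.
#' @return List with `rho1`, `rho2`, `p`, `B`.
#' @export
compare_correlations_bootstrap <- function(x, y1, y2, B = 2000L, seed = 1L) {
  n <- length(x)
  if (length(y1) != n || length(y2) != n)
    stop("x, y1 and y2 must have equal length", call. = FALSE)
  if (n < 10L)
    stop("need at least 10 triples for a meaningful bootstrap comparison; ",
         "collect more observations", call. = FALSE)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  obs <- spearman_rho(x, y1) - spearman_rho(x, y2)
  dstar <- .with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y1[i]) == 0 || stats::sd(y2[i]) == 0)
        return(NA_real_)
      stats::cor(x[i], y1[i], method = "spearman") -
        stats::cor(x[i], y2[i], method = "spearman")
    }, numeric(1))
  })
  dstar <- dstar[is.finite(dstar)]
  sdd <- stats::sd(dstar)
  p <- if (!is.finite(sdd) || sdd == 0) {
    if (abs(obs) < .Machine$double.eps) 1 else 0
  } else {
    2 * pnorm(-abs(obs / sdd))
  }
  list(rho1 = spearman_rho(x, y1), rho2 = spearman_rho(x, y2),
       p = p, B = as.integer(B))
}

#' Benjamini-Hochberg correction
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) together with the
#' raw-p significance threshold: the largest raw p-value `p(k)` satisfying
#' `p(k) <= (k/m) * alpha`, or 0 if none does.
#'
#' @param pvalues numeric vector of raw p-values in `[0, 1]`.
#' @param alpha nominal false-discovery rate (default 0.05).
#' @return List with `adjusted` (same order as input) and `threshold`.
#' @export
benjamini_hochberg <- function(pvalues, alpha = 0.05) {
  p <- as.double(pvalues)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must be in [0, 1]", call. = FALSE)
  m <- length(p)
  adj <- p.adjust(p, method = "BH")
  ps <- sort(p)
  ok <- ps <= seq_len(m) / m * alpha
  threshold <- if (any(ok)) ps[max(which(ok))] else 0
  list(adjusted = adj, threshold = threshold)
}
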