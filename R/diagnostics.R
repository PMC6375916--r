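# Diagnostic evaluation: group comparisons, correlation, empirical ROC
# curves, AUC, Youden-index cutoffs and likelihood ratios for separating
# cirrhotic from noncirrhotic livers.

default_orientations <- c(t1rho_croi = "higher_is_positive",
                          t1rho_wl = "higher_is_positive",
                          re = "lower_is_positive",
                          ffq = "higher_is_positive")

cohort_scores <- function(cohort, biomarker) {
  col <- biomarker_column(biomarker)
  if (!col %in% names(cohort))
    stop(sprintf("cohort lacks biomarker column '%s'", col))
  scores <- cohort[[col]]
  labels <- cohort$group == "cirrhosis"
  ok <- is.finite(scores)
  list(scores = scores[ok], labels = labels[ok])
}

#' Compare a biomarker between cirrhotic and noncirrhotic groups
#'
#' Group means and SDs (n-1 denominator) with a two-sided Student's t-test;
#' pooled variance by default, Welch by flag.
#'
#' @param cohort a `"cohort_table"`.
#' @param biomarker one of `"t1rho_croi"`, `"t1rho_wl"`, `"re"`, `"ffq"`.
#' @param var_equal pooled-variance t-test if `TRUE` (default); Welch
#'   otherwise.
#' @return List with per-group `mean`, `sd`, `n`, the mean difference
#'   (cirrhosis minus none), `statistic` and `p_value`.
#' @export
compare_groups <- function(cohort, biomarker, var_equal = TRUE) {
  s <- cohort_scores(cohort, biomarker)
  x <- s$scores[s$labels]; y <- s$scores[!s$labels]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 subjects")
  tt <- t.test(x, y, var.equal = var_equal)
  list(biomarker = biomarker,
       mean = c(cirrhosis = mean(x), none = mean(y)),
       sd = c(cirrhosis = sd(x), none = sd(y)),
       n = c(cirrhosis = length(x), none = length(y)),
       difference = mean(x) - mean(y),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Pearson correlation between two biomarkers
#'
#' Pooled over the whole cohort (both groups), with the p-value from the
#' t-distributed transform of r.
#'
#' @param cohort a `"cohort_table"`.
#' @param x,y biomarker labels.
#' @return List with `r`, `p_value` and `n`.
#' @export
pearson_r <- function(cohort, x, y) {
  sx <- cohort[[biomarker_column(x)]]
  sy <- cohort[[biomarker_column(y)]]
  ok <- is.finite(sx) & is.finite(sy)
  if (sum(ok) < 3) stop("need at least 3 paired finite values")
  if (sd(sx[ok]) == 0 || sd(sy[ok]) == 0)
    stop("zero variance in one of the variables")
  ct <- cor.test(sx[ok], sy[ok], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}

#' Empirical ROC curve for a biomarker
#'
#' A positive is the presence of cirrhosis. For markers that fall with
#' disease (RE), the ranking is done on the negated score — for strictly
#' positive scores this yields the same curve as the reciprocal transform —
#' while thresholds are reported on the original scale with the decision
#' rule "positive if score <= cutoff".
#'
#' @param cohort a `"cohort_table"`, or a numeric vector of scores (then
#'   supply `labels`).
#' @param biomarker biomarker label (ignored when `cohort` is numeric).
#' @param orientation `"higher_is_positive"` or `"lower_is_positive"`;
#'   defaults to the biomarker's conventional direction.
#' @param labels logical vector (`TRUE` = positive class) when `cohort` is a
#'   numeric score vector.
#' @return Object of class `"roc_curve"` with `cutoffs` (original scale,
#'   from most to least stringent), `tpr`, `fpr`, `orientation`, and the
#'   scores/labels it was built from.
#' @export
roc_curve <- function(cohort, biomarker = NULL,
                      orientation = NULL, labels = NULL) {
  if (is.numeric(cohort)) {
    scores <- cohort
    stopifnot(is.logical(labels), length(labels) == length(scores))
    ok <- is.finite(scores)
    scores <- scores[ok]; labels <- labels[ok]
    if (is.null(orientation)) orientation <- "higher_is_positive"
  } else {
    s <- cohort_scores(cohort, biomarker)
    scores <- s$scores; labels <- s$labels
    if (is.null(orientation))
      orientation <- default_orientations[[sub("_ms$", "", biomarker)]]
  }
  orientation <- match.arg(orientation,
                           c("higher_is_positive", "lower_is_positive"))
  if (!any(labels) || all(labels))
    stop("both classes must be present to build a ROC curve")
  sgn <- if (orientation == "lower_is_positive") -1 else 1
  s <- sgn * scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  pos <- s[labels]; neg <- s[!labels]
  tpr <- vapply(thr, function(ci) mean(pos >= ci), numeric(1))
  fpr <- vapply(thr, function(ci) mean(neg >= ci), numeric(1))
  structure(list(cutoffs = sgn * thr, tpr = tpr, fpr = fpr,
                 orientation = orientation, scores = scores,
                 labels = labels,
                 biomarker = if (is.character(biomarker)) biomarker else "score"),
            class = "roc_curve")
}

#' Area under an ROC curve
#'
#' Trapezoidal area over the empirical curve; on any dataset this equals the
#' Mann-Whitney pair-counting statistic with ties counted one half.
#'
#' @param curve a [roc_curve()].
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-length(curve$tpr)]) / 2)
}

#' Youden-index cutoff
#'
#' The threshold maximising J = sensitivity + specificity - 1; ties are
#' broken toward the most sensitive (least stringent) cutoff. The cutoff is
#' reported on the biomarker's original scale: the decision rule is
#' "positive if score >= cutoff" for rising markers and
#' "positive if score <= cutoff" for falling ones.
#'
#' @param curve a [roc_curve()].
#' @return List with `cutoff`, `sensitivity`, `specificity` and `youden_j`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  finite <- is.finite(curve$cutoffs)
  if (!any(finite)) stop("no finite thresholds on the curve")
  jmax <- max(j[finite])
  cand <- which(finite & j >= jmax - 1e-12)
  best <- cand[length(cand)]          # last = smallest internal threshold
  list(cutoff = curve$cutoffs[best], sensitivity = curve$tpr[best],
       specificity = 1 - curve$fpr[best], youden_j = j[best])
}

#' Positive and negative likelihood ratios
#'
#' `PLR = sens / (1 - spec)` and `NLR = (1 - sens) / spec`,
#' prevalence-independent summaries of test performance. Boundary cases
#' yield `Inf` (perfect specificity for PLR, zero specificity for NLR).
#'
#' @param sensitivity,specificity fractions in \[0, 1\].
#' @return List with `plr` and `nlr`.
#' @export
likelihood_ratios <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  plr <- if (specificity == 1) Inf else sensitivity / (1 - specificity)
  nlr <- if (specificity == 0) Inf else (1 - sensitivity) / specificity
  list(plr = plr, nlr = nlr)
}

#' Evaluate the diagnostic performance of all four biomarkers
#'
#' Builds the ROC curve of each biomarker (T1rho-cROI, T1rho-wl and FFQ rise
#' with cirrhosis; RE falls), finds the Youden cutoff, and derives
#' sensitivity, specificity and likelihood ratios at that cutoff.
#'
#' @param cohort a `"cohort_table"` carrying all four biomarker columns.
#' @param biomarkers biomarker labels to evaluate.
#' @return Object of class `"diagnostic_report"`: a data frame with one row
#'   per biomarker and columns `biomarker`, `orientation`, `auc`, `cutoff`,
#'   `sensitivity`, `specificity`, `plr`, `nlr`. The ROC curves are attached
#'   as attribute `"curves"`.
#' @export
evaluate_biomarkers <- function(cohort,
                                biomarkers = c("t1rho_croi", "t1rho_wl",
                                               "re", "ffq")) {
  for (b in biomarkers) {
    col <- biomarker_column(b)
    if (!col %in% names(cohort))
      stop(sprintf("cohort lacks biomarker column '%s'", col))
  }
  n1 <- sum(cohort$group == "cirrhosis"); n0 <- sum(cohort$group == "none")
  if (min(n1, n0) < 2)
    warning(sprintf("very small class (%d vs %d subjects): estimates unstable",
                    n1, n0))
  curves <- list()
  rows <- lapply(biomarkers, function(b) {
    cur <- roc_curve(cohort, b)
    curves[[b]] <<- cur
    yc <- youden_cutoff(cur)
    lr <- likelihood_ratios(yc$sensitivity, yc$specificity)
    data.frame(biomarker = b, orientation = cur$orientation,
               auc = roc_auc(cur), cutoff = yc$cutoff,
               sensitivity = yc$sensitivity, specificity = yc$specificity,
               plr = lr$plr, nlr = lr$nlr)
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  class(out) <- c("diagnostic_report", "data.frame")
  out
}

# Round half away from zero, the convention of printed clinical tables
# (base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.diagnostic_report <- function(x, digits = 2, ...) {
  cat("Diagnostic performance (cirrhosis vs none)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round_half_up, digits = digits)
  attr(df, "curves") <- NULL
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, add = FALSE, col = 1, ...) {
  if (!add) {
    plot(x$fpr, x$tpr, type = "l", col = col, xlim = c(0, 1), ylim = c(0, 1),
         xlab = "1 - specificity", ylab = "sensitivity",
         main = sprintf("ROC: %s (AUC = %.2f)", x$biomarker, roc_auc(x)), ...)
    graphics::abline(0, 1, lty = 3, col = "grey")
  } else {
    graphics::lines(x$fpr, x$tpr, col = col, ...)
  }
  invisible(x)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve for %s (%s): %d thresholds, AUC = %.3f\n",
              x$biomarker, x$orientation, length(x$cutoffs), roc_auc(x)))
  invisible(x)
}
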