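# Diagnostic statistics: t-tests, Pearson correlation, empirical ROC
# construction against brute-force sweeps, AUC pair-count equivalence,
# Youden search, likelihood-ratio identities, and the four-biomarker report.

make_cohort <- function(pos, neg, biomarker = "t1rho_croi_ms") {
  n1 <- length(pos); n0 <- length(neg)
  tab <- data.frame(subject_id = sprintf("S%03d", seq_len(n1 + n0)),
                    group = rep(c("cirrhosis", "none"), c(n1, n0)),
                    prior_intervention = 0L,
                    t1rho_croi_ms = 50, t1rho_wl_ms = 50, re = 0.6,
                    ffq_ms = 80)
  tab[[biomarker]] <- c(pos, neg)
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

test_that("group comparison: identical groups give p = 1, separated groups
           give vanishing p with the right sign", {
  same <- make_cohort(c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- compare_groups(same, "t1rho_croi")
  expect_equal(res$p_value, 1)
  expect_equal(res$difference, 0)
  sep <- make_cohort(c(10, 10.1, 9.9, 10), c(0, 0.1, -0.1, 0))
  res2 <- compare_groups(sep, "t1rho_croi")
  expect_lt(res2$p_value, 1e-6)
  expect_gt(res2$difference, 0)
  expect_error(compare_groups(make_cohort(1, c(1, 2)), "t1rho_croi"),
               "2 subjects")
  # Welch and pooled agree on balanced equal-variance data
  expect_equal(compare_groups(same, "t1rho_croi", var_equal = FALSE)$p_value, 1)
})

test_that("simulated reference cohorts reject equality of cROI means at
           alpha = 0.001 nearly always", {
  rej <- vapply(1:100, function(s) {
    co <- generate_cohort(cohort_spec(seed = s))
    compare_groups(co, "t1rho_croi")$p_value < 0.001
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("pearson correlation: exact endpoints and input validation", {
  co <- make_cohort(c(1, 2, 3), c(4, 5, 6))
  co$re <- co$t1rho_croi_ms
  expect_equal(pearson_r(co, "t1rho_croi", "re")$r, 1)
  co$re <- -co$t1rho_croi_ms
  expect_equal(pearson_r(co, "t1rho_croi", "re")$r, -1)
  co$re <- rep(1, 6)
  expect_error(pearson_r(co, "t1rho_croi", "re"), "variance")
})

test_that("ROC curve matches a brute-force threshold sweep in both
           orientations", {
  set.seed(10)
  for (rep in 1:20) {
    scores <- round(rnorm(30), 1)              # force ties
    labels <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (!any(labels) || all(labels)) next
    for (orient in c("higher_is_positive", "lower_is_positive")) {
      cur <- roc_curve(scores, labels = labels, orientation = orient)
      s <- if (orient == "lower_is_positive") -scores else scores
      for (k in seq_along(cur$cutoffs)) {
        ci <- if (orient == "lower_is_positive") -cur$cutoffs[k] else cur$cutoffs[k]
        expect_equal(cur$tpr[k], mean(s[labels] >= ci))
        expect_equal(cur$fpr[k], mean(s[!labels] >= ci))
      }
      expect_equal(cur$tpr[1], 0); expect_equal(cur$fpr[1], 0)
      expect_equal(cur$tpr[length(cur$tpr)], 1)
      expect_equal(cur$fpr[length(cur$fpr)], 1)
      expect_true(!is.unsorted(cur$tpr) && !is.unsorted(cur$fpr))
    }
  }
  expect_error(roc_curve(c(1, 2), labels = c(TRUE, TRUE)), "both classes")
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting on 100 random
           small cohorts (ties included)", {
  set.seed(11)
  for (i in 1:100) {
    n1 <- sample(2:12, 1); n0 <- sample(2:12, 1)
    pos <- round(rnorm(n1, 0.3), sample(0:1, 1))
    neg <- round(rnorm(n0), sample(0:1, 1))
    cur <- roc_curve(c(pos, neg), labels = rep(c(TRUE, FALSE), c(n1, n0)))
    expect_equal(roc_auc(cur), oracle_mw_auc(pos, neg), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and flips under
           orientation reversal", {
  set.seed(12)
  scores <- abs(rnorm(40)) + 0.1
  labels <- rep(c(TRUE, FALSE), 20)
  a <- roc_auc(roc_curve(scores, labels = labels))
  expect_equal(roc_auc(roc_curve(exp(scores), labels = labels)), a)
  expect_equal(roc_auc(roc_curve(scores^3, labels = labels)), a)
  # orientation flip maps a -> 1 - a
  flip <- roc_auc(roc_curve(scores, labels = labels,
                            orientation = "lower_is_positive"))
  expect_equal(flip, 1 - a, tolerance = 1e-12)
  # for positive scores, the reciprocal transform with the opposite
  # orientation is the same test as score negation
  recip <- roc_auc(roc_curve(1 / scores, labels = labels))
  expect_equal(recip, flip, tolerance = 1e-12)
})

test_that("Youden cutoff equals exhaustive search, ties broken toward the
           most sensitive threshold", {
  # perfect separation: cutoff at the smallest positive-class value, J = 1
  cur <- roc_curve(c(2, 3, 0, 1), labels = c(TRUE, TRUE, FALSE, FALSE))
  yc <- youden_cutoff(cur)
  expect_equal(yc$cutoff, 2)
  expect_equal(yc$youden_j, 1)
  expect_equal(yc$sensitivity, 1)
  expect_equal(yc$specificity, 1)
  # degenerate: all scores equal, J = 0
  cur0 <- roc_curve(rep(5, 6), labels = rep(c(TRUE, FALSE), 3))
  expect_equal(youden_cutoff(cur0)$youden_j, 0)
  # random small cohorts vs oracle
  set.seed(13)
  for (i in 1:50) {
    pos <- round(rnorm(sample(3:10, 1), 0.8), 1)
    neg <- round(rnorm(sample(3:10, 1)), 1)
    yc <- youden_cutoff(roc_curve(c(pos, neg),
                                  labels = rep(c(TRUE, FALSE),
                                               c(length(pos), length(neg)))))
    or <- oracle_youden(pos, neg)
    expect_equal(yc$youden_j, or$j, tolerance = 1e-12)
    expect_equal(yc$cutoff, or$cutoff)
  }
})

test_that("ROC and Youden agree with pROC on a reference cohort", {
  skip_if_not_installed("pROC")
  co <- generate_cohort(cohort_spec(seed = 21))
  cur <- roc_curve(co, "t1rho_croi")
  pr <- pROC::roc(co$group == "cirrhosis", co$t1rho_croi_ms,
                  direction = "<", quiet = TRUE)
  expect_equal(roc_auc(cur), as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  # RE, ranked low-to-high for disease
  cur_re <- roc_curve(co, "re")
  pr_re <- pROC::roc(co$group == "cirrhosis", co$re, direction = ">",
                     quiet = TRUE)
  expect_equal(roc_auc(cur_re), as.numeric(pROC::auc(pr_re)),
               tolerance = 1e-10)
  yc <- youden_cutoff(cur)
  best <- pROC::coords(pr, "best", best.method = "youden",
                       transpose = FALSE)
  expect_equal(yc$sensitivity + yc$specificity,
               best$sensitivity + best$specificity, tolerance = 1e-10)
})

test_that("likelihood ratios are the algebraic identities, with flagged
           infinities at the boundaries", {
  lr <- likelihood_ratios(0.702, 0.765)
  expect_equal(lr$plr, 0.702 / 0.235, tolerance = 1e-12)
  lr2 <- likelihood_ratios(0.830, 0.602)
  expect_equal(lr2$nlr, 0.170 / 0.602, tolerance = 1e-12)
  perfect <- likelihood_ratios(1, 1)
  expect_identical(perfect$plr, Inf)
  expect_equal(perfect$nlr, 0)
  expect_identical(likelihood_ratios(0.5, 0)$nlr, Inf)
  expect_error(likelihood_ratios(1.2, 0.5))
})

test_that("evaluate_biomarkers produces one oriented report per biomarker", {
  # perfectly separated synthetic cohort: all AUC = 1
  n1 <- 5; n0 <- 7
  tab <- data.frame(subject_id = sprintf("S%02d", 1:12),
                    group = rep(c("cirrhosis", "none"), c(n1, n0)),
                    prior_intervention = 0L,
                    t1rho_croi_ms = c(rep(60, n1), rep(40, n0)),
                    t1rho_wl_ms = c(rep(58, n1), rep(42, n0)),
                    re = c(rep(0.4, n1), rep(0.9, n0)),
                    ffq_ms = c(rep(150, n1), rep(44, n0)))
  class(tab) <- c("cohort_table", "data.frame")
  rep1 <- evaluate_biomarkers(tab)
  expect_equal(nrow(rep1), 4)
  expect_true(all(rep1$auc == 1))
  expect_equal(rep1$orientation,
               c("higher_is_positive", "higher_is_positive",
                 "lower_is_positive", "higher_is_positive"))
  # RE cutoff is reported on the original scale
  expect_true(rep1$cutoff[rep1$biomarker == "re"] > 0)
  # single subject per class: still works, with a warning
  expect_warning(evaluate_biomarkers(tab[c(1, 6), ]), "small")
  bad <- tab; bad$ffq_ms <- NULL
  expect_error(evaluate_biomarkers(bad), "ffq")
  expect_output(print(rep1), "Diagnostic performance")
})

test_that("reference-parameter cohorts give AUCs near the binormal closed
           form for every biomarker", {
  gp <- ref_params(include_ffq = TRUE)
  pick <- function(b) c(gp$cirrhosis[[b]][["mean"]], gp$cirrhosis[[b]][["sd"]],
                        gp$none[[b]][["mean"]], gp$none[[b]][["sd"]])
  aucs <- matrix(0, 50, 4)
  for (s in 1:50) {
    co <- generate_cohort(cohort_spec(group_params = gp, seed = 300 + s))
    repo <- evaluate_biomarkers(co)
    aucs[s, ] <- repo$auc
  }
  want <- c(oracle_binormal_auc(pick("t1rho_croi")[1], pick("t1rho_croi")[2],
                                pick("t1rho_croi")[3], pick("t1rho_croi")[4]),
            oracle_binormal_auc(pick("t1rho_wl")[1], pick("t1rho_wl")[2],
                                pick("t1rho_wl")[3], pick("t1rho_wl")[4]),
            1 - oracle_binormal_auc(pick("re")[1], pick("re")[2],
                                    pick("re")[3], pick("re")[4]),
            oracle_binormal_auc(pick("ffq")[1], pick("ffq")[2],
                                pick("ffq")[3], pick("ffq")[4]))
  expect_equal(colMeans(aucs), want, tolerance = 0.02)
})
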