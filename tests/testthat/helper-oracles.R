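# Independent oracles: brute-force / closed-form implementations used only
# to check the package's fast paths. They deliberately avoid the package's
# own code paths.

# Closed-form AUC for two Gaussian score distributions (binormal model).
oracle_binormal_auc <- function(mean_pos, sd_pos, mean_neg, sd_neg) {
  pnorm((mean_pos - mean_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

# Mann-Whitney pair-counting AUC, ties counted one half.
oracle_mw_auc <- function(pos, neg) {
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Exhaustive Youden search: try every observed score as "positive if >= c".
oracle_youden <- function(pos, neg) {
  cand <- sort(unique(c(pos, neg)))
  j <- vapply(cand, function(ci) mean(pos >= ci) - mean(neg >= ci), numeric(1))
  jmax <- max(c(j, 0))
  best <- cand[j >= jmax - 1e-12]
  list(cutoff = if (length(best)) min(best) else Inf, j = jmax)
}

# Pooled two-group mixture correlation between two biomarkers that are
# independent within each group, from group parameters alone.
oracle_mixture_r <- function(p1, mu1_x, sd1_x, mu0_x, sd0_x,
                             mu1_y, sd1_y, mu0_y, sd0_y) {
  p0 <- 1 - p1
  dx <- mu1_x - mu0_x; dy <- mu1_y - mu0_y
  cov_xy <- p1 * p0 * dx * dy
  var_x <- p1 * sd1_x^2 + p0 * sd0_x^2 + p1 * p0 * dx^2
  var_y <- p1 * sd1_y^2 + p0 * sd0_y^2 + p1 * p0 * dy^2
  cov_xy / sqrt(var_x * var_y)
}

# Nonlinear signal-domain decay fit by grid search over T1rho, profiling out
# the amplitude analytically for each candidate.
oracle_grid_fit <- function(signals, tsl, grid = seq(10, 150, by = 0.02)) {
  ss <- vapply(grid, function(tr) {
    e <- exp(-tsl / tr)
    a <- sum(signals * e) / sum(e^2)
    sum((signals - a * e)^2)
  }, numeric(1))
  grid[which.min(ss)]
}

# Brute-force disc erosion by a double loop over pixels and offsets.
oracle_erode <- function(mask, radius_px) {
  nx <- nrow(mask); ny <- ncol(mask)
  out <- matrix(FALSE, nx, ny)
  r <- ceiling(radius_px)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    if (!mask[i, j]) next
    keep <- TRUE
    for (dx in -r:r) for (dy in -r:r) {
      if (dx^2 + dy^2 > radius_px^2) next
      ii <- i + dx; jj <- j + dy
      if (ii < 1 || ii > nx || jj < 1 || jj > ny || !mask[ii, jj]) {
        keep <- FALSE
        break
      }
    }
    out[i, j] <- keep
  }
  out
}

# Published group summary statistics used throughout the tests.
ref_params <- function(include_ffq = FALSE) reference_group_params(include_ffq)

protocol_tsl <- c(0, 10, 20, 30, 40, 50)
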