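# Spin-lock relaxometry: log-linear least-squares reconstruction of per-pixel
# T1rho from a series of T1rho-weighted images, ln(S(T_SL)/S0) = -T_SL/T1rho + C.

validate_tsl <- function(tsl) {
  if (length(tsl) == 0) stop("spin_lock_times must be non-empty")
  if (any(tsl < 0)) stop("spin_lock_times must be non-negative")
  if (any(duplicated(tsl))) stop("duplicate spin-lock times are not allowed")
  if (is.unsorted(tsl, strictly = TRUE))
    stop("spin_lock_times must be strictly increasing")
  invisible(tsl)
}

#' Construct a spin-lock image series
#'
#' @param images 3D numeric array `[x, y, k]` with one 2D image per
#'   spin-lock time, or a list of equally shaped matrices.
#' @param spin_lock_times numeric vector of T_SL in ms, one per image;
#'   strictly increasing, >= 0.
#' @param slice_id slice label (e.g. 3 cm cranial / caudal of the hilus).
#' @param truth optional list of ground-truth maps (from the phantom
#'   generator); carried along for validation, never used by the fit.
#' @return Object of class `"spin_lock_series"`.
#' @export
spin_lock_series <- function(images, spin_lock_times, slice_id = "slice1",
                             truth = NULL) {
  if (is.list(images) && !is.array(images))
    images <- simplify2array(images)
  stopifnot(is.array(images), length(dim(images)) == 3L)
  validate_tsl(spin_lock_times)
  if (dim(images)[3] != length(spin_lock_times))
    stop("number of images must equal the number of spin-lock times")
  structure(list(images = images,
                 spin_lock_times = as.numeric(spin_lock_times),
                 slice_id = slice_id, truth = truth),
            class = "spin_lock_series")
}

#' @export
print.spin_lock_series <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("Spin-lock series '%s': %d x %d px, T_SL = {%s} ms\n",
              x$slice_id, d[1], d[2],
              paste(x$spin_lock_times, collapse = ", ")))
  invisible(x)
}

#' Fit a single pixel's mono-exponential spin-lock decay
#'
#' Ordinary least squares of `ln(S/S0)` against T_SL, where `S0` is the
#' signal at the smallest usable spin-lock time; `T1rho = -1/slope`.
#' Nonpositive signals are dropped sample-wise (their log is undefined); the
#' pixel is invalid when fewer than `min_samples` usable samples remain or
#' when the fitted slope is non-negative (no decay).
#'
#' @param signals numeric vector of measured signal intensities.
#' @param spin_lock_times matching vector of T_SL in ms.
#' @param min_samples minimum usable samples for a valid fit (default 5,
#'   the protocol's "at least five images" rule).
#' @return List with `t1rho` (ms, `NA` if invalid), `intercept_c`, `s0`
#'   (fitted signal at the reference time), `r2` and `valid`.
#' @export
fit_pixel <- function(signals, spin_lock_times, min_samples = 5L) {
  if (length(signals) != length(spin_lock_times))
    stop("signals and spin_lock_times differ in length")
  validate_tsl(spin_lock_times)
  use <- is.finite(signals) & signals > 0
  invalid <- list(t1rho = NA_real_, intercept_c = NA_real_, s0 = NA_real_,
                  r2 = NA_real_, valid = FALSE)
  if (sum(use) < min_samples) return(invalid)
  t <- spin_lock_times[use]; s <- signals[use]
  s0_ref <- s[1L]                       # signal at smallest usable T_SL
  y <- log(s / s0_ref)
  n <- length(t)
  tbar <- mean(t); ybar <- mean(y)
  sxx <- sum((t - tbar)^2)
  sxy <- sum((t - tbar) * (y - ybar))
  slope <- sxy / sxx
  intercept <- ybar - slope * tbar
  sst <- sum((y - ybar)^2)
  r2 <- if (sst > 0) (slope^2 * sxx) / sst else NA_real_
  if (!is.finite(slope) || slope >= 0) {
    invalid$r2 <- r2
    return(invalid)
  }
  list(t1rho = -1 / slope, intercept_c = intercept,
       s0 = s0_ref * exp(intercept), r2 = r2, valid = TRUE)
}

#' Fit a T1rho map from a spin-lock series
#'
#' Applies the log-linear pixel fit ([fit_pixel()]) to every pixel inside
#' `mask`, vectorised over the image grid. Returns a classed map object with
#' `print`, `summary`, `coef`, `predict`, `residuals` and `plot` methods.
#'
#' @param series a [spin_lock_series()].
#' @param mask optional logical matrix restricting the fit (e.g. a liver
#'   mask); pixels outside are invalid.
#' @param tsl_subset optional subset of spin-lock times to use (the
#'   acquisition protocol is ambiguous about whether all six images enter
#'   the regression; the default uses all of them).
#' @param min_samples minimum usable samples per pixel (default 5).
#' @return Object of class `"t1rho_map"` with fields `t1rho`, `s0`,
#'   `intercept_c`, `r2` (matrices, `NA` where invalid), `valid_mask`,
#'   `n_used`, and the series it was fitted from.
#' @export
t1rho_fit <- function(series, mask = NULL, tsl_subset = NULL, min_samples = 5L) {
  stopifnot(inherits(series, "spin_lock_series"))
  d <- dim(series$images)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d[1:2])) stop("mask shape does not match images")
  } else {
    mask <- matrix(TRUE, d[1], d[2])
  }
  if (!any(mask)) warning("empty mask: no pixels fitted")
  tsl <- series$spin_lock_times
  keep <- if (is.null(tsl_subset)) seq_along(tsl) else match(tsl_subset, tsl)
  if (anyNA(keep)) stop("tsl_subset contains times absent from the series")
  tsl <- tsl[keep]
  validate_tsl(tsl)

  npix <- d[1] * d[2]
  S <- matrix(series$images[, , keep], npix, length(tsl))
  W <- is.finite(S) & S > 0 & as.vector(mask)
  Y <- suppressWarnings(log(S))
  Y[!W] <- 0
  Wn <- W * 1

  n <- rowSums(Wn)
  st <- drop(Wn %*% tsl)
  st2 <- drop(Wn %*% tsl^2)
  sy <- rowSums(Wn * Y)
  sty <- drop((Wn * Y) %*% tsl)
  sy2 <- rowSums(Wn * Y^2)
  denom <- n * st2 - st^2
  slope <- ifelse(denom > 0, (n * sty - st * sy) / denom, NA_real_)
  sst <- sy2 - sy^2 / pmax(n, 1)
  sxx <- st2 - st^2 / pmax(n, 1)
  r2 <- ifelse(sst > 0, slope^2 * sxx / sst, NA_real_)

  # reference S0: signal at the smallest usable T_SL per pixel
  first_idx <- rep(NA_integer_, npix)
  for (k in rev(seq_along(tsl))) first_idx[W[, k]] <- k
  s0_ref <- S[cbind(seq_len(npix), ifelse(is.na(first_idx), 1L, first_idx))]
  s0_ref[is.na(first_idx)] <- NA_real_
  # intercept of ln(S/S0_ref): shift the ln(S) intercept by ln(S0_ref)
  intercept <- (sy - slope * st) / pmax(n, 1) - log(s0_ref)

  valid <- n >= min_samples & is.finite(slope) & slope < 0
  t1rho <- ifelse(valid, -1 / slope, NA_real_)
  shape_mat <- function(v) matrix(v, d[1], d[2])
  out <- list(t1rho = shape_mat(t1rho),
              s0 = shape_mat(ifelse(valid, s0_ref * exp(intercept), NA_real_)),
              intercept_c = shape_mat(ifelse(valid, intercept, NA_real_)),
              r2 = shape_mat(ifelse(valid, r2, NA_real_)),
              valid_mask = shape_mat(valid),
              n_used = shape_mat(n),
              spin_lock_times = tsl, min_samples = min_samples,
              mask = mask, series = series, call = match.call())
  class(out) <- "t1rho_map"
  out
}

#' @export
print.t1rho_map <- function(x, ...) {
  nv <- sum(x$valid_mask)
  cat(sprintf("T1rho map %d x %d px: %d valid pixels (%.1f%% of mask)\n",
              nrow(x$t1rho), ncol(x$t1rho), nv,
              100 * nv / max(1, sum(x$mask))))
  if (nv > 0)
    cat(sprintf("  T1rho: mean %.2f ms, sd %.2f ms, range [%.2f, %.2f]\n",
                mean(x$t1rho[x$valid_mask]), sd(x$t1rho[x$valid_mask]),
                min(x$t1rho[x$valid_mask]), max(x$t1rho[x$valid_mask])))
  cat(sprintf("  fitted on T_SL = {%s} ms\n",
              paste(x$spin_lock_times, collapse = ", ")))
  invisible(x)
}

#' @export
summary.t1rho_map <- function(object, ...) {
  v <- object$valid_mask
  s <- list(n_mask = sum(object$mask), n_valid = sum(v),
            pct_invalid = 100 * (1 - sum(v) / max(1, sum(object$mask))),
            t1rho = if (any(v)) summary(object$t1rho[v]) else NULL,
            r2 = if (any(v)) summary(object$r2[v]) else NULL)
  class(s) <- "summary.t1rho_map"
  s
}

#' @export
print.summary.t1rho_map <- function(x, ...) {
  cat(sprintf("Pixels in mask: %d; valid fits: %d (%.1f%% invalid)\n",
              x$n_mask, x$n_valid, x$pct_invalid))
  if (!is.null(x$t1rho)) { cat("T1rho (ms):\n"); print(x$t1rho) }
  if (!is.null(x$r2)) { cat("fit R^2:\n"); print(x$r2) }
  invisible(x)
}

#' @export
coef.t1rho_map <- function(object, ...) {
  list(t1rho = object$t1rho, intercept_c = object$intercept_c, s0 = object$s0)
}

#' Predicted signal intensities from a fitted T1rho map
#'
#' @param object a `"t1rho_map"`.
#' @param spin_lock_times times (ms) at which to evaluate the fitted decay;
#'   defaults to the times the map was fitted on.
#' @param ... unused.
#' @return 3D array of fitted signals, `NA` at invalid pixels.
#' @export
predict.t1rho_map <- function(object, spin_lock_times = object$spin_lock_times,
                              ...) {
  d <- dim(object$t1rho)
  out <- array(NA_real_, c(d, length(spin_lock_times)))
  for (k in seq_along(spin_lock_times))
    out[, , k] <- object$s0 * exp(-spin_lock_times[k] / object$t1rho)
  out
}

#' @export
residuals.t1rho_map <- function(object, ...) {
  keep <- match(object$spin_lock_times, object$series$spin_lock_times)
  object$series$images[, , keep, drop = FALSE] - predict(object)
}

#' @export
plot.t1rho_map <- function(x, main = "T1rho map (ms)", ...) {
  img <- x$t1rho
  graphics::image(seq_len(nrow(img)), seq_len(ncol(img)), img,
                  col = grDevices::gray.colors(256), asp = 1,
                  xlab = "x (px)", ylab = "y (px)", main = main, ...)
  invisible(x)
}
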