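# ROI protocols and biomarker arithmetic: circular right-lobe ROIs vs a
# whole-liver ROI per slice, relative enhancement, and the fibrosis function
# quotient FFQ = T1rho-cROI / RE.

#' Construct a labelled ROI set
#'
#' The two protocols mirror clinical practice: `"circular_rll"` holds up to
#' three circular ROIs (2-3 cm diameter) per slice on the right liver lobe,
#' up to two slices (six ROIs total); `"whole_liver"` holds exactly one ROI
#' per slice. Vessels, tumor/ablation areas and an edge margin are supplied
#' as an exclusion mask, which is subtracted from every ROI at construction
#' (as a reader avoids those structures when drawing).
#'
#' @param rois list of `list(label, slice_id, mask)` entries; `mask` is a
#'   logical matrix.
#' @param kind `"circular_rll"` or `"whole_liver"`.
#' @param exclusion_mask optional logical matrix (or named list of matrices
#'   per slice_id) of pixels to exclude.
#' @return Object of class `"roi_set"`.
#' @export
roi_set <- function(rois, kind = c("circular_rll", "whole_liver"),
                    exclusion_mask = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.list(rois), length(rois) >= 1L)
  slice_ids <- vapply(rois, function(r) as.character(r$slice_id), "")
  if (kind == "circular_rll") {
    if (any(table(slice_ids) > 3L))
      stop("circular_rll carries at most 3 ROIs per slice")
    if (length(unique(slice_ids)) > 2L)
      stop("circular_rll carries at most 2 slices")
  } else {
    if (any(table(slice_ids) > 1L))
      stop("whole_liver carries exactly one ROI per slice")
  }
  rois <- lapply(rois, function(r) {
    stopifnot(is.matrix(r$mask), is.logical(r$mask))
    excl <- slice_exclusion(exclusion_mask, r$slice_id)
    if (!is.null(excl)) r$mask <- r$mask & !excl
    if (!any(r$mask))
      stop(sprintf("ROI '%s' is empty after exclusion", r$label))
    r
  })
  structure(list(rois = rois, kind = kind, exclusion_mask = exclusion_mask),
            class = "roi_set")
}

slice_exclusion <- function(exclusion_mask, slice_id) {
  if (is.null(exclusion_mask)) return(NULL)
  if (is.matrix(exclusion_mask)) return(exclusion_mask)
  exclusion_mask[[as.character(slice_id)]]
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set (%s): %d ROI(s)\n", x$kind, length(x$rois)))
  for (r in x$rois)
    cat(sprintf("  %s [slice %s]: %d px\n", r$label, r$slice_id, sum(r$mask)))
  invisible(x)
}

# Resolve a per-slice value matrix (and optional validity mask) from either a
# matrix, a t1rho_map, or a named list of those keyed by slice_id.
slice_values <- function(map, slice_id) {
  if (is.list(map) && !inherits(map, "t1rho_map"))
    map <- map[[as.character(slice_id)]]
  if (is.null(map)) stop(sprintf("no map for slice '%s'", slice_id))
  if (inherits(map, "t1rho_map"))
    list(values = map$t1rho, valid = map$valid_mask)
  else
    list(values = map, valid = NULL)
}

#' Mean value over an ROI
#'
#' Arithmetic mean of the pixel values inside the ROI mask, optionally
#' restricted to a validity mask (invalid relaxometry fits are skipped).
#'
#' @param values numeric matrix (e.g. a T1rho map or signal image).
#' @param roi logical matrix selecting the ROI pixels.
#' @param valid_mask optional logical matrix of usable pixels.
#' @param label ROI label used in error messages.
#' @return Mean value, with attribute `"n_pixels"` giving the count of
#'   contributing pixels.
#' @export
roi_mean <- function(values, roi, valid_mask = NULL, label = "roi") {
  stopifnot(identical(dim(values), dim(roi)))
  eff <- roi
  if (!is.null(valid_mask)) eff <- eff & valid_mask
  n <- sum(eff)
  if (n == 0) stop(sprintf("ROI '%s' has no usable pixels", label))
  structure(mean(values[eff]), n_pixels = n)
}

# Per-ROI means for an roi_set over a (possibly multi-slice) map.
roi_set_means <- function(map, rois) {
  vapply(rois$rois, function(r) {
    sv <- slice_values(map, r$slice_id)
    as.numeric(roi_mean(sv$values, r$mask, sv$valid, label = r$label))
  }, numeric(1))
}

#' Aggregate circular-ROI T1rho (T1rho-cROI)
#'
#' The default follows the protocol of treating each circular ROI as one
#' observation: the unweighted mean of per-ROI means over all available ROIs
#' and slices (six when both slices are usable, fewer otherwise). A
#' pooled-pixel alternative is available; the two agree exactly only when
#' all ROIs contain the same number of pixels.
#'
#' @param map a `"t1rho_map"`, a matrix, or a named list of either keyed by
#'   slice_id.
#' @param rois a [roi_set()] of kind `"circular_rll"`.
#' @param method `"mean_of_means"` (default) or `"pooled"`.
#' @return T1rho-cROI in ms.
#' @export
aggregate_croi <- function(map, rois, method = c("mean_of_means", "pooled")) {
  method <- match.arg(method)
  stopifnot(inherits(rois, "roi_set"))
  if (rois$kind != "circular_rll") stop("rois must be of kind circular_rll")
  if (method == "mean_of_means") return(mean(roi_set_means(map, rois)))
  tot <- 0; n <- 0
  for (r in rois$rois) {
    sv <- slice_values(map, r$slice_id)
    eff <- r$mask
    if (!is.null(sv$valid)) eff <- eff & sv$valid
    tot <- tot + sum(sv$values[eff]); n <- n + sum(eff)
  }
  if (n == 0) stop("no usable pixels in any ROI")
  tot / n
}

#' Aggregate whole-liver T1rho (T1rho-wl)
#'
#' Mean of the per-slice whole-liver ROI means (equal slice weights).
#'
#' @inheritParams aggregate_croi
#' @param rois a [roi_set()] of kind `"whole_liver"`.
#' @return T1rho-wl in ms.
#' @export
aggregate_wl <- function(map, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (rois$kind != "whole_liver") stop("rois must be of kind whole_liver")
  mean(roi_set_means(map, rois))
}

#' Relative enhancement of a pre/post contrast pair
#'
#' `RE = (SI_20min - SI_unenhanced) / SI_unenhanced`, where each SI term is
#' the whole-liver ROI mean averaged over slices (equal slice weights)
#' before the quotient is formed.
#'
#' @param pre,post pre- and post-contrast images: matrices or named lists of
#'   matrices keyed by slice_id, co-registered and equally shaped.
#' @param rois a [roi_set()] of kind `"whole_liver"`.
#' @return Dimensionless relative enhancement.
#' @export
compute_re <- function(pre, post, rois) {
  stopifnot(inherits(rois, "roi_set"))
  if (rois$kind != "whole_liver") stop("rois must be of kind whole_liver")
  si_pre <- mean(roi_set_means(pre, rois))
  si_post <- mean(roi_set_means(post, rois))
  if (si_pre <= 0) stop("pre-contrast SI must be strictly positive")
  (si_post - si_pre) / si_pre
}

#' Fibrosis function quotient
#'
#' `FFQ = T1rho-cROI / RE`, in ms: a composite of the morphological
#' (fibrosis-sensitive) T1rho and the functional (hepatocyte-uptake) RE.
#' Higher values indicate a more impaired liver.
#'
#' @param t1rho_croi circular-ROI T1rho in ms.
#' @param re relative enhancement (> 0).
#' @return FFQ in ms; `NA` if either input is `NA`.
#' @export
compute_ffq <- function(t1rho_croi, re) {
  if (any(!is.na(re) & re <= 0)) stop("re must be > 0")
  t1rho_croi / re
}

#' Build phantom ROI sets
#'
#' Convenience constructor mirroring the manual protocol on a synthetic
#' phantom: three circular ROIs placed on the grid (the right-lobe
#' surrogate) and one whole-liver ROI covering the grid eroded by the edge
#' margin; vessels and lesions form the exclusion mask.
#'
#' @param spec a [phantom_spec()].
#' @param slice_id slice label.
#' @param croi_centers list of 3 centre coordinates for the circular ROIs;
#'   defaults spread them over the upper half of the grid.
#' @param croi_diameter_mm circular-ROI diameter in mm (protocol: 2-3 cm).
#' @param margin_mm edge-margin exclusion in mm (protocol: ~1 cm).
#' @param exclude_vessels,exclude_lesions include these structures in the
#'   exclusion mask (both `TRUE` per protocol; set `FALSE` to demonstrate
#'   the bias that inclusion causes).
#' @return List with elements `croi` and `wl`, both [roi_set()]s.
#' @export
phantom_rois <- function(spec, slice_id = "slice1", croi_centers = NULL,
                         croi_diameter_mm = 25, margin_mm = 10,
                         exclude_vessels = TRUE, exclude_lesions = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_truth(spec)
  shape <- spec$grid_shape
  excl <- matrix(FALSE, shape[1], shape[2])
  if (exclude_vessels) excl <- excl | truth$vessel_mask
  if (exclude_lesions) excl <- excl | truth$lesion_mask
  r_px <- (croi_diameter_mm / 2) / spec$pixdim_mm
  if (is.null(croi_centers)) {
    q <- round(shape / 4)
    croi_centers <- list(c(q[1], q[2]), c(q[1], 2 * q[2]), c(q[1], 3 * q[2]))
  }
  crois <- lapply(seq_along(croi_centers), function(i)
    list(label = paste0("croi", i), slice_id = slice_id,
         mask = circle_mask(shape, croi_centers[[i]], r_px)))
  margin_px <- margin_mm / spec$pixdim_mm
  liver <- erode_mask(matrix(TRUE, shape[1], shape[2]), margin_px)
  wl <- list(list(label = "whole_liver", slice_id = slice_id, mask = liver))
  list(croi = roi_set(crois, "circular_rll", exclusion_mask = excl),
       wl = roi_set(wl, "whole_liver", exclusion_mask = excl))
}
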