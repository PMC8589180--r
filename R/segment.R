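#' Circumscribe DCP telangiectasia inside a marked zone
#'
#' Partially automatic circumscription of dilated, non-tapering deep-plexus
#' vessels: the angiogram is binarized with the Phansalkar local threshold,
#' restricted to the operator-marked region of interest, hole-filled so
#' vessel outlines become solid circumscribed areas, and cleaned of isolated
#' specks below \code{min_object_px}. An optional manual correction is
#' applied last: pixels in \code{add} are forced foreground (within the ROI)
#' and pixels in \code{remove} forced background.
#'
#' @param dcp deep-capillary-plexus angiogram (numeric matrix).
#' @param roi marked telangiectasia zone: a logical mask, or an n x 2 matrix
#'   of polygon vertices (0-based pixel coordinates) rasterized with the
#'   even-odd rule.
#' @param params \code{\link{phansalkar_params}}.
#' @param min_object_px drop 8-connected foreground components smaller than
#'   this (anti-speckle; default 10).
#' @param add,remove optional manual-correction masks.
#' @return logical mask, always a subset of the ROI.
#' @export
circumscribe_telangiectasia <- function(dcp, roi,
                                        params = phansalkar_params(),
                                        min_object_px = 10,
                                        add = NULL, remove = NULL) {
  if (!is.logical(roi)) {
    if (is.matrix(roi) && ncol(roi) == 2 && !is.logical(roi))
      roi <- rasterize_polygon(roi, nrow(dcp), ncol(dcp))
  }
  roi <- as_mask(roi)
  check_same_geometry(unclass(dcp), roi)
  if (!any(roi)) {
    warning("empty ROI: returning empty telangiectasia mask")
    return(roi)
  }
  vessels <- phansalkar_threshold(dcp, params) & roi
  filled <- fill_holes(vessels) & roi
  out <- remove_small_components(filled, min_object_px)
  if (!is.null(add)) out <- (out | as_mask(add)) & roi
  if (!is.null(remove)) out <- out & !as_mask(remove)
  out
}

#' Superficial large-vessel projection-artifact mask
#'
#' Large superficial-capillary-plexus vessels project into deeper OCTA slabs
#' and can mimic telangiectasia. They are extracted by maximum-entropy
#' thresholding of the SCP angiogram, keeping only connected components that
#' are both large (area >= \code{min_large_vessel_px}) and thick (maximum
#' inscribed half-width from the distance transform >= half of
#' \code{min_width_px}), which excludes ordinary capillaries.
#'
#' @param scp superficial-plexus angiogram (numeric matrix).
#' @param min_large_vessel_px minimum component area in pixels.
#' @param min_width_px minimum inscribed vessel width in pixels.
#' @return logical mask of large-vessel pixels (empty, with a warning, for a
#'   constant image).
#' @export
scp_artifact_mask <- function(scp, min_large_vessel_px = 300, min_width_px = 4) {
  scp <- unclass(scp)
  me <- tryCatch(max_entropy_threshold(scp), error = function(e) NULL)
  if (is.null(me)) {
    warning("degenerate SCP histogram: returning empty artifact mask")
    return(matrix(FALSE, nrow(scp), ncol(scp)))
  }
  mask <- me$mask
  ## opening at half the minimum width strips capillaries and thin tendrils
  ## that would otherwise ride along with a touching large vessel
  open_r <- floor(min_width_px / 2)
  if (open_r >= 1) mask <- mask_dilate(mask_erode(mask, open_r), open_r)
  if (!any(mask)) return(mask)
  lab <- label_components(mask, 8)
  sizes <- tabulate(lab[lab > 0])
  dm <- EBImage::distmap(mask * 1)        # distance to background
  nl <- length(sizes)
  maxw <- rep(0, nl)
  agg <- tapply(dm[lab > 0], lab[lab > 0], max)
  maxw[as.integer(names(agg))] <- agg
  keep <- which(sizes >= min_large_vessel_px & 2 * maxw >= min_width_px)
  lab > 0 & lab %in% keep
}

#' Remove superficial-vessel artifacts from a telangiectasia mask
#'
#' Pixels of the telangiectasia mask that coincide with the large-vessel
#' projection mask are removed (the conservative quantitative reading of
#' "distinguishing" artifact from true dilated vessels); the removed pixel
#' count is reported via message so the alternative overlay-only behaviour is
#' auditable.
#'
#' @param tel telangiectasia mask.
#' @param scp_large large-vessel artifact mask of the same geometry.
#' @param quiet suppress the removed-pixel message.
#' @return \code{tel} with artifact pixels removed (always a subset of
#'   \code{tel}).
#' @export
exclude_artifacts <- function(tel, scp_large, quiet = FALSE) {
  tel <- as_mask(tel); scp_large <- as_mask(scp_large)
  check_same_geometry(tel, scp_large)
  removed <- sum(tel & scp_large)
  if (!quiet && removed > 0)
    message(sprintf("excluded %d artifact px from telangiectasia mask", removed))
  tel & !scp_large
}

#' Dice similarity of two masks
#'
#' @param a,b logical matrices of identical geometry.
#' @return 2|a&b| / (|a|+|b|); 1 for two empty masks.
#' @export
dice <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_geometry(a, b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
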