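#' Decompose nested photoreceptor-disruption regions into exclusive classes
#'
#' The traced regions come as three nested combined masks: \code{A} = all
#' photoreceptor disruption (IZ attenuation + IZ loss + EZ loss), \code{B} =
#' IZ loss + EZ loss, and \code{C} = EZ loss; every area of EZ loss also has
#' IZ loss, so \code{C} is contained in \code{B} is contained in \code{A}.
#' Exclusive classes follow by subtraction: IZ attenuation only = A \ B,
#' IZ loss only = B \ C, EZ loss = C.
#'
#' Independent mask files may violate nesting by a few pixels. Under
#' \code{policy = "clip"} (default) the inner masks are clipped
#' (\code{B := B & A}, then \code{C := C & B}) and the clipped pixel counts
#' are recorded; under \code{policy = "strict"} any violation is an error.
#'
#' @param A,B,C logical matrices of identical geometry (outermost to
#'   innermost combined region).
#' @param policy \code{"clip"} or \code{"strict"}.
#' @param scale_mm_per_px pixel pitch in mm, attached to the result.
#' @return object of class \code{region_set}: list with the normalized
#'   \code{A,B,C}, exclusive \code{attn_only}, \code{izloss_only}, the
#'   clipping counts and the scale.
#' @examples
#' disk <- function(r, n = 128) {
#'   d <- sqrt(outer((1:n - n / 2)^2, (1:n - n / 2)^2, "+")); d <= r
#' }
#' rs <- decompose_regions(disk(30), disk(20), disk(10), scale_mm_per_px = 3 / 304)
#' region_areas(rs)
#' @export
decompose_regions <- function(A, B, C, policy = c("clip", "strict"),
                              scale_mm_per_px = 3 / 304) {
  policy <- match.arg(policy)
  A <- as_mask(A); B <- as_mask(B); C <- as_mask(C)
  check_same_geometry(A, B); check_same_geometry(B, C)
  clipped_B <- sum(B & !A)
  B2 <- B & A
  clipped_C <- sum(C & !B2)
  C2 <- C & B2
  if (policy == "strict" && (clipped_B || clipped_C))
    stop(sprintf("nesting violated: %d px of B outside A, %d px of C outside B",
                 clipped_B, clipped_C))
  structure(list(A = A, B = B2, C = C2,
                 attn_only = A & !B2,
                 izloss_only = B2 & !C2,
                 clipped_px = c(B = clipped_B, C = clipped_C),
                 scale_mm_per_px = scale_mm_per_px),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  a <- region_areas(x)
  cat("<region_set>\n")
  cat(sprintf("  IZ attenuation only: %.4f mm^2\n", a[["attn_mm2"]]))
  cat(sprintf("  IZ loss only:        %.4f mm^2\n", a[["izloss_mm2"]]))
  cat(sprintf("  EZ loss:             %.4f mm^2\n", a[["ezloss_mm2"]]))
  if (any(x$clipped_px > 0))
    cat(sprintf("  (clipped %d px of B, %d px of C to restore nesting)\n",
                x$clipped_px[["B"]], x$clipped_px[["C"]]))
  invisible(x)
}

#' Physical areas of the exclusive disruption classes
#'
#' @param rs a \code{region_set}.
#' @return named vector: attenuation-only, IZ-loss-only and EZ-loss areas in
#'   mm^2 (they sum exactly to the area of the combined region A).
#' @export
region_areas <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  s <- rs$scale_mm_per_px
  c(attn_mm2 = area_mm2(rs$attn_only, s),
    izloss_mm2 = area_mm2(rs$izloss_only, s),
    ezloss_mm2 = area_mm2(rs$C, s))
}

#' Percent of telangiectasia area overlapping a region
#'
#' Overlap is expressed relative to the telangiectasia footprint: the number
#' of shared pixels as a percentage of the total telangiectasia pixels. Eyes
#' without any telangiectasia have no defined overlap and return NA with a
#' warning.
#'
#' @param tel,region logical matrices of identical geometry.
#' @return percentage in \code{[0, 100]}, or NA if \code{tel} is empty.
#' @export
percent_overlap <- function(tel, region) {
  tel <- as_mask(tel); region <- as_mask(region)
  check_same_geometry(tel, region)
  n <- sum(tel)
  if (n == 0) {
    warning("empty telangiectasia mask: overlap undefined")
    return(NA_real_)
  }
  100 * sum(tel & region) / n
}

#' Pool an ordinal disease stage into a severity group
#'
#' Stages 0-2 pool to \code{early}, 3-5 to \code{moderate} and stage 6 to
#' \code{advanced}.
#'
#' @param stage integer vector with values in 0..6.
#' @return factor with levels early < moderate < advanced.
#' @export
pool_stage <- function(stage) {
  stage <- as.integer(stage)
  if (any(is.na(stage)) || any(stage < 0L | stage > 6L))
    stop("stage must be in 0..6")
  g <- ifelse(stage <= 2L, "early", ifelse(stage <= 5L, "moderate", "advanced"))
  factor(g, levels = c("early", "moderate", "advanced"))
}

#' Assemble the per-eye record used by the statistics stage
#'
#' Combines a segmented telangiectasia mask and a decomposed region set into
#' one row of areas (mm^2) and percent overlaps, plus identifiers and the
#' pooled stage group.
#'
#' @param patient_id,eye_id,laterality identifiers (laterality "OD"/"OS").
#' @param stage ordinal stage 0-6.
#' @param tel logical telangiectasia mask.
#' @param regions a \code{region_set} of the same geometry.
#' @return one-row data.frame.
#' @export
eye_record <- function(patient_id, eye_id, laterality, stage, tel, regions) {
  stopifnot(inherits(regions, "region_set"))
  a <- region_areas(regions)
  s <- regions$scale_mm_per_px
  has_tel <- sum(tel) > 0
  ov <- function(region) if (has_tel) percent_overlap(tel, region) else NA_real_
  data.frame(patient_id = patient_id, eye_id = eye_id,
             laterality = laterality, stage = as.integer(stage),
             pooled_group = as.character(pool_stage(stage)),
             tel_area_mm2 = area_mm2(tel, s),
             attn_area_mm2 = a[["attn_mm2"]],
             izloss_area_mm2 = a[["izloss_mm2"]],
             ezloss_area_mm2 = a[["ezloss_mm2"]],
             overlap_attn_pct = ov(regions$attn_only),
             overlap_izloss_pct = ov(regions$izloss_only),
             overlap_ezloss_pct = ov(regions$C),
             stringsAsFactors = FALSE)
}
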