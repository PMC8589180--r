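## Plain-file interfaces: 16-bit TIFF images with JSON sidecars carrying the
## physical geometry, 8-bit {0,255} TIFF masks, JSON polygon ROIs and CSV
## cohort tables.

#' Write / read an en-face image as 16-bit TIFF with a JSON sidecar
#'
#' Intensities are clipped to [0, 1] and stored as 16-bit greyscale; the
#' sidecar \code{<path>.json} carries \code{field_mm} plus any extra
#' metadata (eye / patient ids, stage, ...), so the physical scale survives
#' the round trip.
#'
#' @param img an \code{\link{enface_image}} (or numeric matrix in [0, 1]).
#' @param path output TIFF path.
#' @param meta named list of extra sidecar fields.
#' @return \code{path}, invisibly.
#' @export
write_enface_tiff <- function(img, path, meta = list()) {
  fm <- attr(img, "field_mm")
  if (is.null(fm)) fm <- 3.0
  tiff::writeTIFF(pmin(pmax(unclass(img), 0), 1), path, bits.per.sample = 16)
  side <- c(list(field_mm = fm, grid_size = nrow(img)), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_enface_tiff
#' @return \code{read_enface_tiff}: the \code{enface_image}, with sidecar
#'   metadata in the \code{meta} attribute.
#' @export
read_enface_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  side_path <- paste0(path, ".json")
  meta <- if (file.exists(side_path)) jsonlite::read_json(side_path) else list()
  fm <- if (!is.null(meta$field_mm)) meta$field_mm else 3.0
  img <- enface_image(px, field_mm = fm)
  attr(img, "meta") <- meta
  img
}

#' Write / read a binary mask as an 8-bit {0, 255} TIFF
#'
#' @param mask logical matrix.
#' @param path TIFF path.
#' @return \code{path} invisibly; \code{read_mask_tiff} returns the logical
#'   matrix (any nonzero pixel is foreground).
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(as_mask(mask) * 1.0, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px > 0
}

#' Read a marked-ROI polygon from JSON
#'
#' The file holds either one polygon (list of [x, y] pairs, 0-based pixel
#' coordinates) or a list of polygons; polygons are rasterized with the
#' even-odd rule and unioned.
#'
#' @param path JSON file.
#' @param nrow,ncol mask geometry.
#' @return logical mask.
#' @export
read_roi_json <- function(path, nrow, ncol) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  polys <- if (is.list(obj) && !is.data.frame(obj) && !is.matrix(obj)) obj else list(obj)
  out <- matrix(FALSE, nrow, ncol)
  for (p in polys) out <- out | rasterize_polygon(as.matrix(p), nrow, ncol)
  out
}

## short stable hash of a config list (djb2 over its canonical JSON)
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10, force = TRUE)
  b <- as.integer(charToRaw(txt))
  h <- 5381
  for (x in b) h <- (h * 33 + x) %% 2^31
  sprintf("%08x", h)
}
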