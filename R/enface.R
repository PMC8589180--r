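#' En-face image container
#'
#' An en-face image is a 2D intensity grid (rows = y, columns = x) covering a
#' square physical field centred on the fovea. Intensities are stored as
#' doubles, conventionally in \code{[0, 1]}. The physical side length in
#' millimetres travels with the matrix as the \code{field_mm} attribute, so
#' pixel areas can always be converted to mm^2.
#'
#' @param pixels numeric matrix of intensities (square grids are typical:
#'   304 x 304 over 3 mm x 3 mm).
#' @param field_mm physical side length of the imaged field in mm.
#' @return a numeric matrix of class \code{enface_image} carrying the
#'   \code{field_mm} attribute.
#' @examples
#' img <- enface_image(matrix(runif(64^2), 64, 64), field_mm = 3)
#' scale_mm_per_px(img)
#' @export
enface_image <- function(pixels, field_mm = 3.0) {
  stopifnot(is.matrix(pixels), is.numeric(pixels), field_mm > 0)
  structure(pixels, field_mm = field_mm,
            class = c("enface_image", class(matrix())))
}

#' @export
print.enface_image <- function(x, ...) {
  cat(sprintf("<enface_image> %d x %d px, %.3g mm field (%.4g um/px)\n",
              nrow(x), ncol(x), attr(x, "field_mm"),
              1000 * scale_mm_per_px(x)))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x), max(x)))
  invisible(x)
}

#' Physical scale of an en-face image
#'
#' @param img an \code{enface_image}, or any matrix with a \code{field_mm}
#'   attribute.
#' @param field_mm override for plain matrices without the attribute.
#' @return mm per pixel (field side / pixels per side).
#' @export
scale_mm_per_px <- function(img, field_mm = NULL) {
  fm <- if (!is.null(field_mm)) field_mm else attr(img, "field_mm")
  if (is.null(fm)) stop("no field_mm attribute and none supplied")
  fm / nrow(img)
}

## ---- binary masks -------------------------------------------------------
## Masks are plain logical matrices sharing an image's geometry; keeping them
## bare keeps set algebra as fast, transparent base R.

as_mask <- function(x) {
  if (is.logical(x) && is.matrix(x)) return(x)
  stopifnot(is.matrix(x))
  array(as.logical(x), dim = dim(x))
}

check_same_geometry <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask geometry mismatch: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  invisible(TRUE)
}

#' Convert a pixel mask to a physical area
#'
#' Counts foreground pixels and multiplies by the squared pixel pitch. With
#' the default 3 mm / 304 px grid one pixel is (3/304)^2 ~ 9.74e-5 mm^2.
#'
#' @param mask logical matrix.
#' @param scale_mm_per_px pixel pitch in mm (e.g. \code{3/304}).
#' @return area in mm^2.
#' @examples
#' m <- matrix(FALSE, 304, 304); m[1:40, 1:25] <- TRUE
#' area_mm2(m, 3 / 304)
#' @export
area_mm2 <- function(mask, scale_mm_per_px) {
  stopifnot(scale_mm_per_px > 0)
  sum(as_mask(mask)) * scale_mm_per_px^2
}

## ---- polygon rasterization ---------------------------------------------

#' Rasterize a polygon to a binary mask
#'
#' Even-odd rule; a pixel is foreground when its centre lies inside the
#' polygon. Vertex coordinates are 0-based pixel coordinates (x = column,
#' y = row), so the centre of the top-left pixel is (0, 0).
#'
#' @param xy two-column matrix of polygon vertices (x, y), not closed.
#' @param nrow,ncol output geometry in pixels.
#' @return logical matrix.
#' @export
rasterize_polygon <- function(xy, nrow, ncol) {
  stopifnot(is.matrix(xy), ncol(xy) == 2, nrow(xy) >= 3)
  px <- xy[, 1]; py <- xy[, 2]
  n <- length(px)
  jx <- rep(seq_len(ncol) - 1, each = nrow)   # pixel-centre x per column
  iy <- rep(seq_len(nrow) - 1, times = ncol)  # pixel-centre y per row
  inside <- logical(nrow * ncol)
  j <- n
  for (i in seq_len(n)) {            # even-odd crossing count, vectorized per edge
    yi <- py[i]; yj <- py[j]
    if (yi != yj) {
      crosses <- (yi > iy) != (yj > iy)
      xint <- px[i] + (iy - yi) / (yj - yi) * (px[j] - px[i])
      inside <- xor(inside, crosses & (jx < xint))
    }
    j <- i
  }
  matrix(inside, nrow, ncol)
}

## ---- connected components ----------------------------------------------

## 8-connected labelling: EBImage::bwlabel is 4-connected, so labels that
## touch diagonally are merged with a small union-find pass.
label_components <- function(mask, connectivity = 8) {
  mask <- as_mask(mask)
  lab <- EBImage::bwlabel(mask * 1)
  nl <- max(lab)
  if (connectivity == 4 || nl <= 1) return(lab)
  parent <- seq_len(nl)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # \ diagonal
    cbind(as.vector(lab[-1, -nc]), as.vector(lab[-nr, -1])))   # / diagonal
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

## Drop foreground components smaller than min_px (8-connected by default).
remove_small_components <- function(mask, min_px, connectivity = 8) {
  mask <- as_mask(mask)
  if (!any(mask) || min_px <= 1) return(mask)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  lab > 0 & lab %in% keep
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2 * as.integer(radius) + 1, shape = "disc")
}

mask_erode <- function(mask, radius) {
  if (radius < 1) return(as_mask(mask))
  as_mask(EBImage::erode(as_mask(mask) * 1, disc_brush(radius)) > 0.5)
}

mask_dilate <- function(mask, radius) {
  if (radius < 1) return(as_mask(mask))
  as_mask(EBImage::dilate(as_mask(mask) * 1, disc_brush(radius)) > 0.5)
}
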