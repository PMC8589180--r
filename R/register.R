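#' Dense deformation field
#'
#' Per-pixel displacement vectors on the output grid: an operation that
#' resamples image \code{img} through field \code{u} evaluates
#' \code{out[i, j] = img[i + dy[i, j], j + dx[i, j]]}. For longitudinal
#' analysis the field returned by \code{\link{register_scp}} lives on the
#' baseline grid and maps into the follow-up frame, so warping follow-up
#' masks through it brings them into the baseline frame.
#'
#' @param dx,dy numeric matrices of column/row displacements in pixels.
#' @return list of class \code{deformation_field}.
#' @export
deformation_field <- function(dx, dy) {
  stopifnot(is.matrix(dx), is.matrix(dy), identical(dim(dx), dim(dy)),
            all(is.finite(dx)), all(is.finite(dy)))
  structure(list(dx = dx, dy = dy), class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(x$dx^2 + x$dy^2)
  cat(sprintf("<deformation_field> %d x %d px; |d| mean %.3f, max %.3f px\n",
              nrow(x$dx), ncol(x$dx), mean(mag), max(mag)))
  invisible(x)
}

#' Mean endpoint error between two deformation fields
#'
#' @param f1,f2 \code{deformation_field}s on the same grid.
#' @return mean over pixels of the Euclidean distance between the two
#'   displacement vectors, in pixels.
#' @export
field_endpoint_error <- function(f1, f2) {
  check_same_geometry(f1$dx, f2$dx)
  mean(sqrt((f1$dx - f2$dx)^2 + (f1$dy - f2$dy)^2))
}

## bilinear sampling of `img` at (yi, xj); coordinates clamped to the grid
.bilinear_sample <- function(img, yi, xj) {
  n <- nrow(img); m <- ncol(img)
  yi <- pmin(pmax(as.vector(yi), 1), n); xj <- pmin(pmax(as.vector(xj), 1), m)
  y0 <- pmin(floor(yi), n - 1); x0 <- pmin(floor(xj), m - 1)
  fy <- yi - y0; fx <- xj - x0
  i00 <- cbind(y0, x0); i10 <- cbind(y0 + 1, x0)
  i01 <- cbind(y0, x0 + 1); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fy) * (1 - fx) + img[i10] * fy * (1 - fx) +
    img[i01] * (1 - fy) * fx + img[i11] * fy * fx
}

#' Resample an image through a deformation field
#'
#' Backward warping with bilinear interpolation:
#' \code{out[i, j] = img[i + dy, j + dx]}. Sample coordinates are clamped to
#' the image (edge replication), which avoids spurious dark borders during
#' registration.
#'
#' @param img numeric matrix.
#' @param field \code{deformation_field} on the output grid.
#' @return numeric matrix of the same size.
#' @export
warp_image <- function(img, field) {
  stopifnot(inherits(field, "deformation_field"))
  img <- unclass(img)
  check_same_geometry(img, field$dx)
  n <- nrow(img); m <- ncol(img)
  ii <- matrix(seq_len(n), n, m)
  jj <- matrix(seq_len(m), n, m, byrow = TRUE)
  matrix(.bilinear_sample(img, ii + field$dy, jj + field$dx), n, m)
}

#' Resample a binary mask through a deformation field
#'
#' Nearest-neighbour resampling so the mask stays binary; samples falling
#' outside the grid become background. The identity field reproduces the
#' mask exactly.
#'
#' @param mask logical matrix.
#' @param field \code{deformation_field} on the output grid.
#' @return logical matrix.
#' @export
warp_mask <- function(mask, field) {
  stopifnot(inherits(field, "deformation_field"))
  mask <- as_mask(mask)
  check_same_geometry(mask, field$dx)
  n <- nrow(mask); m <- ncol(mask)
  ii <- matrix(seq_len(n), n, m)
  jj <- matrix(seq_len(m), n, m, byrow = TRUE)
  yi <- round(ii + field$dy); xj <- round(jj + field$dx)
  ok <- yi >= 1 & yi <= n & xj >= 1 & xj <= m
  out <- matrix(FALSE, n, m)
  out[ok] <- mask[cbind(yi[ok], xj[ok])]
  out
}

#' Numerically invert a deformation field
#'
#' Fixed-point iteration \code{v(y) <- -u(y + v(y))}; accurate for the
#' smooth, moderate-amplitude fields used here (composition of the field
#' with its inverse is close to identity).
#'
#' @param field a \code{deformation_field}.
#' @param iterations number of fixed-point sweeps.
#' @return the inverse \code{deformation_field}.
#' @export
invert_field <- function(field, iterations = 15) {
  vx <- -field$dx; vy <- -field$dy
  n <- nrow(vx); m <- ncol(vx)
  ii <- matrix(seq_len(n), n, m)
  jj <- matrix(seq_len(m), n, m, byrow = TRUE)
  for (it in seq_len(iterations)) {
    yi <- ii + vy; xj <- jj + vx
    vx <- -matrix(.bilinear_sample(field$dx, yi, xj), n, m)
    vy <- -matrix(.bilinear_sample(field$dy, yi, xj), n, m)
  }
  deformation_field(vx, vy)
}

## integer translation (fixed ~ moving shifted) by phase correlation
.phase_correlate <- function(fixed, moving) {
  F1 <- stats::fft(fixed); F2 <- stats::fft(moving)
  R <- F1 * Conj(F2)
  den <- Mod(R); den[den < 1e-12] <- 1e-12
  r <- Re(stats::fft(R / den, inverse = TRUE))
  pk <- arrayInd(which.max(r), dim(r)) - 1L
  n <- nrow(fixed); m <- ncol(fixed)
  sy <- if (pk[1] > n / 2) pk[1] - n else pk[1]
  sx <- if (pk[2] > m / 2) pk[2] - m else pk[2]
  c(sy = sy, sx = sx)
}

## block-mean downsampling by integer factor (trailing rows/cols cropped)
.downsample <- function(img, f) {
  if (f == 1) return(img)
  n <- (nrow(img) %/% f) * f; m <- (ncol(img) %/% f) * f
  img <- img[seq_len(n), seq_len(m)]
  a <- array(img, c(f, n / f, m))
  cm <- colMeans(a)                       # (n/f) x m
  a2 <- array(t(cm), c(f, m / f, n / f))
  t(colMeans(a2))
}

## bilinear resize of a matrix to nr x nc
.resize_bilinear <- function(img, nr, nc) {
  yi <- seq(1, nrow(img), length.out = nr)
  xj <- seq(1, ncol(img), length.out = nc)
  Y <- matrix(yi, nr, nc); X <- matrix(xj, nr, nc, byrow = TRUE)
  matrix(.bilinear_sample(img, Y, X), nr, nc)
}

.gradient <- function(img) {
  n <- nrow(img); m <- ncol(img)
  gy <- img; gx <- img
  gy[2:(n - 1), ] <- (img[3:n, ] - img[1:(n - 2), ]) / 2
  gy[1, ] <- img[2, ] - img[1, ]; gy[n, ] <- img[n, ] - img[n - 1, ]
  gx[, 2:(m - 1)] <- (img[, 3:m] - img[, 1:(m - 2)]) / 2
  gx[, 1] <- img[, 2] - img[, 1]; gx[, m] <- img[, m] - img[, m - 1]
  list(gx = gx, gy = gy)
}

#' Configuration for elastic SCP registration
#'
#' @param levels integer downsampling factors, coarse to fine.
#' @param iterations per-level iteration counts.
#' @param sigma_fluid Gaussian smoothing (px) of each incremental update.
#' @param sigma_diff Gaussian smoothing (px) of the accumulated field.
#' @param step intensity normalization constant of the demons update
#'   (larger = bolder steps).
#' @param max_displacement_px cap on the displacement magnitude.
#' @param init_translation initialize with phase-correlation translation.
#' @return list of class \code{register_config}.
#' @export
register_config <- function(levels = c(4, 2, 1), iterations = c(100, 60, 20),
                            sigma_fluid = 2.0, sigma_diff = 1.2, step = 1.2,
                            max_displacement_px = 20, init_translation = TRUE) {
  stopifnot(length(levels) == length(iterations), all(levels >= 1))
  structure(list(levels = as.integer(levels), iterations = as.integer(iterations),
                 sigma_fluid = sigma_fluid, sigma_diff = sigma_diff,
                 step = step, max_displacement_px = max_displacement_px,
                 init_translation = init_translation),
            class = "register_config")
}

#' Elastic registration of a follow-up scan onto its baseline
#'
#' Estimates a dense deformation field aligning the follow-up SCP angiogram
#' to the baseline SCP angiogram; the same field is then applied to the
#' traced follow-up regions (the superficial plexus carries the stable
#' vascular landmarks, while the pathology itself changes between visits).
#' The scheme is a translation initialization by phase correlation followed
#' by multiresolution demons-style refinement of a free-form field:
#' intensity-driven updates smoothed with a Gaussian (fluid-like
#' regularization of the update, diffusion-like regularization of the
#' accumulated field), minimizing mean squared intensity error.
#'
#' @param baseline,followup numeric matrices (SCP angiograms) of identical
#'   geometry.
#' @param config a \code{\link{register_config}}.
#' @return \code{deformation_field} on the baseline grid mapping into the
#'   follow-up frame, so \code{warp_image(followup, field)} approximates
#'   \code{baseline} and \code{warp_mask(followup_mask, field)} transfers
#'   follow-up regions to baseline. Attributes: \code{mse_trace} (per-level
#'   final MSE) and \code{mse_identity}. Warns if no improvement over the
#'   identity alignment was achieved.
#' @export
register_scp <- function(baseline, followup, config = register_config()) {
  fixed <- unclass(baseline); moving <- unclass(followup)
  check_same_geometry(fixed, moving)
  norm01 <- function(x) { r <- range(x); if (r[2] > r[1]) (x - r[1]) / (r[2] - r[1]) else x * 0 }
  fixed <- norm01(fixed); moving <- norm01(moving)
  n <- nrow(fixed); m <- ncol(fixed)
  mse_identity <- mean((fixed - moving)^2)

  dx <- matrix(0, n, m); dy <- matrix(0, n, m)
  if (config$init_translation) {
    sh <- .phase_correlate(fixed, moving)
    ## fixed(y) ~ moving(y - shift): sampling displacement is -shift
    dy[] <- -sh[["sy"]]; dx[] <- -sh[["sx"]]
  }

  mse_trace <- numeric(0)
  for (li in seq_along(config$levels)) {
    f <- config$levels[li]
    fx <- .downsample(fixed, f); mv <- .downsample(moving, f)
    nl <- nrow(fx); ml <- ncol(fx)
    dxl <- .resize_bilinear(dx, nl, ml) / f
    dyl <- .resize_bilinear(dy, nl, ml) / f
    cap <- config$max_displacement_px / f
    alpha <- 1 / config$step^2
    best <- Inf; stall <- 0
    for (it in seq_len(config$iterations[li])) {
      fld <- deformation_field(dxl, dyl)
      w <- warp_image(mv, fld)
      d <- fx - w
      mse <- mean(d^2)
      if (mse < best - 1e-9) { best <- mse; stall <- 0 } else stall <- stall + 1
      if (stall > 12) break
      g <- .gradient(w); g2 <- .gradient(fx)
      gx <- (g$gx + g2$gx) / 2; gy <- (g$gy + g2$gy) / 2
      den <- gx^2 + gy^2 + alpha * d^2
      den[den < 1e-8] <- Inf
      ux <- EBImage::gblur(d * gx / den, config$sigma_fluid)
      uy <- EBImage::gblur(d * gy / den, config$sigma_fluid)
      dxl <- EBImage::gblur(dxl + ux, config$sigma_diff)
      dyl <- EBImage::gblur(dyl + uy, config$sigma_diff)
      mag <- sqrt(dxl^2 + dyl^2)
      over <- mag > cap
      if (any(over)) {
        sc <- cap / mag[over]
        dxl[over] <- dxl[over] * sc; dyl[over] <- dyl[over] * sc
      }
    }
    mse_trace <- c(mse_trace, best)
    dx <- .resize_bilinear(dxl, n, m) * f
    dy <- .resize_bilinear(dyl, n, m) * f
  }
  out <- deformation_field(dx, dy)
  final_mse <- mean((fixed - warp_image(moving, out))^2)
  if (final_mse >= mse_identity && mse_identity > 1e-12)
    warning("registration did not improve on identity alignment; returning best field found")
  attr(out, "mse_trace") <- mse_trace
  attr(out, "mse_identity") <- mse_identity
  attr(out, "mse_final") <- final_mse
  out
}
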