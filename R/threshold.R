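#' Parameters for Phansalkar local adaptive thresholding
#'
#' The Phansalkar threshold extends Sauvola's local threshold for low-contrast
#' images. At every pixel the threshold is
#' \deqn{T = \mu (1 + p e^{-q\mu} + k(\sigma/r - 1))}
#' with \eqn{\mu, \sigma} the mean and standard deviation of the normalized
#' intensity over a circular window. Defaults are the widely used constants
#' (k = 0.25, r = 0.5, p = 2, q = 10 on intensities in [0,1]) with a 15 px
#' window radius, matching the common ImageJ Auto Local Threshold settings.
#'
#' @param radius circular window radius in pixels (>= 1).
#' @param k,r,p,q dimensionless formula constants; \code{r} is the dynamic
#'   range of the standard deviation and must be > 0.
#' @return list of class \code{phansalkar_params}.
#' @export
phansalkar_params <- function(radius = 15, k = 0.25, r = 0.5, p = 2, q = 10) {
  stopifnot(radius >= 1, r > 0)
  structure(list(radius = as.integer(radius), k = k, r = r, p = p, q = q),
            class = "phansalkar_params")
}

## Clipped-window local mean / sd via convolution with a disc kernel:
## sums of the zero-padded image are divided by the count of in-image pixels
## under the window, which is exactly the window-clipped-to-image statistic.
local_window_stats <- function(img, radius) {
  sz <- 2L * radius + 1L
  off <- seq_len(sz) - radius - 1L
  kern <- outer(off, off, function(dy, dx) (dx^2 + dy^2) <= radius^2) * 1
  nr <- nrow(img); nc <- ncol(img)
  ## zero-pad images smaller than the kernel (padding never enters the
  ## clipped-window statistics: it adds 0 to sums and 0 to counts)
  pr <- max(sz - nr, 0L); pc <- max(sz - nc, 0L)
  if (pr > 0 || pc > 0) {
    pad <- matrix(0, nr + pr, nc + pc)
    pad[seq_len(nr), seq_len(nc)] <- img
    img_p <- pad
  } else img_p <- img
  ones <- matrix(0, nrow(img_p), ncol(img_p))
  ones[seq_len(nr), seq_len(nc)] <- 1
  conv <- function(x) EBImage::filter2(x, kern, boundary = 0)[seq_len(nr), seq_len(nc)]
  ## FFT convolution leaves ~1e-17 residue where the exact sum is 0, which
  ## would flip the threshold sign in empty windows; snap it out
  counts <- pmax(round(conv(ones)), 1)
  s1 <- conv(img_p); s1[abs(s1) < 1e-9] <- 0
  s2 <- conv(img_p^2); s2[abs(s2) < 1e-9] <- 0
  mu <- s1 / counts
  va <- pmax(s2 / counts - mu^2, 0)
  list(mean = mu, sd = sqrt(va))
}

#' Phansalkar local adaptive threshold
#'
#' Binarizes an image with the Phansalkar local threshold: a pixel is
#' foreground when its normalized intensity exceeds
#' \eqn{T(x) = \mu(x)(1 + p e^{-q\mu(x)} + k(\sigma(x)/r - 1))}, where
#' \eqn{\mu(x)} and \eqn{\sigma(x)} are the mean and standard deviation over
#' the circular window of the given radius centred at \eqn{x}, the window
#' being clipped to the image at the borders. Used here to isolate individual
#' vessels inside marked telangiectasia zones of DCP angiograms, where a
#' global threshold fails due to locally varying flow signal.
#'
#' @param img numeric matrix (an \code{enface_image} works as-is).
#' @param params a \code{\link{phansalkar_params}} object.
#' @param normalize divide by the image maximum first so intensities are in
#'   \code{[0, 1]} and the result is invariant to positive rescaling
#'   (default TRUE). A constant-zero image yields an all-background mask.
#' @return logical matrix, TRUE = vessel/foreground.
#' @export
phansalkar_threshold <- function(img, params = phansalkar_params(),
                                 normalize = TRUE) {
  stopifnot(inherits(params, "phansalkar_params"))
  img <- unclass(img)
  if (normalize) {
    mx <- max(img)
    if (mx > 0) img <- img / mx
  }
  st <- local_window_stats(img, params$radius)
  thr <- st$mean * (1 + params$p * exp(-params$q * st$mean) +
                      params$k * (st$sd / params$r - 1))
  img > thr
}

#' Maximum-entropy (Kapur) global threshold
#'
#' Picks the histogram split maximizing the sum of Shannon entropies of the
#' normalized foreground and background intensity distributions (Kapur's
#' criterion); ties are broken towards the lowest level. Empty bins
#' contribute nothing (0 log 0 := 0). Used to extract bright large
#' superficial-plexus vessels whose projection contaminates deeper slabs.
#'
#' @param img numeric matrix.
#' @param nbins number of histogram bins over the image's intensity range.
#' @return list with \code{level} (threshold on the original intensity scale;
#'   the mask is \code{img > level}) and \code{mask}.
#' @export
max_entropy_threshold <- function(img, nbins = 256) {
  img <- unclass(img)
  lo <- min(img); hi <- max(img)
  if (hi <= lo) stop("degenerate histogram: constant image")
  bin <- pmin(pmax(ceiling((img - lo) / (hi - lo) * nbins), 1L), nbins)
  p <- tabulate(bin, nbins) / length(img)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p)
  S0 <- cumsum(plogp)
  Ptot <- 1; Stot <- sum(plogp)
  t_cand <- seq_len(nbins - 1L)
  P1 <- Ptot - P0[t_cand]
  valid <- P0[t_cand] > 0 & P1 > 0
  Hbg <- log(P0[t_cand]) - S0[t_cand] / P0[t_cand]
  Hfg <- log(P1) - (Stot - S0[t_cand]) / P1
  crit <- ifelse(valid, Hbg + Hfg, -Inf)
  t_best <- t_cand[which.max(crit)]      # which.max takes the first maximum
  level <- lo + t_best * (hi - lo) / nbins
  list(level = level, mask = img > level)
}

#' Fill holes in a binary mask
#'
#' Adds to the foreground every background component that is not 4-connected
#' to the image border (foreground is treated 8-connected, the standard dual
#' convention), turning binarized vessel outlines into circumscribed filled
#' areas. Idempotent and monotone.
#'
#' @param mask logical matrix.
#' @return logical matrix with interior holes filled.
#' @export
fill_holes <- function(mask) {
  mask <- as_mask(mask)
  if (!any(!mask)) return(mask)
  ## pad with a background frame so one 4-connected flood from a corner
  ## reaches all border-connected background
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask * 1
  flooded <- EBImage::floodFill(padded, c(1L, 1L), col = 2)
  core <- flooded[2:(nr + 1L), 2:(nc + 1L)]
  core != 2          # foreground plus enclosed (never-reached) background
}
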