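## Independent brute-force oracles used across the suite. These deliberately
## avoid the implementation's code paths (convolution, cumulative sums,
## chunked enumeration) in favour of plain per-pixel / per-bin loops.

disk_mask <- function(n, r, centre = c((n + 1) / 2, (n + 1) / 2)) {
  d2 <- outer((seq_len(n) - centre[1])^2, (seq_len(n) - centre[2])^2, "+")
  d2 <= r^2
}

## per-pixel double-loop Phansalkar with window clipped to the image
bf_phansalkar <- function(img, params, normalize = TRUE) {
  if (normalize && max(img) > 0) img <- img / max(img)
  n <- nrow(img); m <- ncol(img); rad <- params$radius
  out <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    ii <- max(1, i - rad):min(n, i + rad)
    for (j in seq_len(m)) {
      jj <- max(1, j - rad):min(m, j + rad)
      keep <- outer((ii - i)^2, (jj - j)^2, "+") <= rad^2
      vals <- img[ii, jj][keep]
      mu <- mean(vals)
      sg <- sqrt(max(mean(vals^2) - mu^2, 0))
      thr <- mu * (1 + params$p * exp(-params$q * mu) +
                     params$k * (sg / params$r - 1))
      out[i, j] <- img[i, j] > thr
    }
  }
  out
}

## exhaustive Kapur criterion over all candidate bins
bf_max_entropy_level <- function(img, nbins = 256) {
  lo <- min(img); hi <- max(img)
  bin <- pmin(pmax(ceiling((img - lo) / (hi - lo) * nbins), 1L), nbins)
  p <- tabulate(bin, nbins) / length(img)
  best <- -Inf; best_t <- NA
  for (t in seq_len(nbins - 1)) {
    p0 <- p[1:t]; p1 <- p[(t + 1):nbins]
    P0 <- sum(p0); P1 <- sum(p1)
    if (P0 <= 0 || P1 <= 0) next
    h <- function(v, P) { v <- v[v > 0] / P; -sum(v * log(v)) }
    crit <- h(p0, P0) + h(p1, P1)
    if (crit > best + 1e-12) { best <- crit; best_t <- t }
  }
  lo + best_t * (hi - lo) / nbins
}

## queue-based 4-connected flood fill of background from the border
bf_fill_holes <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  reach <- matrix(FALSE, n, m)
  queue <- which(!mask & (row(mask) %in% c(1, n) | col(mask) %in% c(1, m)))
  reach[queue] <- TRUE
  while (length(queue)) {
    idx <- queue[1]; queue <- queue[-1]
    i <- (idx - 1) %% n + 1; j <- (idx - 1) %/% n + 1
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= n && jj >= 1 && jj <= m) {
        k <- (jj - 1) * n + ii
        if (!mask[k] && !reach[k]) { reach[k] <- TRUE; queue <- c(queue, k) }
      }
    }
  }
  mask | (!mask & !reach)
}

## recursive list-of-vectors permutation enumerator (independent of the
## package's chunked matrix enumeration)
perms_of <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  out
}

## random blob mask for property tests
random_blob <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n * n), n, n)
  sm <- EBImage::gblur(m, n / 10)
  sm > stats::quantile(sm, 0.8)
}
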