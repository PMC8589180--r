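## Synthetic en-face OCT/OCTA scene generator.
##
## Emulates the inputs of the quantification pipeline: a deep-capillary-plexus
## (DCP) angiogram with a circumscribed zone of dilated telangiectatic
## vessels, a superficial-capillary-plexus (SCP) angiogram with thick large
## vessels that project as artifacts, and a photoreceptor-slab reflectance
## image with nested hypo-reflective disruption regions
## (attenuation >= IZ loss >= EZ loss), plus pixel-exact ground truth.

.table3_defaults <- list(
  early = list(tel = c(0.160, 0.059),
               areas = list(attn = c(0.745, 0.500), izloss = c(0.150, 0.149),
                            ezloss = c(0.016, 0.031)),
               overlap = c(attn = 0.4855, izloss = 0.0821, ezloss = 0.0160),
               overlap_sd = c(attn = 0.2268, izloss = 0.1164, ezloss = 0.0373)),
  moderate = list(tel = c(0.313, 0.123),
                  areas = list(attn = c(1.024, 0.856), izloss = c(0.401, 0.221),
                               ezloss = c(0.247, 0.237)),
                  overlap = c(attn = 0.3009, izloss = 0.2549, ezloss = 0.1794),
                  overlap_sd = c(attn = 0.1661, izloss = 0.1055, ezloss = 0.1882)),
  advanced = list(tel = c(0.561, 0.190),
                  areas = list(attn = c(1.095, 0.321), izloss = c(0.711, 0.464),
                               ezloss = c(1.091, 0.560)),
                  overlap = c(attn = 0.1006, izloss = 0.1844, ezloss = 0.6512),
                  overlap_sd = c(attn = 0.0836, izloss = 0.0806, ezloss = 0.1779)))

#' Parameters of a synthetic en-face scene
#'
#' Defaults are taken per pooled severity group from the cohort's by-group
#' means and SDs: exclusive photoreceptor-disruption class areas
#' (IZ attenuation only, IZ loss only, EZ loss), telangiectasia footprint
#' area, and the fraction of the telangiectasia footprint falling in each
#' disruption class. Areas are sampled per scene from normal distributions
#' truncated at zero.
#'
#' @param stage_group \code{"early"}, \code{"moderate"} or \code{"advanced"};
#'   selects the default area/overlap targets.
#' @param grid_size pixels per side (>= 64; default 304).
#' @param field_mm physical side length (default 3 mm).
#' @param target_areas_mm2 optional override: list with elements
#'   \code{attn}, \code{izloss}, \code{ezloss}, each \code{c(mean, sd)} in
#'   mm^2 (exclusive class areas).
#' @param telangiectasia_area_mm2 optional override \code{c(mean, sd)}.
#' @param overlap_fractions optional override: named mean fractions
#'   \code{c(attn=, izloss=, ezloss=)} of telangiectasia area per class,
#'   each in [0,1], summing to <= 1 (the remainder falls outside any
#'   disruption).
#' @param overlap_fractions_sd optional override: per-eye SDs of the overlap
#'   fractions (sampled per scene around the means, zero-truncated, clamped
#'   to a valid simplex), reproducing the between-eye dispersion of the
#'   cohort rather than a frozen mean.
#' @param noise_level multiplicative speckle contrast in [0,1] (default 0.1).
#' @param seed integer seed; the whole scene derives from it.
#' @return list of class \code{scene_params}.
#' @export
scene_params <- function(stage_group = c("early", "moderate", "advanced"),
                         grid_size = 304, field_mm = 3.0,
                         target_areas_mm2 = NULL,
                         telangiectasia_area_mm2 = NULL,
                         overlap_fractions = NULL,
                         overlap_fractions_sd = NULL,
                         noise_level = 0.1, seed = 1) {
  stage_group <- match.arg(stage_group)
  def <- .table3_defaults[[stage_group]]
  areas <- if (is.null(target_areas_mm2)) def$areas else
    utils::modifyList(def$areas, target_areas_mm2)
  tel <- if (is.null(telangiectasia_area_mm2)) def$tel else telangiectasia_area_mm2
  ov <- if (is.null(overlap_fractions)) def$overlap else overlap_fractions
  ov_sd <- if (is.null(overlap_fractions_sd)) def$overlap_sd else overlap_fractions_sd
  stopifnot(grid_size >= 64, field_mm > 0,
            noise_level >= 0, noise_level <= 1,
            all(ov >= 0), all(ov <= 1), sum(ov) <= 1 + 1e-9,
            all(ov_sd >= 0))
  fa <- field_mm^2
  for (nm in names(areas))
    if (areas[[nm]][1] < 0 || areas[[nm]][1] > fa)
      stop("target area out of [0, field area]: ", nm)
  if (tel[1] < 0 || tel[1] > fa) stop("telangiectasia area out of range")
  structure(list(stage_group = stage_group, grid_size = as.integer(grid_size),
                 field_mm = field_mm, target_areas_mm2 = areas,
                 telangiectasia_area_mm2 = tel,
                 overlap_fractions = ov[c("attn", "izloss", "ezloss")],
                 overlap_fractions_sd = ov_sd[c("attn", "izloss", "ezloss")],
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "scene_params")
}

#' Scene parameters for the longitudinal follow-up regime
#'
#' The follow-up cohort is dominated by eyes with substantial IZ loss but
#' small-to-moderate established EZ loss (baseline IZ loss ~0.6 mm^2 within
#' the 9 mm^2 field), the regime in which new EZ loss can appear and its
#' prediction from baseline IZ loss is informative.
#'
#' @param seed integer seed.
#' @param ... further overrides passed to \code{\link{scene_params}}.
#' @return a \code{scene_params} object.
#' @export
longitudinal_scene_params <- function(seed = 1, ...) {
  scene_params(stage_group = "moderate",
               target_areas_mm2 = list(attn = c(1.0, 0.4),
                                       izloss = c(0.6, 0.2),
                                       ezloss = c(0.25, 0.2)),
               seed = seed, ...)
}

## zero-truncated normal with mean equal to `mean` exactly: truncation at 0
## raises the mean of small-mean/large-sd classes (e.g. early-stage EZ
## loss), so the location parameter is re-calibrated; sampling is by
## inverse CDF so correlated draws can share a uniform quantile
qtnorm0 <- function(u, mean, sd) {
  if (mean <= 0) return(rep(0, length(u)))
  if (sd <= 0) return(rep(mean, length(u)))
  mu <- .tnorm_location(mean, sd)
  p0 <- stats::pnorm(-mu / sd)
  mu + sd * stats::qnorm(p0 + u * (1 - p0))
}

rtnorm0 <- function(n, mean, sd) qtnorm0(stats::runif(n), mean, sd)

## one joint draw of the three overlap fractions on the simplex: the EZ and
## attenuation fractions share one quantile in opposite directions (a finite
## telangiectasia footprint redistributes between the classes), each marginal
## is a zero-truncated normal capped at 1, and draws summing beyond 1 are
## rescaled onto the simplex
.overlap_draw <- function(u_ez, u_iz, means, sds) {
  f_at <- pmin(qtnorm0(1 - u_ez, means[1], sds[1]), 1)
  f_iz <- pmin(qtnorm0(u_iz, means[2], sds[2]), 1)
  f_ez <- pmin(qtnorm0(u_ez, means[3], sds[3]), 1)
  s <- f_at + f_iz + f_ez
  sc <- ifelse(s > 1, 1 / s, 1)
  cbind(attn = f_at * sc, izloss = f_iz * sc, ezloss = f_ez * sc)
}

## the simplex projection shrinks the marginal means below their targets
## (strongly so for advanced disease, where the targets sum to ~0.94);
## calibrate the pre-projection location parameters on a deterministic
## quantile grid so the post-projection means equal the configured targets
.calibrate_overlap_means <- function(target, sds) {
  k <- 60
  g <- (seq_len(k) - 0.5) / k
  U <- expand.grid(u_ez = g, u_iz = g)
  m <- target
  for (it in 1:10) {
    p <- colMeans(.overlap_draw(U$u_ez, U$u_iz, m, sds))
    if (max(abs(p - target)) < 1e-4) break
    ratio <- ifelse(target > 0 & p > 0, target / p, 1)
    m <- m * pmin(pmax(ratio, 0.5), 2)
  }
  m
}

## location mu such that E[N(mu, s) | X >= 0] = m
.tnorm_location <- function(m, s) {
  if (m / s > 6) return(m)
  f <- function(mu) { a <- mu / s; mu + s * stats::dnorm(a) / stats::pnorm(a) - m }
  stats::uniroot(f, c(m - 8 * s, m + s), tol = 1e-10)$root
}

## ---- star-shaped nested region rasterization ---------------------------

## harmonic radial shape function, strictly positive
.shape_fun <- function(nharm = 4, wiggle = 0.10) {
  a <- stats::rnorm(nharm, 0, wiggle / seq_len(nharm))
  ph <- stats::runif(nharm, 0, 2 * pi)
  function(theta) {
    s <- rep(1, length(theta))
    for (k in seq_len(nharm)) s <- s + a[k] * cos(k * theta + ph[k])
    pmax(s, 0.35)
  }
}

## rasterize {d <= rho * shape(theta)} and tune rho to hit a pixel-area
## target; returns the mask and the fitted rho
.star_mask <- function(dist, theta, shape, target_px) {
  if (target_px < 4)
    return(list(mask = array(FALSE, dim = dim(dist)), rho = 0))
  sh <- shape(theta)
  rho <- sqrt(target_px / mean(sh^2) / pi)
  for (it in 1:6) {
    m <- dist <= rho * sh
    a <- sum(m)
    if (abs(a - target_px) <= max(4, 0.005 * target_px)) break
    rho <- rho * sqrt(target_px / max(a, 1))
  }
  list(mask = m, rho = rho)
}

## outer region = {d <= r_inner(theta) + m * delta(theta)}: bisection on the
## offset multiplier m, so the result contains the inner region exactly;
## returns the mask and m
.star_shell <- function(dist, theta, r_inner_fun, delta_fun, target_px) {
  sh_in <- r_inner_fun(theta); dl <- delta_fun(theta)
  f <- function(m) sum(dist <= sh_in + m * dl)
  if (f(0) >= target_px)
    return(list(mask = dist <= sh_in, m = 0))
  lo <- 0; hi <- 4
  while (f(hi) < target_px && hi < 400) hi <- hi * 2
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (f(mid) < target_px) lo <- mid else hi <- mid
    if (abs(f(mid) - target_px) <= max(4, 0.005 * target_px)) { lo <- hi <- mid; break }
  }
  m <- (lo + hi) / 2
  list(mask = dist <= sh_in + m * dl, m = m)
}

## ---- vessel rendering ---------------------------------------------------

## stamp a disc of radius r at (ci, cj) into logical canvas
.stamp_disc <- function(canvas, ci, cj, r) {
  n <- nrow(canvas); m <- ncol(canvas)
  i0 <- max(1, floor(ci - r)); i1 <- min(n, ceiling(ci + r))
  j0 <- max(1, floor(cj - r)); j1 <- min(m, ceiling(cj + r))
  if (i0 > i1 || j0 > j1) return(canvas)
  ii <- i0:i1; jj <- j0:j1
  patch <- outer((ii - ci)^2, (jj - cj)^2, "+") <= r^2
  canvas[ii, jj] <- canvas[ii, jj] | patch
  canvas
}

## meandering vessel path as a matrix of (i, j) points
.vessel_path <- function(n, start, dir0, steps, step_px = 1.5, wobble = 0.25) {
  ang <- dir0 + cumsum(stats::rnorm(steps, 0, wobble))
  ii <- start[1] + cumsum(sin(ang)) * step_px
  jj <- start[2] + cumsum(cos(ang)) * step_px
  ok <- ii >= 1 & ii <= n & jj >= 1 & jj <= n
  cbind(ii[ok], jj[ok])
}

## draw a capillary mesh; returns an intensity matrix in [0, 1]
.capillary_mesh <- function(n, n_walks = 140, intensity = c(0.35, 0.55)) {
  img <- matrix(0, n, n)
  for (w in seq_len(n_walks)) {
    start <- stats::runif(2, 5, n - 4)
    path <- .vessel_path(n, start, stats::runif(1, 0, 2 * pi),
                         steps = sample(40:90, 1))
    if (!nrow(path)) next
    idx <- unique(round(path))
    val <- stats::runif(1, intensity[1], intensity[2])
    img[idx] <- pmax(img[idx], val)
    if (stats::runif(1) < 0.4) {        # some vessels 2 px wide
      idx2 <- idx; idx2[, 2] <- pmin(idx2[, 2] + 1L, n)
      img[idx2] <- pmax(img[idx2], val)
    }
  }
  img
}

## thick bright superficial vessels; returns list(mask, img_overlay)
.large_vessels <- function(n, n_vessels, width_px = c(8, 12)) {
  mask <- matrix(FALSE, n, n)
  for (v in seq_len(n_vessels)) {
    side <- sample(1:4, 1)
    start <- switch(side,
                    c(1, stats::runif(1, 10, n - 10)),
                    c(n, stats::runif(1, 10, n - 10)),
                    c(stats::runif(1, 10, n - 10), 1),
                    c(stats::runif(1, 10, n - 10), n))
    dir0 <- switch(side, pi / 2, -pi / 2, 0, pi) + stats::rnorm(1, 0, 0.3)
    path <- .vessel_path(n, start, dir0, steps = round(n / 1.2),
                         step_px = 2, wobble = 0.06)
    w <- stats::runif(1, width_px[1], width_px[2])
    for (k in seq_len(nrow(path)))
      mask <- .stamp_disc(mask, path[k, 1], path[k, 2], w / 2)
  }
  mask
}

## fill a target zone with round blobs totalling target_px pixels; the last
## blob is trimmed from its rim so the footprint lands on the target. Blobs
## below 10 px are never placed (they would be indistinguishable from
## speckle), so a zone may fall short of its target by up to 9 px.
.blob_fill <- function(zone, target_px, radius_range = c(3, 8)) {
  out <- array(FALSE, dim = dim(zone))
  if (target_px < 10 || !any(zone)) return(out)
  placed <- 0; tries <- 0
  while (placed < target_px - 9 && tries < 400) {
    tries <- tries + 1
    remaining <- target_px - placed
    r <- min(max(sqrt(remaining / pi), radius_range[1]), radius_range[2])
    r <- r * stats::runif(1, 0.85, 1.15)
    avail <- which(zone & !out)
    if (!length(avail)) break
    ctr <- arrayInd(avail[sample.int(length(avail), 1)], dim(zone))
    blob <- .stamp_disc(array(FALSE, dim = dim(zone)), ctr[1], ctr[2], r)
    blob <- blob & zone & !out
    nb <- sum(blob)
    if (nb < 10) next
    if (nb > remaining && remaining >= 10) {
      idx <- which(blob)
      pos <- arrayInd(idx, dim(zone))
      d2 <- (pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2
      blob[] <- FALSE
      blob[idx[order(d2)][seq_len(remaining)]] <- TRUE
      nb <- remaining
    }
    out <- out | blob
    placed <- placed + nb
  }
  out
}

## multiplicative gamma speckle with unit mean and sd = noise_level
.speckle <- function(img, noise_level) {
  if (noise_level <= 0) return(img)
  a <- 1 / noise_level^2
  pmin(pmax(img * stats::rgamma(length(img), shape = a, rate = a), 0), 1)
}

#' Generate one synthetic en-face scene with ground truth
#'
#' Produces an SCP angiogram, a DCP angiogram and a photoreceptor-slab
#' reflectance image of the configured geometry, together with pixel-exact
#' ground-truth masks: nested combined disruption regions
#' (\code{A} = attenuation + IZ loss + EZ loss, \code{B} = IZ loss + EZ loss,
#' \code{C} = EZ loss, with \code{C} in \code{B} in \code{A} exactly), the
#' dilated-vessel telangiectasia footprint, and the SCP large-vessel mask.
#' Telangiectatic vessels are rendered as bright loops of 3-5 px wall width
#' whose filled footprint is the truth mask, so Phansalkar binarization plus
#' hole filling can recover it; the slab is increasingly hypo-reflective over
#' attenuation-only, IZ-loss-only and EZ-loss pixels. All randomness derives
#' from \code{params$seed}; equal seeds give bit-identical scenes.
#'
#' @param params a \code{\link{scene_params}} object.
#' @return list of class \code{octa_scene}: \code{scp}, \code{dcp},
#'   \code{slab} (each an \code{\link{enface_image}}) and \code{truth}, a
#'   list of logical masks (\code{telangiectasia}, \code{scp_large_vessels},
#'   \code{region_combined_A}, \code{region_combined_B}, \code{region_ez_C}).
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  n <- params$grid_size
  s <- params$field_mm / n                 # mm per px
  px <- function(a_mm2) a_mm2 / s^2

  ## sampled per-scene targets (zero-truncated normal, mean-matched); each
  ## disruption class shares one quantile between its area and its overlap
  ## fraction, so eyes with larger class areas also show larger overlaps and
  ## a sampled overlap never outruns the region able to host it
  u_cls <- stats::runif(3)            # ezloss, izloss, attn
  a_ez   <- qtnorm0(u_cls[1], params$target_areas_mm2$ezloss[1], params$target_areas_mm2$ezloss[2])
  a_iz   <- qtnorm0(u_cls[2], params$target_areas_mm2$izloss[1], params$target_areas_mm2$izloss[2])
  a_attn <- qtnorm0(u_cls[3], params$target_areas_mm2$attn[1], params$target_areas_mm2$attn[2])
  a_tel  <- rtnorm0(1, params$telangiectasia_area_mm2[1], params$telangiectasia_area_mm2[2])
  if (a_ez + a_iz + a_attn > params$field_mm^2)
    stop("sampled disruption area exceeds the field")

  ## nested star-shaped regions about a jittered foveal centre
  ctr <- n / 2 + stats::runif(2, -n / 20, n / 20)
  iy <- matrix(seq_len(n), n, n) - ctr[1]
  jx <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr[2]
  dist <- sqrt(iy^2 + jx^2)
  theta <- atan2(iy, jx)

  shC <- .shape_fun(); shB <- .shape_fun(); shA <- .shape_fun()
  stC <- .star_mask(dist, theta, shC, px(a_ez))
  C <- stC$mask
  rC_fun <- function(th) stC$rho * shC(th)
  stB <- .star_shell(dist, theta, rC_fun, shB, px(a_ez) + px(a_iz))
  B <- stB$mask                     # contains C by construction
  rB_fun <- function(th) rC_fun(th) + stB$m * shB(th)
  stA <- .star_shell(dist, theta, rB_fun, shA,
                     px(a_ez) + px(a_iz) + px(a_attn))
  A <- stA$mask                     # contains B by construction

  attn_only <- A & !B
  izloss_only <- B & !C

  ## superficial large vessels (placed first: the DCP signal underneath a
  ## large-vessel projection is not measurable, so no ground-truth
  ## telangiectasia is placed there)
  scp_large <- .large_vessels(n, n_vessels = sample(2:3, 1))
  measurable <- !mask_dilate(scp_large, 2)

  ## telangiectasia footprint split over disruption classes; per-eye
  ## fractions are sampled around the configured means with the cohort SDs
  n_tel <- px(a_tel)
  fr_mean <- unname(params$overlap_fractions[c("attn", "izloss", "ezloss")])
  fr_sd <- unname(params$overlap_fractions_sd[c("attn", "izloss", "ezloss")])
  fr_cal <- .calibrate_overlap_means(fr_mean, fr_sd)
  fr <- .overlap_draw(u_cls[1], u_cls[2], fr_cal, fr_sd)[1, ]
  perifovea <- dist <= n * 0.42
  zones <- list(attn = attn_only & measurable, izloss = izloss_only & measurable,
                ezloss = C & measurable,
                outside = (!A) & perifovea & measurable)
  tgt <- c(fr["attn"], fr["izloss"], fr["ezloss"],
           outside = max(0, 1 - sum(fr))) * n_tel
  tel <- array(FALSE, dim = c(n, n))
  for (z in names(zones)) tel <- tel | .blob_fill(zones[[z]], tgt[[z]])

  ## ---- rendering ----
  dcp <- .capillary_mesh(n)
  if (any(tel)) {
    ## the dilated telangiectatic loops displace the normal mesh in and
    ## immediately around their footprint, as in a tightly marked lesion zone
    dcp[mask_dilate(tel, 3)] <- 0
    wall <- sample(3:5, 1)
    ring <- tel & !mask_erode(tel, wall)
    dcp[ring] <- pmin(stats::runif(sum(ring), 0.72, 0.92), 1)
  }
  dcp <- pmax(dcp, 0.04)
  scp <- pmax(.capillary_mesh(n), 0.04)
  scp[scp_large] <- pmin(stats::runif(sum(scp_large), 0.85, 0.98), 1)

  slab <- matrix(0.7, n, n)
  slab[attn_only] <- 0.55
  slab[izloss_only] <- 0.35
  slab[C] <- 0.15

  nl <- params$noise_level
  out <- list(
    scp = enface_image(.speckle(scp, nl), params$field_mm),
    dcp = enface_image(.speckle(dcp, nl), params$field_mm),
    slab = enface_image(.speckle(slab, nl), params$field_mm),
    truth = list(telangiectasia = tel, scp_large_vessels = scp_large,
                 region_combined_A = A, region_combined_B = B, region_ez_C = C),
    sampled_areas_mm2 = c(tel = a_tel, attn = a_attn, izloss = a_iz, ezloss = a_ez),
    sampled_overlap_fractions = fr,
    params = params)
  class(out) <- "octa_scene"
  out
}

#' @export
print.octa_scene <- function(x, ...) {
  s <- scale_mm_per_px(x$dcp)
  cat(sprintf("<octa_scene> %d px, %.3g mm field, stage group '%s', seed %d\n",
              nrow(x$dcp), x$params$field_mm, x$params$stage_group, x$params$seed))
  cat(sprintf("  truth areas (mm^2): tel %.3f | attn-only %.3f | IZ-loss-only %.3f | EZ %.3f\n",
              area_mm2(x$truth$telangiectasia, s),
              area_mm2(x$truth$region_combined_A & !x$truth$region_combined_B, s),
              area_mm2(x$truth$region_combined_B & !x$truth$region_ez_C, s),
              area_mm2(x$truth$region_ez_C, s)))
  invisible(x)
}

#' Parameters of a synthetic longitudinal pair
#'
#' @param deformation_amplitude_px maximum displacement of the smooth
#'   between-visit warp, in pixels (default 3).
#' @param new_ez_area_mm2 \code{c(mean, sd)} of the total new EZ-loss area at
#'   follow-up (default 0.052/0.022 mm^2).
#' @param recovery_area_mm2 \code{c(mean, sd)} of the EZ-recovery rim area
#'   (default 0.045/0.023 mm^2).
#' @param containment_fraction range \code{c(lo, hi)} (or a single value) of
#'   the fraction of new EZ-loss pixels placed inside the baseline
#'   IZ-loss-only class (default 0.90-0.95).
#' @param seed integer seed.
#' @return list of class \code{longitudinal_params}.
#' @export
longitudinal_params <- function(deformation_amplitude_px = 3,
                                new_ez_area_mm2 = c(0.052, 0.022),
                                recovery_area_mm2 = c(0.045, 0.023),
                                containment_fraction = c(0.90, 0.95),
                                seed = 1) {
  if (length(containment_fraction) == 1)
    containment_fraction <- rep(containment_fraction, 2)
  stopifnot(deformation_amplitude_px >= 0,
            new_ez_area_mm2[1] >= 0, recovery_area_mm2[1] >= 0,
            all(containment_fraction >= 0), all(containment_fraction <= 1),
            containment_fraction[1] <= containment_fraction[2])
  structure(list(deformation_amplitude_px = deformation_amplitude_px,
                 new_ez_area_mm2 = new_ez_area_mm2,
                 recovery_area_mm2 = recovery_area_mm2,
                 containment_fraction = containment_fraction,
                 seed = as.integer(seed)),
            class = "longitudinal_params")
}

## smooth random displacement field: sum of Gaussian bumps, scaled so the
## maximum displacement magnitude equals `amplitude`
.random_smooth_field <- function(n, amplitude, n_bumps = 3) {
  dx <- matrix(0, n, n); dy <- matrix(0, n, n)
  if (amplitude > 0) {
    ii <- matrix(seq_len(n), n, n)
    jj <- matrix(seq_len(n), n, n, byrow = TRUE)
    for (b in seq_len(n_bumps)) {
      c0 <- stats::runif(2, n * 0.25, n * 0.75)
      sg <- stats::runif(1, n / 9, n / 4.5)
      g <- exp(-((ii - c0[1])^2 + (jj - c0[2])^2) / (2 * sg^2))
      amp <- stats::runif(2, -1, 1)
      dy <- dy + amp[1] * g
      dx <- dx + amp[2] * g
    }
    mx <- max(sqrt(dx^2 + dy^2))
    if (mx > 0) { dx <- dx * amplitude / mx; dy <- dy * amplitude / mx }
  }
  deformation_field(dx, dy)
}

#' Generate a synthetic longitudinal pair from a baseline scene
#'
#' The follow-up visit is the baseline scene resampled through a known smooth
#' random displacement field (stored with the pair, together with its
#' numerical inverse, so registration accuracy can be scored against truth).
#' Follow-up EZ loss is the warped baseline EZ loss, plus sampled new-loss
#' blobs of which the sampled containment fraction lies inside the warped
#' baseline IZ-loss-only class, minus a sampled recovery rim peeled from the
#' boundary of established EZ loss. Nesting of the follow-up combined
#' regions is preserved (new EZ loss implies IZ loss).
#'
#' @param scene baseline \code{octa_scene}.
#' @param params a \code{\link{longitudinal_params}} object.
#' @return list of class \code{longitudinal_pair}: \code{baseline},
#'   \code{followup} (images + truth in the follow-up frame), \code{field}
#'   (maps follow-up coordinates to baseline coordinates),
#'   \code{field_inverse} (baseline to follow-up; what registration of the
#'   follow-up onto the baseline should recover), and the true change masks
#'   \code{new_ez_true} / \code{recovery_true} in the follow-up frame.
#' @export
generate_longitudinal <- function(scene, params = longitudinal_params()) {
  stopifnot(inherits(scene, "octa_scene"), inherits(params, "longitudinal_params"))
  set.seed(params$seed)
  n <- nrow(scene$dcp)
  s <- scale_mm_per_px(scene$dcp)
  tr <- scene$truth

  u <- .random_smooth_field(n, params$deformation_amplitude_px)

  wimg <- function(img) enface_image(warp_image(unclass(img), u), attr(img, "field_mm"))
  wm <- function(m) warp_mask(m, u)
  A_w <- wm(tr$region_combined_A); B_w <- wm(tr$region_combined_B)
  C_w <- wm(tr$region_ez_C)
  izonly_w <- B_w & !C_w

  ## sampled change magnitudes
  n_new <- round(rtnorm0(1, params$new_ez_area_mm2[1], params$new_ez_area_mm2[2]) / s^2)
  n_rec <- round(rtnorm0(1, params$recovery_area_mm2[1], params$recovery_area_mm2[2]) / s^2)
  cf <- stats::runif(1, params$containment_fraction[1], params$containment_fraction[2])
  n_inside <- round(cf * n_new)
  if (n_inside > sum(izonly_w))
    stop("new EZ-loss area exceeds available baseline IZ-loss area at the requested containment")

  new_in <- .blob_fill(izonly_w, n_inside, radius_range = c(2.5, 6))
  new_out <- .blob_fill(!B_w & .central_disc(n, 0.45),
                        n_new - n_inside, radius_range = c(2, 5))
  new_ez <- (new_in | new_out) & !C_w

  recovery <- .boundary_rim(C_w, n_rec)

  C_fu <- (C_w | new_ez) & !recovery
  B_fu <- B_w | new_ez            # recovered EZ retains IZ loss
  A_fu <- A_w | new_ez

  followup <- list(
    scp = wimg(scene$scp), dcp = wimg(scene$dcp), slab = wimg(scene$slab),
    truth = list(telangiectasia = wm(tr$telangiectasia),
                 scp_large_vessels = wm(tr$scp_large_vessels),
                 region_combined_A = A_fu, region_combined_B = B_fu,
                 region_ez_C = C_fu))

  structure(list(baseline = scene, followup = followup,
                 field = u, field_inverse = invert_field(u),
                 new_ez_true = new_ez, recovery_true = recovery,
                 containment_sampled = cf, params = params),
            class = "longitudinal_pair")
}

.central_disc <- function(n, frac) {
  iy <- matrix(seq_len(n), n, n) - (n + 1) / 2
  jx <- matrix(seq_len(n), n, n, byrow = TRUE) - (n + 1) / 2
  sqrt(iy^2 + jx^2) <= n * frac
}

## peel `target_px` pixels off the boundary of a mask (innermost last),
## using the distance transform so the rim has even depth
.boundary_rim <- function(mask, target_px) {
  out <- array(FALSE, dim = dim(mask))
  npx <- sum(mask)
  if (target_px <= 0 || npx == 0) return(out)
  if (target_px >= npx) return(as_mask(mask))
  dm <- EBImage::distmap(mask * 1)
  vals <- dm[mask]
  cut <- sort(vals)[target_px]
  sel <- mask & dm <= cut
  ## trim ties beyond the target, deterministically by index order
  over <- sum(sel) - target_px
  if (over > 0) {
    tie_idx <- which(sel & dm == cut)
    sel[tie_idx[seq_len(over)]] <- FALSE
  }
  sel
}

#' @export
print.longitudinal_pair <- function(x, ...) {
  s <- scale_mm_per_px(x$baseline$dcp)
  cat(sprintf("<longitudinal_pair> max warp %.2f px; new EZ loss %.4f mm^2 (containment %.2f); recovery %.4f mm^2\n",
              max(sqrt(x$field$dx^2 + x$field$dy^2)),
              area_mm2(x$new_ez_true, s), x$containment_sampled,
              area_mm2(x$recovery_true, s)))
  invisible(x)
}

#' Generate a synthetic cohort manifest
#'
#' Lays out a cross-sectional cohort with \code{n_per_group} eyes in each
#' pooled severity group (early = stages 0-2, moderate = 3-5, advanced = 6).
#' Eyes are grouped under patients (about two thirds of patients contribute
#' both eyes, which share a patient-level multiplicative effect on the area
#' targets, giving the within-patient correlation the GEE stage adjusts for).
#' Scenes themselves are generated lazily from the returned per-eye
#' \code{scene_params}.
#'
#' @param n_per_group eyes per pooled group (>= 1).
#' @param seed master seed; per-eye seeds derive from it.
#' @param noise_level speckle contrast passed to each scene.
#' @return list with \code{manifest} (data.frame: patient_id, eye_id,
#'   laterality, stage, pooled_group, seed) and \code{scene_params} (list of
#'   per-eye \code{scene_params}).
#' @export
generate_cohort <- function(n_per_group, seed = 1, noise_level = 0.1) {
  stopifnot(n_per_group >= 1)
  set.seed(seed)
  groups <- c("early", "moderate", "advanced")
  stage_pool <- list(early = 0:2, moderate = 3:5, advanced = 6)
  rows <- list(); sps <- list()
  eye_i <- 0; patient_i <- 0
  for (g in groups) {
    left <- n_per_group
    while (left > 0) {
      patient_i <- patient_i + 1
      n_eyes <- if (left >= 2 && stats::runif(1) < 0.65) 2 else 1
      pat_eff <- exp(stats::rnorm(1, -0.15^2 / 2, 0.15))  # unit-mean shared area-scale effect
      lats <- sample(c("OD", "OS"))
      for (e in seq_len(n_eyes)) {
        eye_i <- eye_i + 1
        pool <- stage_pool[[g]]
        stage <- if (length(pool) == 1) pool else sample(pool, 1)
        eseed <- sample.int(.Machine$integer.max - 1L, 1)
        base <- .table3_defaults[[g]]
        sp <- scene_params(
          stage_group = g, seed = eseed, noise_level = noise_level,
          target_areas_mm2 = lapply(base$areas, function(v) c(v[1] * pat_eff, v[2])),
          telangiectasia_area_mm2 = c(base$tel[1] * pat_eff, base$tel[2]))
        rows[[eye_i]] <- data.frame(
          patient_id = sprintf("P%03d", patient_i),
          eye_id = sprintf("E%03d", eye_i), laterality = lats[e],
          stage = stage, pooled_group = g, seed = eseed,
          stringsAsFactors = FALSE)
        sps[[eye_i]] <- sp
      }
      left <- left - n_eyes
    }
  }
  manifest <- do.call(rbind, rows)
  manifest$pooled_group <- factor(manifest$pooled_group,
                                  levels = c("early", "moderate", "advanced"))
  list(manifest = manifest, scene_params = sps)
}
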