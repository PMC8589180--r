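#' EZ change maps between registered visits
#'
#' Given the baseline EZ-loss mask and the follow-up EZ-loss mask already
#' registered into the baseline frame, new loss is follow-up minus baseline
#' and recovery is baseline minus follow-up. An optional minimum component
#' size discards isolated specks (e.g. hairline residues of imperfect
#' registration along region boundaries); the default applies no filtering.
#'
#' @param baseline_ez,followup_ez_reg logical masks in the common
#'   (baseline) frame.
#' @param min_change_px drop 8-connected change components smaller than this
#'   (default 0 = keep everything).
#' @return list with \code{new_loss} and \code{recovery} masks.
#' @export
ez_change <- function(baseline_ez, followup_ez_reg, min_change_px = 0) {
  baseline_ez <- as_mask(baseline_ez); followup_ez_reg <- as_mask(followup_ez_reg)
  check_same_geometry(baseline_ez, followup_ez_reg)
  new_loss <- followup_ez_reg & !baseline_ez
  recovery <- baseline_ez & !followup_ez_reg
  if (min_change_px > 0) {
    new_loss <- remove_small_components(new_loss, min_change_px)
    recovery <- remove_small_components(recovery, min_change_px)
  }
  list(new_loss = new_loss, recovery = recovery)
}

#' Chance-normalized predictive values of baseline IZ loss for new EZ loss
#'
#' Within the analysis domain \eqn{\Omega}, the positive predictive value is
#' the fraction of predictor-positive area (baseline IZ loss) that developed
#' the outcome (new EZ loss); the negative predictive value is the fraction
#' of predictor-negative area that stayed outcome-free. Both are normalized
#' by their chance rates — the outcome prevalence inside \eqn{\Omega} and its
#' complement — giving rPPV = PPV / prevalence and
#' rNPV = NPV / (1 - prevalence); a value of 1 means no better than chance.
#'
#' @param iz_baseline baseline IZ-loss (exclusive class) mask.
#' @param new_ez new EZ-loss mask (intersected with the domain).
#' @param domain analysis domain \eqn{\Omega}, typically the full scan minus
#'   baseline EZ loss (new loss cannot occur where loss already exists); see
#'   \code{\link{pv_domain}}.
#' @return object of class \code{predictive_values}: list with \code{ppv},
#'   \code{npv}, \code{prevalence}, \code{rppv}, \code{rnpv} (proportions;
#'   NA where undefined, e.g. PPV with no IZ loss in the domain, rPPV with
#'   zero prevalence) and the underlying pixel counts.
#' @export
predictive_values <- function(iz_baseline, new_ez, domain) {
  iz <- as_mask(iz_baseline); new_ez <- as_mask(new_ez); dom <- as_mask(domain)
  check_same_geometry(iz, new_ez); check_same_geometry(iz, dom)
  n_dom <- sum(dom)
  if (n_dom == 0) stop("empty analysis domain")
  new_ez <- new_ez & dom
  iz_dom <- iz & dom
  n_iz <- sum(iz_dom)
  n_new <- sum(new_ez)
  prevalence <- n_new / n_dom
  ppv <- if (n_iz > 0) sum(new_ez & iz_dom) / n_iz else NA_real_
  n_neg <- n_dom - n_iz
  npv <- if (n_neg > 0) sum(dom & !iz_dom & !new_ez) / n_neg else NA_real_
  rppv <- if (!is.na(ppv) && prevalence > 0) ppv / prevalence else NA_real_
  rnpv <- if (!is.na(npv) && prevalence < 1) npv / (1 - prevalence) else NA_real_
  structure(list(ppv = ppv, npv = npv, prevalence = prevalence,
                 rppv = rppv, rnpv = rnpv,
                 counts = c(domain = n_dom, iz = n_iz, new_ez = n_new)),
            class = "predictive_values")
}

#' @export
print.predictive_values <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4g", v)
  cat(sprintf("<predictive_values> PPV %s | NPV %s | prevalence %s | rPPV %s | rNPV %s\n",
              fmt(x$ppv), fmt(x$npv), fmt(x$prevalence), fmt(x$rppv), fmt(x$rnpv)))
  invisible(x)
}

#' Analysis domain for predictive values
#'
#' Default domain is the whole scan minus established baseline EZ loss (new
#' loss cannot occur where loss already exists, and pre-existing loss cannot
#' stay "outcome-free"); \code{"full"} uses the whole scan.
#'
#' @param baseline_ez baseline EZ-loss mask.
#' @param type \code{"exclude_baseline_ez"} (default) or \code{"full"}.
#' @return logical domain mask.
#' @export
pv_domain <- function(baseline_ez, type = c("exclude_baseline_ez", "full")) {
  type <- match.arg(type)
  baseline_ez <- as_mask(baseline_ez)
  if (type == "full") array(TRUE, dim = dim(baseline_ez)) else !baseline_ez
}

#' Longitudinal analysis of one baseline/follow-up pair
#'
#' Runs the complete longitudinal chain on a pair: estimate the elastic
#' deformation from the SCP angiograms, transfer the follow-up IZ/EZ regions
#' into the baseline frame, derive the EZ change maps, and compute the
#' predictive values of baseline IZ loss for new EZ loss.
#'
#' @param pair a \code{longitudinal_pair} (or any list with \code{baseline} /
#'   \code{followup} elements holding \code{scp} images and truth masks).
#' @param config \code{\link{register_config}} for the registration stage.
#' @param min_change_px speck filter applied to the change maps (default 8 px,
#'   suppressing hairline registration residue at region boundaries).
#' @param domain_type passed to \code{\link{pv_domain}}.
#' @param use_true_field bypass registration and use the pair's stored true
#'   inverse field (for oracle checks).
#' @return one-row data.frame with per-eye areas (mm^2) of new EZ loss and
#'   recovery, the predictive values, and registration diagnostics
#'   (\code{reg_epe_px}: mean endpoint error versus the stored true field,
#'   if available).
#' @export
analyze_pair <- function(pair, config = register_config(), min_change_px = 8,
                         domain_type = c("exclude_baseline_ez", "full"),
                         use_true_field = FALSE) {
  domain_type <- match.arg(domain_type)
  base_tr <- pair$baseline$truth
  fu_tr <- pair$followup$truth
  s <- scale_mm_per_px(pair$baseline$dcp)

  field <- if (use_true_field) pair$field_inverse else
    register_scp(pair$baseline$scp, pair$followup$scp, config)
  epe <- if (!is.null(pair$field_inverse))
    field_endpoint_error(field, pair$field_inverse) else NA_real_

  fu_ez_reg <- warp_mask(fu_tr$region_ez_C, field)
  chg <- ez_change(base_tr$region_ez_C, fu_ez_reg, min_change_px)
  iz_base <- base_tr$region_combined_B & !base_tr$region_ez_C
  dom <- pv_domain(base_tr$region_ez_C, domain_type)
  pv <- predictive_values(iz_base, chg$new_loss, dom)

  data.frame(new_ez_mm2 = area_mm2(chg$new_loss, s),
             recovery_mm2 = area_mm2(chg$recovery, s),
             baseline_iz_mm2 = area_mm2(iz_base, s),
             baseline_ez_mm2 = area_mm2(base_tr$region_ez_C, s),
             ppv = pv$ppv, npv = pv$npv, prevalence = pv$prevalence,
             rppv = pv$rppv, rnpv = pv$rnpv,
             reg_epe_px = epe)
}
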