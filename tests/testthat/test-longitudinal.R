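test_that("ez_change is exact set arithmetic with optional speck filtering", {
  set.seed(5)
  a <- matrix(runif(625) < 0.4, 25, 25)
  b <- matrix(runif(625) < 0.4, 25, 25)
  chg <- ez_change(a, b)
  expect_identical(chg$new_loss, b & !a)
  expect_identical(chg$recovery, a & !b)

  chg0 <- ez_change(a, a)
  expect_false(any(chg0$new_loss) || any(chg0$recovery))

  sup <- a; sup[1, ] <- TRUE
  chg1 <- ez_change(a, sup)
  expect_false(any(chg1$recovery))
  expect_identical(chg1$new_loss, sup & !a)

  ## a 30-px blob survives the 8-px speck filter, a 2-px speck does not
  base <- matrix(FALSE, 40, 40)
  fu <- base; fu[10:15, 10:14] <- TRUE; fu[30, 30:31] <- TRUE
  chg2 <- ez_change(base, fu, min_change_px = 8)
  expect_equal(sum(chg2$new_loss), 30)
})

test_that("predictive values equal hand counts on a 10x10 grid", {
  dom <- matrix(TRUE, 10, 10)
  iz <- matrix(FALSE, 10, 10); iz[1:3, ] <- TRUE          # 30 px
  new_ez <- matrix(FALSE, 10, 10)
  new_ez[1, 1:3] <- TRUE                                   # 3 px inside iz
  new_ez[8, 1:2] <- TRUE                                   # 2 px outside
  pv <- predictive_values(iz, new_ez, dom)
  expect_equal(pv$ppv, 3 / 30)
  expect_equal(pv$prevalence, 5 / 100)
  expect_equal(pv$npv, 68 / 70)
  expect_equal(pv$rppv, (3 / 30) / (5 / 100))
  expect_equal(pv$rnpv, (68 / 70) / (95 / 100))
  expect_equal(unname(pv$counts), c(100, 30, 5))
})

test_that("a predictor equal to the whole domain is exactly chance", {
  dom <- matrix(TRUE, 20, 20)
  set.seed(2)
  new_ez <- matrix(runif(400) < 0.05, 20, 20)
  pv <- predictive_values(dom, new_ez, dom)
  expect_equal(pv$ppv, pv$prevalence)
  expect_equal(pv$rppv, 1)
})

test_that("contained rare outcomes drive NPV and rNPV to one", {
  dom <- matrix(TRUE, 50, 50)
  iz <- matrix(FALSE, 50, 50); iz[20:30, 20:30] <- TRUE
  new_ez <- matrix(FALSE, 50, 50); new_ez[22:23, 22:23] <- TRUE  # inside iz
  pv <- predictive_values(iz, new_ez, dom)
  expect_equal(pv$npv, 1)
  expect_lt(abs(pv$rnpv - 1), 0.005)
  expect_lte(pv$rnpv, 1 / (1 - pv$prevalence) + 1e-12)
})

test_that("undefined predictive values are NA, empty domains an error", {
  dom <- matrix(TRUE, 10, 10)
  none <- matrix(FALSE, 10, 10)
  pv <- predictive_values(none, none, dom)
  expect_true(is.na(pv$ppv))            # no predictor-positive area
  expect_true(is.na(pv$rppv))           # zero prevalence
  expect_equal(pv$npv, 1)
  expect_error(predictive_values(none, none, none), "empty analysis domain")
})

test_that("pv_domain excludes established EZ loss by default", {
  ez <- disk_mask(50, 10)
  expect_identical(pv_domain(ez), !ez)
  expect_true(all(pv_domain(ez, "full")))
})

test_that("analyze_pair with the true field reproduces generator change areas", {
  sc <- generate_scene(longitudinal_scene_params(seed = 55))
  pair <- generate_longitudinal(sc, longitudinal_params(seed = 56))
  row <- analyze_pair(pair, min_change_px = 0, use_true_field = TRUE)
  s <- scale_mm_per_px(sc$dcp)
  ## with the exact inverse field the recovered change masks are near-exact;
  ## nearest-neighbour round trips leave only boundary slivers
  expect_lt(abs(row$new_ez_mm2 - area_mm2(pair$new_ez_true, s)), 0.01)
  expect_lt(abs(row$recovery_mm2 - area_mm2(pair$recovery_true, s)), 0.01)
  expect_gt(row$rppv, 1)                # far better than chance
  expect_gt(row$npv, 0.99)
})

test_that("mean rPPV rises with the containment of new loss in prior IZ loss", {
  sc <- generate_scene(longitudinal_scene_params(seed = 91))
  mean_rppv <- vapply(c(0.5, 0.75, 0.95), function(cf) {
    vals <- vapply(1:6, function(s) {
      pair <- generate_longitudinal(
        sc, longitudinal_params(containment_fraction = cf, seed = 900 + s))
      analyze_pair(pair, min_change_px = 0, use_true_field = TRUE)$rppv
    }, 0)
    mean(vals)
  }, 0)
  expect_true(all(diff(mean_rppv) > 0))
})
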