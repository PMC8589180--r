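test_that("Spearman correlation handles perfect concordance and reversal", {
  r1 <- spearman_cor(1:10, 1:10)
  expect_equal(r1$rho, 1)
  expect_equal(r1$p_value, 2 / factorial(10))  # identity and reversal only
  r2 <- spearman_cor(1:5, 5:1)
  expect_equal(r2$rho, -1)
})

test_that("Spearman rho and exact p match independent oracles under ties", {
  x <- c(1, 2, 2, 3, 4, 4)
  y <- c(2, 1, 3, 3, 5, 6)
  got <- spearman_cor(x, y)
  expect_equal(got$rho, unname(cor.test(x, y, method = "spearman",
                                        exact = FALSE)$estimate))
  ## enumeration oracle over all 6! permutations of y
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  all_rho <- vapply(perms_of(ry), function(p) cor(rx, p), 0)
  expect_equal(got$p_value, mean(abs(all_rho) >= abs(rho_obs) - 1e-12))
})

test_that("Spearman exact p matches cor.test's exact p without ties", {
  set.seed(8)
  x <- sample(1:7); y <- sample(1:7)
  got <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  x <- rnorm(20); y <- runif(20, 1, 2)
  a <- spearman_cor(x, y)
  b <- spearman_cor(exp(x), y^3)
  expect_equal(a$rho, b$rho)
  expect_equal(a$p_value, b$p_value)
})

test_that("constant vectors give NA correlation with a warning", {
  expect_warning(r <- spearman_cor(rep(1, 6), 1:6), "constant")
  expect_true(is.na(r$rho))
})

test_that("ICC is 1 for duplicated graders and ~0 for independent noise", {
  set.seed(3)
  v <- runif(12)
  expect_equal(icc_agreement(cbind(v, v))$icc, 1)
  noise <- cbind(rnorm(300), rnorm(300))
  expect_lt(abs(icc_agreement(noise)$icc), 0.15)
})

test_that("ICC(2,1) equals the two-way ANOVA oracle on a 6x2 table", {
  m <- rbind(c(9, 2), c(4.5, 4), c(5, 5), c(8, 6), c(7.5, 8), c(6, 7))
  got <- icc_agreement(m)
  ## oracle: mean squares from aov on the long layout
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(1:6, 2)), grader = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subj + grader, d))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  icc_ref <- (MSR - MSE) / (MSR + MSE + (2 / 6) * (MSC - MSE))
  expect_equal(got$icc, icc_ref, tolerance = 1e-12)
  p_ref <- 1 - pf(MSR / MSE, 5, 5)
  expect_equal(got$p_value, p_ref, tolerance = 1e-12)
})

test_that("GEE with singleton clusters equals OLS with HC0 covariance", {
  set.seed(21)
  d <- data.frame(y = rnorm(60), x = rnorm(60),
                  g = factor(sample(c("a", "b", "c"), 60, TRUE)),
                  id = 1:60)
  fit <- gee_gauss(y ~ x + g, d, id = "id")
  ols <- lm(y ~ x + g, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(unname(vcov(fit)),
               unname(sandwich::vcovHC(ols, type = "HC0")), tolerance = 1e-8)
  expect_equal(fit$alpha, 0)
})

test_that("GEE recovers known group means under within-cluster correlation", {
  set.seed(14)
  ncl <- 200
  id <- rep(seq_len(ncl), each = 2)
  g <- factor(rep(rep(c("e", "m", "a"), length.out = ncl), each = 2),
              levels = c("e", "m", "a"))
  mu <- c(e = 0, m = 1, a = 2)[as.character(g)]
  cl_eff <- rep(rnorm(ncl, 0, sqrt(0.5)), each = 2)
  y <- mu + cl_eff + rnorm(2 * ncl, 0, sqrt(0.5))
  d <- data.frame(y = y, g = g, id = id)
  fit <- gee_gauss(y ~ g, d, id = "id")
  se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 0), 2 * se[1])
  expect_lt(abs(coef(fit)[["gm"]] - 1), 2 * se[2])
  expect_lt(abs(coef(fit)[["ga"]] - 2), 2 * se[3])
  expect_lt(abs(fit$alpha - 0.5), 0.15)
  gt <- gee_group_test(d, "y", cluster = "id", group = "g")
  expect_lt(gt$p_value, 0.001)
  expect_equal(gt$df, 2)
})

test_that("singular designs are rejected", {
  d <- data.frame(y = rnorm(10), x = 1, id = 1:10)  # x aliased with intercept
  expect_error(gee_gauss(y ~ x, d, id = "id"), "singular")
})

test_that("gee_group_test applies the Bonferroni factor of three", {
  set.seed(30)
  d <- data.frame(y = rnorm(90), g = factor(rep(c("e", "m", "a"), 30)),
                  id = rep(1:45, each = 2))
  gt <- gee_group_test(d, "y", cluster = "id", group = "g")
  expect_equal(nrow(gt$pairwise), 3)
  expect_equal(gt$pairwise$p_bonferroni, pmin(1, 3 * gt$pairwise$p_raw))
  expect_equal(nrow(gt$group_means), 3)
})

test_that("cross-sectional report assembles correlations and group tables", {
  set.seed(44)
  n <- 24
  stage <- rep(c(0, 1, 3, 4, 6, 6), 4)
  rec <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:12), each = 2),
    eye_id = sprintf("E%02d", 1:n),
    stage = stage,
    pooled_group = as.character(pool_stage(stage)),
    tel_area_mm2 = 0.1 + 0.08 * stage + rnorm(n, 0, 0.02),
    attn_area_mm2 = runif(n, 0.5, 1.2),
    izloss_area_mm2 = 0.1 + 0.1 * stage + rnorm(n, 0, 0.05),
    ezloss_area_mm2 = 0.02 + 0.17 * stage + rnorm(n, 0, 0.05),
    overlap_attn_pct = pmax(50 - 6 * stage + rnorm(n, 0, 5), 0),
    overlap_izloss_pct = runif(n, 5, 25),
    overlap_ezloss_pct = pmin(pmax(2 + 10 * stage + rnorm(n, 0, 5), 0), 100))
  rec$overlap_attn_pct[c(3, 9)] <- NA          # eyes without telangiectasia
  rep_ <- cross_sectional_report(rec)
  expect_equal(nrow(rep_$correlations), 7)
  expect_equal(rep_$correlations$n_missing[5], 2)
  expect_equal(rep_$correlations$n[5], 22)     # pairwise deletion
  expect_gt(rep_$correlations$rho[rep_$correlations$parameter == "ezloss_area_mm2"], 0.8)
  expect_lt(rep_$correlations$rho[rep_$correlations$parameter == "overlap_attn_pct"], -0.5)
  expect_true(all(c("wald_chi2", "gee_p") %in% names(rep_$by_group)))
  expect_equal(nrow(rep_$by_group), 7)

  ## single pooled group: GEE columns absent, with a warning
  solo <- rec[rec$pooled_group == "early", ]
  expect_warning(rep1 <- cross_sectional_report(solo), "single pooled group")
  expect_false("gee_p" %in% names(rep1$by_group))
})
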