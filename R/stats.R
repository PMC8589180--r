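#' Spearman rank correlation with exact small-sample p-value
#'
#' The coefficient is the Pearson correlation of midranks (average ranks for
#' ties), appropriate for ordinal severity stages since it assumes no
#' linearity between increasing stages. Two-tailed p-values use exact
#' enumeration of all permutations for n <= 10 and the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} with n - 2 df above.
#'
#' @param x,y numeric (or ordinal-coded) vectors of equal length, n >= 4;
#'   pairs with missing values are dropped.
#' @param p_method \code{"auto"} (exact for n <= 10), \code{"exact"} or
#'   \code{"approx"}.
#' @return list of class \code{spearman_cor}: \code{rho}, \code{p_value},
#'   \code{n}, \code{p_method}. \code{rho} is NA for a constant vector.
#' @export
spearman_cor <- function(x, y, p_method = c("auto", "exact", "approx")) {
  p_method <- match.arg(p_method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n == length(y))
  if (n < 4) stop("need at least 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant vector: rho undefined")
    return(structure(list(rho = NA_real_, p_value = NA_real_, n = n,
                          p_method = p_method), class = "spearman_cor"))
  }
  rho <- stats::cor(rx, ry)
  exact <- p_method == "exact" || (p_method == "auto" && n <= 10)
  if (exact) {
    p <- .spearman_exact_p(rx, ry, rho)
    used <- "exact"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    used <- "approx"
  }
  structure(list(rho = rho, p_value = min(p, 1), n = n, p_method = used),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.4g (n = %d, %s p-value)\n",
              x$rho, x$p_value, x$n, x$p_method))
  invisible(x)
}

## exact two-tailed permutation p-value for the rank correlation, counting
## permutations of y-ranks whose |rho| reaches the observed one; chunked on
## the first position so memory stays at (n-1)! rows
.spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  mu <- mean(rx) * mean(ry) * n
  denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
  if (n <= 8) {
    perms <- .perm_matrix(n)
    S <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    return(mean(abs((S - mu) / denom) >= abs(rho_obs) - 1e-12))
  }
  sub <- .perm_matrix(n - 1L)
  hits <- 0
  for (i in seq_len(n)) {
    rest <- ry[-i]
    S <- rx[1] * ry[i] +
      as.vector(matrix(rest[sub], nrow(sub)) %*% rx[-1])
    hits <- hits + sum(abs((S - mu) / denom) >= abs(rho_obs) - 1e-12)
  }
  hits / (n * nrow(sub))
}

## all permutations of 1..n as an (n!) x n matrix, lexicographic
.perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .perm_matrix(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

#' Intraclass correlation for two-grader agreement
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC (the
#' standard inter-grader agreement form, ICC(2,1)): from the two-way ANOVA
#' mean squares,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))}
#' with MSR the between-subject, MSC the between-grader and MSE the residual
#' mean square. The p-value is from F = MSR/MSE with (n-1, (n-1)(k-1)) df.
#'
#' @param measurements numeric matrix, subjects in rows, the two graders in
#'   columns (k = 2; n >= 5; no missing cells).
#' @return list of class \code{icc_agreement}: \code{icc}, \code{p_value},
#'   \code{n}, \code{k} and the mean squares. Zero between-subject variance
#'   yields ICC <= 0, reported as computed.
#' @export
icc_agreement <- function(measurements) {
  m <- as.matrix(measurements)
  stopifnot(is.numeric(m), ncol(m) == 2, nrow(m) >= 5, !anyNA(m))
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SSE <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  Fv <- if (MSE > 0) MSR / MSE else Inf
  p <- 1 - stats::pf(Fv, n - 1, (n - 1) * (k - 1))
  structure(list(icc = icc, p_value = p, n = n, k = k,
                 ms = c(MSR = MSR, MSC = MSC, MSE = MSE)),
            class = "icc_agreement")
}

#' @export
print.icc_agreement <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement = %.4f, p = %.4g (n = %d subjects, k = %d)\n",
              x$icc, x$p_value, x$n, x$k))
  invisible(x)
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Generalized estimating equations for a continuous outcome with
#' identity link, accounting for correlated observations within clusters
#' (the two eyes of one patient). The exchangeable correlation parameter is
#' estimated by moment equations from the standardized residual
#' cross-products, the scale by the mean squared residual, and coefficients
#' by iteratively reweighted least squares until the coefficient change is
#' below \code{tol}. Standard errors come from the robust sandwich
#' covariance, so inference is valid even if the working correlation is
#' wrong. With all clusters of size one the fit reduces to ordinary least
#' squares with heteroscedasticity-robust (HC0) covariance.
#'
#' @param formula model formula.
#' @param data data.frame.
#' @param id cluster identifier: a column name in \code{data} or a vector.
#' @param tol convergence tolerance on the coefficient change.
#' @param maxit maximum iterations (error, with the coefficient trace
#'   attached, if exceeded).
#' @return object of class \code{gee_gauss} with the usual accessors
#'   (\code{coef}, \code{vcov}, \code{residuals}, \code{fitted},
#'   \code{print}, \code{summary}).
#' @examples
#' d <- data.frame(y = rnorm(20), g = gl(2, 10), pid = rep(1:10, each = 2))
#' fit <- gee_gauss(y ~ g, d, id = "pid")
#' summary(fit)
#' @export
gee_gauss <- function(formula, data, id, tol = 1e-8, maxit = 100) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  idv <- if (is.character(id) && length(id) == 1) data[[id]] else id
  if (!is.null(attr(mf, "na.action")))
    idv <- idv[-attr(mf, "na.action")]
  idv <- factor(idv)
  N <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("singular design matrix")
  ni <- as.vector(table(idv))

  beta <- stats::lm.fit(X, y)$coefficients
  trace <- list(beta)
  alpha <- 0
  for (it in seq_len(maxit)) {
    e <- y - as.vector(X %*% beta)
    phi <- sum(e^2) / (N - p)
    se_c <- as.vector(rowsum(e, idv))
    se2_c <- as.vector(rowsum(e^2, idv))
    npairs <- sum(ni * (ni - 1) / 2)
    alpha <- if (npairs > 0)
      sum((se_c^2 - se2_c) / 2) / (phi * max(npairs - p, 1)) else 0
    alpha <- max(min(alpha, 0.95), -0.95 / max(max(ni) - 1, 1))
    gam <- alpha / (1 + (ni - 1) * alpha)
    Sx <- rowsum(X, idv)                          # cluster sums of rows of X
    Sy <- as.vector(rowsum(y, idv))
    A <- (crossprod(X) - crossprod(Sx, gam * Sx)) / (phi * (1 - alpha))
    b <- (crossprod(X, y) - crossprod(Sx, gam * Sy)) / (phi * (1 - alpha))
    beta_new <- solve(A, b)[, 1]
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    trace[[length(trace) + 1]] <- beta
    if (delta < tol) break
    if (it == maxit) {
      cond <- simpleError(sprintf("GEE did not converge in %d iterations", maxit))
      cond$trace <- do.call(rbind, trace)
      stop(cond)
    }
  }
  e <- y - as.vector(X %*% beta)
  gam <- alpha / (1 + (ni - 1) * alpha)
  Sx <- rowsum(X, idv)
  se_c <- as.vector(rowsum(e, idv))
  Xe <- rowsum(X * e, idv)
  Mi <- (Xe - (gam * se_c) * Sx) / (phi * (1 - alpha))
  A <- (crossprod(X) - crossprod(Sx, gam * Sx)) / (phi * (1 - alpha))
  Ainv <- solve(A)
  V <- Ainv %*% crossprod(Mi) %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  structure(list(coefficients = stats::setNames(beta, colnames(X)),
                 vcov = V, alpha = alpha, phi = phi,
                 n = N, n_clusters = nlevels(idv), iterations = it,
                 residuals = e, fitted = as.vector(X %*% beta),
                 formula = formula, call = match.call()),
            class = "gee_gauss")
}

#' @export
coef.gee_gauss <- function(object, ...) object$coefficients

#' @export
vcov.gee_gauss <- function(object, ...) object$vcov

#' @export
residuals.gee_gauss <- function(object, ...) object$residuals

#' @export
fitted.gee_gauss <- function(object, ...) object$fitted

#' @export
print.gee_gauss <- function(x, ...) {
  cat("Gaussian GEE, exchangeable working correlation\n")
  cat(sprintf("  %d observations in %d clusters; alpha = %.3f, scale = %.4g\n",
              x$n, x$n_clusters, x$alpha, x$phi))
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.gee_gauss <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- cbind(Estimate = object$coefficients, `Robust SE` = se,
               z = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab), class = "summary.gee_gauss")
}

#' @export
print.summary.gee_gauss <- function(x, ...) {
  print(x$fit)
  cat("\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' Wald test for a linear hypothesis on a GEE fit
#'
#' @param fit a \code{gee_gauss} object.
#' @param L contrast matrix (rows = hypotheses on the coefficients).
#' @return list with \code{wald_chi2}, \code{df}, \code{p_value}.
#' @export
gee_wald <- function(fit, L) {
  L <- rbind(L)
  est <- as.vector(L %*% coef(fit))
  W <- as.numeric(t(est) %*% solve(L %*% vcov(fit) %*% t(L)) %*% est)
  df <- nrow(L)
  list(wald_chi2 = W, df = df, p_value = 1 - stats::pchisq(W, df))
}

#' Pooled-group comparison of an outcome via GEE
#'
#' Fits a Gaussian GEE of the outcome on the three pooled severity groups
#' with clustering on patient, tests the overall group effect with a Wald
#' chi-square on 2 df, and reports the three pairwise contrasts with
#' Bonferroni adjustment (adjusted p = min(1, 3 raw p)). Group means and
#' robust standard errors come from the fitted model.
#'
#' @param records data.frame of per-eye records (see
#'   \code{\link{eye_record}}).
#' @param outcome column name of the numeric outcome.
#' @param cluster column name of the cluster id (default
#'   \code{"patient_id"}).
#' @param group column name of the pooled group factor (default
#'   \code{"pooled_group"}).
#' @return list of class \code{gee_group_test}: \code{wald_chi2}, \code{df},
#'   \code{p_value}, \code{group_means} (mean, robust SE per group),
#'   \code{pairwise} (estimate, raw and Bonferroni-adjusted p), \code{fit}.
#' @export
gee_group_test <- function(records, outcome, cluster = "patient_id",
                           group = "pooled_group") {
  d <- records[stats::complete.cases(records[[outcome]]), , drop = FALSE]
  g <- factor(d[[group]])
  if (nlevels(droplevels(g)) < 2) stop("need at least 2 groups")
  d$..g <- droplevels(g)
  d$..y <- d[[outcome]]
  fit <- gee_gauss(..y ~ ..g, d, id = cluster)
  lev <- levels(d$..g)
  p <- length(coef(fit))
  Lgrp <- cbind(0, diag(p - 1))
  wald <- gee_wald(fit, Lgrp)
  ## group means: intercept + group effect
  Cm <- cbind(1, rbind(0, diag(p - 1)))
  mu <- as.vector(Cm %*% coef(fit))
  mu_se <- sqrt(diag(Cm %*% vcov(fit) %*% t(Cm)))
  means <- data.frame(group = lev, mean = mu, robust_se = mu_se)
  ## pairwise contrasts between all group pairs
  pairs <- utils::combn(seq_along(lev), 2)
  ctr <- t(apply(pairs, 2, function(ij) Cm[ij[2], ] - Cm[ij[1], ]))
  est <- as.vector(ctr %*% coef(fit))
  se <- sqrt(diag(ctr %*% vcov(fit) %*% t(ctr)))
  praw <- 2 * stats::pnorm(-abs(est / se))
  pw <- data.frame(contrast = apply(pairs, 2, function(ij)
                     paste(lev[ij[2]], "-", lev[ij[1]])),
                   estimate = est, robust_se = se, p_raw = praw,
                   p_bonferroni = pmin(1, length(praw) * praw))
  structure(list(wald_chi2 = wald$wald_chi2, df = wald$df,
                 p_value = wald$p_value, group_means = means,
                 pairwise = pw, fit = fit),
            class = "gee_group_test")
}

#' @export
print.gee_group_test <- function(x, ...) {
  cat(sprintf("GEE group test: Wald chi2 = %.3f on %d df, p = %.4g\n",
              x$wald_chi2, x$df, x$p_value))
  print(x$group_means, row.names = FALSE)
  cat("Pairwise (Bonferroni-adjusted):\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

.report_params <- c("tel_area_mm2", "attn_area_mm2", "izloss_area_mm2",
                    "ezloss_area_mm2", "overlap_attn_pct",
                    "overlap_izloss_pct", "overlap_ezloss_pct")

#' Cross-sectional report: stage correlations and by-group comparisons
#'
#' For each of the seven imaging parameters (telangiectasia area, the three
#' exclusive disruption-class areas, and the three percent overlaps) this
#' computes (i) the Spearman correlation with the ordinal severity stage and
#' (ii) pooled-group means with SD and the GEE Wald p-value plus
#' Bonferroni-adjusted pairwise contrasts. Eyes with undefined overlap (no
#' telangiectasia) are dropped pairwise, and the dropped count is recorded.
#'
#' @param records data.frame of per-eye records (>= 4 eyes).
#' @return list of class \code{cross_sectional_report}: \code{correlations},
#'   \code{by_group}, \code{pairwise} data.frames. If only one pooled group
#'   is present the GEE columns are absent, with a warning.
#' @export
cross_sectional_report <- function(records) {
  stopifnot(nrow(records) >= 4)
  grp <- factor(records$pooled_group, levels = c("early", "moderate", "advanced"))
  multi_group <- nlevels(droplevels(grp)) >= 2
  if (!multi_group)
    warning("single pooled group: GEE by-group comparison not computed")
  cors <- list(); bygrp <- list(); pws <- list()
  for (par in .report_params) {
    v <- records[[par]]
    n_missing <- sum(is.na(v))
    sc <- tryCatch(spearman_cor(records$stage, v),
                   warning = function(w) list(rho = NA, p_value = NA,
                                              n = sum(!is.na(v))))
    cors[[par]] <- data.frame(parameter = par, rho = sc$rho,
                              p_value = sc$p_value, n = sc$n,
                              n_missing = n_missing)
    means <- tapply(v, grp, mean, na.rm = TRUE)
    sds <- tapply(v, grp, stats::sd, na.rm = TRUE)
    row <- data.frame(parameter = par,
                      early_mean = means[["early"]], early_sd = sds[["early"]],
                      moderate_mean = means[["moderate"]], moderate_sd = sds[["moderate"]],
                      advanced_mean = means[["advanced"]], advanced_sd = sds[["advanced"]])
    if (multi_group) {
      gt <- tryCatch(gee_group_test(records, par), error = function(e) NULL)
      row$wald_chi2 <- if (is.null(gt)) NA_real_ else gt$wald_chi2
      row$gee_p <- if (is.null(gt)) NA_real_ else gt$p_value
      if (!is.null(gt)) {
        pwp <- gt$pairwise
        pwp$parameter <- par
        pws[[par]] <- pwp
      }
    }
    bygrp[[par]] <- row
  }
  structure(list(correlations = do.call(rbind, c(cors, make.row.names = FALSE)),
                 by_group = do.call(rbind, c(bygrp, make.row.names = FALSE)),
                 pairwise = if (length(pws))
                   do.call(rbind, c(pws, make.row.names = FALSE)) else NULL),
            class = "cross_sectional_report")
}

#' @export
print.cross_sectional_report <- function(x, ...) {
  cat("Stage correlations (Spearman):\n")
  print(x$correlations, row.names = FALSE, digits = 3)
  cat("\nBy pooled group:\n")
  print(x$by_group, row.names = FALSE, digits = 3)
  invisible(x)
}
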