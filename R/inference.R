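#' Normality-gated choice between parametric and non-parametric tests
#'
#' Every group comparison and correlation in the pipeline routes through
#' this gate: each sample is submitted to a Shapiro-Wilk test, and if any
#' sample rejects normality at `alpha` the non-parametric branch is taken.
#' A constant sample (for which Shapiro-Wilk is undefined) is classified
#' as non-normal.
#'
#' @param x numeric sample
#' @param y optional second sample
#' @param alpha gate significance level (default 0.05)
#' @return list with `route` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (one p per sample; `NA` for constant samples)
#' @export
normality_gate <- function(x, y = NULL, alpha = 0.05) {
  samples <- if (is.null(y)) list(x) else list(x, y)
  ps <- vapply(samples, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3) stop("normality gate needs n >= 3 per sample")
    if (stats::sd(v) == 0) return(NA_real_)  # degenerate: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  nonpar <- any(is.na(ps) | ps < alpha)
  list(route = if (nonpar) "nonparametric" else "parametric",
       shapiro_p = ps)
}

#' Cohen's d from group summaries
#'
#' Pooled-SD standardised mean difference:
#' \deqn{d = (m_1 - m_2) / s_p, \quad
#'   s_p = \sqrt{\frac{(n_1-1)s_1^2 + (n_2-1)s_2^2}{n_1+n_2-2}}.}
#' By convention 0.2-0.3 is a small, 0.5 a medium and >= 0.8 a large
#' effect.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1
#' @param m2,sd2,n2 mean, SD and size of group 2
#' @return signed Cohen's d (antisymmetric in the two groups)
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  (m1 - m2) / sp
}

# tie-corrected Mann-Whitney U with signed z (direction: group1 ranks high
# => z > 0); the degenerate all-tied case has zero variance and is defined
# as z = 0, p = 1
mann_whitney_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(list(u = u1, z = 0, p = 1))
  z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
  list(u = u1, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Normality-gated two-group comparison
#'
#' Applies the Shapiro-Wilk gate to both samples, then either a
#' pooled-variance two-sample t test (parametric route) or a Mann-Whitney
#' U test with tie-corrected normal approximation and signed z
#' (non-parametric route). Cohen's d (pooled SD) is reported whenever the
#' null is rejected at `alpha`, and always stored in the object.
#'
#' @param x,y the two samples, in (group1, group2) order
#' @param labels group labels for printing
#' @param alpha significance level for the gate and the rejection rule
#' @param gate_alpha optional separate alpha for the normality gate
#' @return object of class `group_comparison`: fields `test`, `statistic`
#'   (t or z), `u` (Mann-Whitney U, non-parametric route only), `df`, `p`,
#'   `effect_size_d`, `rejected`, `gate`, `means`, `sds`, `n`
#' @export
compare_groups <- function(x, y, labels = c("group1", "group2"),
                           alpha = 0.05, gate_alpha = alpha) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3) stop("need n >= 3 per group")
  gate <- normality_gate(x, y, alpha = gate_alpha)
  d <- cohens_d(mean(x), max(stats::sd(x), .Machine$double.eps),
                length(x),
                mean(y), max(stats::sd(y), .Machine$double.eps),
                length(y))
  if (gate$route == "parametric") {
    tt <- stats::t.test(x, y, var.equal = TRUE)
    res <- list(test = "t_two_sample", statistic = unname(tt$statistic),
                u = NA_real_, df = unname(tt$parameter),
                p = tt$p.value)
  } else {
    mw <- mann_whitney_z(x, y)
    res <- list(test = "mann_whitney", statistic = mw$z, u = mw$u,
                df = NA_real_, p = mw$p)
  }
  res$rejected <- res$p < alpha
  res$effect_size_d <- d
  res$gate <- gate
  res$means <- c(mean(x), mean(y))
  res$sds <- c(stats::sd(x), stats::sd(y))
  res$n <- c(length(x), length(y))
  res$labels <- labels
  res$alpha <- alpha
  structure(res, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  lab <- if (x$test == "t_two_sample") {
    sprintf("t(%g) = %.2f", x$df, x$statistic)
  } else {
    sprintf("z = %.2f (U = %g)", x$statistic, x$u)
  }
  cat(sprintf("%s vs %s: %s, %s, p = %.3g%s\n",
              x$labels[1], x$labels[2],
              if (x$test == "t_two_sample") "two-sample t" else
                "Mann-Whitney U",
              lab, x$p,
              if (x$rejected) sprintf(", d = %.2f", x$effect_size_d) else ""))
  invisible(x)
}

#' Normality-gated one-sample comparison against a null value
#'
#' One-sample t test when the sample passes the Shapiro-Wilk gate,
#' Wilcoxon signed-rank test otherwise.
#'
#' @param x numeric sample
#' @param mu null value (default 0)
#' @param alpha significance level for the gate
#' @return list: `test` (`t_one_sample` or `wilcoxon_signed`),
#'   `statistic`, `df`, `p`, `gate`
#' @export
compare_one_sample <- function(x, mu = 0, alpha = 0.05) {
  gate <- normality_gate(x, alpha = alpha)
  if (gate$route == "parametric") {
    tt <- stats::t.test(x, mu = mu)
    list(test = "t_one_sample", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, gate = gate)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, mu = mu, exact = FALSE))
    list(test = "wilcoxon_signed", statistic = unname(wt$statistic),
         df = NA_real_, p = wt$p.value, gate = gate)
  }
}

#' Normality-gated correlation
#'
#' Pearson when both variables pass the Shapiro-Wilk gate, Spearman
#' otherwise (or force a method). Two-sided p; Spearman p uses the
#' t-approximation (ties make the exact distribution unavailable).
#'
#' @param x,y numeric vectors of equal length (n >= 4)
#' @param method `"auto"` (gated), `"pearson"`, or `"spearman"`
#' @param alpha gate level
#' @return list: `r`, `p`, `method`
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman"),
                      alpha = 0.05) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 4) stop("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined")
  }
  if (method == "auto") {
    gate <- normality_gate(x, y, alpha = alpha)
    method <- if (gate$route == "parametric") "pearson" else "spearman"
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method)
}

#' Spearman rank partial correlation
#'
#' Rank-transforms all variables, residualises x and y on the covariate
#' ranks by least squares, and Pearson-correlates the residuals. With no
#' covariates this reduces exactly to the Spearman correlation. The p
#' value uses the t approximation with n - 2 - k degrees of freedom for k
#' covariates.
#'
#' @param x,y numeric vectors
#' @param covariates numeric vector, matrix or data.frame of covariates
#'   (NULL for none)
#' @return list: `r`, `p`, `df`, `n_covariates`
#' @export
rank_partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates) || (is.matrix(covariates) && !ncol(covariates))) {
    k <- 0L
    rx <- rank(x); ry <- rank(y)
  } else {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != n) stop("covariates must match x in length")
    k <- ncol(cv)
    if (n <= k + 3) stop("need n > k + 3 observations")
    rcv <- apply(cv, 2, rank)
    if (qr(cbind(1, rcv))$rank < k + 1) stop("collinear covariates")
    resid_on <- function(v) stats::lm.fit(cbind(1, rcv), v)$residuals
    rx <- resid_on(rank(x))
    ry <- resid_on(rank(y))
  }
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("constant (or fully explained) vector: correlation undefined")
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df, n_covariates = k)
}

#' Covariate-adjusted group comparison (ANCOVA-style)
#'
#' Fits `value ~ group + covariate` by least squares and reports the t
#' test on the group coefficient. A constant covariate is dropped by the
#' fit, in which case the result equals the plain pooled-variance
#' two-sample t test.
#'
#' @param values numeric outcomes
#' @param group two-level grouping vector
#' @param covariate numeric covariate (vector or matrix)
#' @return list: `estimate` (group effect), `t`, `df`, `p`, `coefficients`
#' @export
covariate_adjusted_group_test <- function(values, group, covariate) {
  group <- factor(group)
  if (nlevels(group) != 2) stop("group must have exactly two levels")
  dat <- data.frame(values = values, group = group)
  cv <- as.matrix(as.data.frame(covariate))
  colnames(cv) <- paste0("cov", seq_len(ncol(cv)))
  dat <- cbind(dat, cv)
  fm <- stats::as.formula(paste("values ~ group +",
                                paste(colnames(cv), collapse = " + ")))
  fit <- stats::lm(fm, data = dat)
  sm <- summary(fit)$coefficients
  row <- grep("^group", rownames(sm))
  if (!length(row)) stop("rank-deficient fit: group effect not estimable")
  list(estimate = sm[row, 1], t = sm[row, 3], df = fit$df.residual,
       p = sm[row, 4], coefficients = stats::coef(fit))
}
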