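zscore <- function(v) (v - mean(v)) / sd(v)

test_that("orthogonal regressors recover an exact unit coefficient", {
  n <- 64
  X <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))        # orthonormal columns
  X <- apply(X, 2, zscore)
  colnames(X) <- c("a", "b", "c")
  beta <- fit_rdm_regression(X[, "a"], X)
  expect_equal(unname(beta["a"]), 1, tolerance = 1e-10)
  expect_equal(unname(beta["b"]), 0, tolerance = 1e-10)
  expect_equal(unname(beta["c"]), 0, tolerance = 1e-10)
})

test_that("coefficients equal the normal-equations oracle", {
  set.seed(91)
  for (rep in 1:20) {
    X <- matrix(rnorm(50 * 3), 50, 3)
    y <- rnorm(50)
    beta <- fit_rdm_regression(y, X)
    M <- cbind(1, X)
    oracle <- solve(t(M) %*% M, t(M) %*% y)[-1]
    expect_equal(unname(beta), as.numeric(oracle), tolerance = 1e-10)
  }
})

test_that("rank deficiency errors naming the collinear column", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  X <- cbind(X, c = X[, "a"] + X[, "b"])
  expect_error(fit_rdm_regression(rnorm(20), X), "collinear")
  expect_error(fit_rdm_regression(rnorm(19), X), "nrow")
})

test_that("scaling the dependent vector scales all coefficients", {
  set.seed(92)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- rnorm(40)
  b1 <- fit_rdm_regression(y, X)
  b2 <- fit_rdm_regression(3.7 * y, X)
  expect_equal(b2, 3.7 * b1, tolerance = 1e-10)
})

test_that("permutation p is minimal for a self-predicting regressor and
           near one for its negation", {
  set.seed(93)
  X <- apply(matrix(rnorm(200 * 2), 200, 2), 2, zscore)
  colnames(X) <- c("signal", "other")
  res <- permutation_test(X[, "signal"], X, n_perm = 1000, seed = 5)
  expect_lte(res$p_perm["signal"], 1 / 1000)
  res_neg <- permutation_test(-X[, "signal"], X, n_perm = 1000, seed = 5)
  expect_gte(res_neg$p_perm["signal"], 0.99)
})

test_that("permutation p equals a replayed shuffle-by-shuffle oracle", {
  set.seed(94)
  n <- 30
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  dv <- 0.4 * X[, "a"] + rnorm(n)
  res <- permutation_test(dv, X, n_perm = 100, seed = 7)
  # replay the identical seeded shuffle stream and refit with lm()
  set.seed(7)
  idx <- replicate(100, sample.int(n))
  obs <- coef(lm(dv ~ X))[-1]
  counts <- c(a = 0, b = 0)
  for (k in 1:100) {
    bk <- coef(lm(dv[idx[, k]] ~ X))[-1]
    counts <- counts + (bk >= obs)
  }
  expect_equal(unname(res$p_perm), unname(counts / 100))
  expect_equal(unname(res$p_smooth), unname((counts + 1) / 101))
  expect_error(permutation_test(dv, X, n_perm = 50), "100")
})

test_that("permutation inference is bit-reproducible under one seed", {
  co <- small_cohort()
  nr <- neural_rdm(co$patterns$NT02$BA1)
  reg <- build_regressors(co$design, "general")
  f1 <- rsa_regression(nr, reg, n_perm = 150, seed = 99)
  f2 <- rsa_regression(nr, reg, n_perm = 150, seed = 99)
  expect_identical(f1$betas, f2$betas)
  expect_identical(f1$p_perm, f2$p_perm)
})

test_that("BH correction matches the brute-force step-up definition", {
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- sapply(seq_len(m), function(i) {
      min(sapply(i:m, function(j) m * p[o][j] / j), 1)
    })
    q <- numeric(m)
    q[o] <- q_sorted
    q
  }
  expect_equal(fdr_correct(0.037), 0.037)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(95)
  for (rep in 1:50) {
    p <- runif(sample(3:12, 1))^sample(1:3, 1)
    q <- fdr_correct(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    perm <- sample(length(p))
    expect_equal(fdr_correct(p[perm]), q[perm], tolerance = 1e-12)
  }
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the fitted model object supports the standard accessors", {
  co <- small_cohort()
  nr <- neural_rdm(co$patterns$NT03$TPJ)
  reg <- build_regressors(co$design, "general")
  fit <- rsa_regression(nr, reg, n_perm = 120, seed = 3, roi = "TPJ")
  expect_s3_class(fit, "rsa_regression")
  expect_named(coef(fit), reg$names)
  expect_equal(length(fitted(fit)), 2775)
  expect_equal(fitted(fit) + residuals(fit), fit$dv, tolerance = 1e-12)
  expect_equal(predict(fit, reg), fitted(fit), tolerance = 1e-10)
  sm <- summary(fit)
  expect_true(all(c("regressor", "beta", "p_perm", "fdr_q") %in% names(sm)))
  expect_output(print(fit), "RSA multiple regression")
})

test_that("noise ceilings are exact for clones and honour the exclusion
           contract", {
  co <- small_cohort()
  base <- neural_rdm(co$patterns$NT01$BA1)
  clones <- list(a = base, b = base, c = base, d = base)
  nc <- noise_ceiling(clones)
  expect_true(all(nc$per_subject$r == 1))

  others <- lapply(sprintf("NT%02d", 2:4), function(s)
    neural_rdm(co$patterns[[s]]$BA1))
  rdms <- c(list(base), others)
  names(rdms) <- sprintf("NT%02d", 1:4)
  nc1 <- noise_ceiling(rdms)
  # subject 1's reference excludes subject 1, so rescaling subject 1's own
  # RDM (Pearson is scale-invariant) leaves subject 1's LOSO r unchanged,
  # even though every other subject's reference now differs
  rdms2 <- rdms
  rdms2$NT01 <- rdm(rdms$NT01$values * 2, labels = rdms$NT01$labels,
                    kind = "neural")
  nc2 <- noise_ceiling(rdms2)
  expect_equal(nc2$per_subject$r[1], nc1$per_subject$r[1],
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(nc2$per_subject$r[-1],
                                nc1$per_subject$r[-1],
                                tolerance = 1e-12)))
})

test_that("independent-noise subjects have near-zero ceilings and two-group
           input yields a gated comparison", {
  set.seed(96)
  mk <- function() {
    m <- matrix(rnorm(30 * 20), 30, 20,
                dimnames = list(paste0("s", 1:30), NULL))
    neural_rdm(m)
  }
  rdms <- replicate(10, mk(), simplify = FALSE)
  names(rdms) <- paste0("S", 1:10)
  nc <- noise_ceiling(rdms, groups = rep(c("A", "B"), each = 5))
  expect_lt(max(abs(nc$per_subject$r)), 0.5)
  expect_s3_class(nc$comparison, "group_comparison")
  expect_equal(nrow(nc$summary), 2)
})
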