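#' Build the regressor matrix of z-scored model-RDM vectors
#'
#' Assembles the design matrix of the RSA regression: one column per
#' candidate model RDM, each vectorised (row-major upper triangle) and
#' z-scored, rows aligned to the dependent RDM's upper-triangle order.
#'
#' Two standard models are provided. The `general` model predicts the
#' full-design ("general touch") RDM from the binary social/non-social
#' model, the motor-response model, the three physical-feature models and
#' the action-type model. The `social` model predicts the social-stimuli
#' RDM, replacing the binary social model by the group's affective
#' dissimilarity matrix (see [affect_dissimilarity()]).
#'
#' @param design stimulus design table
#' @param model `"general"` or `"social"`
#' @param affect an affect [rdm()] over the social stimuli (required for
#'   the social model)
#' @param stimuli stimulus ids the dependent RDM is defined on; defaults
#'   to the full design (`general`) or the social stimuli (`social`)
#' @return a `regressor_set`: list with `names`, `stimuli`, and the
#'   column matrix `X` of z-scored model vectors
#' @export
build_regressors <- function(design, model = c("general", "social"),
                             affect = NULL, stimuli = NULL) {
  model <- match.arg(model)
  validate_design(design)
  if (is.null(stimuli)) {
    stimuli <- if (model == "general") design$stimulus_id else
      social_ids(design)
  }
  stimuli <- as.character(stimuli)
  sub <- function(r) subset_rdm(r, stimuli)

  mods <- list()
  if (model == "general") {
    mods$social <- sub(model_rdm_binary(design))
  } else {
    if (is.null(affect)) stop("the social model requires an affect RDM")
    stopifnot(is_rdm(affect))
    mods$affect <- sub(affect)
  }
  mods$motor_response <- sub(model_rdm_features(design, "motor_response",
                                                metric = "binary"))
  mods$intensity <- sub(model_rdm_features(design, "intensity"))
  mods$motion_energy_pixel <-
    sub(model_rdm_features(design, "motion_energy_pixel"))
  mods$motion_energy_total <-
    sub(model_rdm_features(design, "motion_energy_total"))
  mods$action_type <- sub(model_rdm_features(design, "action_type",
                                             metric = "binary"))

  X <- vapply(mods, vectorize_z, numeric(length(stimuli) *
                                           (length(stimuli) - 1) / 2))
  structure(list(names = names(mods), stimuli = stimuli, X = X),
            class = "regressor_set")
}

#' Ordinary least-squares fit of an RDM vector on model vectors
#'
#' Fits `dv ~ intercept + X` and returns the slope coefficients in
#' regressor order. The design must be full column rank; a rank-deficient
#' fit errors naming the collinear columns rather than silently dropping
#' them.
#'
#' @param dv z-scored dependent RDM vector
#' @param X numeric matrix of regressor columns (or a `regressor_set`)
#' @param intercept include an intercept (default TRUE; with z-scored
#'   inputs it is ~0 but is kept for generality)
#' @return named numeric vector of slope coefficients
#' @export
fit_rdm_regression <- function(dv, X, intercept = TRUE) {
  if (inherits(X, "regressor_set")) X <- X$X
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(dv) != nrow(X)) {
    stop("length(dv) = ", length(dv), " but nrow(X) = ", nrow(X))
  }
  M <- if (intercept) cbind(`(Intercept)` = 1, X) else X
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M)) {
    dropped <- colnames(M)[qr_m$pivot[seq(qr_m$rank + 1, ncol(M))]]
    stop("rank-deficient regressor matrix; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qr_m, dv)
  if (intercept) beta <- beta[-1]
  beta
}

#' Permutation test for RSA regression coefficients
#'
#' Builds the null by randomly shuffling the entries of the dependent
#' vector and refitting the full regression; the same shuffled vector is
#' used for all regressors within an iteration. For each regressor the
#' empirical p is the fraction of permutations whose coefficient is
#' greater than or equal to the observed one (one-sided, beta > 0; the
#' two-sided variant counts `|beta|` exceedances). This count rule can
#' return p = 0, which is reported as such (printed "p < 1/n_perm"); the
#' add-one smoothed value (count + 1)/(n_perm + 1) is stored alongside
#' for downstream use.
#'
#' @param dv z-scored dependent RDM vector
#' @param X regressor matrix or `regressor_set`
#' @param n_perm number of permutations (>= 100; default 1000)
#' @param seed integer seed; the permutation stream is fully reproducible
#' @param alternative `"greater"` (default, matching the count rule) or
#'   `"two.sided"`
#' @param intercept passed to the fit
#' @return list: `betas` (observed), `p_perm` (count/n_perm), `p_smooth`
#'   ((count+1)/(n_perm+1)), `n_perm`, `seed`, `alternative`
#' @export
permutation_test <- function(dv, X, n_perm = 1000, seed = 1,
                             alternative = c("greater", "two.sided"),
                             intercept = TRUE) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (inherits(X, "regressor_set")) X <- X$X
  X <- as.matrix(X)
  obs <- fit_rdm_regression(dv, X, intercept = intercept)
  n <- length(dv)
  M <- if (intercept) cbind(1, X) else X
  qr_m <- qr(M)
  local_seed(seed, {
    idx <- replicate(n_perm, sample.int(n))
  })
  DV <- matrix(dv[idx], nrow = n)           # one shuffled dv per column
  B <- qr.coef(qr_m, DV)                    # all permuted fits at once
  if (intercept) B <- B[-1, , drop = FALSE]
  counts <- if (alternative == "greater") {
    rowSums(B >= obs)
  } else {
    rowSums(abs(B) >= abs(obs))
  }
  list(betas = obs,
       p_perm = stats::setNames(counts / n_perm, names(obs)),
       p_smooth = stats::setNames((counts + 1) / (n_perm + 1), names(obs)),
       n_perm = n_perm, seed = seed, alternative = alternative)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p values (monotone, capped at 1). A thin, validated
#' front over `p.adjust(method = "BH")` so every q value in the pipeline
#' flows through one audited entry point.
#'
#' @param p numeric vector of p values in \[0, 1\]
#' @return vector of q values, same order as the input
#' @export
fdr_correct <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Multiple-regression representational similarity analysis
#'
#' The package's core model: the vectorised, z-scored upper triangle of a
#' (typically group-average) neural RDM is regressed on a set of z-scored
#' model-RDM vectors by ordinary least squares; each coefficient indexes
#' that model's independent contribution to the neural dissimilarity
#' structure. Inference is by a one-sided permutation test (shuffle the
#' neural vector, refit, count coefficient exceedances) with
#' Benjamini-Hochberg FDR correction across the regressors.
#'
#' @param dv a neural [rdm()], or an already z-scored upper-triangle
#'   vector
#' @param regressors a `regressor_set` from [build_regressors()], or a
#'   plain column matrix of z-scored model vectors
#' @param n_perm permutations for the null (default 1000); 0 skips
#'   inference and returns coefficients only
#' @param seed integer seed for the permutation stream
#' @param alternative `"greater"` (default) or `"two.sided"`
#' @param intercept include an intercept term
#' @param roi,level,subject_id provenance carried into the result
#' @return an object of class `rsa_regression` with methods [print()],
#'   [summary()], [coef()], [fitted()], [residuals()], [predict()] and
#'   [plot()]. Fields include `betas`, `p_perm`, `p_smooth`, `fdr_q`,
#'   `n_perm`, `seed`.
#' @export
#' @examples
#' design <- make_design(seed = 2)
#' truth <- ground_truth()
#' roster <- data.frame(subject_id = "S01", group = "NT")
#' pats <- simulate_patterns(design, truth, n_voxels = 60, roster, seed = 3)
#' nr <- neural_rdm(pats$S01$BA1)
#' fit <- rsa_regression(nr, build_regressors(design, "general"),
#'                       n_perm = 200, seed = 4)
#' coef(fit)
rsa_regression <- function(dv, regressors, n_perm = 1000, seed = 1,
                           alternative = c("greater", "two.sided"),
                           intercept = TRUE, roi = NA_character_,
                           level = "group", subject_id = NA_character_) {
  alternative <- match.arg(alternative)
  dv_vec <- if (is_rdm(dv)) vectorize_z(dv) else as.numeric(dv)
  X <- if (inherits(regressors, "regressor_set")) regressors$X else
    as.matrix(regressors)
  if (n_perm > 0) {
    pt <- permutation_test(dv_vec, X, n_perm = n_perm, seed = seed,
                           alternative = alternative, intercept = intercept)
    betas <- pt$betas
    p_perm <- pt$p_perm
    p_smooth <- pt$p_smooth
    q <- stats::setNames(fdr_correct(p_perm), names(p_perm))
  } else {
    betas <- fit_rdm_regression(dv_vec, X, intercept = intercept)
    p_perm <- p_smooth <- q <- stats::setNames(
      rep(NA_real_, length(betas)), names(betas))
  }
  M <- if (intercept) cbind(1, X) else X
  coefs_full <- qr.coef(qr(M), dv_vec)
  fitted_vals <- drop(M %*% coefs_full)
  structure(list(betas = betas, p_perm = p_perm, p_smooth = p_smooth,
                 fdr_q = q, n_perm = n_perm, seed = seed,
                 alternative = alternative, intercept = intercept,
                 roi = roi, level = level, subject_id = subject_id,
                 regressor_names = colnames(X),
                 dv = dv_vec, X = X, fitted = fitted_vals,
                 residuals = dv_vec - fitted_vals),
            class = "rsa_regression")
}

#' @export
coef.rsa_regression <- function(object, ...) object$betas

#' @export
fitted.rsa_regression <- function(object, ...) object$fitted

#' @export
residuals.rsa_regression <- function(object, ...) object$residuals

#' @export
predict.rsa_regression <- function(object, newX = NULL, ...) {
  if (is.null(newX)) return(object$fitted)
  if (inherits(newX, "regressor_set")) newX <- newX$X
  b0 <- if (object$intercept) {
    mean(object$dv) - sum(object$betas * colMeans(object$X))
  } else 0
  drop(as.matrix(newX) %*% object$betas) + b0
}

#' @export
print.rsa_regression <- function(x, ...) {
  cat(sprintf("RSA multiple regression (%s level%s)\n", x$level,
              if (!is.na(x$roi)) paste0(", ROI ", x$roi) else ""))
  cat(sprintf("  %d dissimilarity pairs, %d regressors, %d permutations\n",
              length(x$dv), length(x$betas), x$n_perm))
  print(summary(x), ...)
  invisible(x)
}

#' @export
summary.rsa_regression <- function(object, ...) {
  fmt_p <- function(p, n_perm) {
    ifelse(is.na(p), NA_character_,
           ifelse(p == 0, sprintf("<%.3g", 1 / n_perm),
                  sprintf("%.3g", p)))
  }
  out <- data.frame(regressor = names(object$betas),
                    beta = as.numeric(object$betas),
                    p_perm = as.numeric(object$p_perm),
                    p_label = fmt_p(object$p_perm, object$n_perm),
                    p_smooth = as.numeric(object$p_smooth),
                    fdr_q = as.numeric(object$fdr_q),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("summary.rsa_regression", "data.frame")
  out
}

#' @export
plot.rsa_regression <- function(x, alpha = 0.05, ...) {
  b <- x$betas
  bp <- graphics::barplot(b, names.arg = names(b), las = 2,
                          ylab = "beta", ...)
  sig <- !is.na(x$fdr_q) & x$fdr_q < alpha
  if (any(sig)) {
    graphics::text(bp[sig], b[sig], labels = "*", pos = 3, cex = 1.4)
  }
  invisible(x)
}
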