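#' Leave-one-subject-out noise ceiling
#'
#' Quantifies the reliability of the neural dissimilarity structure within
#' a group: each subject's RDM vector (row-major upper triangle) is
#' Pearson-correlated with the element-wise mean of the remaining
#' subjects' RDMs — the held-out subject never contributes to its own
#' reference. The group mean of these leave-one-subject-out correlations
#' is the noise ceiling against which model fits are read, and the
#' per-subject values support a gated group comparison of reliability.
#'
#' @param rdms named list of subject [rdm()]s, all on the same stimuli
#' @param groups group label per subject (same order as `rdms`); NULL
#'   treats all subjects as one group
#' @return list: `per_subject` (`data.frame` subject_id, group, r),
#'   `summary` (mean r per group), `comparison` (a
#'   [compare_groups()] result when exactly two groups are present)
#' @export
noise_ceiling <- function(rdms, groups = NULL) {
  n <- length(rdms)
  if (is.null(groups)) groups <- rep("all", n)
  if (length(groups) != n) stop("groups must match the RDM list in length")
  ids <- names(rdms) %||% paste0("S", seq_len(n))
  vecs <- vapply(rdms, function(r) upper_tri_vec(r$values),
                 numeric(length(upper_tri_vec(rdms[[1]]$values))))
  per <- vector("list", 0L)
  for (g in unique(groups)) {
    cols <- which(groups == g)
    if (length(cols) < 3) stop("need at least 3 subjects in group ", g)
    for (j in cols) {
      ref <- rowMeans(vecs[, setdiff(cols, j), drop = FALSE])
      if (stats::sd(vecs[, j]) == 0 || stats::sd(ref) == 0) {
        stop("constant RDM vector for subject ", ids[j])
      }
      per[[length(per) + 1L]] <-
        data.frame(subject_id = ids[j], group = g,
                   r = stats::cor(vecs[, j], ref), stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  summ <- stats::aggregate(r ~ group, data = per, FUN = mean)
  comparison <- NULL
  gs <- unique(groups)
  if (length(gs) == 2) {
    comparison <- compare_groups(per$r[per$group == gs[1]],
                                 per$r[per$group == gs[2]], labels = gs)
  }
  list(per_subject = per, summary = summ, comparison = comparison)
}

#' Subject-level RSA with group comparison of coefficients
#'
#' Fits the multiple-regression RSA to every individual subject's neural
#' RDM in one ROI, then compares the two groups regressor-by-regressor
#' with the normality-gated test ([compare_groups()]), reporting Cohen's d
#' on rejection. For the `social` model each group's own affect RDM is
#' used in that group's subject fits, mirroring the group-level analysis.
#'
#' @param patterns list of [pattern_set()]s for one ROI (one per subject)
#' @param design stimulus design table
#' @param model `"general"` or `"social"`
#' @param affect_by_group named list of affect [rdm()]s per group
#'   (required for the social model)
#' @param n_perm permutations per subject fit (0 = coefficients only,
#'   which is all the group test needs)
#' @param seed integer seed
#' @param dissim dissimilarity transform for the neural RDMs
#' @param groups optional explicit group ordering for the comparison
#' @return list: `fits` (per-subject `rsa_regression` objects), `betas`
#'   (subject x regressor matrix), `table` (long `data.frame` of subject
#'   betas and p values), `group_tests` (per-regressor `data.frame` with
#'   test, statistic, p, fdr q, Cohen's d), `roi`
#' @export
subject_level_analysis <- function(patterns, design,
                                   model = c("general", "social"),
                                   affect_by_group = NULL, n_perm = 0,
                                   seed = 1,
                                   dissim = c("one_minus_r", "neg_r"),
                                   groups = NULL) {
  model <- match.arg(model)
  dissim <- match.arg(dissim)
  stopifnot(all(vapply(patterns, inherits, logical(1), "pattern_set")))
  roi <- unique(vapply(patterns, `[[`, character(1), "roi"))
  if (length(roi) != 1) stop("patterns must all come from one ROI")
  subj_groups <- vapply(patterns, `[[`, character(1), "group")
  if (is.null(groups)) groups <- unique(subj_groups)

  reg_by_group <- lapply(stats::setNames(groups, groups), function(g) {
    build_regressors(design, model = model,
                     affect = if (model == "social")
                       affect_by_group[[g]] else NULL)
  })
  fits <- vector("list", length(patterns))
  names(fits) <- vapply(patterns, `[[`, character(1), "subject_id")
  for (i in seq_along(patterns)) {
    ps <- patterns[[i]]
    nr <- neural_rdm(ps, dissim = dissim)
    if (model == "social") nr <- subset_rdm(nr, social_ids(design))
    fits[[i]] <- rsa_regression(nr, reg_by_group[[ps$group]],
                                n_perm = n_perm,
                                seed = derive_seed(seed, i),
                                roi = roi, level = "subject",
                                subject_id = ps$subject_id)
  }
  betas <- t(vapply(fits, coef, coef(fits[[1]])))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(subject_id = f$subject_id, group = subj_groups[i],
               roi = roi, regressor = names(f$betas),
               beta = as.numeric(f$betas),
               p_perm = as.numeric(f$p_perm),
               fdr_q = as.numeric(f$fdr_q), stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL

  group_tests <- NULL
  if (length(groups) == 2) {
    group_tests <- do.call(rbind, lapply(colnames(betas), function(rg) {
      cmp <- compare_groups(betas[subj_groups == groups[1], rg],
                            betas[subj_groups == groups[2], rg],
                            labels = groups)
      data.frame(roi = roi, regressor = rg, test = cmp$test,
                 statistic = cmp$statistic, df = cmp$df, p = cmp$p,
                 cohens_d = if (cmp$rejected) cmp$effect_size_d else
                   NA_real_, stringsAsFactors = FALSE)
    }))
    group_tests$fdr_q <- fdr_correct(group_tests$p)
    rownames(group_tests) <- NULL
  }
  list(fits = fits, betas = betas, table = tab, group_tests = group_tests,
       roi = roi, model = model, groups = groups)
}
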