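#' Analysis parameters for a full pipeline run
#'
#' Defaults follow the target study design: 1000 permutations, one-sided
#' permutation inference, Shapiro-Wilk gate at alpha = 0.05, `1 - r`
#' correlation distance, and joint FDR correction across regressors and
#' ROIs within each (group, model) family.
#'
#' @param n_perm permutations for group-level inference
#' @param gate_alpha Shapiro-Wilk gate level
#' @param alternative permutation sidedness
#' @param dissim neural dissimilarity transform
#' @param fdr_family FDR correction family: `"joint"` (regressors x ROIs
#'   within group and model), `"roi"` (within each fit), or
#'   `"regressor"` (across ROIs within each regressor)
#' @param subject_n_perm permutations for subject-level fits (0 = skip;
#'   group tests only need the coefficients)
#' @param cohort a [cohort_config()] used when the run simulates its data
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(n_perm = 1000, gate_alpha = 0.05,
                            alternative = c("greater", "two.sided"),
                            dissim = c("one_minus_r", "neg_r"),
                            fdr_family = c("joint", "roi", "regressor"),
                            subject_n_perm = 0,
                            cohort = cohort_config()) {
  structure(list(n_perm = n_perm, gate_alpha = gate_alpha,
                 alternative = match.arg(alternative),
                 dissim = match.arg(dissim),
                 fdr_family = match.arg(fdr_family),
                 subject_n_perm = subject_n_perm, cohort = cohort),
            class = "pipeline_config")
}

# re-apply FDR over the chosen family on a long (group, model, roi,
# regressor, p) table
apply_fdr_family <- function(tab, family) {
  tab$fdr_q <- NA_real_
  key <- switch(family,
                joint = interaction(tab$group, tab$model, drop = TRUE),
                roi = interaction(tab$group, tab$model, tab$roi,
                                  drop = TRUE),
                regressor = interaction(tab$group, tab$model,
                                        tab$regressor, drop = TRUE))
  for (k in levels(key)) {
    sel <- key == k
    tab$fdr_q[sel] <- fdr_correct(tab$p_perm[sel])
  }
  tab
}

#' Run the complete analysis pipeline
#'
#' Orchestrates every stage on one cohort: session aggregation and
#' category summaries of the ratings, rating reliabilities and group
#' comparisons, per-group affect dissimilarity matrices, per-subject and
#' group-average neural RDMs (general 75-stimulus and social 39-stimulus
#' variants), group-level multiple-regression RSA with permutation
#' inference and family-wise FDR, leave-one-subject-out noise ceilings,
#' subject-level RSA with gated group tests per regressor, questionnaire
#' group statistics, and the brain-behaviour correlations between
#' questionnaire scores and somatosensory affect coefficients (plain
#' Spearman and rank partial correlation controlling age and head
#' motion). Identical (cohort, config, seed) inputs reproduce identical
#' outputs.
#'
#' @param cohort a `touch_cohort` from [simulate_cohort()] or
#'   [read_cohort()]; `NULL` simulates one from `config$cohort`
#' @param config a [pipeline_config()]
#' @param seed master seed for all permutation streams (and the cohort,
#'   when simulated here)
#' @param out_dir optional directory; when given, all result tables are
#'   written there as TSV/JSON
#' @return a `run_report` list: `behavioral` (category summaries, group
#'   comparisons, reliabilities), `affect_rdms`, `neural` (per-subject
#'   and group RDMs), `group_rsa` (long beta table across group x model
#'   x ROI x regressor), `noise_ceilings`, `subject_rsa` (per-ROI group
#'   tests), `questionnaire_stats`, `brain_behaviour`, `params`
#' @export
run_pipeline <- function(cohort = NULL, config = pipeline_config(),
                         seed = 1, out_dir = NULL) {
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$cohort, seed = seed)
  }
  design <- cohort$design
  groups <- unique(cohort$roster$group)
  rois <- names(cohort$patterns[[1]])
  agg <- cohort$agg

  ## ---- behavioural stage ----
  cat_sum <- category_summary(agg, design)
  cmp_specs <- list(c("social_positive", "valence"),
                    c("social_negative", "valence"),
                    c("nonsocial", "valence"),
                    c("social", "arousal"),
                    c("nonsocial", "arousal"))
  rating_tests <- do.call(rbind, lapply(cmp_specs, function(sp) {
    cmp <- compare_groups_ratings(agg, design, sp[1], sp[2],
                                  groups = rev(groups),
                                  alpha = config$gate_alpha)
    data.frame(category = sp[1], dimension = sp[2], test = cmp$test,
               statistic = cmp$statistic, p = cmp$p,
               cohens_d = if (cmp$rejected) cmp$effect_size_d else
                 NA_real_, stringsAsFactors = FALSE)
  }))
  wsr <- within_subject_reliability(cohort$ratings)
  bsr <- lapply(stats::setNames(groups, groups), function(g)
    between_subject_reliability(agg, g))
  affect_rdms <- lapply(stats::setNames(groups, groups), function(g) {
    affect_dissimilarity(agg, design,
                         subjects = cohort$roster$subject_id[
                           cohort$roster$group == g])
  })

  ## ---- RDM stage ----
  subj_ids <- cohort$roster$subject_id
  general_rdms <- lapply(stats::setNames(rois, rois), function(roi) {
    out <- lapply(subj_ids, function(s)
      neural_rdm(cohort$patterns[[s]][[roi]], dissim = config$dissim))
    names(out) <- subj_ids
    out
  })
  soc <- social_ids(design)
  social_rdms <- lapply(general_rdms, function(l)
    lapply(l, subset_rdm, keep = soc))
  group_mean_rdm <- function(rdms_roi, g) {
    average_rdms(rdms_roi[subj_ids[cohort$roster$group == g]])
  }

  ## ---- group-level RSA ----
  fit_rows <- list()
  fit_idx <- 0L
  for (model in c("general", "social")) {
    rdm_set <- if (model == "general") general_rdms else social_rdms
    for (g in groups) {
      reg <- build_regressors(design, model = model,
                              affect = affect_rdms[[g]])
      for (roi in rois) {
        fit_idx <- fit_idx + 1L
        fit <- rsa_regression(group_mean_rdm(rdm_set[[roi]], g), reg,
                              n_perm = config$n_perm,
                              seed = derive_seed(seed, 100 + fit_idx),
                              alternative = config$alternative,
                              roi = roi, level = "group")
        fit_rows[[fit_idx]] <-
          data.frame(group = g, model = model, roi = roi,
                     regressor = names(fit$betas),
                     beta = as.numeric(fit$betas),
                     p_perm = as.numeric(fit$p_perm),
                     p_smooth = as.numeric(fit$p_smooth),
                     stringsAsFactors = FALSE)
      }
    }
  }
  group_rsa <- apply_fdr_family(do.call(rbind, fit_rows),
                                config$fdr_family)
  rownames(group_rsa) <- NULL

  ## ---- noise ceilings (general-touch RDMs) ----
  ceilings <- lapply(stats::setNames(rois, rois), function(roi)
    noise_ceiling(general_rdms[[roi]], groups = cohort$roster$group))

  ## ---- subject-level RSA + group tests ----
  subject_rsa <- list()
  for (model in c("general", "social")) {
    subject_rsa[[model]] <- lapply(stats::setNames(rois, rois),
                                   function(roi) {
      pats <- lapply(subj_ids, function(s) cohort$patterns[[s]][[roi]])
      subject_level_analysis(pats, design, model = model,
                             affect_by_group = affect_rdms,
                             n_perm = config$subject_n_perm,
                             seed = derive_seed(seed, 500 + match(roi,
                                                                  rois)),
                             dissim = config$dissim, groups = groups)
    })
  }

  ## ---- questionnaire statistics ----
  qs <- cohort$questionnaires
  q_scales <- intersect(c("stq_total", "srs_total", "srs_awareness",
                          "srs_communication", "srs_motivation",
                          "srs_rrb"), names(qs))
  questionnaire_stats <- do.call(rbind, lapply(q_scales, function(sc) {
    cmp <- compare_groups(qs[[sc]][qs$group == groups[1]],
                          qs[[sc]][qs$group == groups[2]],
                          labels = groups, alpha = config$gate_alpha)
    data.frame(scale = sc, test = cmp$test, statistic = cmp$statistic,
               p = cmp$p, cohens_d = cmp$effect_size_d,
               mean_1 = cmp$means[1], sd_1 = cmp$sds[1],
               mean_2 = cmp$means[2], sd_2 = cmp$sds[2],
               stringsAsFactors = FALSE)
  }))
  stq_srs <- correlate(qs$stq_total, qs$srs_total)

  ## ---- brain-behaviour correlations ----
  somato <- intersect(cohort$truth$somatosensory_rois %||% rois, rois)
  bb_rows <- list()
  for (roi in somato) {
    betas <- subject_rsa$social[[roi]]$betas[, "affect"]
    betas <- betas[qs$subject_id]
    covs <- if (all(c("age", "mean_fd") %in% names(qs))) {
      cbind(age = qs$age, mean_fd = qs$mean_fd)
    } else NULL
    for (sc in intersect(c("stq_total", "srs_total"), q_scales)) {
      plain <- correlate(qs[[sc]], betas, method = "spearman")
      partial <- if (!is.null(covs)) {
        rank_partial_corr(qs[[sc]], betas, covs)
      } else list(r = NA_real_, p = NA_real_)
      bb_rows[[length(bb_rows) + 1L]] <-
        data.frame(roi = roi, scale = sc, r_spearman = plain$r,
                   p = plain$p, r_partial = partial$r,
                   p_partial = partial$p, stringsAsFactors = FALSE)
    }
  }
  brain_behaviour <- do.call(rbind, bb_rows)

  report <- list(behavioral = list(category_summary = cat_sum,
                                   rating_tests = rating_tests,
                                   within_subject = wsr,
                                   between_subject = bsr),
                 affect_rdms = affect_rdms,
                 neural = list(general = general_rdms,
                               social = social_rdms),
                 group_rsa = group_rsa,
                 noise_ceilings = ceilings,
                 subject_rsa = subject_rsa,
                 questionnaire_stats = questionnaire_stats,
                 stq_srs_correlation = stq_srs,
                 brain_behaviour = brain_behaviour,
                 params = list(seed = seed, n_perm = config$n_perm,
                               alternative = config$alternative,
                               dissim = config$dissim,
                               fdr_family = config$fdr_family,
                               gate_alpha = config$gate_alpha,
                               groups = groups, rois = rois,
                               n_subjects = nrow(cohort$roster),
                               n_stimuli = nrow(design)))
  class(report) <- "run_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  p <- x$params
  cat(sprintf(paste0("touchrsa run: %d subjects, %d stimuli, ROIs %s\n",
                     "  n_perm = %d (%s), dissim = %s, FDR family = %s, ",
                     "seed = %d\n"),
              p$n_subjects, p$n_stimuli, paste(p$rois, collapse = ", "),
              p$n_perm, p$alternative, p$dissim, p$fdr_family, p$seed))
  sig <- subset(x$group_rsa, x$group_rsa$fdr_q < 0.05)
  cat(sprintf("  %d of %d group-level coefficients significant at q < 0.05\n",
              nrow(sig), nrow(x$group_rsa)))
  invisible(x)
}

# write all tabular results of a run as TSV + a JSON parameter echo
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  wt(report$behavioral$category_summary, "category_summary.tsv")
  wt(report$behavioral$rating_tests, "rating_group_tests.tsv")
  wt(report$behavioral$within_subject, "within_subject_reliability.tsv")
  wt(report$group_rsa, "group_rsa_betas.tsv")
  ceil <- do.call(rbind, lapply(names(report$noise_ceilings), function(r) {
    df <- report$noise_ceilings[[r]]$per_subject
    df$roi <- r
    df
  }))
  wt(ceil, "noise_ceilings.tsv")
  subj_tests <- do.call(rbind, lapply(names(report$subject_rsa),
                                      function(m) {
    do.call(rbind, lapply(report$subject_rsa[[m]], function(sr) {
      df <- sr$group_tests
      df$model <- m
      df
    }))
  }))
  wt(subj_tests, "subject_rsa_group_tests.tsv")
  wt(report$questionnaire_stats, "questionnaire_stats.tsv")
  wt(report$brain_behaviour, "brain_behaviour.tsv")
  jsonlite::write_json(report$params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
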