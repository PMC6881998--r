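#' Configuration for a synthetic cohort
#'
#' Bundles every generator parameter with defaults matching the study
#' design the package targets: 75 stimuli (13 positive + 26 negative
#' social, 36 non-social), 21 subjects per group (NT and ASD), two rating
#' sessions, 200 voxels per ROI, and the [ground_truth()] embedding
#' structure.
#'
#' @param n_pos,n_neg,n_nonsocial stimulus counts per category
#' @param n_action_types matched physical-action classes
#' @param n_subjects_per_group subjects per group
#' @param n_sessions rating sessions
#' @param n_voxels voxels per ROI
#' @param groups group labels (control first)
#' @param truth a [ground_truth()]
#' @param profile a [default_rating_profile()]
#' @return list of class `cohort_config`
#' @export
cohort_config <- function(n_pos = 13, n_neg = 26, n_nonsocial = 36,
                          n_action_types = 12, n_subjects_per_group = 21,
                          n_sessions = 2, n_voxels = 200,
                          groups = c("NT", "ASD"),
                          truth = ground_truth(groups = groups),
                          profile = default_rating_profile()) {
  structure(list(n_pos = n_pos, n_neg = n_neg, n_nonsocial = n_nonsocial,
                 n_action_types = n_action_types,
                 n_subjects_per_group = n_subjects_per_group,
                 n_sessions = n_sessions, n_voxels = n_voxels,
                 groups = groups, truth = truth, profile = profile),
            class = "cohort_config")
}

#' Generate a complete synthetic cohort
#'
#' Runs the full generative model in one seeded call: stimulus design,
#' per-subject gain deviates, two-session ratings, group-mean affect
#' coordinates, voxel patterns for every (subject, ROI), and
#' questionnaire/covariate scores. The ground truth used is returned with
#' the data so recovery can always be checked. The output is a pure
#' function of (config, seed).
#'
#' @param config a [cohort_config()]
#' @param seed master integer seed; stage seeds are derived from it
#' @return list of class `touch_cohort`: `design`, `roster` (subject_id,
#'   group, gain_z), `ratings`, `agg` (session-averaged ratings),
#'   `affect_coords` (per group), `patterns`, `questionnaires`, `truth`,
#'   `config`, `seed`
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  design <- make_design(config$n_pos, config$n_neg, config$n_nonsocial,
                        n_action_types = config$n_action_types,
                        seed = derive_seed(seed, 1))
  npg <- config$n_subjects_per_group
  roster <- data.frame(
    subject_id = unlist(lapply(config$groups, function(g)
      sprintf("%s%02d", g, seq_len(npg)))),
    group = rep(config$groups, each = npg),
    stringsAsFactors = FALSE)
  roster$gain_z <- local_seed(derive_seed(seed, 2),
                              stats::rnorm(nrow(roster)))

  ratings <- simulate_ratings(design, n_subjects_per_group = npg,
                              n_sessions = config$n_sessions,
                              profile = config$profile,
                              groups = config$groups,
                              seed = derive_seed(seed, 3))
  agg <- aggregate_sessions(ratings)
  affect_coords <- lapply(stats::setNames(config$groups, config$groups),
                          function(g) {
    sub <- agg[agg$group == g, ]
    v <- tapply(sub$valence, sub$stimulus_id, mean)[design$stimulus_id]
    a <- tapply(sub$arousal, sub$stimulus_id, mean)[design$stimulus_id]
    cbind(valence = unname(v), arousal = unname(a))
  })
  patterns <- simulate_patterns(design, config$truth,
                                n_voxels = config$n_voxels,
                                subjects = roster,
                                affect_coords = affect_coords,
                                seed = derive_seed(seed, 4))
  questionnaires <- simulate_questionnaires(roster, config$truth,
                                            seed = derive_seed(seed, 5))
  structure(list(design = design, roster = roster, ratings = ratings,
                 agg = agg, affect_coords = affect_coords,
                 patterns = patterns, questionnaires = questionnaires,
                 truth = config$truth, config = config, seed = seed),
            class = "touch_cohort")
}

#' @export
print.touch_cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic touch-observation cohort: %d stimuli, ",
                     "%d subjects (%s), %d ROIs x %d voxels, seed %d\n"),
              nrow(x$design), nrow(x$roster),
              paste(table(x$roster$group)[unique(x$roster$group)],
                    collapse = " + "),
              length(x$truth$rois), x$config$n_voxels, x$seed))
  invisible(x)
}
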