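#' Average rating sessions per subject and stimulus
#'
#' The two rating repetitions are averaged for each participant and
#' stimulus before any further analysis. Works with any number of sessions
#' (>= 1); with a single session the values pass through unchanged.
#'
#' @param ratings long-format rating table (see [simulate_ratings()] for
#'   the required columns)
#' @param design optional stimulus design; when given, coverage is checked
#'   against the full stimulus list rather than the ids present in
#'   `ratings`
#' @return `data.frame` with one row per (subject, stimulus): `subject_id`,
#'   `group`, `stimulus_id`, `valence`, `arousal` (session means)
#' @export
aggregate_sessions <- function(ratings, design = NULL) {
  validate_ratings(ratings)
  # complete coverage: every (subject, session) must rate every stimulus once
  if (!is.null(design)) {
    ratings$stimulus_id <- factor(ratings$stimulus_id,
                                  levels = design$stimulus_id)
    if (anyNA(ratings$stimulus_id)) {
      stop("ratings reference stimuli absent from the design")
    }
  }
  cover <- table(ratings$subject_id, ratings$session, ratings$stimulus_id)
  if (any(cover != 1)) {
    off <- which(cover != 1, arr.ind = TRUE)[1, ]
    stop("incomplete coverage: subject ", dimnames(cover)[[1]][off[1]],
         ", session ", dimnames(cover)[[2]][off[2]], ", stimulus ",
         dimnames(cover)[[3]][off[3]], " rated ",
         cover[off[1], off[2], off[3]], " times")
  }
  agg <- stats::aggregate(cbind(valence, arousal) ~ subject_id + group +
                            stimulus_id, data = ratings, FUN = mean)
  agg$stimulus_id <- as.character(agg$stimulus_id)
  agg <- agg[order(agg$subject_id, agg$stimulus_id), ]
  rownames(agg) <- NULL
  agg
}

#' Median and MAD of ratings per group and stimulus category
#'
#' For each (group, category, dimension) cell, pools the session-averaged
#' ratings of all stimuli in the category across the group's subjects and
#' reports the median and the median absolute deviation. The MAD is the
#' plain median of absolute deviations from the median, with no
#' normal-consistency scaling.
#'
#' @param agg session-averaged table from [aggregate_sessions()]
#' @param design stimulus design table
#' @param merge_social also report a pooled `social` category (positive and
#'   negative together), used for arousal summaries
#' @return `data.frame` with columns `group`, `category`, `dimension`,
#'   `median`, `mad`, `n`
#' @export
category_summary <- function(agg, design, merge_social = TRUE) {
  validate_design(design)
  cat_of <- stats::setNames(as.character(design$category),
                            design$stimulus_id)
  agg$category <- cat_of[agg$stimulus_id]
  if (anyNA(agg$category)) stop("ratings reference stimuli absent from design")
  cats <- list(social_positive = "social_positive",
               social_negative = "social_negative",
               nonsocial = "nonsocial")
  if (merge_social) {
    cats$social <- c("social_positive", "social_negative")
  }
  rows <- list()
  raw_mad <- function(x) stats::median(abs(x - stats::median(x)))
  for (g in sort(unique(agg$group))) {
    for (cn in names(cats)) {
      sel <- agg$group == g & agg$category %in% cats[[cn]]
      if (!any(sel)) stop("empty category ", cn, " for group ", g)
      for (dim in c("valence", "arousal")) {
        x <- agg[[dim]][sel]
        rows[[length(rows) + 1L]] <-
          data.frame(group = g, category = cn, dimension = dim,
                     median = stats::median(x), mad = raw_mad(x),
                     n = sum(sel), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group comparison of category-level ratings
#'
#' Reduces each subject to one summary value over the category's stimuli
#' (mean by default, median optionally), then compares the two groups with
#' the normality-gated test: Shapiro-Wilk at alpha = 0.05 on each group;
#' if either is non-normal, a Mann-Whitney U test (tie-corrected normal
#' approximation, signed z), else a pooled-variance two-sample t test.
#' Cohen's d is attached when the null is rejected.
#'
#' @param agg session-averaged rating table
#' @param design stimulus design table
#' @param category one of `social_positive`, `social_negative`,
#'   `nonsocial`, or `social` (positive + negative pooled)
#' @param dimension `"valence"` or `"arousal"`
#' @param groups the two group labels to compare, in (group1, group2) order
#' @param reduce per-subject reduction across the category's stimuli
#' @param alpha significance level for the gate and the d-reporting rule
#' @return a `group_comparison` object (see [compare_groups()])
#' @export
compare_groups_ratings <- function(agg, design, category, dimension,
                                   groups = c("ASD", "NT"),
                                   reduce = c("mean", "median"),
                                   alpha = 0.05) {
  reduce <- match.arg(reduce)
  dimension <- match.arg(dimension, c("valence", "arousal"))
  members <- switch(category,
                    social = c("social_positive", "social_negative"),
                    category)
  ids <- design$stimulus_id[as.character(design$category) %in% members]
  if (!length(ids)) stop("empty category: ", category)
  sel <- agg$stimulus_id %in% ids
  redfun <- if (reduce == "mean") mean else stats::median
  per_subj <- tapply(agg[[dimension]][sel],
                     list(agg$subject_id[sel]), redfun)
  grp <- tapply(agg$group[sel], list(agg$subject_id[sel]),
                function(g) g[1])
  x <- as.numeric(per_subj[grp == groups[1]])
  y <- as.numeric(per_subj[grp == groups[2]])
  compare_groups(x, y, labels = groups, alpha = alpha)
}

#' Affective dissimilarity matrix from valence and arousal ratings
#'
#' The overall-affect distance between two stimuli is the two-dimensional
#' Euclidean distance between their (valence, arousal) coordinates —
#' computed for each subject from that subject's session-averaged ratings,
#' then averaged across subjects. By default the matrix is restricted to
#' the social stimuli, since this model predicts the social-touch neural
#' RDM.
#'
#' @param agg session-averaged rating table
#' @param design stimulus design table
#' @param stimuli stimulus ids to include (default: the social stimuli)
#' @param subjects subject ids to average over (default: all in `agg`;
#'   pass one group's subjects to build a group-specific affect model)
#' @return a model [rdm()] of mean Euclidean affect distances
#' @export
affect_dissimilarity <- function(agg, design, stimuli = social_ids(design),
                                 subjects = unique(agg$subject_id)) {
  stimuli <- as.character(stimuli)
  if (length(stimuli) < 2) stop("need at least 2 stimuli")
  acc <- matrix(0, length(stimuli), length(stimuli),
                dimnames = list(stimuli, stimuli))
  for (s in subjects) {
    rows <- agg[agg$subject_id == s & agg$stimulus_id %in% stimuli, ]
    if (nrow(rows) != length(stimuli)) {
      stop("subject ", s, " does not cover all requested stimuli")
    }
    coords <- as.matrix(rows[match(stimuli, rows$stimulus_id),
                             c("valence", "arousal")])
    acc <- acc + as.matrix(stats::dist(coords))
  }
  rdm(acc / length(subjects), labels = stimuli, kind = "model",
      source = "affect")
}

#' Within-subject rating reliability across sessions
#'
#' Correlates each subject's session-1 and session-2 ratings across all
#' stimuli, separately for valence and arousal. Spearman by default
#' (integer Likert scales); Pearson available. A subject whose ratings are
#' constant in either session gets `NA` with a flag rather than being
#' silently dropped.
#'
#' @param ratings long-format rating table with exactly two sessions
#' @param method correlation type
#' @return `data.frame`: `subject_id`, `group`, `dimension`, `r`,
#'   `degenerate` (TRUE when a constant vector made r undefined)
#' @export
within_subject_reliability <- function(ratings,
                                       method = c("spearman", "pearson")) {
  method <- match.arg(method)
  validate_ratings(ratings)
  if (!setequal(unique(ratings$session), c(1, 2))) {
    stop("within-subject reliability requires exactly sessions 1 and 2")
  }
  rows <- list()
  for (s in unique(ratings$subject_id)) {
    r1 <- ratings[ratings$subject_id == s & ratings$session == 1, ]
    r2 <- ratings[ratings$subject_id == s & ratings$session == 2, ]
    r2 <- r2[match(r1$stimulus_id, r2$stimulus_id), ]
    for (dim in c("valence", "arousal")) {
      a <- r1[[dim]]; b <- r2[[dim]]
      degen <- stats::sd(a) == 0 || stats::sd(b) == 0
      rho <- if (degen) NA_real_ else stats::cor(a, b, method = method)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = s, group = r1$group[1], dimension = dim,
                   r = rho, degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Between-subject rating reliability (leave-one-out)
#'
#' For each subject in a group, correlates the subject's session-averaged
#' stimulus ratings with the mean rating vector of the remaining group
#' members (the held-out subject never contributes to its own reference).
#'
#' @param agg session-averaged rating table
#' @param group group label to analyse
#' @param method correlation type (Spearman default, as for the
#'   within-subject statistic)
#' @return list with `per_subject` (`data.frame`: subject, dimension, r,
#'   degenerate flag) and `summary` (group mean r per dimension)
#' @export
between_subject_reliability <- function(agg, group,
                                        method = c("spearman", "pearson")) {
  method <- match.arg(method)
  sub <- agg[agg$group == group, ]
  subjects <- unique(sub$subject_id)
  if (length(subjects) < 3) stop("need at least 3 subjects in group ", group)
  stim <- sort(unique(sub$stimulus_id))
  get_mat <- function(dim) {
    m <- matrix(NA_real_, length(stim), length(subjects),
                dimnames = list(stim, subjects))
    for (s in subjects) {
      rows <- sub[sub$subject_id == s, ]
      m[rows$stimulus_id, s] <- rows[[dim]]
    }
    if (anyNA(m)) stop("incomplete stimulus coverage in group ", group)
    m
  }
  rows <- list()
  for (dim in c("valence", "arousal")) {
    m <- get_mat(dim)
    for (s in subjects) {
      ref <- rowMeans(m[, setdiff(subjects, s), drop = FALSE])
      degen <- stats::sd(m[, s]) == 0 || stats::sd(ref) == 0
      rho <- if (degen) NA_real_ else stats::cor(m[, s], ref, method = method)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = s, dimension = dim, r = rho,
                   degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  summ <- stats::aggregate(r ~ dimension, data = per, FUN = mean,
                           na.action = stats::na.omit)
  list(per_subject = per, summary = summ)
}
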