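#' Default rating-generation profile
#'
#' Category anchors for the two affect dimensions, per group, on the 1-9
#' Likert scales (valence: 1 extremely unpleasant, 5 neutral, 9 extremely
#' pleasant; arousal: 1 extremely calm, 9 extremely exciting). The anchors
#' reproduce the group median structure the behavioural stage is expected
#' to recover: positive touch pleasant, negative touch unpleasant,
#' non-social touch neutral; social touch arousing, non-social touch calm;
#' the case group rates positive touch somewhat less pleasant and social
#' touch slightly more arousing. The three noise scales control
#' stimulus-to-stimulus spread, stable subject offsets, and
#' session-to-session jitter (all on the 9-point scale).
#'
#' @param stimulus_sd SD of the stimulus-level effects shared by all raters
#' @param subject_sd SD of stable per-subject offsets
#' @param session_sd SD of the session-to-session noise
#' @return a list with elements `anchors` (per-group matrix, dimensions x
#'   categories) and the three noise SDs
#' @export
default_rating_profile <- function(stimulus_sd = 0.8, subject_sd = 0.4,
                                   session_sd = 0.5) {
  cats <- c("social_positive", "social_negative", "nonsocial")
  mk <- function(val, aro) {
    m <- rbind(valence = val, arousal = aro)
    colnames(m) <- cats
    m
  }
  list(anchors = list(NT = mk(c(7.4, 2.9, 4.8), c(5.7, 5.7, 2.4)),
                      ASD = mk(c(6.8, 3.0, 4.8), c(6.2, 6.2, 2.5))),
       stimulus_sd = stimulus_sd,
       subject_sd = subject_sd,
       session_sd = session_sd)
}

#' Simulate a two-session valence/arousal rating table
#'
#' Generates integer 1-9 ratings as truncated Gaussians around per-category
#' group anchors: a shared stimulus effect (common to all raters, so that
#' between-subject consistency is high), a stable subject offset, and
#' session noise are added, then the value is rounded and clipped to the
#' scale. With all noise SDs zero the two sessions are identical.
#'
#' @param design stimulus design from [make_design()]
#' @param n_subjects_per_group subjects per group (default 21)
#' @param n_sessions rating repetitions per subject (default 2)
#' @param profile see [default_rating_profile()]
#' @param groups group labels; must match names in `profile$anchors`
#' @param seed integer seed
#' @return long-format `data.frame` with columns `subject_id`, `group`,
#'   `session`, `stimulus_id`, `valence`, `arousal`; one row per
#'   (subject, session, stimulus)
#' @export
simulate_ratings <- function(design, n_subjects_per_group = 21,
                             n_sessions = 2,
                             profile = default_rating_profile(),
                             groups = c("NT", "ASD"), seed = 1) {
  validate_design(design)
  if (n_sessions < 1) stop("n_sessions must be >= 1")
  if (n_subjects_per_group < 1) stop("need at least one subject per group")
  stopifnot(all(groups %in% names(profile$anchors)))

  n_stim <- nrow(design)
  cat_chr <- as.character(design$category)

  local_seed(seed, {
    # stimulus effects shared across groups and subjects (drives the high
    # between-subject agreement the behavioural stage checks)
    stim_eff <- matrix(stats::rnorm(2 * n_stim, 0, profile$stimulus_sd),
                       nrow = 2, dimnames = list(c("valence", "arousal"),
                                                 design$stimulus_id))
    out <- vector("list", length(groups) * n_subjects_per_group)
    k <- 0L
    for (g in groups) {
      anchors <- profile$anchors[[g]]
      base <- anchors[, cat_chr, drop = FALSE] + stim_eff  # 2 x n_stim
      for (s in seq_len(n_subjects_per_group)) {
        subj <- sprintf("%s%02d", g, s)
        subj_off <- stats::rnorm(2, 0, profile$subject_sd)
        for (sess in seq_len(n_sessions)) {
          noise <- matrix(stats::rnorm(2 * n_stim, 0, profile$session_sd),
                          nrow = 2)
          vals <- clamp(round(base + subj_off + noise), 1, 9)
          k <- k + 1L
          out[[k]] <- data.frame(subject_id = subj, group = g, session = sess,
                                 stimulus_id = design$stimulus_id,
                                 valence = as.integer(vals["valence", ]),
                                 arousal = as.integer(vals["arousal", ]),
                                 stringsAsFactors = FALSE)
        }
      }
    }
  })
  ratings <- do.call(rbind, out)
  rownames(ratings) <- NULL
  ratings
}

validate_ratings <- function(ratings, design = NULL) {
  need <- c("subject_id", "group", "session", "stimulus_id", "valence",
            "arousal")
  missing_cols <- setdiff(need, names(ratings))
  if (length(missing_cols)) {
    stop("rating table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- with(ratings, valence < 1 | valence > 9 | arousal < 1 | arousal > 9)
  if (any(bad)) {
    stop(sum(bad), " rating(s) outside the 1-9 scale (first offending row ",
         which(bad)[1], ")")
  }
  if (!is.null(design)) {
    tab <- table(ratings$subject_id, ratings$session)
    if (any(tab != nrow(design))) {
      off <- which(tab != nrow(design), arr.ind = TRUE)[1, ]
      stop("subject ", rownames(tab)[off[1]], " session ",
           colnames(tab)[off[2]], " does not cover the design exactly once")
    }
  }
  invisible(ratings)
}
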