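#' Build a stimulus design table
#'
#' Creates the catalogue of touch-video stimuli that every other stage keys
#' on. The default mirrors the study design this package targets: 75 short
#' touch clips, of which 39 depict interpersonal ("social") touch — positive
#' scenes such as hugging, negative scenes such as slapping — and 36 depict
#' matched object manipulations ("non-social" touch, e.g. holding a large
#' box instead of hugging a person). Social and non-social stimuli share a
#' set of matched physical-action classes, each stimulus carries the
#' motor-response label of the orthogonal shirt-colour task, and three
#' low-level physical covariates (pixel-wise intensity, pixel-wise motion
#' energy, total motion energy) stand in for values measured from the video
#' frames.
#'
#' @param n_pos number of positive social stimuli (default 13)
#' @param n_neg number of negative social stimuli (default 26)
#' @param n_nonsocial number of non-social stimuli (default 36)
#' @param n_action_types number of matched physical-action classes shared
#'   between the social and non-social sets
#' @param seed integer seed driving the physical-feature draws and task
#'   labels
#'
#' @return a `data.frame` with one row per stimulus and columns
#'   `stimulus_id`, `category` (factor: `social_positive`,
#'   `social_negative`, `nonsocial`), `action_type`, `motor_response`,
#'   `intensity`, `motion_energy_pixel`, `motion_energy_total`.
#' @export
#' @examples
#' d <- make_design(seed = 1)
#' table(d$category)
make_design <- function(n_pos = 13, n_neg = 26, n_nonsocial = 36,
                        n_action_types = 12, seed = 1) {
  counts <- c(n_pos = n_pos, n_neg = n_neg, n_nonsocial = n_nonsocial)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("stimulus counts must be positive integers")
  }
  if (n_action_types < 1) stop("need at least one action class")
  n <- n_pos + n_neg + n_nonsocial

  ids <- c(sprintf("pos%02d", seq_len(n_pos)),
           sprintf("neg%02d", seq_len(n_neg)),
           sprintf("obj%02d", seq_len(n_nonsocial)))
  category <- factor(rep(c("social_positive", "social_negative", "nonsocial"),
                         times = counts),
                     levels = c("social_positive", "social_negative",
                                "nonsocial"))

  actions <- sprintf("act%02d", seq_len(n_action_types))
  # matched pairing: the same action classes cycle through the social and
  # the non-social set, so every class occurs on both sides of the divide
  action_type <- c(rep_len(actions, n_pos + n_neg),
                   rep_len(actions, n_nonsocial))

  local_seed(seed, {
    motor_response <- sample(c("blue", "red"), n, replace = TRUE)
    intensity <- clamp(stats::rnorm(n, mean = 0.5, sd = 0.12), 0.05, 0.95)
    motion_px <- stats::rlnorm(n, meanlog = 0, sdlog = 0.4)
    motion_total <- motion_px * clamp(stats::rnorm(n, 3, 0.5), 1, 5)
  })

  data.frame(stimulus_id = ids,
             category = category,
             action_type = action_type,
             motor_response = motor_response,
             intensity = intensity,
             motion_energy_pixel = motion_px,
             motion_energy_total = motion_total,
             stringsAsFactors = FALSE)
}

#' @rdname make_design
#' @param design a design table
#' @return `social_ids()`: the stimulus ids of the social stimuli, in design
#'   order.
#' @export
social_ids <- function(design) {
  design$stimulus_id[design$category %in% c("social_positive",
                                            "social_negative")]
}

# column names treated as physical nuisance features throughout
physical_features <- function() {
  c("intensity", "motion_energy_pixel", "motion_energy_total")
}

validate_design <- function(design) {
  need <- c("stimulus_id", "category", "action_type", "motor_response",
            physical_features())
  missing_cols <- setdiff(need, names(design))
  if (length(missing_cols)) {
    stop("design table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(design$stimulus_id)) stop("duplicate stimulus ids")
  feat <- as.matrix(design[, physical_features()])
  if (any(!is.finite(feat))) stop("non-finite physical feature values")
  invisible(design)
}
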