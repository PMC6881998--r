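#' Ground-truth structure for the synthetic cohort
#'
#' Describes exactly what is planted in the simulated voxel patterns and
#' questionnaires: a non-negative embedding gain per (group, ROI, model
#' RDM), the voxel noise SD, per-subject gain variability, and the coupling
#' between each subject's somatosensory affect-embedding strength and the
#' questionnaire scores. The defaults encode the hypothesised case-control
#' dissociation: both groups embed the affect geometry in the
#' theory-of-mind ROI (TPJ), but only the control (NT) group embeds it in
#' the somatosensory ROIs (BA3, BA1, BA2); the social/non-social
#' distinction and the nuisance structures (motor response, action type,
#' physical features) are embedded everywhere in both groups.
#'
#' Questionnaire parameters default to the case-control summaries the
#' generator is meant to reproduce: social-touch preference (STQ, 20 items
#' on 1-5, totals 20-100) mean 69.2 (SD 9.6) in NT vs 56.8 (13.2) in ASD,
#' coupled positively to the somatosensory embedding; autistic-trait scores
#' (SRS-A total and subscales) higher in ASD and coupled negatively.
#'
#' @param rois ROI labels to simulate
#' @param groups group labels (first is the control group)
#' @param gains optional 3-d array `[group, roi, model]` of embedding
#'   gains; defaults as described above
#' @param noise_sd SD of the i.i.d. Gaussian voxel noise (default 1)
#' @param subject_gain_sd SD of the log-normal per-subject multiplier
#'   applied to the affect gain in somatosensory ROIs
#' @param somatosensory_rois ROIs whose affect gain varies by subject and
#'   drives the questionnaire coupling
#' @param stq_coupling,srs_coupling correlation between a subject's
#'   standardised somatosensory gain and the questionnaire score
#' @return a list of class `ground_truth`
#' @export
ground_truth <- function(rois = c("BA3", "BA1", "BA2", "TPJ"),
                         groups = c("NT", "ASD"),
                         gains = NULL,
                         noise_sd = 1,
                         subject_gain_sd = 0.3,
                         somatosensory_rois = intersect(rois,
                           c("BA3", "BA1", "BA2")),
                         stq_coupling = 0.5,
                         srs_coupling = -0.5) {
  models <- c("social", "affect", "motor_response", "action_type",
              "intensity", "motion_energy_pixel", "motion_energy_total")
  if (is.null(gains)) {
    gains <- array(0, dim = c(length(groups), length(rois), length(models)),
                   dimnames = list(groups, rois, models))
    gains[, , "social"] <- 1.0
    gains[, , c("motor_response", "action_type")] <- 0.25
    gains[, , c("intensity", "motion_energy_pixel",
                "motion_energy_total")] <- 0.15
    # affect: planted in TPJ for both groups, in somatosensory ROIs for the
    # control group only (a weak residual in BA3 for the case group)
    if ("TPJ" %in% rois) gains[, "TPJ", "affect"] <- 0.5
    for (r in somatosensory_rois) {
      gains[1, r, "affect"] <- 0.65
      if (length(groups) > 1 && r == "BA3") gains[2, r, "affect"] <- 0.15
    }
  }
  stopifnot(identical(dimnames(gains)[[1]], groups),
            identical(dimnames(gains)[[2]], rois))
  if (any(gains < 0)) stop("embedding gains must be non-negative")
  if (noise_sd <= 0) stop("noise_sd must be positive")

  q <- list(
    stq_total = list(mean = c(NT = 69.2, ASD = 56.8),
                     sd = c(NT = 9.6, ASD = 13.2),
                     coupling = stq_coupling, integer = TRUE,
                     range = c(20, 100)),
    srs_total = list(mean = c(NT = 51.9, ASD = 63.8),
                     sd = c(NT = 8.9, ASD = 11.6),
                     coupling = srs_coupling, integer = FALSE, range = NULL),
    srs_awareness = list(mean = c(NT = 50.2, ASD = 60.9),
                         sd = c(NT = 10.1, ASD = 11.6),
                         coupling = srs_coupling, integer = FALSE,
                         range = NULL),
    srs_communication = list(mean = c(NT = 51.4, ASD = 61.4),
                             sd = c(NT = 8.2, ASD = 11.2),
                             coupling = srs_coupling, integer = FALSE,
                             range = NULL),
    srs_motivation = list(mean = c(NT = 51.4, ASD = 60.5),
                          sd = c(NT = 8.8, ASD = 11.6),
                          coupling = srs_coupling, integer = FALSE,
                          range = NULL),
    srs_rrb = list(mean = c(NT = 50.0, ASD = 58.0),
                   sd = c(NT = 9.0, ASD = 11.0),
                   coupling = srs_coupling, integer = FALSE, range = NULL))
  covar <- list(age = list(mean = c(NT = 23.9, ASD = 25.0),
                           sd = c(NT = 2.8, ASD = 4.4)),
                mean_fd = list(mean = c(NT = 0.13, ASD = 0.13),
                               sd = c(NT = 0.04, ASD = 0.04)))

  structure(list(groups = groups, rois = rois, models = models,
                 gains = gains, noise_sd = noise_sd,
                 subject_gain_sd = subject_gain_sd,
                 somatosensory_rois = somatosensory_rois,
                 questionnaires = q, covariates = covar),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$groups), "groups x", length(x$rois),
      "ROIs x", length(x$models), "model channels\n")
  cat("  noise_sd =", x$noise_sd, "; subject_gain_sd =", x$subject_gain_sd,
      "\n")
  cat("  affect gains:\n")
  print(x$gains[, , "affect", drop = FALSE])
  invisible(x)
}

# JSON round-trip so the truth is always serialized next to generated data
truth_to_json <- function(truth, path) {
  out <- unclass(truth)
  out$gains <- list(dim = dim(truth$gains),
                    dimnames = dimnames(truth$gains),
                    values = as.numeric(truth$gains))
  # named vectors must become JSON objects, not bare arrays
  out$questionnaires <- lapply(out$questionnaires, function(q) {
    q$mean <- as.list(q$mean); q$sd <- as.list(q$sd)
    q
  })
  out$covariates <- lapply(out$covariates, function(q) {
    list(mean = as.list(q$mean), sd = as.list(q$sd))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

truth_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  gains <- array(raw$gains$values, dim = raw$gains$dim,
                 dimnames = raw$gains$dimnames)
  qs <- lapply(raw$questionnaires, function(q) {
    q$mean <- unlist(q$mean); q$sd <- unlist(q$sd)
    if (!is.null(q$range)) q$range <- unlist(q$range)
    q
  })
  cov <- lapply(raw$covariates, function(q) {
    list(mean = unlist(q$mean), sd = unlist(q$sd))
  })
  structure(list(groups = raw$groups, rois = raw$rois, models = raw$models,
                 gains = gains, noise_sd = raw$noise_sd,
                 subject_gain_sd = raw$subject_gain_sd,
                 somatosensory_rois = raw$somatosensory_rois,
                 questionnaires = qs, covariates = cov),
            class = "ground_truth")
}
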