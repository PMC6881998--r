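# Model feature channels: each model RDM the regression will fit has a
# matching feature matrix (stimuli x channel dims). Patterns are built as a
# gain-weighted sum of random orthonormal projections of these channels, so
# the planted pattern geometry is exactly the geometry the model RDMs
# describe.
model_channels <- function(design, affect_coords = NULL) {
  zcol <- function(m) {
    m <- as.matrix(m)
    apply(m, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  }
  onehot <- function(f) {
    f <- factor(f)
    m <- stats::model.matrix(~ f - 1)
    colnames(m) <- levels(f)
    m
  }
  social <- as.numeric(design$category %in% c("social_positive",
                                              "social_negative"))
  if (is.null(affect_coords)) {
    # fall back to category anchors when no rating data are wired in
    anch <- default_rating_profile()$anchors[[1]]
    affect_coords <- t(anch[, as.character(design$category), drop = FALSE])
  }
  affect_coords <- as.matrix(affect_coords)
  stopifnot(nrow(affect_coords) == nrow(design), ncol(affect_coords) == 2)
  list(social = zcol(social),
       affect = zcol(affect_coords),
       motor_response = zcol(onehot(design$motor_response)),
       action_type = zcol(onehot(design$action_type)),
       intensity = zcol(design$intensity),
       motion_energy_pixel = zcol(design$motion_energy_pixel),
       motion_energy_total = zcol(design$motion_energy_total))
}

#' Simulate multi-voxel response patterns for a cohort
#'
#' For every subject and ROI, generates a stimulus x voxel response matrix
#' as a weighted sum of model-channel embeddings plus i.i.d. Gaussian
#' noise:
#' \deqn{P = \sum_m g(group, roi, m)\; F_m Q_{roi,m}^\top + \epsilon,}
#' where \eqn{F_m} is the (column-standardised) feature matrix of model
#' channel m and \eqn{Q_{roi,m}} is a random orthonormal voxel projection,
#' drawn once per (ROI, model) and shared by all subjects — so subjects
#' within a group share representational geometry up to noise. The affect
#' channel uses each group's mean (valence, arousal) stimulus coordinates,
#' making the planted affect geometry identical to the affect
#' dissimilarity model the regression stage fits. In somatosensory ROIs
#' the affect gain is additionally scaled per subject by
#' `exp(subject_gain_sd * gain_z)`, the hook that couples questionnaire
#' scores to embedding strength.
#'
#' @param design stimulus design table
#' @param truth a [ground_truth()] object
#' @param n_voxels voxels per ROI (>= 2; default 200)
#' @param subjects roster `data.frame` with columns `subject_id`, `group`
#'   and optionally `gain_z` (standard-normal subject deviates; defaults
#'   to 0)
#' @param affect_coords optional list, per group, of stimulus x 2 matrices
#'   of mean (valence, arousal) coordinates; a single matrix is shared by
#'   all groups; `NULL` falls back to category anchors
#' @param seed integer seed
#' @return named list (by subject id) of named lists (by ROI) of
#'   [pattern_set()] objects
#' @export
simulate_patterns <- function(design, truth, n_voxels = 200, subjects,
                              affect_coords = NULL, seed = 1) {
  validate_design(design)
  if (n_voxels < 2) stop("n_voxels must be >= 2 (pairwise correlation)")
  stopifnot(all(c("subject_id", "group") %in% names(subjects)))
  if (!all(subjects$group %in% truth$groups)) {
    stop("roster contains groups absent from the ground truth")
  }
  gain_z <- subjects$gain_z %||% rep(0, nrow(subjects))

  coords_for <- function(g) {
    if (is.null(affect_coords)) return(NULL)
    if (is.list(affect_coords) && !is.data.frame(affect_coords)) {
      affect_coords[[g]]
    } else {
      affect_coords
    }
  }
  channels_by_group <- lapply(stats::setNames(truth$groups, truth$groups),
                              function(g) {
                                model_channels(design, coords_for(g))
                              })
  models <- truth$models
  n_stim <- nrow(design)

  local_seed(seed, {
    # fixed per (roi, model): orthonormal projection into voxel space
    proj <- lapply(stats::setNames(truth$rois, truth$rois), function(roi) {
      lapply(stats::setNames(models, models), function(m) {
        d <- ncol(channels_by_group[[1]][[m]])
        if (d > n_voxels) stop("n_voxels smaller than channel dimension")
        q <- qr.Q(qr(matrix(stats::rnorm(n_voxels * d), n_voxels, d)))
        q[, seq_len(d), drop = FALSE]
      })
    })
    out <- vector("list", nrow(subjects))
    names(out) <- subjects$subject_id
    for (i in seq_len(nrow(subjects))) {
      g <- subjects$group[i]
      mult <- exp(truth$subject_gain_sd * gain_z[i])
      ch <- channels_by_group[[g]]
      out[[i]] <- lapply(stats::setNames(truth$rois, truth$rois),
                         function(roi) {
        p <- matrix(0, n_stim, n_voxels,
                    dimnames = list(design$stimulus_id, NULL))
        for (m in models) {
          gain <- truth$gains[g, roi, m]
          if (m == "affect" && roi %in% truth$somatosensory_rois) {
            gain <- gain * mult
          }
          if (gain > 0) p <- p + gain * (ch[[m]] %*% t(proj[[roi]][[m]]))
        }
        p <- p + matrix(stats::rnorm(n_stim * n_voxels, 0, truth$noise_sd),
                        n_stim, n_voxels)
        pattern_set(p, subject_id = subjects$subject_id[i], group = g,
                    roi = roi)
      })
    }
  })
  out
}

#' Simulate questionnaire and covariate scores
#'
#' Each scale is drawn around its group mean with the group SD, with a
#' fraction of the variance (the squared coupling) carried by the
#' subject's standardised somatosensory embedding strength `gain_z`:
#' social-touch preference (STQ) couples positively, autistic-trait scores
#' (SRS-A total and subscales) negatively. Age and mean framewise head
#' displacement are drawn uncoupled, for use as covariates.
#'
#' @param subjects roster with `subject_id`, `group`, optional `gain_z`
#' @param truth a [ground_truth()]
#' @param seed integer seed
#' @return `data.frame` with one row per subject: questionnaire totals,
#'   SRS-A subscales, `age`, `mean_fd`
#' @export
simulate_questionnaires <- function(subjects, truth, seed = 1) {
  stopifnot(all(c("subject_id", "group") %in% names(subjects)))
  gain_z <- subjects$gain_z %||% rep(0, nrow(subjects))
  n <- nrow(subjects)
  g <- subjects$group
  local_seed(seed, {
    cols <- lapply(truth$questionnaires, function(q) {
      rho <- q$coupling
      v <- q$mean[g] + q$sd[g] * (rho * gain_z +
             sqrt(1 - rho^2) * stats::rnorm(n))
      if (isTRUE(q$integer)) v <- round(v)
      if (!is.null(q$range)) v <- clamp(v, q$range[1], q$range[2])
      unname(v)
    })
    covs <- lapply(truth$covariates, function(q) {
      unname(pmax(q$mean[g] + q$sd[g] * stats::rnorm(n), 0))
    })
  })
  out <- data.frame(subject_id = subjects$subject_id, group = g,
                    stringsAsFactors = FALSE)
  for (nm in names(cols)) out[[nm]] <- cols[[nm]]
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  out
}
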