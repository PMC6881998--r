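test_that("rating generation honours the study bounds and determinism", {
  d <- tiny_design()
  r1 <- simulate_ratings(d, n_subjects_per_group = 3, seed = 21)
  r2 <- simulate_ratings(d, n_subjects_per_group = 3, seed = 21)
  expect_identical(r1, r2)
  expect_true(all(r1$valence %in% 1:9) && all(r1$arousal %in% 1:9))
  expect_equal(length(unique(r1$subject_id)), 6)
  expect_error(simulate_ratings(d, n_sessions = 0), "n_sessions")
})

test_that("a zero-noise profile makes the two sessions identical", {
  d <- tiny_design()
  prof <- default_rating_profile(stimulus_sd = 0, subject_sd = 0,
                                 session_sd = 0)
  r <- simulate_ratings(d, n_subjects_per_group = 2, profile = prof,
                        seed = 3)
  s1 <- r[r$session == 1, c("subject_id", "stimulus_id", "valence",
                            "arousal")]
  s2 <- r[r$session == 2, c("subject_id", "stimulus_id", "valence",
                            "arousal")]
  expect_equal(s1[order(s1$subject_id, s1$stimulus_id), ],
               s2[order(s2$subject_id, s2$stimulus_id), ],
               ignore_attr = TRUE)
})

test_that("default group medians land on the planted category structure", {
  co <- small_cohort()
  cs <- category_summary(co$agg, co$design)
  nt_ns_val <- cs$median[cs$group == "NT" & cs$category == "nonsocial" &
                           cs$dimension == "valence"]
  expect_gte(nt_ns_val, 4)
  expect_lte(nt_ns_val, 6)
  nt_pos <- cs$median[cs$group == "NT" & cs$category == "social_positive" &
                        cs$dimension == "valence"]
  nt_neg <- cs$median[cs$group == "NT" & cs$category == "social_negative" &
                        cs$dimension == "valence"]
  expect_gt(nt_pos, 6)
  expect_lt(nt_neg, 4)
  aro_soc <- cs$median[cs$group == "NT" & cs$category == "social" &
                         cs$dimension == "arousal"]
  aro_ns <- cs$median[cs$group == "NT" & cs$category == "nonsocial" &
                        cs$dimension == "arousal"]
  expect_gt(aro_soc, aro_ns)
})

test_that("pattern simulation is seeded, validated, and reproducible", {
  d <- tiny_design()
  truth <- ground_truth(rois = "BA1")
  roster <- data.frame(subject_id = c("NT01", "ASD01"),
                       group = c("NT", "ASD"))
  p1 <- simulate_patterns(d, truth, n_voxels = 12, roster, seed = 8)
  p2 <- simulate_patterns(d, truth, n_voxels = 12, roster, seed = 8)
  expect_identical(p1$NT01$BA1$matrix, p2$NT01$BA1$matrix)
  expect_identical(p1$ASD01$BA1$matrix, p2$ASD01$BA1$matrix)
  expect_error(simulate_patterns(d, truth, n_voxels = 1, roster),
               "n_voxels")
})

test_that("a single strongly planted model dominates the recovered
           geometry as noise vanishes", {
  d <- make_design(seed = 23)
  truth <- ground_truth(rois = "ROI1", groups = "NT",
                        somatosensory_rois = character(0))
  truth$gains[] <- 0
  truth$gains["NT", "ROI1", "social"] <- 5
  truth$noise_sd <- 1e-6
  roster <- data.frame(subject_id = "S1", group = "NT")
  pats <- simulate_patterns(d, truth, n_voxels = 80, roster, seed = 31)
  nr <- neural_rdm(pats$S1$ROI1)
  model <- model_rdm_binary(d)
  # a pure one-bit channel puts same-class patterns at r = 1 (distance 0)
  # and cross-class patterns at r = -1 (distance 2)
  expect_lt(max(abs(nr$values - 2 * model$values)), 1e-3)
  expect_gt(cor(upper_tri_vec(nr$values), upper_tri_vec(model$values)),
            0.999)
})

test_that("with all gains zero, permutation p-values are uniform", {
  d <- make_design(4, 4, 8, n_action_types = 4, seed = 41)
  truth <- ground_truth(rois = "ROI1", groups = "NT",
                        somatosensory_rois = character(0))
  truth$gains[] <- 0
  roster <- data.frame(subject_id = "S1", group = "NT")
  reg <- build_regressors(d, "general")
  ps <- vapply(1:200, function(rep) {
    pats <- simulate_patterns(d, truth, n_voxels = 30, roster,
                              seed = 5000 + rep)
    fit <- rsa_regression(neural_rdm(pats$S1$ROI1), reg, n_perm = 100,
                          seed = 6000 + rep)
    unname(fit$p_smooth["social"])
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
})

test_that("questionnaire generation couples scores to the planted
           somatosensory gains", {
  truth <- ground_truth()
  set.seed(61)
  roster <- data.frame(
    subject_id = sprintf("S%03d", 1:400),
    group = rep(c("NT", "ASD"), each = 200),
    gain_z = rnorm(400))
  q <- simulate_questionnaires(roster, truth, seed = 62)
  expect_true(all(q$stq_total >= 20 & q$stq_total <= 100))
  # positive STQ coupling, negative SRS coupling
  expect_gt(cor(q$stq_total[1:200], roster$gain_z[1:200]), 0.2)
  expect_lt(cor(q$srs_total[1:200], roster$gain_z[1:200]), -0.2)
  # shared gain_z induces a negative STQ-SRS correlation
  expect_lt(cor(q$stq_total, q$srs_total), 0)

  # null case: zero coupling and equal offsets leave no group difference
  truth0 <- truth
  for (nm in names(truth0$questionnaires)) {
    truth0$questionnaires[[nm]]$coupling <- 0
    truth0$questionnaires[[nm]]$mean[] <- 50
    truth0$questionnaires[[nm]]$sd[] <- 10
  }
  q0 <- simulate_questionnaires(roster, truth0, seed = 63)
  expect_lt(abs(mean(q0$stq_total[roster$group == "NT"]) -
                  mean(q0$stq_total[roster$group == "ASD"])), 3)
})

test_that("full cohort generation is a pure function of (config, seed)", {
  cfg <- cohort_config(n_subjects_per_group = 3, n_voxels = 16,
                       truth = ground_truth(rois = "BA1"))
  c1 <- simulate_cohort(cfg, seed = 77)
  c2 <- simulate_cohort(cfg, seed = 77)
  expect_identical(c1$ratings, c2$ratings)
  expect_identical(c1$questionnaires, c2$questionnaires)
  expect_identical(c1$patterns$NT01$BA1$matrix, c2$patterns$NT01$BA1$matrix)
  c3 <- simulate_cohort(cfg, seed = 78)
  expect_false(identical(c1$patterns$NT01$BA1$matrix,
                         c3$patterns$NT01$BA1$matrix))
})
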