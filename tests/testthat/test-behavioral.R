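make_agg <- function(df) {
  # convenience: a session-averaged table from explicit rows
  df$session <- NULL
  df
}

test_that("session aggregation averages repetitions per subject/stimulus", {
  d <- tiny_design()
  base <- expand.grid(subject_id = "S1", group = "NT", session = 1:2,
                      stimulus_id = d$stimulus_id,
                      stringsAsFactors = FALSE)
  base$valence <- ifelse(base$session == 1, 4, 6)
  base$arousal <- 5
  agg <- aggregate_sessions(base)
  expect_true(all(agg$valence == 5))
  expect_equal(nrow(agg), nrow(d))

  single <- base[base$session == 1, ]
  agg1 <- aggregate_sessions(single)
  expect_equal(sort(agg1$valence), sort(single$valence))
})

test_that("session aggregation equals an independent group-by-mean oracle", {
  co <- small_cohort()
  agg <- aggregate_sessions(co$ratings)
  r <- co$ratings
  for (i in sample(nrow(agg), 25)) {
    sel <- r$subject_id == agg$subject_id[i] &
      r$stimulus_id == agg$stimulus_id[i]
    expect_equal(agg$valence[i], mean(r$valence[sel]))
    expect_equal(agg$arousal[i], mean(r$arousal[sel]))
  }
})

test_that("incomplete stimulus coverage is reported with ids", {
  d <- tiny_design()
  base <- expand.grid(subject_id = "S1", group = "NT", session = 1,
                      stimulus_id = d$stimulus_id,
                      stringsAsFactors = FALSE)
  base$valence <- 5; base$arousal <- 5
  broken <- base[-3, ]
  expect_error(aggregate_sessions(broken, design = d), base$stimulus_id[3])
})

test_that("category medians and MADs are hand-countable", {
  d <- make_design(1, 1, 1, n_action_types = 1, seed = 9)
  ns <- d$stimulus_id[d$category == "nonsocial"]
  rows <- do.call(rbind, lapply(1:5, function(s) {
    data.frame(subject_id = paste0("S", s), group = "NT",
               stimulus_id = d$stimulus_id,
               valence = c(7, 3, s), arousal = c(5, 5, 5),
               stringsAsFactors = FALSE)
  }))
  cs <- category_summary(make_agg(rows), d)
  got <- cs[cs$category == "nonsocial" & cs$dimension == "valence", ]
  expect_equal(got$median, 3)  # values 1..5
  expect_equal(got$mad, 1)
  aro <- cs[cs$category == "nonsocial" & cs$dimension == "arousal", ]
  expect_equal(aro$mad, 0)     # constant values
})

test_that("category summaries are invariant to row order", {
  co <- small_cohort()
  cs1 <- category_summary(co$agg, co$design)
  shuffled <- co$agg[sample(nrow(co$agg)), ]
  cs2 <- category_summary(shuffled, co$design)
  expect_equal(cs1, cs2)
})

test_that("identical groups yield p = 1 under the exact-tie convention", {
  d <- tiny_design()
  rows <- do.call(rbind, lapply(sprintf("S%02d", 1:8), function(s) {
    data.frame(subject_id = s, group = ifelse(s <= "S04", "ASD", "NT"),
               stimulus_id = d$stimulus_id, valence = 5, arousal = 5,
               stringsAsFactors = FALSE)
  }))
  cmp <- compare_groups_ratings(make_agg(rows), d, "nonsocial", "valence",
                                groups = c("ASD", "NT"))
  expect_equal(cmp$p, 1)
  expect_equal(cmp$statistic, 0)
  expect_false(cmp$rejected)
})

test_that("disjoint supports drive the Mann-Whitney U to its extremum", {
  x <- c(rep(1, 10), rep(2, 11))        # heavily discrete: non-normal
  y <- c(rep(101, 11), rep(102, 10))
  cmp <- compare_groups(x, y, labels = c("lo", "hi"))
  expect_equal(cmp$test, "mann_whitney")
  expect_true(cmp$u %in% c(0, 21 * 21))
  expect_lt(cmp$p, 0.001)
})

test_that("affect distances follow the two-dimensional Pythagorean rule", {
  d <- make_design(1, 1, 1, n_action_types = 1, seed = 10)
  soc <- social_ids(d)
  agg <- data.frame(subject_id = "S1", group = "NT",
                    stimulus_id = d$stimulus_id,
                    valence = c(7, 3, 5), arousal = c(5, 2, 5),
                    stringsAsFactors = FALSE)
  ar <- affect_dissimilarity(agg, d)
  expect_equal(ar$values[soc[1], soc[2]], 5)  # 3-4-5 triangle
  agg2 <- agg; agg2$valence <- 4; agg2$arousal <- 4
  expect_true(all(affect_dissimilarity(agg2, d)$values == 0))
  expect_error(affect_dissimilarity(agg, d, stimuli = soc[1]), "2 stimuli")
})

test_that("affect matrix equals a per-subject-then-average double loop", {
  set.seed(31)
  d <- make_design(2, 2, 1, n_action_types = 1, seed = 30)
  soc <- social_ids(d)
  subs <- c("A", "B", "C")
  agg <- do.call(rbind, lapply(subs, function(s) {
    data.frame(subject_id = s, group = "NT", stimulus_id = d$stimulus_id,
               valence = sample(1:9, 5, TRUE),
               arousal = sample(1:9, 5, TRUE), stringsAsFactors = FALSE)
  }))
  got <- affect_dissimilarity(agg, d)$values
  brute <- matrix(0, 4, 4, dimnames = list(soc, soc))
  for (s in subs) {
    rows <- agg[agg$subject_id == s, ]
    for (i in soc) for (j in soc) {
      vi <- rows[rows$stimulus_id == i, ]
      vj <- rows[rows$stimulus_id == j, ]
      brute[i, j] <- brute[i, j] +
        sqrt((vi$valence - vj$valence)^2 + (vi$arousal - vj$arousal)^2)
    }
  }
  expect_equal(got, brute / 3, tolerance = 1e-12)
})

test_that("within-subject reliability recovers perfect and reversed
           consistency", {
  d <- make_design(2, 2, 2, n_action_types = 2, seed = 12)
  one <- data.frame(subject_id = "S1", group = "NT", session = 1,
                    stimulus_id = d$stimulus_id,
                    valence = c(1, 3, 4, 6, 8, 9),
                    arousal = c(2, 3, 4, 5, 6, 7),
                    stringsAsFactors = FALSE)
  two <- one; two$session <- 2
  wsr <- within_subject_reliability(rbind(one, two))
  expect_true(all(wsr$r == 1))
  two$valence <- rev(one$valence)
  two$arousal <- rev(one$arousal)
  wsr2 <- within_subject_reliability(rbind(one, two))
  expect_true(all(wsr2$r == -1))
  # constant vectors are flagged, not dropped
  one$valence <- 5; two$valence <- rev(one$valence)
  wsr3 <- within_subject_reliability(rbind(one, two))
  val <- wsr3[wsr3$dimension == "valence", ]
  expect_true(val$degenerate)
  expect_true(is.na(val$r))
})

test_that("within-subject reliability matches the textbook formula on noisy
           data", {
  co <- small_cohort()
  wsr <- within_subject_reliability(co$ratings)
  r <- co$ratings
  s <- wsr$subject_id[1]
  v1 <- r$valence[r$subject_id == s & r$session == 1]
  v2 <- r$valence[r$subject_id == s & r$session == 2]
  expect_equal(wsr$r[wsr$subject_id == s & wsr$dimension == "valence"],
               cor(rank(v1), rank(v2)), tolerance = 1e-12)
})

test_that("leave-one-out between-subject reliability honours the exclusion
           contract", {
  d <- tiny_design()
  mk <- function(s, vals) {
    data.frame(subject_id = s, group = "NT", stimulus_id = d$stimulus_id,
               valence = vals, arousal = vals, stringsAsFactors = FALSE)
  }
  clone_vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 1)
  agg <- rbind(mk("S1", clone_vals), mk("S2", clone_vals),
               mk("S3", clone_vals), mk("S4", clone_vals))
  bsr <- between_subject_reliability(agg, "NT")
  expect_true(all(bsr$per_subject$r == 1))

  set.seed(55)
  s4_vals <- sample(1:9, 10, TRUE)
  agg2 <- rbind(mk("S1", clone_vals), mk("S2", clone_vals),
                mk("S3", clone_vals), mk("S4", s4_vals))
  bsr2 <- between_subject_reliability(agg2, "NT")
  per <- bsr2$per_subject
  r4 <- per$r[per$subject_id == "S4" & per$dimension == "valence"]
  expect_true(abs(r4) < 0.9)
  # exclusion contract: S4's reference is the clone mean, untouched by
  # S4's own ratings — so S4's LOO r is exactly cor(S4, clones)
  expect_equal(r4, cor(rank(s4_vals), rank(clone_vals)),
               tolerance = 1e-12)
  # and it is identical under a different draw for S4's reference side
  agg3 <- agg2
  agg3$valence[agg3$subject_id == "S4"] <- rev(s4_vals)
  bsr3 <- between_subject_reliability(agg3, "NT")
  per3 <- bsr3$per_subject
  expect_equal(per3$r[per3$subject_id == "S4" & per3$dimension == "valence"],
               cor(rank(rev(s4_vals)), rank(clone_vals)),
               tolerance = 1e-12)
})

test_that("swapping group labels flips the statistic and keeps p", {
  set.seed(77)
  x <- rnorm(15); y <- rnorm(15, 0.5)
  a <- compare_groups(x, y)
  b <- compare_groups(y, x)
  expect_equal(a$p, b$p, tolerance = 1e-12)
  if (a$test == "t_two_sample") {
    expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
  } else {
    expect_equal(a$u, 15 * 15 - b$u)
  }
  xb <- c(rep(1, 8), rep(9, 7)); yb <- c(rep(2, 7), rep(8, 8))
  a <- compare_groups(xb, yb)
  b <- compare_groups(yb, xb)
  expect_equal(a$test, "mann_whitney")
  expect_equal(a$u, 15 * 15 - b$u)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})
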