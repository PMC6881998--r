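# shared small fixtures, built in code

tiny_design <- function(seed = 101) {
  make_design(n_pos = 3, n_neg = 3, n_nonsocial = 4, n_action_types = 3,
              seed = seed)
}

# a small but complete cohort reused by several files (6 + 6 subjects,
# 40 voxels, 2 ROIs); built once per test run
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- cohort_config(n_subjects_per_group = 6, n_voxels = 40,
                           truth = ground_truth(rois = c("BA1", "TPJ")))
      cache <<- simulate_cohort(cfg, seed = 424242)
    }
    cache
  }
})

# hand-rolled symmetric matrix with distinct, position-coded entries:
# value(i, j) = 10 * min(i,j) + max(i,j)
position_coded_matrix <- function(n) {
  m <- outer(seq_len(n), seq_len(n),
             function(i, j) 10 * pmin(i, j) + pmax(i, j))
  diag(m) <- 0
  m
}
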