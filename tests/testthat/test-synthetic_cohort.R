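test_that("cohort_spec validates its fields and names the offender", {
  expect_error(cohort_spec(n_rois = 0), "n_rois")
  expect_error(cohort_spec(n_rois = 10, n_blocks = 11), "n_blocks")
  expect_error(cohort_spec(within_block_mu = 1.2), "within_block_mu")
  expect_error(cohort_spec(between_block_mu = 0), "between_block_mu")
  expect_error(cohort_spec(group_effect = -0.1), "group_effect")
  expect_error(cohort_spec(noise_sd = -1), "noise_sd")
  expect_error(cohort_spec(n_blocks = 4, effect_blocks = 5), "effect_blocks")
})

test_that("every generated FC matrix satisfies the FC invariants", {
  spec <- cohort_spec(n_rois = 30, n_subjects_per_group = 4, n_blocks = 3,
                      noise_sd = 0.08, seed = 11)
  ch <- generate_cohort(spec)
  expect_length(ch$fc, 8)
  for (fc in ch$fc) {
    m <- fc$matrix
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 1))
    expect_true(all(abs(m) <= 1))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  expect_setequal(ch$subjects$group, c("A", "B"))
  expect_true(all(ch$subjects$age > 0))
  expect_true(all(ch$subjects$gender %in% c("F", "M")))
  expect_true(all(is.na(ch$subjects$clinical_score)))
})

test_that("zero effect and zero noise give identical group expectations", {
  spec <- cohort_spec(n_rois = 12, n_subjects_per_group = 2, n_blocks = 2,
                      group_effect = 0, noise_sd = 0, seed = 1)
  ch <- generate_cohort(spec)
  expect_identical(ch$fc[[1]]$matrix, ch$fc[[3]]$matrix)  # an A vs a B subject
})

test_that("noiseless block construction is exact", {
  spec <- cohort_spec(n_rois = 10, n_subjects_per_group = 1, n_blocks = 2,
                      within_block_mu = 0.6, between_block_mu = 0.1,
                      noise_sd = 0, group_effect = 0.2, seed = 1)
  ch <- generate_cohort(spec)
  b <- ch$blocks
  same <- outer(b, b, "==")
  mB <- ch$fc[[2]]$matrix           # group B
  off <- upper.tri(mB)
  expect_true(all(mB[off & same] == 0.6))
  expect_true(all(mB[off & !same] == 0.1))
  mA <- ch$fc[[1]]$matrix           # group A: within reduced by the effect
  expect_true(all(abs(mA[off & same] - 0.4) < 1e-12))
})

test_that("generation is a pure function of the seed", {
  spec <- cohort_spec(n_rois = 15, n_subjects_per_group = 3, n_blocks = 3,
                      seed = 7)
  ch1 <- generate_cohort(spec)
  ch2 <- generate_cohort(spec)
  expect_identical(ch1, ch2)
  ch3 <- generate_cohort(cohort_spec(n_rois = 15, n_subjects_per_group = 3,
                                     n_blocks = 3, seed = 8))
  expect_false(identical(ch1$fc[[1]]$matrix, ch3$fc[[1]]$matrix))
})

test_that("planted effect lowers group A within-block correlation", {
  hits <- 0L
  for (seed in 1:20) {
    spec <- cohort_spec(n_rois = 20, n_subjects_per_group = 20, n_blocks = 2,
                        group_effect = 0.15, noise_sd = 0.05, seed = seed)
    ch <- generate_cohort(spec)
    same <- outer(ch$blocks, ch$blocks, "==") & upper.tri(diag(20))
    wmean <- vapply(ch$fc, function(f) mean(f$matrix[same]), numeric(1))
    grp <- ch$subjects$group
    hits <- hits + (mean(wmean[grp == "A"]) < mean(wmean[grp == "B"]))
  }
  expect_gte(hits / 20, 0.95)
})

test_that("time-series mode emits the exact sample correlation of its series", {
  spec <- cohort_spec(n_rois = 8, n_subjects_per_group = 2, n_blocks = 2,
                      n_timepoints = 60, seed = 5)
  ch <- generate_cohort(spec)
  for (fc in ch$fc) {
    ts <- attr(fc, "timeseries")
    expect_equal(dim(ts), c(8, 60))
    expect_lt(max(abs(cor(t(ts)) - fc$matrix)), 1e-12)
  }
})

test_that("clinical scores follow the stated linear model", {
  spec <- cohort_spec(n_rois = 10, n_subjects_per_group = 4, n_blocks = 2,
                      score_slope = 0, score_noise_sd = 0, seed = 2)
  ch <- generate_cohort(spec)
  s <- generate_clinical_scores(ch$subjects, rep(1.5, 4), spec)
  expect_true(all(s$clinical_score[s$group == "A"] == 0))
  expect_true(all(is.na(s$clinical_score[s$group == "B"])))

  spec2 <- cohort_spec(n_rois = 10, n_subjects_per_group = 4, n_blocks = 2,
                       score_slope = 2, score_noise_sd = 0, seed = 2)
  s2 <- generate_clinical_scores(ch$subjects, rep(1.5, 4), spec2)
  expect_equal(s2$clinical_score[s2$group == "A"], rep(3.0, 4))

  expect_error(generate_clinical_scores(ch$subjects, rep(1, 3), spec),
               "length")
})

test_that("score noise keeps the generating correlation high at slope 1", {
  spec <- cohort_spec(n_rois = 10, n_subjects_per_group = 200, n_blocks = 2,
                      score_slope = 1, score_noise_sd = 0.1, seed = 3)
  nodal <- with(list(), {set.seed(31); rnorm(200)})
  ch_subj <- data.frame(subject_id = sprintf("A%03d", 1:200), group = "A",
                        age = 20, gender = "M", clinical_score = NA_real_)
  s <- generate_clinical_scores(ch_subj, nodal, spec)
  expect_gt(cor(s$clinical_score, nodal), 0.9)
})

test_that("term table plants enrichment as specified", {
  at <- synthetic_atlas(28)
  n_def <- sum(at$rsn == "Default")
  tt1 <- generate_term_table(at, "Default", c("social", "memory"),
                             c("task"), p_hit = 1, seed = 1)
  cnt <- term_counts(at$roi_id[at$rsn == "Default"], tt1)
  expect_equal(unname(cnt[c("social", "memory")]), rep(n_def, 2))

  tt0 <- generate_term_table(at, "Default", c("social"), c("task"),
                             p_hit = 0, seed = 1)
  expect_false("social" %in% tt0$term)

  tt <- generate_term_table(at, "Default", "social", "task",
                            p_hit = 0.8, seed = 9)
  k <- sum(tt$term == "social")
  expect_true(k >= 0 && k <= n_def)   # binomial(n_def, 0.8) support
  expect_identical(tt, generate_term_table(at, "Default", "social", "task",
                                           p_hit = 0.8, seed = 9))
  expect_error(generate_term_table(at, "NoSuchRSN", "a", "b", 1, 1),
               "unknown RSN")
})

test_that("cohort artifacts round-trip through the plain-text writers", {
  spec <- cohort_spec(n_rois = 8, n_subjects_per_group = 2, n_blocks = 2,
                      seed = 4)
  ch <- generate_cohort(spec)
  d <- withr::local_tempdir()
  write_cohort(ch, d)
  fc_back <- read_fc_matrix(file.path(d, "fc", "A001.csv"))
  expect_equal(fc_back$matrix, ch$fc[[1]]$matrix, tolerance = 0)
  subj <- read.delim(file.path(d, "subjects.tsv"))
  expect_equal(subj$subject_id, ch$subjects$subject_id)
})
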