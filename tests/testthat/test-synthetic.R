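test_that("make_paradigm reproduces the sparse alternating design", {
  p <- make_paradigm(4)
  expect_length(p$stim_onsets, 2)                 # 4 scans -> 2 stimuli
  expect_equal(diff(p$stim_onsets), 32)           # 32 s stimulus spacing
  expect_equal(p$acq_onsets, c(0, 16, 32, 48))    # acquisitions every TR
  # each 6 s stimulus ends exactly at every second acquisition's onset
  expect_equal(p$stim_onsets + 6, p$acq_onsets[c(2, 4)])
  expect_equal(p$sample_times, p$acq_onsets + 2.5)  # TA/2 reference point
  expect_s3_class(make_paradigm(1), "dcm_paradigm") # degenerate but valid
  expect_error(make_paradigm(4, TA = -1), "positive")
  expect_error(make_paradigm(4, stim_dur = 20), "exceeds TR")
})

test_that("simulate_subject is seeded, additive and exact at zero noise", {
  spec <- build_pruned_winner()
  truth <- auditory_ground_truth(spec)
  par <- make_paradigm(8, dt = 0.25)
  clean <- predict_bold(truth, par)
  s0 <- simulate_subject(spec, truth, par, noise_sd = 0, seed = 4)
  expect_equal(s0$bold, clean)
  s1 <- simulate_subject(spec, truth, par, noise_sd = 0.01, seed = 4)
  s2 <- simulate_subject(spec, truth, par, noise_sd = 0.01, seed = 4)
  expect_identical(s1$bold, s2$bold)
  s3 <- simulate_subject(spec, truth, par, noise_sd = 0.01, seed = 5)
  expect_false(identical(s1$bold, s3$bold))
})

test_that("the realized noise SD matches the request over 1000 scans", {
  spec <- build_pruned_winner()
  truth <- auditory_ground_truth(spec)
  par <- make_paradigm(1000, dt = 0.5)
  clean <- predict_bold(truth, par)
  s <- simulate_subject(spec, truth, par, noise_sd = 0.005, seed = 9)
  expect_lt(abs(sd(s$bold - clean) / 0.005 - 1), 0.1)
})

test_that("ground-truth parameters carry the published group means", {
  tr <- auditory_ground_truth()
  expect_equal(tr$a["LHG", "LSTG"], 0.0973)
  expect_equal(tr$a["RHG", "LSTG"], 0.0801)
  expect_equal(tr$a["LHG", "RSTG"], 0.1716)
  expect_equal(tr$a["RHG", "RSTG"], 0.1339)
  expect_equal(unname(diag(tr$a)), rep(-0.5, 4))
  expect_equal(unname(tr$c["LSTG", 1]), 0.1356)
  expect_equal(unname(tr$c["RSTG", 1]), 0.2551)
  # a fully connected spec picks up all 12 published couplings
  full <- build_fully_connected(auditory_regions(), c("LSTG", "RSTG"))
  trf <- auditory_ground_truth(full)
  expect_equal(sum(trf$a[row(trf$a) != col(trf$a)] != 0), 12)
  expect_equal(trf$a["LSTG", "RHG"], -0.0011)  # sign-restored published mean
  # gating/modulation values fill the supports
  m10 <- build_nonlinear_family(build_pruned_winner())[[1]]
  trn <- auditory_ground_truth(m10, d_value = 0.5)
  expect_equal(sum(unlist(trn$d) != 0), 4)
  expect_true(all(unlist(trn$d)[unlist(trn$d) != 0] == 0.5))
})

test_that("cohorts are seeded, jittered around the mean, and reproducible", {
  cs <- cohort_spec(n_subjects = 10, n_scans = 8, dt = 0.5, seed = 6)
  co <- simulate_cohort(cs)
  expect_length(co$subjects, 10)
  # distinct noise across subjects
  expect_false(identical(co$subjects[[1]]$bold, co$subjects[[2]]$bold))
  # per-subject couplings jitter around the published mean
  draws <- vapply(co$truth$subject_params, function(p) p$a["LHG", "RSTG"],
                  numeric(1))
  expect_gt(sd(draws), 0)
  expect_lt(abs(mean(draws) - 0.1716), 3 * 0.05 / sqrt(10))
  # identical spec -> identical data
  co2 <- simulate_cohort(cs)
  expect_identical(co$subjects[[7]]$bold, co2$subjects[[7]]$bold)
  # sd_between = 0 -> all subjects share the mean parameters
  cs0 <- cohort_spec(n_subjects = 3, sd_between = 0, n_scans = 8, dt = 0.5,
                     seed = 6)
  co0 <- simulate_cohort(cs0)
  expect_identical(co0$truth$subject_params[[1]]$a,
                   co0$truth$subject_params[[3]]$a)
})

test_that("log-evidence fixtures have the stated structure", {
  tab <- make_logevidence_fixture(10, 6, winner_index = 2, effect_nats = 5,
                                  seed = 12)
  expect_equal(dim(tab$F), c(10, 6))
  expect_identical(tab, make_logevidence_fixture(10, 6, winner_index = 2,
                                                 effect_nats = 5, seed = 12))
  expect_error(make_logevidence_fixture(10, 2, winner_index = 3),
               "winner_index")
})

test_that("cohorts round-trip through the on-disk format byte-identically", {
  cs <- cohort_spec(n_subjects = 3, n_scans = 8, dt = 0.5, seed = 14)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  co <- simulate_cohort(cs)
  write_cohort(co, dir1)
  write_cohort(simulate_cohort(cs), dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  back <- read_cohort(dir1)
  expect_length(back$subjects, 3)
  expect_equal(back$subjects[[2]]$bold, co$subjects[[2]]$bold,
               tolerance = 1e-10)
  expect_equal(back$paradigm$sample_times, co$paradigm$sample_times)
  # ground truth stored in the manifest
  expect_equal(back$manifest$truth$mean_a[[1]][[4]], 0.1716)
})
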