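test_that("one_sample_t matches stats::t.test", {
  set.seed(31)
  x <- rnorm(10, mean = 0.1, sd = 0.1)
  got <- one_sample_t(x)
  ref <- t.test(x)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$n, 10)
  # scale invariance of t
  expect_equal(one_sample_t(3.7 * x)$t, got$t, tolerance = 1e-12)
  expect_error(one_sample_t(1), "at least 2")
})

test_that("t recomputes from the published summaries", {
  expect_lt(abs(t_from_summary(0.0973, 0.0974, 10)$t - 3.158), 0.005)
  expect_lt(abs(t_from_summary(0.1339, 0.1032, 10)$t - 4.101), 0.005)
  expect_lt(abs(t_from_summary(0.1716, 0.1432, 10)$t - 3.790), 0.005)
  expect_warning(t_from_summary(0.1, 0, 10), "infinite t")
  expect_error(t_from_summary(0.1, -1, 10), "non-negative")
})

test_that("the Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 12), 0.05 / 12)
  expect_equal(signif(bonferroni_threshold(0.05, 12), 4), 4.167e-3)
  expect_error(bonferroni_threshold(1.5, 12), "family_alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m_tests")
})

test_that("pruning the published table retains exactly the four bold rows", {
  ref <- reference_connection_stats()
  cons <- ref[ref$type == "coupling", ]
  expect_equal(nrow(cons), 12)
  # pruning the printed (p, P) columns against alpha/12: the printed
  # p-column is the plain two-sided p divided by the 12 tests, so this
  # matches the published retention pattern
  kept <- prune_connections(cons, threshold = bonferroni_threshold(0.05, 12))
  expect_equal(nrow(kept), 4)
  expect_setequal(paste(kept$source, kept$target, sep = "->"),
                  c("LSTG->LHG", "LSTG->RHG", "RSTG->LHG", "RSTG->RHG"))
  expect_setequal(paste(kept$source, kept$target, sep = "->"),
                  paste(cons$source[cons$highlighted == 1],
                        cons$target[cons$highlighted == 1], sep = "->"))
  # idempotence
  kept2 <- prune_connections(kept, bonferroni_threshold(0.05, 12))
  expect_equal(kept2[, c("source", "target")], kept[, c("source", "target")],
               ignore_attr = TRUE)
})

test_that("connection_stats aggregates per-subject posteriors correctly", {
  spec <- build_pruned_winner()
  nms <- default_priors(spec)$theta$name
  set.seed(5)
  fits <- lapply(1:10, function(i) {
    mean <- setNames(rnorm(length(nms), 0.1, 0.02), nms)
    cov <- diag(0.002, length(nms)); dimnames(cov) <- list(nms, nms)
    structure(list(mean = mean, cov = cov), class = "dcm_fit")
  })
  st <- connection_stats(fits)
  expect_s3_class(st, "dcm_connection_stats")
  expect_equal(sum(st$type == "coupling"), 4)
  expect_equal(sum(st$type == "input"), 2)
  i <- which(st$parameter == "a:LSTG->LHG")
  vals <- vapply(fits, function(f) f$mean[["a:LSTG->LHG"]], numeric(1))
  expect_equal(st$mean_hz[i], mean(vals), tolerance = 1e-12)
  expect_equal(st$t[i], one_sample_t(vals)$t, tolerance = 1e-12)
  wantP <- mean(vapply(fits, function(f) {
    pnorm(0, f$mean[["a:LSTG->LHG"]], sqrt(0.002), lower.tail = FALSE)
  }, numeric(1)))
  expect_equal(st$P[i], wantP, tolerance = 1e-12)
  expect_equal(st$p_adj, pmin(1, st$p * 4), tolerance = 1e-12)
  # inputs never enter the retention set
  expect_false(any(st$retained[st$type == "input"]))
})

test_that("pruned_spec_from_stats rebuilds the retained skeleton", {
  full <- build_fully_connected(auditory_regions(), c("LSTG", "RSTG"))
  retained <- data.frame(source = c("LSTG", "RSTG"), target = c("LHG", "LHG"))
  sp <- pruned_spec_from_stats(full, retained, name = "pr")
  expect_equal(sum(sp$a_support) - 4, 2)
  expect_equal(sp$a_support["LHG", "LSTG"], 1L)
  expect_equal(sp$a_support["LHG", "RSTG"], 1L)
  expect_identical(sp$c_support, full$c_support)
})

test_that("connection stats round-trip through delimited text", {
  ref <- reference_connection_stats()
  expect_equal(nrow(ref), 14)
  path <- withr::local_tempfile(fileext = ".tsv")
  stats <- ref
  stats$p_adj <- pmin(1, stats$p * 12)
  stats$retained <- stats$highlighted == 1
  class(stats) <- c("dcm_connection_stats", "data.frame")
  write_connection_stats(stats, path)
  back <- read_connection_stats(path)
  expect_equal(back$mean_hz, ref$mean_hz, tolerance = 1e-10)
  expect_equal(back$t, ref$t, tolerance = 1e-10)
})

test_that("published t values recompute from printed mean and SD", {
  ref <- reference_connection_stats()
  t_re <- ref$mean_hz / (ref$sd / sqrt(10))
  # printed summaries are rounded to 4 decimals; all rows agree within the
  # resulting propagation bound, and the three headline rows within 0.005
  expect_lt(max(abs(t_re - ref$t)), 0.06)
  hl <- ref$highlighted == 1 & ref$type == "coupling"
  expect_true(all(abs(t_re[hl] - ref$t[hl]) < 0.005))
})

test_that("the published BMS reference table is internally consistent", {
  bt <- reference_bms_table()
  # with alpha0 = 1 per model, sum(alpha) = N + K = 10 + K, so every row's
  # expected posterior probability recomputes as alpha / (10 + K)
  expect_equal(bt$expected_r, round(bt$alpha / (10 + bt$K), 4),
               tolerance = 1e-9)
  inp <- bt[bt$comparison == "input_stage", ]
  expect_equal(inp$expected_r, round(expected_posterior(inp$alpha), 4),
               tolerance = 1e-9)
  expect_equal(inp$phi, round(exceedance_prob(inp$alpha), 4),
               tolerance = 1e-9)
})
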