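test_that("region sets validate labels and fix the canonical order", {
  expect_error(region_set("LHG"), "at least 2")
  expect_error(region_set(c("A", "A")), "unique")
  expect_error(region_set(c("A", "")), "unique and non-empty")
  expect_identical(auditory_regions()$labels, c("LHG", "LSTG", "RHG", "RSTG"))
  expect_identical(auditory_regions()$n, 4L)
})

test_that("model_spec enforces self-connections and validates supports", {
  reg <- auditory_regions()
  a <- matrix(0L, 4, 4)
  cmat <- matrix(c(0L, 1L, 0L, 1L), 4, 1)
  sp <- model_spec(reg, a, cmat)
  expect_s3_class(sp, "dcm_model_spec")
  expect_true(all(diag(sp$a_support) == 1L))
  # modulation outside a_support is rejected at construction
  b_bad <- matrix(0L, 4, 4); b_bad[1, 2] <- 1L
  expect_error(model_spec(reg, a, cmat, b_supports = list(b_bad)),
               "outside a_support")
})

test_that("validate_spec reports every violation and never throws", {
  sp <- build_pruned_winner()
  sp$b_supports[[1]][3, 1] <- 1L   # LHG -> RHG not in the skeleton
  sp$d_supports[[1]][4, 1] <- 1L   # LHG -> RSTG not in the skeleton
  v <- validate_spec(sp)
  expect_length(v, 2)
  expect_true(any(grepl("b_supports", v)))
  expect_true(any(grepl("d_supports", v)))
  expect_identical(validate_spec(build_pruned_winner()), character(0))
})

test_that("fully connected input candidates have 12 connections and one input", {
  mA <- build_fully_connected(auditory_regions(), c("LHG", "RHG"),
                              name = "input_HG")
  expect_equal(sum(mA$a_support) - 4, 12)
  expect_equal(unname(mA$c_support[, 1]), c(1L, 0L, 1L, 0L))
  expect_false(is_nonlinear_spec(mA))
  expect_error(build_fully_connected(auditory_regions(), "XHG"),
               "unknown region")
  expect_error(build_fully_connected(auditory_regions(), character(0)),
               "non-empty")
})

test_that("the pruned winner has exactly the four STG->HG connections", {
  sp <- build_pruned_winner()
  cons <- nldcm:::connection_pairs(sp)
  expect_equal(nrow(cons), 4)
  got <- paste(cons$source, cons$target, sep = "->")
  expect_setequal(got, c("LSTG->LHG", "LSTG->RHG", "RSTG->LHG", "RSTG->RHG"))
  expect_equal(unname(sp$c_support[, 1]), c(0L, 1L, 0L, 1L))
})

test_that("the default bilinear family has six members with valid supports", {
  fam <- build_bilinear_family(build_pruned_winner())
  expect_length(fam, 6)
  expect_equal(sum(fam[[1]]$b_supports[[1]]), 4)   # all four modulated
  expect_equal(sum(fam[[6]]$b_supports[[1]]), 0)   # unmodulated copy
  for (sp in fam) {
    expect_identical(validate_spec(sp), character(0))
    expect_false(is_nonlinear_spec(sp))
  }
})

test_that("the default non-linear family has six members, first gating 4 entries", {
  fam <- build_nonlinear_family(build_pruned_winner())
  expect_length(fam, 6)
  expect_true(is_nonlinear_spec(fam[[1]]))
  expect_equal(sum(vapply(fam[[1]]$d_supports, sum, numeric(1))), 4)
  # member 1: each STG gates its own outgoing connections
  lab <- fam[[1]]$regions$labels
  d_lstg <- fam[[1]]$d_supports[[match("LSTG", lab)]]
  # LSTG gates LSTG->LHG and LSTG->RHG (row = target, column = source)
  expect_equal(d_lstg[match("LHG", lab), match("LSTG", lab)], 1L)
  expect_equal(d_lstg[match("RHG", lab), match("LSTG", lab)], 1L)
  expect_false(is_nonlinear_spec(fam[[6]]))  # "none" member is linear
  for (sp in fam) expect_identical(validate_spec(sp), character(0))
})

test_that("family builders adapt to non-canonical skeletons", {
  reg <- auditory_regions()
  a <- matrix(0L, 4, 4); a[1, 2] <- 1L  # single connection LSTG -> LHG
  cmat <- matrix(c(0L, 1L, 0L, 1L), 4, 1)
  base <- model_spec(reg, a, cmat, name = "partial")
  bil <- build_bilinear_family(base)
  nl <- build_nonlinear_family(base)
  expect_gte(length(bil), 2)
  expect_gte(length(nl), 2)
  for (sp in c(bil, nl)) expect_identical(validate_spec(sp), character(0))
  # degenerate empty skeleton still yields valid (linear) families
  empty <- model_spec(reg, matrix(0L, 4, 4), cmat, name = "empty")
  for (sp in c(build_bilinear_family(empty), build_nonlinear_family(empty))) {
    expect_identical(validate_spec(sp), character(0))
  }
})

test_that("requesting a variant on an absent connection is an input error", {
  base <- build_pruned_winner()
  expect_error(
    build_bilinear_family(base, list(bad = list(c("LHG", "LSTG")))),
    "not present in base model")
})

test_that("model specs round-trip through YAML losslessly", {
  sp <- build_nonlinear_family(build_pruned_winner())[[1]]
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(sp, path)
  sp2 <- read_model_spec(path)
  expect_identical(sp2$a_support, sp$a_support)
  expect_identical(sp2$c_support, sp$c_support)
  expect_identical(sp2$b_supports, sp$b_supports)
  expect_identical(sp2$d_supports, sp$d_supports)
  expect_identical(sp2$name, sp$name)
})
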