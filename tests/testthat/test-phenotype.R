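test_that("panel validation flags range, quartet-sum and intersection violations", {
  expect_equal(nrow(validate_panel(make_panel())), 0)
  v <- validate_panel(make_panel(cd4_emra = 25))  # quartet sums to 110
  expect_true("quartet_sum_100" %in% v$rule)
  v <- validate_panel(make_panel(cd8_senescent = 30, cd8_cd28neg = 10))
  expect_true("intersection_bound" %in% v$rule)
  v <- validate_panel(make_panel(treg_of_cd4 = 120))
  expect_true("range_0_100" %in% v$rule)
  expect_error(validate_panel(c(make_panel(), bogus_subset = 5)), "bogus_subset")
})

test_that("absolute counts chain the parent path and reproduce hand arithmetic", {
  p <- make_panel(tcell_of_lymphs = 50, cd4_of_t = 60, cd4_naive = 50)
  ac <- absolute_counts(p, lymphocyte_count = 2.0)
  expect_equal(unname(ac["cd4_naive"]), 0.30)
  expect_equal(unname(ac["tcell_of_lymphs"]), 1.0)
  p0 <- make_panel(cd8_em = 0)
  expect_equal(unname(absolute_counts(p0, 2.0)["cd8_em"]), 0)
})

test_that("absolute counts agree with an independent per-step multiplication oracle", {
  schema <- subset_schema()
  parent_of <- setNames(schema$parent, schema$name)
  oracle <- function(panel, lymph) {
    out <- numeric(length(panel)); names(out) <- names(panel)
    for (nm in names(panel)) {
      path <- nm; cur <- nm
      while (parent_of[[cur]] != "lymphocytes") {
        cur <- parent_of[[cur]]; path <- c(path, cur)
      }
      v <- lymph
      for (step in rev(path)) v <- v * panel[[step]] / 100
      out[nm] <- v
    }
    out
  }
  set.seed(42)
  for (i in 1:20) {
    p <- make_panel()
    p[] <- runif(length(p), 0, 100)
    lymph <- runif(1, 0.2, 4)
    got <- absolute_counts(p, lymph)
    want <- oracle(p, lymph)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("absolute counts are homogeneous of degree 1 in the lymphocyte count", {
  p <- make_panel()
  expect_equal(absolute_counts(p, 3.4), 2 * absolute_counts(p, 1.7),
               tolerance = 1e-12)
})

test_that("subset counts never exceed their parent counts", {
  coh <- default_cohort()
  schema <- subset_schema()
  parent_of <- setNames(schema$parent, schema$name)
  for (i in c(1, 25, 100)) {
    lymph <- coh$subjects$lymphocytes_1e9_per_L[i]
    ac <- absolute_counts(coh$panels[i, , drop = FALSE], lymph)
    for (nm in names(ac)) {
      pc <- if (parent_of[[nm]] == "lymphocytes") lymph else ac[[parent_of[[nm]]]]
      expect_lte(ac[[nm]], pc + 1e-12)
    }
  }
})

test_that("a missing lymphocyte count is an explicit error, not a silent zero", {
  expect_error(absolute_counts(make_panel(), NA_real_), "missing",
               class = "immflow_missing_data_error")
  expect_error(absolute_counts(make_panel(), 0), "positive")
})

test_that("naive:memory ratio is the quartet complement ratio", {
  p <- make_panel(cd4_naive = 40, cd4_cm = 10, cd4_em = 5, cd4_emra = 5)
  expect_equal(naive_memory_ratio(p, "cd4"), 2.0)
  p <- make_panel(cd8_naive = 0, cd8_cm = 40, cd8_em = 30, cd8_emra = 30)
  expect_equal(naive_memory_ratio(p, "cd8"), 0)
  p <- make_panel(cd4_naive = 25, cd4_cm = 25, cd4_em = 25, cd4_emra = 25)
  expect_equal(naive_memory_ratio(p, "cd4"), 1 / 3)
  p <- make_panel(cd8_naive = 100, cd8_cm = 0, cd8_em = 0, cd8_emra = 0)
  expect_error(naive_memory_ratio(p, "cd8"), "undefined",
               class = "immflow_degenerate_error")
})

test_that("shipped JSON schema matches the in-code dictionary", {
  path <- system.file("extdata", "subset_schema.json", package = "immflow")
  js <- jsonlite::fromJSON(path)$subsets
  sc <- subset_schema()
  expect_equal(js$name, sc$name)
  expect_equal(js$parent, sc$parent)
  expect_equal(js$quartet, sc$quartet)
})
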