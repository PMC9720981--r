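planted_rf_data <- function(seed, n = 200, p_noise = 9) {
  set.seed(seed)
  labels <- rep(c(FALSE, TRUE), length.out = n)
  X <- as.data.frame(matrix(rnorm(n * p_noise), n, p_noise))
  names(X) <- paste0("noise", seq_len(p_noise))
  X$signal <- as.numeric(labels)
  list(X = X, labels = labels)
}

test_that("a label-informative feature outranks pure noise", {
  d <- planted_rf_data(31)
  res <- fit_rank(d$X, d$labels, rf_config(seed = 31))
  expect_equal(res$ranking[1], "signal")
  expect_true(all(res$mda["signal"] > res$mda[paste0("noise", 1:9)]))
  expect_gt(res$oob_accuracy, 0.9)
})

test_that("all-noise features give chance-level OOB accuracy", {
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    labels <- rep(c(FALSE, TRUE), each = 100)
    X <- as.data.frame(matrix(rnorm(200 * 10), 200, 10))
    fit_rank(X, labels, rf_config(seed = s))$oob_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("fits are deterministic given the seed", {
  d <- planted_rf_data(32)
  r1 <- fit_rank(d$X, d$labels, rf_config(seed = 5))
  r2 <- fit_rank(d$X, d$labels, rf_config(seed = 5))
  expect_identical(r1$ranking, r2$ranking)
  expect_identical(r1$mda, r2$mda)
  expect_identical(r1$oob_accuracy, r2$oob_accuracy)
})

test_that("OOB accuracy equals the accuracy implied by the confusion table", {
  d <- planted_rf_data(33)
  r <- fit_rank(d$X, d$labels, rf_config(seed = 33))
  expect_equal(sum(r$confusion), r$n_used)
  expect_identical(r$oob_accuracy, sum(diag(r$confusion)) / sum(r$confusion))
})

test_that("a duplicated informative feature splits importance but both precede noise", {
  d <- planted_rf_data(34)
  d$X$signal2 <- d$X$signal
  res <- fit_rank(d$X, d$labels, rf_config(seed = 34))
  pos <- match(c("signal", "signal2"), res$ranking)
  first_noise <- min(match(paste0("noise", 1:9), res$ranking))
  expect_true(all(pos < first_noise))
})

test_that("rows with missing features are dropped and counted", {
  d <- planted_rf_data(35)
  d$X$noise1[1:7] <- NA
  r <- fit_rank(d$X, d$labels, rf_config(seed = 35))
  expect_equal(r$n_dropped, 7)
  expect_equal(r$n_used, 193)
  expect_error(fit_rank(d$X, rep(TRUE, 200)), class = "immflow_config_error")
})

test_that("univariate screening finds the planted feature and is null-calibrated", {
  d <- planted_rf_data(36)
  tab <- univariate_feature_tests(d$X, d$labels)
  expect_equal(tab$feature[1], "signal")
  # calibration: 1000 label-independent features, fraction below 0.05
  set.seed(37)
  labels <- rep(c(FALSE, TRUE), each = 50)
  Xnull <- as.data.frame(matrix(rnorm(100 * 1000), 100, 1000))
  tabn <- univariate_feature_tests(Xnull, labels)
  frac <- mean(tabn$p_value < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
})

test_that("with default synthetic cohorts the forest surfaces the planted sepsis features", {
  informative <- c("il6_pg_ml", "tnfa_pg_ml", "il10_pg_ml", "crp_mg_ml", "il8_pg_ml")
  feats <- c("immage_score", "lymphocytes_1e9_per_L", informative, immage_features())
  hits <- vapply(1:20, function(s) {
    coh <- generate_cohort(sim_config(seed = s))
    fit <- immage(coh$panels)
    dat <- merge(coh$subjects, coh$panels, by = "subject_id")
    dat$immage_score <- unname(coef(fit)[dat$subject_id])
    d3 <- dat[dat$group == "trauma" & dat$timepoint_day == 3, ]
    r <- fit_rank(d3[, feats], d3$sepsis, rf_config(seed = s))
    sum(utils::head(r$ranking, 5) %in% informative)
  }, numeric(1))
  expect_gte(mean(hits >= 3), 0.8)
})
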