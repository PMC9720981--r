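test_that("invalid configurations are rejected with the field named", {
  expect_error(sim_config(n_controls = 0), "n_controls")
  expect_error(sim_config(sepsis_rate = 1.2), "sepsis_rate")
  expect_error(sim_config(dropout_rate = 1), "dropout_rate")
  expect_error(sim_config(timepoints = c(14, 3)), "timepoints")
  expect_error(sim_config(age_range = c(85, 20)), "age_range")
})

test_that("cohort structure matches the study design and all frequencies are in range", {
  coh <- default_cohort()
  subj <- coh$subjects
  expect_equal(sum(subj$group == "HC"), 55)
  tr <- subj[subj$group == "trauma", ]
  expect_gte(nrow(tr), 57)  # one row per retained trauma timepoint
  expect_equal(length(unique(sub("_D[0-9]+$", "", tr$subject_id))), 57)
  expect_true(all(tr$iss > 15))  # inclusion criterion
  freq <- as.matrix(coh$panels[, -1])
  expect_true(all(freq >= 0 & freq <= 100, na.rm = TRUE))
  expect_true(all(subj$age_years >= 20 & subj$age_years <= 85))
})

test_that("generation is deterministic and subject-stable under cohort-size changes", {
  a <- generate_cohort(sim_config(seed = 7, n_controls = 12, n_trauma = 10))
  b <- generate_cohort(sim_config(seed = 7, n_controls = 12, n_trauma = 10))
  expect_identical(a, b)
  bigger <- generate_cohort(sim_config(seed = 7, n_controls = 15, n_trauma = 10))
  shared <- intersect(a$subjects$subject_id, bigger$subjects$subject_id)
  rows <- function(df) {
    out <- df[match(shared, df$subject_id), ]
    rownames(out) <- NULL
    out
  }
  expect_identical(rows(a$subjects), rows(bigger$subjects))
})

test_that("simplex invariants hold: quartets exhaustive, siblings bounded", {
  p <- default_cohort()$panels
  for (lin in c("cd4", "cd8")) {
    q <- rowSums(p[, paste0(lin, c("_naive", "_cm", "_em", "_emra"))])
    expect_true(all(abs(q - 100) <= 0.5))
  }
  expect_true(all(p$cd4_of_t + p$cd8_of_t <= 100))
  expect_true(all(p$b_naive + p$b_switched_mem + p$b_unswitched_mem <= 100))
  expect_true(all(p$cd8_senescent <= pmin(p$cd8_cd28neg, p$cd8_cd57pos) + 0.5))
  expect_true(all(p$cd4_senescent <= pmin(p$cd4_cd28neg, p$cd4_cd57pos) + 0.5))
})

test_that("every generated panel passes the phenotype validator", {
  expect_equal(nrow(validate_panels(default_cohort()$panels)), 0)
})

test_that("zero offsets and zero sepsis give a null: naive CD4 indistinguishable between arms", {
  nonsig <- 0
  for (s in 1:100) {
    coh <- generate_cohort(sim_config(seed = s, n_controls = 25, n_trauma = 25,
                                      timepoints = 3, trauma_offsets = c("3" = 0),
                                      sepsis_rate = 0, dropout_rate = 0))
    hcv <- coh$panels$cd4_naive[grepl("^HC", coh$panels$subject_id)]
    trv <- coh$panels$cd4_naive[grepl("^TR", coh$panels$subject_id)]
    if (two_group_test(hcv, trv)$p_value > 0.01) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 95)
})

test_that("default offsets shift naive CD8 down at day 3 relative to controls", {
  coh <- default_cohort()
  p <- coh$panels
  hc <- p$cd8_naive[grepl("^HC", p$subject_id)]
  d3 <- p$cd8_naive[grepl("_D03$", p$subject_id)]
  expect_lt(mean(d3), mean(hc))
})

test_that("trauma lymphocyte counts drop with a nadir before day 60", {
  subj <- default_cohort()$subjects
  hc_mean <- mean(subj$lymphocytes_1e9_per_L[subj$group == "HC"])
  by_day <- tapply(subj$lymphocytes_1e9_per_L[subj$group == "trauma"],
                   subj$timepoint_day[subj$group == "trauma"], mean)
  expect_true(all(by_day < hc_mean))
  expect_lt(as.numeric(names(which.min(by_day))), 60)
})

test_that("cytokines are right-skewed, elevated in trauma and further in sepsis", {
  subj <- default_cohort()$subjects
  hc <- subj[subj$group == "HC", ]
  tr <- subj[subj$group == "trauma", ]
  for (col in c("il6_pg_ml", "tnfa_pg_ml", "il10_pg_ml", "crp_mg_ml")) {
    expect_gt(mean(tr[[col]]), mean(hc[[col]]))
    expect_gt(mean(tr[[col]][tr$sepsis]), mean(tr[[col]][!tr$sepsis]))
    expect_gt(mean(tr[[col]]), median(tr[[col]]))  # right skew
  }
})

test_that("planted truth is deterministic and matches the generating run", {
  cfg <- sim_config(seed = 5, n_controls = 10, n_trauma = 8)
  expect_identical(planted_truth(cfg), planted_truth(cfg))
  expect_identical(planted_truth(cfg), generate_cohort(cfg)$truth)
})

test_that("trauma day-14 latent values stochastically dominate control latents", {
  cfg <- sim_config(seed = 3, n_controls = 500, n_trauma = 500, dropout_rate = 0)
  tr <- planted_truth(cfg)
  hc <- tr[grepl("^HC", names(tr))]
  d14 <- tr[grepl("_D14$", names(tr))]
  probs <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(quantile(d14, probs) > quantile(hc, probs)))
})

test_that("zero offsets leave trauma and control latents equal in law", {
  cfg <- sim_config(seed = 4, n_controls = 300, n_trauma = 300,
                    timepoints = 3, trauma_offsets = c("3" = 0),
                    sepsis_rate = 0, dropout_rate = 0)
  tr <- planted_truth(cfg)
  hc <- tr[grepl("^HC", names(tr))]
  tt <- tr[grepl("^TR", names(tr))]
  expect_gt(suppressWarnings(ks.test(hc, tt)$p.value), 0.01)
})

test_that("latent immune age tracks chronological age in controls", {
  cfg <- sim_config(seed = 9, n_controls = 200, n_trauma = 1)
  coh <- generate_cohort(cfg)
  hc_ids <- coh$subjects$subject_id[coh$subjects$group == "HC"]
  ages <- coh$subjects$age_years[match(hc_ids, coh$subjects$subject_id)]
  expect_gte(cor(coh$truth[hc_ids], ages, method = "spearman"), 0.5)
})

test_that("per-feature missingness knob plants missing panel entries", {
  coh <- generate_cohort(sim_config(seed = 2, n_controls = 30, n_trauma = 30,
                                    feature_missing_rate = 0.05))
  frac <- mean(is.na(as.matrix(coh$panels[grepl("^TR", coh$panels$subject_id), -1])))
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.15)
})
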