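#' Configuration for the synthetic trauma/healthy-control cohort
#'
#' Builds the configuration object consumed by \code{\link{generate_cohort}}.
#' Defaults emulate the structure of a severe-trauma immunophenotyping
#' study: 55 healthy controls sampled once, 57 trauma patients sampled at
#' days 3, 14, 28 and 60 post-hospitalisation, ages uniform on 20-85 years,
#' and a sepsis incidence near 65% among trauma patients.
#'
#' Every sample carries a latent immune age on an approximately unit scale:
#' in controls it increases linearly with chronological age plus noise; in
#' trauma patients it is the control expectation plus a positive,
#' timepoint-specific offset that peaks at day 14 (\code{trauma_offsets}).
#' All subset-frequency means, the lymphocyte drop, and cytokine elevation
#' are driven by this latent variable (and, for lymphocytes/cytokines, by
#' the offset itself), so setting all offsets to zero makes trauma and
#' control feature distributions identical in law.
#'
#' @param n_controls,n_trauma Numbers of healthy controls and trauma
#'   subjects (each >= 1).
#' @param timepoints Strictly increasing post-admission sampling days for
#'   trauma subjects.
#' @param age_range Two-element (low, high) range in years; ages are drawn
#'   uniformly then clipped.
#' @param sepsis_rate Target sepsis probability among trauma subjects in
#'   [0,1]; labels are drawn from a logistic model on the latent immune age
#'   with its intercept calibrated so the mean probability equals this rate.
#' @param trauma_offsets Named numeric vector, one entry per timepoint
#'   (names = day labels), giving the additive latent-immune-age shift.
#' @param latent_effect_sizes Named list of slopes of feature means against
#'   the latent immune age (percentage points per latent unit; negative
#'   entries are declines).
#' @param noise_scales Named list of dispersion knobs: \code{quartet_precision}
#'   and \code{sibling_precision} (Dirichlet concentrations), \code{scalar_sd}
#'   (multiplier on scalar-frequency SDs), \code{cytokine_sdlog} (log-normal
#'   sdlog), \code{latent_sd} (subject-level latent noise).
#' @param dropout_rate Probability in [0,1) that a trauma subject misses any
#'   given timepoint after the first (completely at random).
#' @param feature_missing_rate Probability that an individual panel entry is
#'   missing (default 0); exercises the missing-value exclusion rule of the
#'   scoring pipeline.
#' @param seed Integer global seed; every subject draws from a stream
#'   derived from it, so output is fully deterministic.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(n_controls = 55,
                       n_trauma = 57,
                       timepoints = c(3, 14, 28, 60),
                       age_range = c(20, 85),
                       sepsis_rate = 0.65,
                       trauma_offsets = c("3" = 0.35, "14" = 0.45,
                                          "28" = 0.30, "60" = 0.20),
                       latent_effect_sizes = list(
                         tcell_of_lymphs = -8, cd4_naive = -28,
                         cd8_naive = -30, cd8_cd28neg = 38, cd8_cd57pos = 32,
                         cd4_cd28neg = 18, cd4_cd57pos = 15,
                         treg_of_cd4 = 3.5, rte_of_naive_cd4 = -14,
                         b_naive = -20, b_switched_mem = 15, breg_of_b = -3),
                       noise_scales = list(quartet_precision = 120,
                                           sibling_precision = 100,
                                           scalar_sd = 1,
                                           cytokine_sdlog = 0.8,
                                           latent_sd = 0.12),
                       dropout_rate = 0.30,
                       feature_missing_rate = 0,
                       seed = 1L) {
  cfg <- list(n_controls = n_controls, n_trauma = n_trauma,
              timepoints = timepoints, age_range = age_range,
              sepsis_rate = sepsis_rate, trauma_offsets = trauma_offsets,
              latent_effect_sizes = latent_effect_sizes,
              noise_scales = noise_scales, dropout_rate = dropout_rate,
              feature_missing_rate = feature_missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    stop_immflow("invalid sim_config field '%s': %s", field, why,
                 class = "immflow_config_error")
  if (length(cfg$n_controls) != 1 || cfg$n_controls < 1) bad("n_controls", ">= 1 required")
  if (length(cfg$n_trauma) != 1 || cfg$n_trauma < 1) bad("n_trauma", ">= 1 required")
  if (length(cfg$timepoints) < 1 || is.unsorted(cfg$timepoints, strictly = TRUE))
    bad("timepoints", "must be strictly increasing")
  if (length(cfg$age_range) != 2 || cfg$age_range[1] >= cfg$age_range[2])
    bad("age_range", "must be (low, high) with low < high")
  if (cfg$sepsis_rate < 0 || cfg$sepsis_rate > 1) bad("sepsis_rate", "must be in [0,1]")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) bad("dropout_rate", "must be in [0,1)")
  if (cfg$feature_missing_rate < 0 || cfg$feature_missing_rate >= 1)
    bad("feature_missing_rate", "must be in [0,1)")
  if (!all(as.character(cfg$timepoints) %in% names(cfg$trauma_offsets)))
    bad("trauma_offsets", "must name every timepoint")
  invisible(cfg)
}

# Latent immune age expected for a healthy control of a given age: linear
# map of the configured age range onto [0,1].
hc_latent_expectation <- function(age, age_range) {
  (age - age_range[1]) / (age_range[2] - age_range[1])
}

# Draw the full feature panel for one sample with latent immune age `l`.
# Called inside the subject's RNG stream.
draw_panel_row <- function(l, cfg) {
  es <- cfg$latent_effect_sizes
  ns <- cfg$noise_scales
  lc <- clip(l, 0, 1.6)

  redistribute <- function(base, slope_naive, weights) {
    m <- base
    m[1] <- base[1] + slope_naive * lc
    m[-1] <- base[-1] - slope_naive * lc * weights
    m <- clip(m, 1, 97)
    m / sum(m)
  }
  cd4_mean <- redistribute(c(55, 22, 14, 9), es$cd4_naive, c(0.35, 0.25, 0.40))
  cd8_mean <- redistribute(c(45, 15, 22, 18), es$cd8_naive, c(0.15, 0.35, 0.50))
  cd4_q <- 100 * rdirichlet1(cd4_mean, ns$quartet_precision)
  cd8_q <- 100 * rdirichlet1(cd8_mean, ns$quartet_precision)

  # CD4/CD8 split within T cells (third component = other T)
  split_mean <- clip(c(55 - 6 * lc, 32 + 5 * lc, 10), 2, 95)
  split <- 100 * rdirichlet1(split_mean / sum(split_mean), ns$sibling_precision)

  # B-cell memory split (fourth component = double-negative/other B)
  b_mean <- clip(c(62 + es$b_naive * lc, 18 + es$b_switched_mem * lc,
                   10 + 4 * lc, 8), 1, 95)
  b_split <- 100 * rdirichlet1(b_mean / sum(b_mean), ns$sibling_precision * 0.8)

  sc <- function(base, slope, sd, lo = 0.2, hi = 98)
    clip(base + slope * lc + stats::rnorm(1, 0, sd * ns$scalar_sd), lo, hi)

  cd8_c28 <- sc(12, es$cd8_cd28neg, 5)
  cd8_c57 <- sc(10, es$cd8_cd57pos, 5)
  cd4_c28 <- sc(5, es$cd4_cd28neg, 3)
  cd4_c57 <- sc(4, es$cd4_cd57pos, 3)
  # senescent = a Beta-distributed fraction of the smaller marker frequency,
  # which keeps the intersection bound satisfied by construction
  cd8_sen <- stats::rbeta(1, 8, 2) * min(cd8_c28, cd8_c57)
  cd4_sen <- stats::rbeta(1, 8, 2) * min(cd4_c28, cd4_c57)

  row <- c(
    tcell_of_lymphs = sc(65, es$tcell_of_lymphs, 6, lo = 1, hi = 95),
    bcell_of_lymphs = sc(10, 0, 2.5, lo = 1, hi = 30),
    cd4_of_t = split[1], cd8_of_t = split[2],
    stats::setNames(cd4_q, quartet_cols("cd4")),
    stats::setNames(cd8_q, quartet_cols("cd8")),
    cd4_cd28neg = cd4_c28, cd4_cd57pos = cd4_c57, cd4_senescent = cd4_sen,
    cd8_cd28neg = cd8_c28, cd8_cd57pos = cd8_c57, cd8_senescent = cd8_sen,
    rte_of_naive_cd4 = sc(25, es$rte_of_naive_cd4, 4, lo = 0.5, hi = 80),
    treg_of_cd4 = sc(3.5, es$treg_of_cd4, 0.8, lo = 0.2, hi = 20),
    b_naive = b_split[1], b_switched_mem = b_split[2],
    b_unswitched_mem = b_split[3],
    breg_of_b = sc(6, es$breg_of_b, 1.2, lo = 0.2, hi = 25)
  )
  row
}

# Lymphocyte count (1e9/L) and serum cytokines for one sample; `off` is the
# trauma latent offset at this timepoint (0 for controls), `septic` TRUE
# further elevates IL6/TNFa/IL10/CRP per the sepsis-vs-non-sepsis pattern.
draw_bloods <- function(off, septic, cfg) {
  sdl <- cfg$noise_scales$cytokine_sdlog
  sep_mult <- if (isTRUE(septic)) c(il6 = 4, tnfa = 2.5, il10 = 2, il8 = 1.5,
                                    crp = 1.8)
              else c(il6 = 1, tnfa = 1, il10 = 1, il8 = 1, crp = 1)
  med <- c(il6 = 4, tnfa = 0.35, il10 = 2, il8 = 6, crp = 2)
  k <- c(il6 = 8, tnfa = 5, il10 = 3, il8 = 2, crp = 10)
  cyt <- med * exp(k * off) * sep_mult *
    exp(stats::rnorm(5, 0, sdl))
  lymph <- stats::rlnorm(1, meanlog = log(1.8) - 1.1 * off, sdlog = 0.25)
  list(lymph = lymph, cyt = cyt)
}

#' Generate a synthetic trauma/healthy-control cohort
#'
#' Produces the two cohort tables the downstream analyses consume: a
#' subjects table (one row per sample: identifiers, group, timepoint,
#' demographics, clinical severity scores, sepsis flag, stay lengths,
#' lymphocyte count, serum cytokines) and a panels table (one row per
#' sample: parent-relative subset frequencies per the
#' \code{\link{subset_schema}} dictionary). Trauma sample identifiers encode
#' the person and the day (e.g. \code{TR012_D14}); controls are sampled
#' once.
#'
#' Compositional subsets (the CD45RA/CCR7 quartets, the CD4/CD8 split, the
#' B-cell memory split) are Dirichlet draws whose mean shifts with the
#' latent immune age, so simplex constraints hold exactly. Cytokines are
#' log-normal, elevated in trauma proportionally to the latent offset and
#' further elevated under sepsis. Sepsis labels follow a logistic model on
#' the subject's latent immune age calibrated to \code{sepsis_rate}.
#' Everything is deterministic given \code{config$seed}, with per-subject
#' streams so an individual's draws do not depend on cohort size.
#'
#' @param config A \code{\link{sim_config}}.
#' @return A list with elements \code{subjects} (data.frame),
#'   \code{panels} (data.frame) and \code{truth} (named vector: the latent
#'   immune age actually used for each sample id).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  cfg <- config
  tps <- cfg$timepoints
  lat_sd <- cfg$noise_scales$latent_sd

  subj_rows <- list(); panel_rows <- list(); truth <- c()

  # ---- healthy controls: one sample each -------------------------------
  for (i in seq_len(cfg$n_controls)) {
    set.seed(stream_seed(cfg$seed, 1000000 + i))
    id <- sprintf("HC%03d", i)
    age <- clip(stats::runif(1, cfg$age_range[1], cfg$age_range[2]),
                cfg$age_range[1], cfg$age_range[2])
    l <- hc_latent_expectation(age, cfg$age_range) + stats::rnorm(1, 0, lat_sd) +
      stats::rnorm(1, 0, 0.05)
    bl <- draw_bloods(0, FALSE, cfg)
    pr <- draw_panel_row(l, cfg)
    sex <- if (stats::runif(1) < 0.88) "M" else "F"
    subj_rows[[id]] <- data.frame(
      subject_id = id, group = "HC", timepoint_day = NA_integer_,
      age_years = round(age, 1), sex = sex,
      iss = NA_integer_, niss = NA_integer_, apache2 = NA_integer_,
      sofa = NA_integer_, saps2 = NA_integer_, sepsis = NA,
      icu_los_days = NA_real_, hospital_los_days = NA_real_,
      ventilator_days = NA_real_,
      lymphocytes_1e9_per_L = round(bl$lymph, 3),
      il6_pg_ml = round(bl$cyt[["il6"]], 2), tnfa_pg_ml = round(bl$cyt[["tnfa"]], 2),
      il10_pg_ml = round(bl$cyt[["il10"]], 2), il8_pg_ml = round(bl$cyt[["il8"]], 2),
      crp_mg_ml = round(bl$cyt[["crp"]], 2), stringsAsFactors = FALSE)
    panel_rows[[id]] <- pr
    truth[id] <- l
  }

  # ---- trauma subjects: person-level state then per-timepoint samples ---
  person <- vector("list", cfg$n_trauma)
  for (j in seq_len(cfg$n_trauma)) {
    set.seed(stream_seed(cfg$seed, 2000000 + j))
    age <- clip(stats::runif(1, cfg$age_range[1], cfg$age_range[2]),
                cfg$age_range[1], cfg$age_range[2])
    base <- hc_latent_expectation(age, cfg$age_range) + stats::rnorm(1, 0, lat_sd)
    sev <- clip(base + max(cfg$trauma_offsets) + stats::rnorm(1, 0, 0.25), 0, 2)
    iss <- as.integer(clip(round(16 + stats::rgamma(1, shape = 2, scale = 5)), 16, 75))
    retained <- c(TRUE, stats::runif(length(tps) - 1) >= cfg$dropout_rate)
    person[[j]] <- list(
      age = age, base = base, sev = sev, iss = iss,
      sex = if (stats::runif(1) < 0.85) "M" else "F",
      niss = as.integer(clip(iss + round(stats::rgamma(1, 2, scale = 3)), 16, 75)),
      apache2 = as.integer(clip(round(12 + 14 * sev + stats::rnorm(1, 0, 3)), 0, 71)),
      sofa = as.integer(clip(round(3 + 7 * sev + stats::rnorm(1, 0, 1.5)), 0, 24)),
      saps2 = as.integer(clip(round(28 + 26 * sev + stats::rnorm(1, 0, 6)), 0, 163)),
      icu = round(clip(exp(1 + 1.4 * sev + stats::rnorm(1, 0, 0.5)), 0, 120), 1),
      retained = retained)
  }

  # sepsis: logistic on the subject's peak latent immune age, intercept
  # calibrated so the mean probability matches the configured rate
  bases <- vapply(person, function(p) p$base + max(cfg$trauma_offsets), numeric(1))
  slope <- 2.5
  if (cfg$sepsis_rate <= 0) {
    p_sep <- rep(0, cfg$n_trauma)
  } else if (cfg$sepsis_rate >= 1) {
    p_sep <- rep(1, cfg$n_trauma)
  } else {
    a <- stats::qlogis(cfg$sepsis_rate) - slope * mean(bases)
    p_sep <- stats::plogis(a + slope * bases)
  }
  set.seed(stream_seed(cfg$seed, 3000000))
  septic <- stats::runif(cfg$n_trauma) < p_sep

  for (j in seq_len(cfg$n_trauma)) {
    p <- person[[j]]
    for (t_idx in seq_along(tps)) {
      if (!p$retained[t_idx]) next
      day <- tps[t_idx]
      set.seed(stream_seed(cfg$seed, 2000000 + j) + 13 * t_idx)
      id <- sprintf("TR%03d_D%02d", j, day)
      off <- cfg$trauma_offsets[[as.character(day)]]
      l <- p$base + off + stats::rnorm(1, 0, 0.05)
      bl <- draw_bloods(off, septic[j], cfg)
      pr <- draw_panel_row(l, cfg)
      if (cfg$feature_missing_rate > 0) {
        miss <- stats::runif(length(pr)) < cfg$feature_missing_rate
        pr[miss] <- NA_real_
      }
      hosp <- round(clip(p$icu + exp(2 + 1.2 * p$sev + stats::rnorm(1, 0, 0.4)),
                         1, 400), 1)
      subj_rows[[id]] <- data.frame(
        subject_id = id, group = "trauma", timepoint_day = as.integer(day),
        age_years = round(p$age, 1), sex = p$sex,
        iss = p$iss, niss = p$niss, apache2 = p$apache2, sofa = p$sofa,
        saps2 = p$saps2, sepsis = septic[j],
        icu_los_days = p$icu, hospital_los_days = hosp,
        ventilator_days = round(0.7 * p$icu, 1),
        lymphocytes_1e9_per_L = round(bl$lymph, 3),
        il6_pg_ml = round(bl$cyt[["il6"]], 2), tnfa_pg_ml = round(bl$cyt[["tnfa"]], 2),
        il10_pg_ml = round(bl$cyt[["il10"]], 2), il8_pg_ml = round(bl$cyt[["il8"]], 2),
        crp_mg_ml = round(bl$cyt[["crp"]], 2), stringsAsFactors = FALSE)
      panel_rows[[id]] <- pr
      truth[id] <- l
    }
  }

  subjects <- do.call(rbind, subj_rows)
  rownames(subjects) <- NULL
  panels <- as.data.frame(do.call(rbind, panel_rows))
  panels <- cbind(subject_id = names(panel_rows), round(panels, 4))
  rownames(panels) <- NULL
  list(subjects = subjects, panels = panels, truth = truth)
}

#' Latent immune ages actually used for a configuration
#'
#' Re-derives the per-sample latent immune age that
#' \code{\link{generate_cohort}} used (or would use) under the same
#' configuration; identical seeds give identical maps. Enables
#' parameter-recovery tests of the scoring pipeline against planted truth.
#'
#' @param config A \code{\link{sim_config}}.
#' @return Named numeric vector: sample id to latent immune age.
#' @export
planted_truth <- function(config) {
  generate_cohort(config)$truth
}
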