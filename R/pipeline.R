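#' Cohort summary statistics
#'
#' Per-group sample and person counts, per-timepoint sample counts, age
#' mean/SD, and the sepsis fraction among trauma subjects as a percentage
#' (1 decimal). Trauma persons are identified by stripping the timepoint
#' suffix (\code{_D<day>}) from the sample id, so longitudinal samples of
#' one person are counted once.
#'
#' @param subjects Subjects data.frame (see \code{\link{read_subjects}}).
#' @return List of class \code{cohort_summary} with, among others,
#'   \code{n_controls}, \code{n_trauma}, \code{n_septic},
#'   \code{sepsis_pct}, \code{samples_per_timepoint}.
#' @export
cohort_summary <- function(subjects) {
  hc <- subjects[subjects$group == "HC", , drop = FALSE]
  tr <- subjects[subjects$group == "trauma", , drop = FALSE]
  person <- sub("_D[0-9]+$", "", tr$subject_id)
  first <- !duplicated(person)
  n_trauma <- sum(first)
  n_septic <- sum(tr$sepsis[first], na.rm = TRUE)
  out <- list(
    n_samples = nrow(subjects),
    n_controls = nrow(hc),
    n_trauma = n_trauma,
    n_trauma_samples = nrow(tr),
    samples_per_timepoint = if (nrow(tr)) table(tr$timepoint_day) else table(integer()),
    n_septic = n_septic,
    sepsis_pct = if (n_trauma > 0) round(100 * n_septic / n_trauma, 1) else NA_real_,
    age_hc = c(mean = mean(hc$age_years), sd = stats::sd(hc$age_years)),
    age_trauma = c(mean = mean(tr$age_years[first]),
                   sd = stats::sd(tr$age_years[first])))
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d samples; %d healthy controls, %d trauma subjects (%d trauma samples)\n",
              x$n_samples, x$n_controls, x$n_trauma, x$n_trauma_samples))
  if (length(x$samples_per_timepoint)) {
    cat("  trauma samples per day:",
        paste(sprintf("d%s=%d", names(x$samples_per_timepoint),
                      as.integer(x$samples_per_timepoint)), collapse = ", "), "\n")
  }
  cat(sprintf("  sepsis: %d/%d trauma subjects (%.1f%%)\n",
              x$n_septic, x$n_trauma, x$sepsis_pct))
  cat(sprintf("  age (years): HC %.1f +/- %.1f; trauma %.1f +/- %.1f\n",
              x$age_hc["mean"], x$age_hc["sd"],
              x$age_trauma["mean"], x$age_trauma["sd"]))
  invisible(x)
}

#' Pipeline configuration
#'
#' Assembles the configuration for \code{\link{run_pipeline}}. Either a
#' simulation block (\code{sim}) or paths to existing subjects/panels
#' tables must be supplied. A YAML file with the same structure may be
#' passed to \code{run_pipeline} directly.
#'
#' @param out_dir Output directory for result tables and the manifest.
#' @param sim A \code{\link{sim_config}} or NULL to load tables from paths.
#' @param subjects_path,panels_path CSV paths, used when \code{sim} is NULL.
#' @param immage An \code{\link{immage_config}}.
#' @param rf List with \code{timepoint} (trauma day whose samples feed the
#'   sepsis forest, default 3) and an optional \code{features} character
#'   vector; NULL skips the random-forest stage.
#' @param seed Global seed echoed into every artifact.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            subjects_path = NULL, panels_path = NULL,
                            immage = immage_config(),
                            rf = list(timepoint = 3),
                            seed = 1L) {
  if (is.null(sim) && (is.null(subjects_path) || is.null(panels_path)))
    stop_immflow("either a sim block or both table paths are required",
                 class = "immflow_config_error")
  structure(list(out_dir = out_dir, sim = sim,
                 subjects_path = subjects_path, panels_path = panels_path,
                 immage = immage, rf = rf, seed = as.integer(seed)),
            class = "pipeline_config")
}

load_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  imm <- if (!is.null(y$immage)) do.call(immage_config, y$immage) else immage_config()
  pipeline_config(out_dir = y$out_dir, sim = sim,
                  subjects_path = y$subjects_path, panels_path = y$panels_path,
                  immage = imm, rf = y$rf %||% list(timepoint = 3),
                  seed = y$seed %||% 1L)
}

write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  path
}

#' Run the full cohort analysis pipeline
#'
#' Orchestrates the study sequence end to end: simulate (or load) the
#' cohort tables, validate the panels, compute immune-age scores, compare
#' scores and the scoring features between healthy controls and each trauma
#' timepoint (one-way ANOVA with Bonferroni post hoc contrasts), run the
#' univariate regressions (score vs age in controls; score vs injury
#' severity, ICU stay and IL6 at day 3 in trauma), and rank
#' sepsis-associated features with the random forest. Each stage's outputs
#' are written as CSV under \code{out_dir} together with a JSON manifest
#' recording stage status, sample counts, the global seed and a
#' configuration hash; two runs with the same configuration are
#' byte-identical. Errors fail fast with the stage named; the manifest is
#' still written with the failing stage marked FAILED.
#'
#' @param config A \code{\link{pipeline_config}} or path to a YAML file.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_yaml(config)
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, config_hash = config_hash(unclass(cfg)),
                   package_version = as.character(utils::packageVersion("immflow")),
                   stages = list())
  stage_names <- c("simulate", "validate", "score", "compare", "regress", "rf")
  finish <- function(stage, status, ...) {
    manifest$stages[[stage]] <<- c(list(status = status), list(...))
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      finish(stage, "FAILED", error = conditionMessage(e))
      for (s in setdiff(stage_names, names(manifest$stages)))
        manifest$stages[[s]] <<- list(status = "not_run")
      write_manifest()
      stop_immflow("pipeline stage '%s' failed: %s", stage, conditionMessage(e),
                   class = "immflow_pipeline_error")
    })
  }

  # -- simulate / load ----------------------------------------------------
  subjects <- panels <- NULL
  run_stage("simulate", function() {
    if (!is.null(cfg$sim)) {
      sim <- cfg$sim
      sim$seed <- cfg$seed
      coh <- generate_cohort(do.call(sim_config, unclass(sim)))
      write_cohort(coh, cfg$out_dir)
      subjects <<- coh$subjects; panels <<- coh$panels
      finish("simulate", "completed", n_samples = nrow(subjects))
    } else {
      subjects <<- read_subjects(cfg$subjects_path)
      panels <<- read_panels(cfg$panels_path)
      finish("simulate", "loaded", n_samples = nrow(subjects))
    }
  })

  # -- validate -----------------------------------------------------------
  run_stage("validate", function() {
    v <- validate_panels(panels)
    write_table(v, file.path(cfg$out_dir, "violations.csv"))
    finish("validate", "completed", n_violations = nrow(v))
  })

  # -- score --------------------------------------------------------------
  fit <- NULL
  run_stage("score", function() {
    fit <<- immage(panels, cfg$immage)
    scores_df <- data.frame(subject_id = as.character(panels$subject_id),
                            stringsAsFactors = FALSE)
    scores_df <- merge(scores_df,
                       subjects[, c("subject_id", "group", "timepoint_day")],
                       by = "subject_id", sort = FALSE)
    scores_df$immage_score <- unname(fit$scores[scores_df$subject_id])
    scores_df$excluded_flag <- scores_df$subject_id %in% fit$excluded_ids
    scores_df <- scores_df[order(scores_df$subject_id), ]
    write_table(scores_df, file.path(cfg$out_dir, "scores.csv"))
    diag <- list(root_id = fit$root_id, eigenvalues = fit$eigenvalues,
                 bandwidth = fit$bandwidth, excluded_ids = fit$excluded_ids,
                 config = unclass(fit$config))
    jsonlite::write_json(diag, file.path(cfg$out_dir, "immage_diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    finish("score", "completed", n_scored = length(fit$scores),
           n_excluded = length(fit$excluded_ids), root_id = fit$root_id)
  })

  # -- compare ------------------------------------------------------------
  run_stage("compare", function() {
    dat <- merge(subjects, panels, by = "subject_id")
    dat$immage_score <- unname(fit$scores[dat$subject_id])
    dat$cohort <- ifelse(dat$group == "HC", "HC",
                         paste0("day", dat$timepoint_day))
    measures <- c("immage_score", immage_features())
    lvls <- c("HC", paste0("day", sort(unique(
      dat$timepoint_day[dat$group == "trauma"]))))
    rows <- list()
    for (m in measures) {
      grps <- lapply(lvls, function(l) {
        v <- dat[[m]][dat$cohort == l]
        v[!is.na(v)]
      })
      names(grps) <- lvls
      grps <- grps[vapply(grps, length, integer(1)) >= 2]
      if (length(grps) < 2) next
      contrasts <- lapply(setdiff(names(grps), "HC"), function(l) c("HC", l))
      av <- anova_bonferroni(grps, contrasts)
      rows[[length(rows) + 1]] <- data.frame(
        measure = m, contrast = "omnibus", statistic_name = "F",
        statistic = av$omnibus$statistic, p_value = av$omnibus$p_value,
        adjusted_p = NA_real_, stringsAsFactors = FALSE)
      for (cr in av$contrasts)
        rows[[length(rows) + 1]] <- data.frame(
          measure = m, contrast = cr$contrast, statistic_name = "t",
          statistic = cr$statistic, p_value = cr$p_value,
          adjusted_p = cr$adjusted_p, stringsAsFactors = FALSE)
    }
    comp <- do.call(rbind, rows)
    comp[c("statistic", "p_value", "adjusted_p")] <-
      lapply(comp[c("statistic", "p_value", "adjusted_p")], signif, 6)
    write_table(comp, file.path(cfg$out_dir, "comparisons.csv"))
    finish("compare", "completed", n_comparisons = nrow(comp))
  })

  # -- regress ------------------------------------------------------------
  run_stage("regress", function() {
    dat <- subjects
    dat$immage_score <- unname(fit$scores[dat$subject_id])
    hc <- dat[dat$group == "HC", ]
    d3 <- dat[dat$group == "trauma" & dat$timepoint_day ==
                min(dat$timepoint_day, na.rm = TRUE), ]
    spec <- list(
      list(subset = "HC", y = "immage_score", x = "age_years", d = hc),
      list(subset = "trauma_day3", y = "immage_score", x = "iss", d = d3),
      list(subset = "trauma_day3", y = "immage_score", x = "icu_los_days", d = d3),
      list(subset = "trauma_day3", y = "immage_score", x = "il6_pg_ml", d = d3))
    rows <- lapply(spec, function(s) {
      r <- tryCatch(univariate_regression(s$d[[s$x]], s$d[[s$y]]),
                    error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(subset = s$subset, outcome = s$y, predictor = s$x,
                 slope = signif(r$slope, 6), r_squared = signif(r$r_squared, 6),
                 f_statistic = signif(r$f_statistic, 6),
                 p_value = signif(r$p_value, 6), n = r$n,
                 stringsAsFactors = FALSE)
    })
    reg <- do.call(rbind, rows)
    write_table(reg, file.path(cfg$out_dir, "regressions.csv"))
    finish("regress", "completed", n_regressions = nrow(reg))
  })

  # -- rf -----------------------------------------------------------------
  if (is.null(cfg$rf)) {
    finish("rf", "skipped")
  } else {
    run_stage("rf", function() {
      day <- cfg$rf$timepoint %||% 3
      dat <- merge(subjects, panels, by = "subject_id")
      dat$immage_score <- unname(fit$scores[dat$subject_id])
      dat <- dat[dat$group == "trauma" & dat$timepoint_day == day, ]
      feats <- cfg$rf$features %||%
        c("immage_score", "lymphocytes_1e9_per_L", "il6_pg_ml", "tnfa_pg_ml",
          "il10_pg_ml", "il8_pg_ml", "crp_mg_ml", immage_features())
      res <- fit_rank(dat[, feats, drop = FALSE], dat$sepsis,
                      rf_config(seed = cfg$seed))
      write_table(data.frame(feature = res$ranking,
                             mean_decrease_accuracy = signif(res$mda[res$ranking], 6),
                             row.names = NULL),
                  file.path(cfg$out_dir, "rf_ranking.csv"))
      finish("rf", "completed", n_samples = res$n_used,
             n_dropped = res$n_dropped, oob_accuracy = res$oob_accuracy)
    })
  }

  write_manifest()
  invisible(manifest)
}
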