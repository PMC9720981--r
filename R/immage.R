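#' Immune-age pseudotime score from gated subset frequencies
#'
#' Fits the IMM-AGE flow score over a cohort of samples: samples missing any
#' of the eight required subset frequencies are excluded; each retained
#' feature is standardized by its 10% two-tailed trimmed mean and SD over
#' the pooled analysis set; a diffusion-map trajectory is built over the
#' standardized samples; pseudotime is measured as diffusion distance from
#' a CD28-defined root (the sample with the highest CD28+ / lowest CD28-
#' CD8 fraction); and the scores are min-max scaled to [0,1]. Higher scores
#' indicate a phenotypically older adaptive immune compartment. Repeated
#' measures of one person are scored as independent samples.
#'
#' The eight features are those listed by \code{\link{immage_features}}:
#' total T cells, naive CD4, effector memory CD4 and CD8, EMRA CD8, CD28-
#' CD8, CD57+ CD8 and regulatory T cells.
#'
#' @param panels Data.frame with a \code{subject_id} column and at least the
#'   eight feature columns (percent of stated parent).
#' @param config An \code{\link{immage_config}}.
#' @return An object of class \code{immage}: a list with \code{scores}
#'   (named vector in [0,1]; min exactly 0 at the root, max exactly 1),
#'   \code{raw_scores}, \code{root_id}, \code{excluded_ids},
#'   \code{eigenvalues}, \code{embedding}, \code{standardization}
#'   (per-feature trimmed mean/SD), \code{bandwidth}, \code{config}.
#' @seealso \code{\link{generate_cohort}} for synthetic input,
#'   \code{print.immage}, \code{summary.immage}, \code{coef.immage},
#'   \code{plot.immage}.
#' @examples
#' coh <- generate_cohort(sim_config(n_controls = 20, n_trauma = 10, seed = 7))
#' fit <- immage(coh$panels)
#' range(coef(fit))
#' @export
immage <- function(panels, config = immage_config()) {
  feats <- immage_features()
  if (!"subject_id" %in% names(panels))
    stop_immflow("panels table lacks a subject_id column",
                 class = "immflow_schema_error")
  missing_cols <- setdiff(feats, names(panels))
  if (length(missing_cols))
    stop_immflow("panels table lacks required feature column(s): %s",
                 paste(missing_cols, collapse = ", "),
                 class = "immflow_schema_error")
  ids <- as.character(panels$subject_id)
  if (anyDuplicated(ids))
    stop_immflow("duplicated sample ids in panels table",
                 class = "immflow_schema_error")
  F <- as.matrix(panels[, feats])
  rownames(F) <- ids
  complete <- stats::complete.cases(F)
  excluded <- ids[!complete]
  F <- F[complete, , drop = FALSE]
  if (nrow(F) < 8)
    stop_immflow("scoring needs at least 8 samples with complete features, got %d",
                 nrow(F), class = "immflow_insufficient_samples_error")

  # trimmed standardization, pooled over the retained analysis set
  std <- lapply(feats, function(f)
    trimmed_standardize(F[, f], config$trim_fraction, feature = f))
  names(std) <- feats
  Z <- vapply(std, `[[`, numeric(nrow(F)), "standardized")
  rownames(Z) <- rownames(F)

  dm <- build_diffusion_map(Z, config)
  root_id <- select_root(stats::setNames(F[, "cd8_cd28neg"], rownames(F)),
                         config$root_rule)
  raw <- pseudotime_scores(dm$embedding, root_id)
  rng <- range(raw)
  if (rng[2] <= rng[1])
    stop_immflow("all pseudotime values identical; scores undefined",
                 class = "immflow_degenerate_error")
  scores <- (raw - rng[1]) / (rng[2] - rng[1])

  structure(list(
    scores = scores,
    raw_scores = raw,
    root_id = root_id,
    excluded_ids = excluded,
    eigenvalues = dm$eigenvalues,
    all_eigenvalues = dm$all_eigenvalues,
    embedding = dm$embedding,
    standardization = data.frame(
      feature = feats,
      trimmed_mean = vapply(std, `[[`, numeric(1), "trimmed_mean"),
      trimmed_sd = vapply(std, `[[`, numeric(1), "trimmed_sd"),
      row.names = NULL),
    bandwidth = dm$bandwidth,
    config = config), class = "immage")
}

#' @export
print.immage <- function(x, ...) {
  cat("Immune-age pseudotime fit\n")
  cat(sprintf("  samples scored: %d (excluded for missing features: %d)\n",
              length(x$scores), length(x$excluded_ids)))
  cat(sprintf("  root: %s (lowest CD28- CD8 frequency)\n", x$root_id))
  cat(sprintf("  diffusion components: %d, kernel bandwidth: %.4g\n",
              length(x$eigenvalues), x$bandwidth))
  cat(sprintf("  eigenvalues: %s\n",
              paste(sprintf("%.4f", x$eigenvalues), collapse = ", ")))
  cat(sprintf("  score range: [%.3f, %.3f] (scaled)\n",
              min(x$scores), max(x$scores)))
  invisible(x)
}

#' @export
summary.immage <- function(object, ...) {
  out <- list(n_scored = length(object$scores),
              n_excluded = length(object$excluded_ids),
              root_id = object$root_id,
              eigenvalues = object$eigenvalues,
              score_quantiles = stats::quantile(object$scores,
                                                c(0, .25, .5, .75, 1)))
  class(out) <- "summary.immage"
  out
}

#' @export
print.summary.immage <- function(x, ...) {
  cat(sprintf("Immune-age scores: n = %d (excluded %d), root = %s\n",
              x$n_scored, x$n_excluded, x$root_id))
  cat("Score quantiles:\n")
  print(round(x$score_quantiles, 3))
  invisible(x)
}

#' Extract the scaled scores from an immune-age fit
#' @param object An \code{immage} fit.
#' @param ... Unused.
#' @return Named numeric vector of scores in [0,1].
#' @export
coef.immage <- function(object, ...) object$scores

#' Plot the diffusion embedding of an immune-age fit
#'
#' First two diffusion components, points shaded by score, root marked.
#'
#' @param x An \code{immage} fit.
#' @param ... Passed to \code{plot}.
#' @export
plot.immage <- function(x, ...) {
  emb <- x$embedding
  if (ncol(emb) < 2) emb <- cbind(emb, 0)
  shade <- grDevices::gray(1 - 0.85 * x$scores)
  graphics::plot(emb[, 1], emb[, 2], pch = 19, col = shade,
                 xlab = "diffusion component 1", ylab = "diffusion component 2",
                 main = "Immune-age trajectory", ...)
  graphics::points(emb[x$root_id, 1], emb[x$root_id, 2], pch = 4, cex = 2,
                   lwd = 2, col = "red")
}
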