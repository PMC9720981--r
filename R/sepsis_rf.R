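#' Random-forest configuration for sepsis feature ranking
#'
#' @param ntree Number of trees (default 500).
#' @param mtry Features sampled per split; default \code{floor(sqrt(p))},
#'   resolved at fit time from the number of features.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param stratified Use a stratified bootstrap balancing the two classes
#'   per tree (default FALSE).
#' @return List of class \code{rf_config}.
#' @export
rf_config <- function(ntree = 500, mtry = NULL, seed = 1L, stratified = FALSE) {
  if (ntree < 1) stop_immflow("ntree must be >= 1", class = "immflow_config_error")
  structure(list(ntree = as.integer(ntree), mtry = mtry,
                 seed = as.integer(seed), stratified = isTRUE(stratified)),
            class = "rf_config")
}

#' Random-forest ranking of sepsis-associated features
#'
#' Fits a bootstrap random-forest classifier of sepsis status and ranks the
#' features by permutation importance computed on out-of-bag (OOB) samples
#' (mean decrease in accuracy, averaged over trees). OOB predictions also
#' give the reported accuracy and confusion table. Rows with any missing
#' feature are dropped and counted.
#'
#' @param features Data.frame or matrix, samples in rows, numeric features
#'   in columns.
#' @param labels Logical or two-level factor of sepsis status, one per row.
#' @param config An \code{\link{rf_config}}.
#' @return Object of class \code{rf_result}: \code{ranking} (features by
#'   decreasing mean decrease in accuracy), \code{mda} (named vector),
#'   \code{oob_accuracy}, \code{confusion} (2x2 OOB table, truth in rows),
#'   \code{n_used}, \code{n_dropped}, \code{config_echo}.
#' @export
fit_rank <- function(features, labels, config = rf_config()) {
  X <- as.data.frame(features)
  if (ncol(X) == 0) stop_immflow("no features supplied", class = "immflow_config_error")
  if (is.logical(labels))
    labels <- factor(ifelse(labels, "sepsis", "no_sepsis"),
                     levels = c("no_sepsis", "sepsis"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop_immflow("labels must contain exactly 2 classes, got %d", nlevels(labels),
                 class = "immflow_config_error")
  keep <- stats::complete.cases(X) & !is.na(labels)
  n_dropped <- sum(!keep)
  X <- X[keep, , drop = FALSE]
  labels <- labels[keep]
  if (any(table(labels) < 2))
    stop_immflow("need at least 2 samples per class",
                 class = "immflow_insufficient_samples_error")
  p <- ncol(X)
  mtry <- config$mtry %||% max(1L, floor(sqrt(p)))
  set.seed(config$seed)
  args <- list(x = X, y = labels, ntree = config$ntree, mtry = mtry,
               importance = TRUE)
  if (config$stratified) {
    nmin <- min(table(labels))
    args$strata <- labels
    args$sampsize <- c(nmin, nmin)
  }
  rf <- do.call(randomForest::randomForest, args)
  mda <- randomForest::importance(rf, type = 1)[, 1]
  ranking <- names(sort(mda, decreasing = TRUE))
  pred <- rf$predicted  # OOB predictions
  confusion <- table(truth = labels, predicted = pred)
  oob_accuracy <- mean(pred == labels)
  structure(list(ranking = ranking, mda = mda,
                 oob_accuracy = oob_accuracy, confusion = confusion,
                 n_used = nrow(X), n_dropped = n_dropped,
                 mtry = mtry, config_echo = config),
            class = "rf_result")
}

#' @export
print.rf_result <- function(x, ...) {
  cat(sprintf("Random-forest sepsis model: n = %d (dropped %d), mtry = %d\n",
              x$n_used, x$n_dropped, x$mtry))
  cat(sprintf("OOB accuracy: %.3f\n", x$oob_accuracy))
  cat("Top features (mean decrease in accuracy):\n")
  top <- utils::head(x$ranking, 10)
  for (f in top) cat(sprintf("  %-28s %.3f\n", f, x$mda[[f]]))
  invisible(x)
}

#' Univariate screening of features against sepsis status
#'
#' Per-feature two-group t test of septic vs non-septic samples, returned
#' sorted by p value.
#'
#' @param features Data.frame or matrix of numeric features.
#' @param labels Logical or two-level factor of sepsis status.
#' @param variant Passed to \code{\link{two_group_test}}.
#' @return Data.frame with columns \code{feature}, \code{statistic},
#'   \code{p_value}, sorted by ascending p.
#' @export
univariate_feature_tests <- function(features, labels,
                                     variant = c("student", "welch")) {
  variant <- match.arg(variant)
  X <- as.data.frame(features)
  if (is.logical(labels))
    labels <- factor(ifelse(labels, "sepsis", "no_sepsis"),
                     levels = c("no_sepsis", "sepsis"))
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2)
    stop_immflow("labels must contain exactly 2 classes",
                 class = "immflow_config_error")
  lv <- levels(labels)
  res <- lapply(names(X), function(f) {
    a <- X[[f]][labels == lv[1]]
    b <- X[[f]][labels == lv[2]]
    r <- two_group_test(a, b, variant = variant)
    data.frame(feature = f, statistic = r$statistic, p_value = r$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value, out$feature), , drop = FALSE]
}
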