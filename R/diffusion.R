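#' Scoring-pipeline configuration
#'
#' Tunable parameters of the immune-age scoring pipeline.
#'
#' @param trim_fraction Proportion trimmed per tail during feature
#'   standardization (default 0.10, i.e. a 10% two-tailed trim).
#' @param kernel_bandwidth Either \code{"median_pairwise_distance"} (the
#'   Gaussian kernel bandwidth is the median of the non-zero pairwise
#'   distances; scale-free default) or a fixed positive number.
#' @param n_components Number of non-trivial diffusion components retained
#'   (default 3).
#' @param diffusion_time Diffusion time t >= 1; components are weighted by
#'   eigenvalue^t (default 1).
#' @param root_rule \code{"min_cd28neg_cd8"} (default: the sample with the
#'   lowest CD28- CD8 frequency, i.e. the highest CD28+ fraction, anchors
#'   the young end of the trajectory) or an explicit sample id.
#' @return A list of class \code{immage_config}.
#' @export
immage_config <- function(trim_fraction = 0.10,
                          kernel_bandwidth = "median_pairwise_distance",
                          n_components = 3,
                          diffusion_time = 1,
                          root_rule = "min_cd28neg_cd8") {
  if (trim_fraction < 0 || trim_fraction >= 0.5)
    stop_immflow("trim_fraction must be in [0, 0.5)", class = "immflow_config_error")
  if (n_components < 1) stop_immflow("n_components must be >= 1",
                                     class = "immflow_config_error")
  if (diffusion_time < 1) stop_immflow("diffusion_time must be >= 1",
                                       class = "immflow_config_error")
  structure(list(trim_fraction = trim_fraction,
                 kernel_bandwidth = kernel_bandwidth,
                 n_components = n_components,
                 diffusion_time = diffusion_time,
                 root_rule = root_rule),
            class = "immage_config")
}

#' Diffusion-map embedding of standardized samples
#'
#' Builds the spectral embedding underlying the pseudotime score: Euclidean
#' pairwise distances in standardized feature space; Gaussian kernel
#' \code{w(i,j) = exp(-d^2 / (2 sigma^2))}; density normalization
#' (anisotropic, alpha = 1) to remove sampling-density bias; row
#' normalization to a Markov transition matrix; eigendecomposition via the
#' symmetric conjugate. The trivial unit eigenvalue/constant eigenvector is
#' dropped and the \code{n_components} eigenvectors with the largest
#' remaining eigenvalues are returned, each scaled by
#' \code{eigenvalue^diffusion_time}, so Euclidean distance in the embedding
#' is the diffusion distance at that time. Deterministic: each component's
#' sign is fixed so its largest-magnitude entry is positive.
#'
#' @param X Numeric matrix, samples in rows (rownames = sample ids),
#'   standardized features in columns; at least 8 rows.
#' @param config An \code{\link{immage_config}}.
#' @return List with \code{eigenvalues} (retained, non-increasing),
#'   \code{embedding} (samples x components matrix, eigenvalue-weighted),
#'   \code{all_eigenvalues} (full Markov spectrum), \code{bandwidth}.
#' @export
build_diffusion_map <- function(X, config = immage_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 8)
    stop_immflow("diffusion map needs at least 8 complete samples, got %d", n,
                 class = "immflow_insufficient_samples_error")
  if (any(!is.finite(X)))
    stop_immflow("non-finite values in standardized feature matrix",
                 class = "immflow_data_error")
  D <- as.matrix(stats::dist(X))
  if (identical(config$kernel_bandwidth, "median_pairwise_distance")) {
    dv <- D[upper.tri(D)]
    dv <- dv[dv > 0]
    if (!length(dv))
      stop_immflow("all samples identical; kernel bandwidth undefined",
                   class = "immflow_degenerate_error")
    sigma <- stats::median(dv)
  } else {
    sigma <- as.numeric(config$kernel_bandwidth)
    if (!is.finite(sigma) || sigma <= 0)
      stop_immflow("fixed kernel bandwidth must be positive",
                   class = "immflow_config_error")
  }
  K <- exp(-D^2 / (2 * sigma^2))
  # anisotropic alpha = 1 density normalization
  q <- rowSums(K)
  Ka <- K / tcrossprod(q)
  d <- rowSums(Ka)
  # symmetric conjugate of the Markov matrix P = D^-1 Ka
  S <- Ka / tcrossprod(sqrt(d))
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  lambda <- eig$values
  # right eigenvectors of P
  psi <- eig$vectors / sqrt(d)
  m <- min(config$n_components, n - 1)
  keep <- seq(2, m + 1)
  lam <- lambda[keep]
  emb <- psi[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry positive
  for (jj in seq_len(ncol(emb))) {
    idx <- which.max(abs(emb[, jj]))
    if (emb[idx, jj] < 0) emb[, jj] <- -emb[, jj]
  }
  emb <- sweep(emb, 2, lam^config$diffusion_time, `*`)
  rownames(emb) <- rownames(X)
  list(eigenvalues = lam, embedding = emb, all_eigenvalues = lambda,
       bandwidth = sigma)
}

#' Select the trajectory root
#'
#' Default rule: the retained sample with the minimum CD28- CD8 frequency
#' (equivalently the maximum CD28+ fraction), anchoring the trajectory at
#' the senescence-low end; ties are broken by lexicographic sample id. An
#' explicit sample id may be supplied instead.
#'
#' @param cd28neg_cd8 Named numeric vector of CD28- CD8 frequencies for the
#'   retained samples.
#' @param rule \code{"min_cd28neg_cd8"} or an explicit sample id present in
#'   \code{names(cd28neg_cd8)}.
#' @return The root sample id.
#' @export
select_root <- function(cd28neg_cd8, rule = "min_cd28neg_cd8") {
  if (!identical(rule, "min_cd28neg_cd8")) {
    if (!rule %in% names(cd28neg_cd8))
      stop_immflow("explicit root '%s' is not among the retained samples", rule,
                   class = "immflow_lookup_error")
    return(rule)
  }
  ids <- names(cd28neg_cd8)
  ord <- order(cd28neg_cd8, ids)
  ids[ord[1]]
}

#' Pseudotime as diffusion distance from the root
#'
#' The raw pseudotime of a sample is its Euclidean distance from the root in
#' the eigenvalue-weighted diffusion embedding (the diffusion distance at
#' the configured diffusion time); the root scores exactly 0.
#'
#' @param embedding Eigenvalue-weighted embedding from
#'   \code{\link{build_diffusion_map}} (samples x components, rownames ids).
#' @param root_id Sample id of the root; must be among the rows.
#' @return Named numeric vector of raw (unscaled) pseudotime values.
#' @export
pseudotime_scores <- function(embedding, root_id) {
  if (!root_id %in% rownames(embedding))
    stop_immflow("root id '%s' not found in embedding", root_id,
                 class = "immflow_lookup_error")
  delta <- sweep(embedding, 2, embedding[root_id, ], `-`)
  raw <- sqrt(rowSums(delta^2))
  raw[root_id] <- 0
  raw
}
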