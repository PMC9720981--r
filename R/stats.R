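#' Normality screen
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test of normality (the reference
#' normal has mean and SD estimated from the sample), with a pass flag at
#' the given alpha.
#'
#' @param values Numeric vector, n >= 4, not constant.
#' @param alpha Significance level for the flag (default 0.05).
#' @return List with \code{statistic}, \code{p_value}, \code{normal}
#'   (TRUE when p > alpha).
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  if (length(values) < 4)
    stop_immflow("normality check needs at least 4 values",
                 class = "immflow_insufficient_samples_error")
  if (stats::sd(values) == 0)
    stop_immflow("constant input; normality undefined",
                 class = "immflow_degenerate_error")
  ks <- nortest::lillie.test(values)
  list(statistic = unname(ks$statistic), p_value = unname(ks$p.value),
       normal = unname(ks$p.value) > alpha)
}

t_from_summary <- function(m1, s1, n1, m2, s2, n2, variant) {
  if (variant == "student") {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) {
    if (m1 == m2)
      stop_immflow("zero variance in both groups with equal means; t undefined",
                   class = "immflow_degenerate_error")
    t <- sign(m1 - m2) * Inf
  } else t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

#' Two-group t test (raw vectors or printed summary statistics)
#'
#' Two-sided t test between two groups, either from raw vectors or from
#' published summary statistics (each group a list with \code{mean},
#' \code{sd}, \code{n}), which allows printed cohort tables to be re-tested.
#' The \code{student} variant pools variances; \code{welch} uses the
#' Welch-Satterthwaite approximation.
#'
#' @param a,b Numeric vectors (each n >= 2), or lists with elements
#'   \code{mean}, \code{sd}, \code{n}.
#' @param variant \code{"student"} (default) or \code{"welch"}.
#' @return List of class \code{comparison_result}: \code{groups} (n per
#'   group), \code{statistic_name} ("t"), \code{statistic}, \code{df},
#'   \code{p_value}, \code{method}.
#' @export
two_group_test <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  if (is.list(a) != is.list(b))
    stop_immflow("both groups must be raw vectors or both summary lists",
                 class = "immflow_config_error")
  if (is.list(a)) {
    ns <- c(a$n, b$n)
    if (any(ns < 2)) stop_immflow("each group needs n >= 2",
                                  class = "immflow_insufficient_samples_error")
    res <- t_from_summary(a$mean, a$sd, a$n, b$mean, b$sd, b$n, variant)
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    ns <- c(length(a), length(b))
    if (any(ns < 2)) stop_immflow("each group needs n >= 2",
                                  class = "immflow_insufficient_samples_error")
    res <- t_from_summary(mean(a), stats::sd(a), length(a),
                          mean(b), stats::sd(b), length(b), variant)
  }
  structure(list(groups = ns, statistic_name = "t",
                 statistic = res$statistic, df = res$df,
                 p_value = res$p_value,
                 method = paste0("t_test_", variant)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  adj <- if (!is.null(x$adjusted_p)) sprintf(", adj. p = %.3g", x$adjusted_p) else ""
  cat(sprintf("%s: %s = %.4g, df = %.4g, p = %.3g%s (n = %s)\n",
              x$method, x$statistic_name, x$statistic, x$df %||% NA,
              x$p_value, adj, paste(x$groups, collapse = "/")))
  invisible(x)
}

#' One-way ANOVA with Bonferroni post hoc contrasts
#'
#' Omnibus one-way ANOVA over k groups followed by pairwise t tests for the
#' requested contrasts using the pooled within-group variance (residual MS,
#' df = N - k); each contrast's p value is Bonferroni-adjusted as
#' \code{min(1, m * p)} with m the number of requested contrasts.
#'
#' @param groups Named list of numeric vectors (each n >= 2).
#' @param contrasts List of 2-element character vectors naming group pairs;
#'   defaults to all pairs.
#' @return List with \code{omnibus} (a \code{comparison_result} with an F
#'   statistic) and \code{contrasts} (list of \code{comparison_result}s with
#'   \code{adjusted_p}).
#' @export
anova_bonferroni <- function(groups, contrasts = NULL) {
  if (length(groups) < 2)
    stop_immflow("need at least 2 groups", class = "immflow_config_error")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2))
    stop_immflow("group '%s' has n < 2", names(groups)[which(ns < 2)[1]],
                 class = "immflow_insufficient_samples_error")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ns), levels = names(groups))
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1]]
  Fv <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  omnibus <- structure(list(groups = ns, statistic_name = "F",
                            statistic = Fv, df = unname(tab[["Df"]]),
                            p_value = p, method = "anova"),
                       class = "comparison_result")
  if (is.null(contrasts))
    contrasts <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(contrasts)
  mse <- tab[["Mean Sq"]][2]
  df_res <- tab[["Df"]][2]
  cr <- lapply(contrasts, function(pair) {
    if (!all(pair %in% names(groups)))
      stop_immflow("contrast names unknown group '%s'",
                   setdiff(pair, names(groups))[1], class = "immflow_lookup_error")
    x1 <- groups[[pair[1]]]; x2 <- groups[[pair[2]]]
    se <- sqrt(mse * (1 / length(x1) + 1 / length(x2)))
    t <- (mean(x1) - mean(x2)) / se
    pv <- 2 * stats::pt(-abs(t), df_res)
    structure(list(groups = c(length(x1), length(x2)),
                   statistic_name = "t", statistic = t, df = df_res,
                   p_value = pv, adjusted_p = min(1, m * pv),
                   method = "anova_bonferroni",
                   contrast = paste(pair, collapse = " vs ")),
              class = "comparison_result")
  })
  list(omnibus = omnibus, contrasts = cr)
}

#' Univariate linear regression
#'
#' Ordinary least squares of y on a single predictor; the p value is from
#' the F test of the slope.
#'
#' @param x Predictor vector (not constant), \code{y} response; n >= 3
#'   after removing pairs with missing values.
#' @param y Response vector.
#' @return List of class \code{regression_result}: \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{f_statistic}, \code{p_value},
#'   \code{n}.
#' @export
univariate_regression <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    stop_immflow("regression needs at least 3 complete pairs",
                 class = "immflow_insufficient_samples_error")
  if (stats::sd(x) == 0)
    stop_immflow("degenerate predictor: x is constant",
                 class = "immflow_degenerate_error")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  fs <- sm$fstatistic
  if (is.null(fs)) { # zero residual-model F unavailable (e.g. perfect fit edge)
    f <- NA_real_; p <- NA_real_
  } else {
    f <- unname(fs[1])
    p <- unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
  }
  r2 <- sm$r.squared
  if (r2 == 0) { f <- 0; p <- 1 }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, f_statistic = f, p_value = p,
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS (n = %d): slope = %.4g, intercept = %.4g, R^2 = %.3f, F = %.4g, p = %.3g\n",
              x$n, x$slope, x$intercept, x$r_squared, x$f_statistic, x$p_value))
  invisible(x)
}
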