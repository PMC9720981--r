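#' Canonical gated-subset dictionary
#'
#' Returns the schema of cell-subset frequencies handled by the package: one
#' row per subset with its column name, the parent population the percentage
#' refers to, the lineage, and (where applicable) the exhaustive
#' differentiation quartet it belongs to. All stored frequencies are
#' percent-of-stated-parent, exactly as gated; the parent path makes the
#' chain rule for absolute counts unambiguous.
#'
#' The T-lineage covers total T cells of lymphocytes, the CD4/CD8 split, the
#' CD45RA/CCR7 differentiation quartet (naive, central memory, effector
#' memory, EMRA) within each lineage, senescence markers (CD28-, CD57+, and
#' their CD28-CD57+ intersection), recent thymic emigrants (PTK7+ of naive
#' CD4) and regulatory T cells (CD25+Foxp3+ of CD4). The B-lineage covers
#' total B cells, the CD27/IgD memory split (naive CD27-IgD+, switched
#' memory CD27+IgD-, unswitched memory CD27+IgD+) and regulatory B cells
#' (CD24hi CD38hi).
#'
#' A machine-readable copy ships as \code{subset_schema.json} in the
#' package's \code{extdata} directory.
#'
#' @return A data.frame with columns \code{name}, \code{parent},
#'   \code{lineage}, \code{quartet} (logical).
#' @export
subset_schema <- function() {
  s <- function(name, parent, lineage, quartet = FALSE)
    data.frame(name = name, parent = parent, lineage = lineage,
               quartet = quartet, stringsAsFactors = FALSE)
  rbind(
    s("tcell_of_lymphs", "lymphocytes", "T"),
    s("bcell_of_lymphs", "lymphocytes", "B"),
    s("cd4_of_t", "tcell_of_lymphs", "T"),
    s("cd8_of_t", "tcell_of_lymphs", "T"),
    s("cd4_naive", "cd4_of_t", "T", TRUE),
    s("cd4_cm",    "cd4_of_t", "T", TRUE),
    s("cd4_em",    "cd4_of_t", "T", TRUE),
    s("cd4_emra",  "cd4_of_t", "T", TRUE),
    s("cd8_naive", "cd8_of_t", "T", TRUE),
    s("cd8_cm",    "cd8_of_t", "T", TRUE),
    s("cd8_em",    "cd8_of_t", "T", TRUE),
    s("cd8_emra",  "cd8_of_t", "T", TRUE),
    s("cd4_cd28neg",   "cd4_of_t", "T"),
    s("cd4_cd57pos",   "cd4_of_t", "T"),
    s("cd4_senescent", "cd4_of_t", "T"),
    s("cd8_cd28neg",   "cd8_of_t", "T"),
    s("cd8_cd57pos",   "cd8_of_t", "T"),
    s("cd8_senescent", "cd8_of_t", "T"),
    s("rte_of_naive_cd4", "cd4_naive", "T"),
    s("treg_of_cd4", "cd4_of_t", "T"),
    s("b_naive",          "bcell_of_lymphs", "B"),
    s("b_switched_mem",   "bcell_of_lymphs", "B"),
    s("b_unswitched_mem", "bcell_of_lymphs", "B"),
    s("breg_of_b",        "bcell_of_lymphs", "B")
  )
}

#' Names of the eight subset frequencies entering the immune-age score
#'
#' Total T cells, naive CD4, effector memory CD4 and CD8, EMRA CD8, CD28-
#' CD8, CD57+ CD8 and regulatory T cells.
#'
#' @return Character vector of column names in the panels table.
#' @export
immage_features <- function() {
  c("tcell_of_lymphs", "cd4_naive", "cd4_em", "cd8_em", "cd8_emra",
    "cd8_cd28neg", "cd8_cd57pos", "treg_of_cd4")
}

quartet_cols <- function(lineage) paste0(lineage, c("_naive", "_cm", "_em", "_emra"))

as_panel_row <- function(panel) {
  if (is.data.frame(panel)) {
    if (nrow(panel) != 1L)
      stop_immflow("expected a single panel row, got %d rows", nrow(panel),
                   class = "immflow_schema_error")
    v <- panel
    id <- if ("subject_id" %in% names(v)) as.character(v$subject_id) else NA_character_
    v <- v[, setdiff(names(v), "subject_id"), drop = FALSE]
    out <- as.numeric(v[1, ])
    names(out) <- names(v)
  } else {
    out <- panel
    id <- NA_character_
  }
  known <- subset_schema()$name
  unknown <- setdiff(names(out), known)
  if (length(unknown))
    stop_immflow("unknown subset name(s): %s", paste(unknown, collapse = ", "),
                 class = "immflow_schema_error")
  attr(out, "subject_id") <- id
  out
}

#' Validate one phenotype panel against the subset invariants
#'
#' Checks that every frequency lies in [0,100], that the CD45RA/CCR7 quartet
#' is exhaustive (sums to 100 within \code{tol}) in each of CD4 and CD8, and
#' that the senescent (CD28-CD57+) frequency does not exceed the smaller of
#' the CD28- and CD57+ frequencies by more than \code{tol} (intersection
#' bound). Rules whose inputs are missing are skipped; unknown subset names
#' are a schema error.
#'
#' @param panel One-row data.frame or named numeric vector of subset
#'   frequencies (percent of stated parent).
#' @param tol Tolerance in percentage points for the sum and intersection
#'   rules (default 0.5, allowing for gating round-off).
#' @return Data.frame of violations with columns \code{subset}, \code{rule},
#'   \code{observed}; zero rows when the panel is valid.
#' @export
validate_panel <- function(panel, tol = 0.5) {
  x <- as_panel_row(panel)
  out <- data.frame(subset = character(), rule = character(),
                    observed = numeric(), stringsAsFactors = FALSE)
  add <- function(subset, rule, observed)
    rbind(out, data.frame(subset = subset, rule = rule, observed = observed,
                          stringsAsFactors = FALSE))
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.na(v)) next
    if (v < 0 || v > 100) out <- add(nm, "range_0_100", v)
  }
  for (lin in c("cd4", "cd8")) {
    q <- x[quartet_cols(lin)]
    if (all(quartet_cols(lin) %in% names(x)) && !anyNA(q)) {
      s <- sum(q)
      if (abs(s - 100) > tol) out <- add(lin, "quartet_sum_100", s)
    }
    sen <- x[[paste0(lin, "_senescent")]]
    c28 <- x[[paste0(lin, "_cd28neg")]]
    c57 <- x[[paste0(lin, "_cd57pos")]]
    if (!is.null(sen) && !is.null(c28) && !is.null(c57) &&
        !anyNA(c(sen, c28, c57))) {
      bound <- min(c28, c57)
      if (sen > bound + tol) out <- add(paste0(lin, "_senescent"),
                                        "intersection_bound", sen)
    }
  }
  out
}

#' Validate every panel in a cohort table
#'
#' @param panels Data.frame with a \code{subject_id} column and subset
#'   frequency columns.
#' @param tol Passed to \code{\link{validate_panel}}.
#' @return Data.frame of violations with a leading \code{subject_id} column.
#' @export
validate_panels <- function(panels, tol = 0.5) {
  out <- lapply(seq_len(nrow(panels)), function(i) {
    v <- validate_panel(panels[i, , drop = FALSE], tol = tol)
    if (nrow(v)) cbind(subject_id = as.character(panels$subject_id[i]), v)
    else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(subject_id = character(), subset = character(),
                      rule = character(), observed = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Absolute cell counts from parent-relative frequencies
#'
#' Converts parent-relative percentages into absolute counts (10^9 cells/L)
#' by chaining products along each subset's parent path down to the
#' lymphocyte count, e.g. naive CD8 absolute = lymphocytes x T-of-lymphs/100
#' x CD8-of-T/100 x naive/100.
#'
#' @param panel One-row data.frame or named numeric vector of frequencies.
#' @param lymphocyte_count Lymphocyte count in 10^9 cells/L (must be present
#'   and positive; a missing count is an error, never a silent zero).
#' @return Named numeric vector of absolute counts (10^9 cells/L), one per
#'   subset present in the panel.
#' @export
absolute_counts <- function(panel, lymphocyte_count) {
  if (length(lymphocyte_count) != 1 || is.na(lymphocyte_count))
    stop_immflow("lymphocyte count is missing; absolute counts undefined",
                 class = "immflow_missing_data_error")
  if (lymphocyte_count <= 0)
    stop_immflow("lymphocyte count must be positive, got %g", lymphocyte_count,
                 class = "immflow_missing_data_error")
  x <- as_panel_row(panel)
  schema <- subset_schema()
  parent_of <- stats::setNames(schema$parent, schema$name)
  count_of <- function(nm) {
    if (nm == "lymphocytes") return(lymphocyte_count)
    f <- x[[nm]]
    if (is.null(f) || is.na(f))
      stop_immflow("frequency for '%s' needed on the parent path is missing", nm,
                   class = "immflow_missing_data_error")
    count_of(parent_of[[nm]]) * f / 100
  }
  out <- vapply(names(x)[!is.na(x)], count_of, numeric(1))
  out
}

#' Naive-to-memory T cell ratio
#'
#' Ratio of the naive frequency to the total memory frequency within one
#' lineage, memory being the quartet complement of naive (central memory +
#' effector memory + EMRA).
#'
#' @param panel One-row data.frame or named numeric vector of frequencies.
#' @param lineage \code{"cd4"} or \code{"cd8"}.
#' @return The ratio naive / (cm + em + emra).
#' @export
naive_memory_ratio <- function(panel, lineage = c("cd4", "cd8")) {
  lineage <- match.arg(lineage)
  x <- as_panel_row(panel)
  q <- quartet_cols(lineage)
  if (!all(q %in% names(x)) || anyNA(x[q]))
    stop_immflow("quartet frequencies for %s incomplete", lineage,
                 class = "immflow_missing_data_error")
  mem <- sum(x[q[-1]])
  if (mem == 0)
    stop_immflow("memory total is zero for %s; ratio undefined", lineage,
                 class = "immflow_degenerate_error")
  unname(x[[q[1]]] / mem)
}
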