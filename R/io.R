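# Readers/writers for the cohort CSV dialect (comma-separated, UTF-8,
# header row, empty field = missing).

subjects_columns <- function() {
  list(subject_id = "character", group = "character",
       timepoint_day = "integer", age_years = "numeric", sex = "character",
       iss = "integer", niss = "integer", apache2 = "integer",
       sofa = "integer", saps2 = "integer", sepsis = "logical",
       icu_los_days = "numeric", hospital_los_days = "numeric",
       ventilator_days = "numeric", lymphocytes_1e9_per_L = "numeric",
       il6_pg_ml = "numeric", tnfa_pg_ml = "numeric",
       il10_pg_ml = "numeric", il8_pg_ml = "numeric", crp_mg_ml = "numeric")
}

check_schema <- function(found, expected, what) {
  unknown <- setdiff(found, expected)
  missing <- setdiff(expected, found)
  if (length(unknown) || length(missing))
    stop_immflow("%s schema mismatch%s%s", what,
                 if (length(missing)) paste0("; missing column(s): ",
                                             paste(missing, collapse = ", ")) else "",
                 if (length(unknown)) paste0("; unknown column(s): ",
                                             paste(unknown, collapse = ", ")) else "",
                 class = "immflow_schema_error")
}

coerce_column <- function(x, type, col) {
  if (type == "character") return(x)
  out <- switch(type,
    integer = suppressWarnings(as.integer(x)),
    numeric = suppressWarnings(as.numeric(x)),
    logical = {
      v <- rep(NA, length(x))
      v[x %in% c("TRUE", "true", "1")] <- TRUE
      v[x %in% c("FALSE", "false", "0")] <- FALSE
      v
    })
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop_immflow("cannot parse column '%s' at data line %d: '%s'",
                 col, bad[1], x[bad[1]], class = "immflow_parse_error")
  out
}

#' Read a subjects table
#'
#' Reads the per-sample subjects CSV (identifier, group, timepoint,
#' demographics, clinical scores, sepsis flag, stay lengths, lymphocyte
#' count, serum cytokines). The header must match the published schema
#' exactly (case-sensitive); empty fields become missing values; cells that
#' fail numeric parsing are reported with their data line number.
#'
#' @param path Path to subjects.csv.
#' @return Typed data.frame, one row per sample.
#' @export
read_subjects <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  spec <- subjects_columns()
  check_schema(names(raw), names(spec), "subjects")
  raw <- raw[, names(spec), drop = FALSE]
  for (col in names(spec)) raw[[col]] <- coerce_column(raw[[col]], spec[[col]], col)
  bad_group <- setdiff(unique(raw$group), c("HC", "trauma"))
  if (length(bad_group))
    stop_immflow("unknown group label(s): %s", paste(bad_group, collapse = ", "),
                 class = "immflow_parse_error")
  raw
}

#' Read a panels table
#'
#' Reads the per-sample subset-frequency CSV: \code{subject_id} plus one
#' column per subset in the canonical \code{\link{subset_schema}}
#' dictionary. Unknown or missing columns are a schema error.
#'
#' @param path Path to panels.csv.
#' @return Typed data.frame, one row per sample.
#' @export
read_panels <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = "", fileEncoding = "UTF-8")
  expected <- c("subject_id", subset_schema()$name)
  check_schema(names(raw), expected, "panels")
  raw <- raw[, expected, drop = FALSE]
  for (col in setdiff(expected, "subject_id"))
    raw[[col]] <- coerce_column(raw[[col]], "numeric", col)
  raw
}

#' Write cohort tables to a directory
#'
#' Writes \code{subjects.csv} and \code{panels.csv} (comma-separated,
#' UTF-8, header row, empty field = missing) in the dialect read back by
#' \code{\link{read_subjects}} / \code{\link{read_panels}}. Output is
#' byte-deterministic for a given cohort.
#'
#' @param cohort List with \code{subjects} and \code{panels} data.frames
#'   (as from \code{\link{generate_cohort}}).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- file.path(dir, "subjects.csv")
  pp <- file.path(dir, "panels.csv")
  utils::write.csv(cohort$subjects, sp, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  utils::write.csv(cohort$panels, pp, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(c(subjects = sp, panels = pp))
}
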