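DEMOG_COLS <- c("subject_id", "group", "age", "sex", "bmi", "batch", "dm_status")

#' Construct a validated cohort table
#'
#' A cohort is a data.frame with one row per participant: demographic columns
#' (`subject_id`, `group`, `age`, `sex`, `bmi`, `batch`, optional
#' `dm_status`) followed by one column per panel metabolite holding plasma
#' concentrations.  `group` is the case-control label: `OA` (knee
#' osteoarthritis, the positive class) versus `HV` (healthy volunteer).
#' Metabolite columns are identified by their names parsing as panel
#' metabolites and are renamed to the canonical compact dialect.
#'
#' @param df data.frame with the columns above.
#' @return An object of class `cohort` (a data.frame) with attributes
#'   `metabolites` (canonical metabolite column names), `batch_adjusted` and
#'   `log_transformed` (logical provenance flags).
#' @export
as_cohort <- function(df) {
  stopifnot(is.data.frame(df))
  mandatory <- c("subject_id", "group", "age", "sex", "bmi", "batch")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  metab_cols <- setdiff(names(df), DEMOG_COLS)
  if (length(metab_cols) == 0L) {
    stop("cohort has no metabolite columns", call. = FALSE)
  }
  parseable <- is_metabolite_name(metab_cols)
  if (any(!parseable)) {
    stop("non-metabolite column(s) outside the demographic schema: ",
         paste(sQuote(metab_cols[!parseable]), collapse = ", "), call. = FALSE)
  }
  out <- df
  canon <- canonical_metabolite_name(metab_cols)
  names(out)[match(metab_cols, names(out))] <- canon

  grp <- toupper(as.character(out$group))
  if (!all(grp %in% c("OA", "HV"))) {
    stop("group labels must be 'OA' or 'HV' (case-insensitive)", call. = FALSE)
  }
  out$group <- factor(grp, levels = c("HV", "OA"))
  sex <- tolower(as.character(out$sex))
  if (!all(sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  out$sex <- factor(sex, levels = c("male", "female"))
  out$subject_id <- as.character(out$subject_id)
  out$batch <- factor(out$batch)
  if (!"dm_status" %in% names(out)) {
    out$dm_status <- factor(rep("unknown", nrow(out)),
                            levels = c("yes", "no", "unknown"))
  } else {
    dm <- tolower(as.character(out$dm_status))
    dm[is.na(dm)] <- "unknown"
    if (!all(dm %in% c("yes", "no", "unknown"))) {
      stop("dm_status must be 'yes', 'no' or 'unknown'", call. = FALSE)
    }
    out$dm_status <- factor(dm, levels = c("yes", "no", "unknown"))
  }
  stopifnot(is.numeric(out$age), all(out$age > 0),
            is.numeric(out$bmi), all(out$bmi > 0))

  conc <- out[canon]
  if (!all(vapply(conc, is.numeric, TRUE))) {
    stop("metabolite columns must be numeric", call. = FALSE)
  }
  if (anyNA(conc)) {
    stop("missing metabolite concentrations are not supported", call. = FALSE)
  }
  if (any(as.matrix(conc) < 0)) {
    stop("negative metabolite concentrations", call. = FALSE)
  }
  out <- out[c(DEMOG_COLS, canon)]
  structure(out, metabolites = canon,
            batch_adjusted = isTRUE(attr(df, "batch_adjusted")),
            log_transformed = isTRUE(attr(df, "log_transformed")),
            class = c("cohort", "data.frame"))
}

#' Read a cohort table from CSV
#'
#' @param path path to a CSV file with a header row: the demographic columns
#'   of [as_cohort()] followed by metabolite concentration columns (either
#'   name dialect).
#' @return A validated `cohort` object.
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  as_cohort(df)
}

#' Write a cohort table to CSV
#'
#' Values round-trip through [read_cohort_csv()] up to column order.
#'
#' @param cohort a `cohort` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Metabolite column names of a cohort
#' @param cohort a `cohort` object.
#' @return character vector of canonical metabolite names.
#' @export
metabolites <- function(cohort) attr(cohort, "metabolites")

#' Concentration matrix of a cohort
#' @param cohort a `cohort` object.
#' @param columns optional subset of metabolite names.
#' @return numeric matrix, participants x metabolites, rownames = subject ids.
#' @export
cohort_matrix <- function(cohort, columns = metabolites(cohort)) {
  stopifnot(all(columns %in% metabolites(cohort)))
  m <- as.matrix(as.data.frame(cohort)[columns])
  rownames(m) <- cohort$subject_id
  m
}

#' Binary case labels of a cohort (OA = 1, HV = 0)
#' @param cohort a `cohort` object.
#' @return integer vector of 0/1 labels.
#' @export
cohort_labels <- function(cohort) as.integer(cohort$group == "OA")

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants (%d OA / %d HV), %d metabolites\n",
              nrow(x), sum(x$group == "OA"), sum(x$group == "HV"),
              length(metabolites(x))))
  cat(sprintf("  batches: %d; batch_adjusted: %s; log_transformed: %s\n",
              nlevels(x$batch), attr(x, "batch_adjusted"),
              attr(x, "log_transformed")))
  invisible(x)
}

# Rebuild a cohort after row subsetting or value replacement, keeping flags.
cohort_like <- function(df, template, batch_adjusted = NULL,
                        log_transformed = NULL) {
  structure(as.data.frame(df),
            metabolites = attr(template, "metabolites"),
            batch_adjusted = if (is.null(batch_adjusted))
              attr(template, "batch_adjusted") else batch_adjusted,
            log_transformed = if (is.null(log_transformed))
              attr(template, "log_transformed") else log_transformed,
            class = c("cohort", "data.frame"))
}
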