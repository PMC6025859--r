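#' Load a packaged machine-readable study table
#'
#' Three reference tables ship with the package as TSV, transcribed as
#' printed:
#' \describe{
#'   \item{`table1`}{Cohort demographics per stratum: counts, age and BMI
#'     means/SDs per group, and the printed p-values (kept as character so
#'     bounds like `"< 0.001"` survive; see [fixture_pvalue()]).}
#'   \item{`table2`}{The per-stratum metabolite signatures: 39 metabolites x
#'     10 strata of median out-of-bag bootstrap AUCs; blank cells (metabolite
#'     not selected in that stratum) are `NA`.}
#'   \item{`table3`}{Model consistency grid: 18 (model, quantile) rows with
#'     train/test/difference AUCs for six strata plus the printed
#'     mean-absolute-difference columns.}
#' }
#'
#' @param table_id one of `"table1"`, `"table2"`, `"table3"`.
#' @return A data.frame of the printed values.
#' @examples
#' t2 <- load_fixture("table2")
#' t2[t2$metabolite == "PCaeC38:0", "males_age_gt50"]  # 0.74
#' @export
load_fixture <- function(table_id) {
  file <- switch(table_id,
    table1 = "table1_demographics.tsv",
    table2 = "table2_signatures.tsv",
    table3 = "table3_consistency.tsv",
    stop("unknown table_id: ", table_id, call. = FALSE)
  )
  path <- system.file("extdata", file, package = "metabosig", mustWork = TRUE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  df
}

#' Parse a printed p-value string
#'
#' Printed p-values are either plain numbers (`"0.312"`) or bounds
#' (`"< 0.001"`).  Returns the numeric value with an attribute `bound` set to
#' `TRUE` where the print is an upper bound.
#'
#' @param x character vector of printed p-values.
#' @return numeric vector with logical attribute `bound`.
#' @export
fixture_pvalue <- function(x) {
  bound <- grepl("<", x)
  val <- as.numeric(gsub("[<= ]", "", x))
  structure(val, bound = bound)
}

#' Extract the signature of one stratum from the printed signature table
#'
#' @param stratum a stratum key (a `table2` column name, e.g.
#'   `"males_age_gt50"`) .
#' @param table2 optionally a pre-loaded `table2` fixture.
#' @return character vector of canonical metabolite names with a value
#'   printed in that stratum's column.
#' @export
fixture_signature <- function(stratum, table2 = load_fixture("table2")) {
  if (!stratum %in% names(table2)) {
    stop("unknown stratum column: ", stratum, call. = FALSE)
  }
  table2$metabolite[!is.na(table2[[stratum]])]
}
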