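#' Parse a phosphatidylcholine panel metabolite name
#'
#' The targeted panel measures three lipid classes: lysophosphatidylcholines
#' (`lysoPC`), diacyl-phosphatidylcholines (`PCaa`) and
#' acyl-alkyl-phosphatidylcholines (`PCae`).  Names encode the total acyl
#' carbon count and number of double bonds, e.g. `"PCaaC32:3"` is a diacyl PC
#' with 32 carbons and 3 double bonds.  Both the compact dialect
#' (`"PCaaC32:3"`, `"lysoPCaC16:0"`) and the spaced Biocrates export dialect
#' (`"PC aa C32:3"`, `"lysoPC a C16:0"`) are accepted; the compact form is
#' canonical.
#'
#' @param name character vector of metabolite names in either dialect.
#' @return A data.frame with one row per name and columns `name` (canonical
#'   compact form), `lipid_class` (factor: `lysoPC`, `PCaa`, `PCae`),
#'   `carbons` and `double_bonds` (non-negative integers).
#' @examples
#' classify_metabolite_name(c("PCaaC32:3", "PC ae C38:0", "lysoPC a C16:0"))
#' @export
classify_metabolite_name <- function(name) {
  stopifnot(is.character(name), length(name) >= 1L)
  compact <- gsub("[ _-]+", "", name)
  m <- regmatches(compact,
                  regexec("^(lysoPCa|PCaa|PCae)C([0-9]+):([0-9]+)$", compact))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("unrecognized metabolite name(s): ",
         paste(sQuote(name[bad]), collapse = ", "),
         " (expected lysoPCaCx:y, PCaaCx:y or PCaeCx:y)", call. = FALSE)
  }
  prefix <- vapply(m, `[`, "", 2L)
  cls <- c(lysoPCa = "lysoPC", PCaa = "PCaa", PCae = "PCae")[prefix]
  data.frame(
    name = compact,
    lipid_class = factor(unname(cls), levels = c("lysoPC", "PCaa", "PCae")),
    carbons = as.integer(vapply(m, `[`, "", 3L)),
    double_bonds = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

#' Test whether strings are parseable panel metabolite names
#' @param name character vector.
#' @return logical vector.
#' @export
is_metabolite_name <- function(name) {
  compact <- gsub("[ _-]+", "", name)
  grepl("^(lysoPCa|PCaa|PCae)C[0-9]+:[0-9]+$", compact)
}

#' Canonicalize metabolite names to the compact dialect
#' @param name character vector of names in either dialect.
#' @return character vector of canonical compact names.
#' @export
canonical_metabolite_name <- function(name) {
  classify_metabolite_name(name)$name
}
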