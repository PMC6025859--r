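#' Remove batch effects from metabolite concentrations
#'
#' Default method `"median-ratio"`: per metabolite, every batch is rescaled
#' multiplicatively so its within-batch median equals the all-cohort median
#' of that metabolite.  This is scale-based, robust and preserves
#' positivity; it is applied on the raw concentration scale before the log
#' transform.  The alternative `"log-center"` centers per-batch means on the
#' log(x+1) scale and maps back, for cohorts whose batch effects are
#' additive after the transform.
#'
#' @param cohort a `cohort` object (raw concentration scale).
#' @param method `"median-ratio"` (default) or `"log-center"`.
#' @return The adjusted `cohort` with the `batch_adjusted` flag set.
#' @export
adjust_batch <- function(cohort, method = c("median-ratio", "log-center")) {
  stopifnot(inherits(cohort, "cohort"))
  method <- match.arg(method)
  if (isTRUE(attr(cohort, "log_transformed"))) {
    stop("adjust_batch expects raw-scale concentrations", call. = FALSE)
  }
  batches <- levels(droplevels(cohort$batch))
  if (length(batches) == 1L) {
    return(cohort_like(as.data.frame(cohort), cohort, batch_adjusted = TRUE))
  }
  if (any(table(droplevels(cohort$batch)) < 2L)) {
    stop("every batch needs >= 2 participants", call. = FALSE)
  }
  df <- as.data.frame(cohort)
  mets <- metabolites(cohort)
  x <- as.matrix(df[mets])
  for (m in seq_along(mets)) {
    global_med <- stats::median(x[, m])
    for (b in batches) {
      rows <- cohort$batch == b
      if (method == "median-ratio") {
        bmed <- stats::median(x[rows, m])
        if (bmed <= 0) {
          stop("batch ", b, " has non-positive median for ", mets[m],
               ": multiplicative adjustment undefined", call. = FALSE)
        }
        x[rows, m] <- x[rows, m] * global_med / bmed
      } else {
        lx <- log1p(x[rows, m])
        x[rows, m] <- expm1(lx - mean(lx) + mean(log1p(x[, m])))
      }
    }
  }
  x[x < 0] <- 0  # log-center back-transform can graze zero
  df[mets] <- x
  cohort_like(df, cohort, batch_adjusted = TRUE)
}

#' Apply the log(x+1) transform to metabolite concentrations
#'
#' Natural-log `log(x + 1)` per concentration; monotone and
#' order-preserving within each metabolite, so univariate AUCs are invariant
#' under it.  Values enter non-negative and leave non-negative.
#'
#' @param cohort a `cohort` object with raw-scale concentrations.
#' @return The transformed `cohort` with the `log_transformed` flag set.
#' @export
log1p_transform <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (isTRUE(attr(cohort, "log_transformed"))) {
    stop("cohort is already log-transformed", call. = FALSE)
  }
  df <- as.data.frame(cohort)
  mets <- metabolites(cohort)
  if (any(as.matrix(df[mets]) < 0)) {
    stop("negative concentrations cannot be log(x+1) transformed",
         call. = FALSE)
  }
  df[mets] <- log1p(as.matrix(df[mets]))
  cohort_like(df, cohort, log_transformed = TRUE)
}

#' Standard preprocessing: batch adjustment then log(x+1)
#'
#' @param cohort a raw `cohort`.
#' @param batch_method passed to [adjust_batch()].
#' @return The preprocessed `cohort`.
#' @export
preprocess_cohort <- function(cohort, batch_method = "median-ratio") {
  log1p_transform(adjust_batch(cohort, method = batch_method))
}
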