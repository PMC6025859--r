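#' Bootstrap out-of-bag AUC distribution of a single metabolite
#'
#' Per replicate, `N` individuals are drawn with replacement as a training
#' set; the out-of-bag (OOB) individuals — those never drawn, about
#' `(1 - 1/N)^N ~ 37%` of the cohort — form the test set.  A univariate
#' logistic regression is fit on the training draw and OOB individuals are
#' scored by the fitted linear predictor; the OOB AUC is recorded.
#' Replicates whose training draw or OOB set lacks one of the classes are
#' discarded and counted, not redrawn.
#'
#' @param x numeric vector of one metabolite's (transformed) values.
#' @param y binary labels (1 = case).
#' @param B number of bootstrap replicates (study value 1000).
#' @param seed integer seed; results are deterministic given it.
#' @param metabolite optional name carried into the result.
#' @return An object of class `bootstrap_auc_dist`: `replicate_aucs` (valid
#'   replicates only), `quantiles` (`q025`, `q50`, `q975`, type-7),
#'   `n_valid`, `n_discarded`, `B`, `oob_fraction` (mean OOB share).
#' @export
bootstrap_oob_auc <- function(x, y, B = 1000L, seed, metabolite = NA_character_) {
  y <- as_binary_labels(y)
  n <- length(x)
  stopifnot(length(y) == n, n >= 10L, B >= 1L)
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in the full data", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  aucs <- numeric(B)
  oob_frac <- numeric(B)
  valid <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag <- logical(n); inbag[idx] <- TRUE
    oob <- which(!inbag)
    oob_frac[b] <- length(oob) / n
    ytr <- y[idx]
    if (length(oob) == 0L || length(unique(ytr)) < 2L ||
        length(unique(y[oob])) < 2L) next
    beta <- logistic_uni(x[idx], ytr)
    scores <- beta[1L] + beta[2L] * x[oob]
    aucs[b] <- auc(scores, y[oob])
    valid[b] <- TRUE
  }
  n_valid <- sum(valid)
  if (n_valid < 0.5 * B) {
    stop(sprintf(
      "bootstrap unstable: only %d of %d replicates valid (%d discarded)",
      n_valid, B, B - n_valid), call. = FALSE)
  }
  q <- boot_quantiles(aucs[valid])
  structure(list(
    metabolite = metabolite,
    replicate_aucs = aucs[valid],
    quantiles = c(q025 = q[1L], q50 = q[2L], q975 = q[3L]),
    n_valid = n_valid, n_discarded = B - n_valid, B = as.integer(B),
    oob_fraction = mean(oob_frac)
  ), class = "bootstrap_auc_dist")
}

#' @export
print.bootstrap_auc_dist <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_auc_dist> %s: q025=%.3f q50=%.3f q975=%.3f (%d/%d valid)\n",
    x$metabolite, x$quantiles["q025"], x$quantiles["q50"],
    x$quantiles["q975"], x$n_valid, x$B))
  invisible(x)
}

#' Signature selection rule
#'
#' Metabolites enter a stratum's signature when the 2.5% quantile of their
#' out-of-bag AUC distribution clears 0.5 — i.e. at least 97.5% of bootstrap
#' replicates rank cases above controls better than chance.  The default is
#' the strict inequality `q(0.025) > 0.5`.
#'
#' @param quantile which quantile of the OOB AUC distribution is thresholded.
#' @param threshold the AUC threshold.
#' @param strict `TRUE` for `>`, `FALSE` for `>=`.
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(quantile = 0.025, threshold = 0.5, strict = TRUE) {
  stopifnot(quantile > 0, quantile < 1, threshold >= 0, threshold <= 1)
  structure(list(quantile = quantile, threshold = threshold,
                 strict = isTRUE(strict)), class = "selection_rule")
}

#' Select a stratum's metabolite signature from bootstrap AUC distributions
#'
#' @param dists list of [bootstrap_oob_auc()] results, all computed on the
#'   same stratified cohort.
#' @param stratum the [stratum_spec()] the distributions belong to.
#' @param rule a [selection_rule()].
#' @return An object of class `signature`: `entries` is a data.frame
#'   (metabolite, q025, q50, q975, n_valid) of selected metabolites sorted
#'   by name, with the reported AUC being the bootstrap median `q50`.  An
#'   empty selection is a valid (empty) signature.
#' @export
select_signature <- function(dists, stratum, rule = selection_rule()) {
  stopifnot(is.list(dists), inherits(stratum, "stratum_spec"),
            inherits(rule, "selection_rule"))
  rows <- lapply(dists, function(d) {
    stopifnot(inherits(d, "bootstrap_auc_dist"))
    qsel <- if (rule$quantile %in% c(0.025, 0.5, 0.975)) {
      d$quantiles[[sprintf("q%03.0f", rule$quantile * 1000)]]
    } else {
      boot_quantiles(d$replicate_aucs, rule$quantile)
    }
    data.frame(metabolite = d$metabolite, q025 = unname(d$quantiles["q025"]),
               q50 = unname(d$quantiles["q50"]),
               q975 = unname(d$quantiles["q975"]),
               n_valid = d$n_valid, q_rule = qsel,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  keep <- if (rule$strict) tab$q_rule > rule$threshold
          else tab$q_rule >= rule$threshold
  entries <- tab[keep, setdiff(names(tab), "q_rule"), drop = FALSE]
  entries <- entries[order(entries$metabolite), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(stratum = stratum, entries = entries, rule = rule),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> stratum '%s': %d metabolites\n",
              x$stratum$name, nrow(x$entries)))
  if (nrow(x$entries) > 0L) print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Metabolite names of a signature
#' @param signature a `signature` object.
#' @return character vector.
#' @export
signature_metabolites <- function(signature) signature$entries$metabolite

#' Run bootstrap selection for one stratum of a preprocessed cohort
#'
#' Computes [bootstrap_oob_auc()] for every panel metabolite within the
#' stratum and applies the selection rule.  Each metabolite's bootstrap is
#' seeded by `derive_seed(seed, stratum$name, metabolite)`, so results do
#' not depend on panel order.
#'
#' @param cohort a preprocessed (log-transformed) `cohort`.
#' @param stratum a [stratum_spec()].
#' @param B replicates per metabolite.
#' @param seed master seed.
#' @param rule a [selection_rule()].
#' @return A list with `signature` and `dists` (all per-metabolite
#'   distributions, named).
#' @export
stratum_signature <- function(cohort, stratum, B = 1000L, seed,
                              rule = selection_rule()) {
  sub <- stratify(cohort, stratum)
  y <- cohort_labels(sub)
  mets <- metabolites(sub)
  x <- cohort_matrix(sub)
  dists <- lapply(mets, function(m) {
    bootstrap_oob_auc(x[, m], y, B = B,
                      seed = derive_seed(seed, stratum$name, m),
                      metabolite = m)
  })
  names(dists) <- mets
  list(signature = select_signature(dists, stratum, rule), dists = dists)
}
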