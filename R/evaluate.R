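#' Bootstrap train/test AUC distribution of a multivariate classifier
#'
#' Per replicate, `N` participants are drawn with replacement; the model is
#' refit on the draw, its training AUC recorded on the draw and its test AUC
#' on the out-of-bag participants.  The feature set is fixed in advance (the
#' stratum's signature or the class aggregates) — metabolite selection is
#' not re-run inside replicates.  Degenerate replicates (a class missing
#' from draw or OOB set, or an infeasible fit) are discarded and counted.
#'
#' @param X numeric matrix, participants x features.
#' @param y binary labels (1 = case).
#' @param spec a [model_spec()].
#' @param B replicate count (study value 1000).
#' @param seed integer seed.
#' @param stratum_name optional label carried into the result.
#' @param keep_scores retain per-replicate out-of-bag and training
#'   score/label pairs (needed by [roc_band_export()]).
#' @return An object of class `model_bootstrap_summary` with type-7
#'   `train_quantiles` / `test_quantiles` at 2.5/50/97.5%, the per-replicate
#'   `(train, test)` AUC pairs, `n_valid`, `n_discarded`, `B` and `seed`.
#' @export
bootstrap_model_auc <- function(X, y, spec, B = 1000L, seed,
                                stratum_name = NA_character_,
                                keep_scores = FALSE) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  n <- nrow(X)
  stopifnot(length(y) == n, B >= 1L)
  if (length(unique(y)) < 2L) stop("both classes required", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  train_auc <- test_auc <- rep(NA_real_, B)
  scores <- if (keep_scores) vector("list", B) else NULL
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    inbag <- logical(n); inbag[idx] <- TRUE
    oob <- which(!inbag)
    if (length(oob) == 0L || length(unique(y[idx])) < 2L ||
        length(unique(y[oob])) < 2L) next
    fit <- tryCatch(fit_model(X[idx, , drop = FALSE], y[idx], spec),
                    error = function(e) NULL)
    if (is.null(fit)) next
    s_tr <- predict(fit, X[idx, , drop = FALSE])
    s_te <- predict(fit, X[oob, , drop = FALSE])
    train_auc[b] <- auc(s_tr, y[idx])
    test_auc[b] <- auc(s_te, y[oob])
    if (keep_scores) {
      scores[[b]] <- list(train = s_tr, train_labels = y[idx],
                          test = s_te, test_labels = y[oob])
    }
  }
  valid <- !is.na(train_auc)
  n_valid <- sum(valid)
  if (n_valid < 0.5 * B) {
    stop(sprintf("bootstrap unstable: only %d of %d replicates valid",
                 n_valid, B), call. = FALSE)
  }
  qt <- boot_quantiles(train_auc[valid])
  qe <- boot_quantiles(test_auc[valid])
  structure(list(
    stratum = stratum_name, spec = spec,
    train_quantiles = c(q025 = qt[1L], q50 = qt[2L], q975 = qt[3L]),
    test_quantiles = c(q025 = qe[1L], q50 = qe[2L], q975 = qe[3L]),
    replicates = data.frame(train = train_auc[valid], test = test_auc[valid]),
    scores = if (keep_scores) scores[valid] else NULL,
    n_valid = n_valid, n_discarded = B - n_valid, B = as.integer(B),
    seed = seed
  ), class = "model_bootstrap_summary")
}

#' @export
print.model_bootstrap_summary <- function(x, ...) {
  cat(sprintf(
    "<model_bootstrap_summary> %s%s on '%s': train q50=%.3f test q50=%.3f (%d/%d)\n",
    x$spec$family,
    if (x$spec$family != "logistic") sprintf("(k=%d)", x$spec$n_components) else "",
    x$stratum, x$train_quantiles["q50"], x$test_quantiles["q50"],
    x$n_valid, x$B))
  invisible(x)
}

#' Choose the number of components by minimizing bootstrap overfit
#'
#' For each candidate `k`, runs [bootstrap_model_auc()] (with the same seed,
#' so replicate draws are paired across candidates) and measures overfit as
#' the absolute difference between the average training and average test
#' AUC.  Returns the `k` with the smallest gap; ties break toward smaller
#' `k`.
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param family `"pcr"` or `"pls"`.
#' @param k_range integer vector of candidate component counts.
#' @param B replicates per candidate.
#' @param seed integer seed.
#' @return The selected `k`, with attribute `gaps` (named numeric vector).
#' @export
select_components <- function(X, y, family = c("pcr", "pls"), k_range,
                              B = 200L, seed) {
  family <- match.arg(family)
  if (length(k_range) == 0L) stop("empty k_range", call. = FALSE)
  k_range <- sort(unique(as.integer(k_range)))
  gaps <- vapply(k_range, function(k) {
    s <- bootstrap_model_auc(X, y, model_spec(family, n_components = k),
                             B = B, seed = seed)
    abs(mean(s$replicates$train) - mean(s$replicates$test))
  }, numeric(1L))
  names(gaps) <- k_range
  structure(k_range[which.min(gaps)], gaps = gaps)
}

#' Assemble a train/test consistency grid
#'
#' Takes long-format cells — one row per (model, quantile, stratum) with
#' `train` and `test` AUCs — and computes `difference = train - test`, the
#' mean absolute difference per (model, quantile) across strata, and the
#' overall mean absolute difference per model across all
#' (quantile x stratum) cells.  Smaller values mean a more consistent
#' (less overfit) model.
#'
#' @param cells data.frame with columns `model`, `quantile`, `stratum`,
#'   `train`, `test`, and optionally a pre-computed `difference` (used as-is
#'   when present, e.g. printed values).
#' @return An object of class `consistency_table`: `cells` (with
#'   `difference`), `mad_quantile` (model, quantile, mad) and `mad_all`
#'   (model, mad).
#' @export
consistency_table <- function(cells) {
  req <- c("model", "quantile", "stratum", "train", "test")
  stopifnot(is.data.frame(cells), all(req %in% names(cells)))
  counts <- table(cells$model, cells$stratum)
  if (length(unique(counts)) > 1L) {
    stop("models do not cover identical strata", call. = FALSE)
  }
  cells <- cells[order(cells$model, cells$quantile, cells$stratum), ]
  if (!"difference" %in% names(cells)) {
    cells$difference <- cells$train - cells$test
  }
  mad_quantile <- stats::aggregate(
    list(mad = abs(cells$difference)),
    by = list(model = cells$model, quantile = cells$quantile), FUN = mean)
  mad_all <- stats::aggregate(
    list(mad = abs(cells$difference)), by = list(model = cells$model),
    FUN = mean)
  structure(list(cells = cells, mad_quantile = mad_quantile,
                 mad_all = mad_all),
            class = "consistency_table")
}

#' @export
print.consistency_table <- function(x, ...) {
  cat("<consistency_table>\n per-model overall mean absolute difference:\n")
  print(x$mad_all, row.names = FALSE)
  invisible(x)
}

#' Long-format cells of the packaged consistency grid
#'
#' Reshapes the wide printed grid (`load_fixture("table3")`) into the
#' long format [consistency_table()] consumes, keeping the printed
#' `difference` values.
#'
#' @param models optional subset of model labels (`"pls"`, `"pcr"`,
#'   `"log"`, `"sum_pls"`, `"sum_pcr"`, `"sum_log"`).
#' @return data.frame with columns model, quantile, stratum, train, test,
#'   difference.
#' @export
table3_cells <- function(models = NULL) {
  t3 <- load_fixture("table3")
  strata <- c("all", "age_gt50", "males", "males_age_gt50",
              "age_gt50_bmi_ge30", "age_gt50_bmi_lt30")
  out <- do.call(rbind, lapply(strata, function(s) {
    data.frame(model = t3$model, quantile = t3$quantile, stratum = s,
               train = t3[[paste0(s, "_train")]],
               test = t3[[paste0(s, "_test")]],
               difference = t3[[paste0(s, "_diff")]],
               stringsAsFactors = FALSE)
  }))
  if (!is.null(models)) out <- out[out$model %in% models, ]
  rownames(out) <- NULL
  out
}

#' Set algebra over named metabolite signatures
#'
#' @param signatures named list of character vectors (or `signature`
#'   objects) sharing the canonical name space.
#' @return An object of class `signature_comparison`: the input `sets`,
#'   their `union` and `intersection`, pairwise differences, and — for 2 or
#'   3 sets — exclusive `venn_regions` counts.
#' @export
signature_set_ops <- function(signatures) {
  stopifnot(is.list(signatures), length(signatures) >= 1L,
            !is.null(names(signatures)))
  sets <- lapply(signatures, function(s) {
    if (inherits(s, "signature")) s <- signature_metabolites(s)
    sort(unique(as.character(s)))
  })
  nm <- names(sets)
  uni <- sort(Reduce(union, sets))
  inter <- sort(Reduce(intersect, sets))
  diffs <- list()
  for (a in nm) for (b in nm) if (a != b) {
    diffs[[paste0(a, " \\ ", b)]] <- setdiff(sets[[a]], sets[[b]])
  }
  venn <- NULL
  if (length(sets) %in% c(2L, 3L)) {
    membership <- vapply(sets, function(s) uni %in% s, logical(length(uni)))
    membership <- matrix(membership, nrow = length(uni),
                         dimnames = list(NULL, nm))
    key <- apply(membership, 1L, function(r) paste(nm[r], collapse = "&"))
    venn <- table(factor(key))
  }
  structure(list(sets = sets, union = uni, intersection = inter,
                 differences = diffs, venn_regions = venn),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("<signature_comparison> %d sets; |union|=%d |intersection|=%d\n",
              length(x$sets), length(x$union), length(x$intersection)))
  if (!is.null(x$venn_regions)) {
    cat(" exclusive regions:\n"); print(x$venn_regions)
  }
  invisible(x)
}

#' Vertically averaged bootstrap ROC band
#'
#' Averages replicate ROC curves over a false-positive-rate grid (for each
#' replicate, the TPR attained at each grid FPR) and adds 2.5%/97.5%
#' envelopes — the construction behind train/test ROC plots with confidence
#' bands.  Requires a summary computed with `keep_scores = TRUE`.
#'
#' @param summary a `model_bootstrap_summary` with retained scores.
#' @param grid increasing FPR grid in `[0, 1]`.
#' @param which `"test"` (out-of-bag, default) or `"train"` curves.
#' @return data.frame with columns `fpr`, `tpr_mean`, `tpr_lo`, `tpr_hi`.
#' @export
roc_band_export <- function(summary, grid = seq(0, 1, by = 0.02),
                            which = c("test", "train")) {
  stopifnot(inherits(summary, "model_bootstrap_summary"))
  which <- match.arg(which)
  if (is.null(summary$scores)) {
    stop("summary was computed without keep_scores = TRUE", call. = FALSE)
  }
  if (any(grid < 0 | grid > 1)) stop("grid outside [0, 1]", call. = FALSE)
  grid <- sort(grid)
  tprs <- vapply(summary$scores, function(sc) {
    s <- sc[[which]]
    l <- sc[[paste0(which, "_labels")]]
    roc_tpr_at_fpr(s, l, grid)
  }, numeric(length(grid)))
  tprs <- matrix(tprs, nrow = length(grid))
  data.frame(
    fpr = grid,
    tpr_mean = rowMeans(tprs),
    tpr_lo = apply(tprs, 1L, function(v) boot_quantiles(v, 0.025)),
    tpr_hi = apply(tprs, 1L, function(v) boot_quantiles(v, 0.975))
  )
}

# Empirical ROC evaluated on a FPR grid by linear interpolation between the
# curve's vertices (the standard vertical-averaging convention; a raw step
# function would bias the average near the grid ends at test-set sizes in
# the tens).
roc_tpr_at_fpr <- function(scores, labels, grid) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  # collapse score ties: cumulative counts at distinct thresholds
  s <- scores[ord]
  last <- c(s[-1] != s[-length(s)], TRUE)
  tpr <- c(0, cumsum(y == 1L)[last] / n1)
  fpr <- c(0, cumsum(y == 0L)[last] / n0)
  stats::approx(fpr, tpr, xout = grid, ties = max)$y
}
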