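#' Specify a classification model
#'
#' Three families are compared: plain multivariate logistic regression
#' (`"logistic"`), principal component regression (`"pcr"`: unsupervised
#' principal-component scores of the standardized features fed to logistic
#' regression) and partial least squares (`"pls"`: supervised
#' covariance-maximizing components fed to logistic regression).
#'
#' @param family `"logistic"`, `"pcr"` or `"pls"`.
#' @param n_components number of components (ignored for `"logistic"`).
#' @param inputs `"signature"` (the stratum's selected metabolites) or
#'   `"aggregate"` (per-class concentration sums); informational label.
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("logistic", "pcr", "pls"),
                       n_components = 1L, inputs = c("signature", "aggregate")) {
  family <- match.arg(family)
  inputs <- match.arg(inputs)
  stopifnot(n_components >= 1L)
  structure(list(family = family, n_components = as.integer(n_components),
                 inputs = inputs), class = "model_spec")
}

#' Fit an unpenalized logistic regression classifier
#'
#' Maximum likelihood via iteratively reweighted least squares
#' (`stats::glm.fit`, binomial logit link), iteration cap 100, deviance
#' tolerance 1e-8.  Zero-variance columns are dropped with a warning.
#' Complete separation is not an error: the fit is flagged and the diverged
#' direction's scores are still returned — their ranking (hence the AUC) is
#' well-defined.
#'
#' @param X numeric matrix, participants x features.
#' @param y binary labels (1 = case).
#' @return An object of class `metabosig_model`.
#' @export
fit_logistic <- function(X, y) {
  X <- as.matrix(X)
  y <- as_binary_labels(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) < 2L) stop("single-class y", call. = FALSE)
  keep <- apply(X, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L) stop("no non-constant features", call. = FALSE)
  sep <- FALSE
  noconv <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                   family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg)) sep <<- TRUE
      if (grepl("did not converge", msg)) noconv <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  # glm.fit's boundary warning misses separation reached smoothly within the
  # iteration cap; detect it from the fitted direction: training scores that
  # rank the classes perfectly together with a diverged coefficient scale
  lp <- drop(cbind(1, X) %*% fit$coefficients)
  ranked_apart <- min(lp[y == 1L]) > max(lp[y == 0L])
  new_metabosig_model(
    family = "logistic", k = ncol(X), feature_names = colnames(X),
    center = rep(0, ncol(X)), scale = rep(1, ncol(X)), projection = NULL,
    coef = fit$coefficients, converged = fit$converged && !noconv,
    separation_flag = sep || !fit$converged ||
      (ranked_apart && max(abs(fit$coefficients[-1L])) > 15)
  )
}

#' Fit a principal component regression classifier
#'
#' Features are centered and scaled to unit variance; principal axes come
#' from the singular value decomposition of the standardized matrix with a
#' deterministic sign convention (the largest-magnitude loading of each axis
#' is positive); the first `k` component scores are fed to
#' [fit_logistic()].
#'
#' @param X numeric matrix, participants x features.
#' @param y binary labels.
#' @param k number of components, at most the rank of the standardized
#'   matrix.
#' @return A `metabosig_model`.
#' @export
fit_pcr <- function(X, y, k = 1L) {
  std <- standardize(X)
  sv <- svd(std$Z)
  rank <- sum(sv$d > max(dim(std$Z)) * .Machine$double.eps * sv$d[1L])
  if (k > rank) {
    stop("k = ", k, " exceeds rank ", rank, " of the standardized matrix",
         call. = FALSE)
  }
  V <- fix_signs(sv$v[, seq_len(k), drop = FALSE])
  scores <- std$Z %*% V
  colnames(scores) <- paste0("PC", seq_len(k))
  inner <- fit_logistic(scores, y)
  new_metabosig_model(
    family = "pcr", k = k, feature_names = colnames(std$Z),
    center = std$center, scale = std$scale, projection = V,
    coef = inner$coef, converged = inner$converged,
    separation_flag = inner$separation_flag
  )
}

#' Fit a partial least squares (PLS1) logistic classifier
#'
#' Univariate-response NIPALS: features standardized, labels centered
#' (0/1 coding); each component's weight vector is the normalized
#' covariance between the deflated feature matrix and the response (so the
#' first weight vector is proportional to the per-feature correlations with
#' the outcome), with feature-matrix deflation between components and no
#' randomness.  The first `k` scores are fed to [fit_logistic()].  If a
#' deflation step leaves zero covariance, extraction stops early with fewer
#' components and the model is flagged.
#'
#' @inheritParams fit_pcr
#' @return A `metabosig_model` (element `k` may be smaller than requested).
#' @export
fit_pls <- function(X, y, k = 1L) {
  std <- standardize(X)
  yv <- as_binary_labels(y)
  Zd <- std$Z
  yc <- yv - mean(yv)
  p <- ncol(Zd)
  if (k > min(p, nrow(Zd) - 1L)) stop("k exceeds dimension bounds", call. = FALSE)
  W <- P <- matrix(0, p, 0)
  Tm <- matrix(0, nrow(Zd), 0)
  early <- FALSE
  for (comp in seq_len(k)) {
    wv <- drop(crossprod(Zd, yc))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) { early <- TRUE; break }
    wv <- wv / nw
    tv <- drop(Zd %*% wv)
    tt <- sum(tv^2)
    pv <- drop(crossprod(Zd, tv)) / tt
    Zd <- Zd - tcrossprod(tv, pv)
    yc <- yc - tv * sum(tv * yc) / tt
    W <- cbind(W, wv); P <- cbind(P, pv); Tm <- cbind(Tm, tv)
  }
  k_eff <- ncol(W)
  if (k_eff == 0L) stop("no covariance between features and labels", call. = FALSE)
  # rotation mapping standardized X directly to scores: T = Z W (P'W)^-1
  R <- W %*% solve(crossprod(P, W))
  colnames(Tm) <- paste0("LV", seq_len(k_eff))
  inner <- fit_logistic(Tm, yv)
  new_metabosig_model(
    family = "pls", k = k_eff, feature_names = colnames(std$Z),
    center = std$center, scale = std$scale, projection = R,
    coef = inner$coef, converged = inner$converged,
    separation_flag = inner$separation_flag || early
  )
}

#' Fit a model given its specification
#' @param X feature matrix.
#' @param y binary labels.
#' @param spec a [model_spec()].
#' @return A `metabosig_model`.
#' @export
fit_model <- function(X, y, spec) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$family,
         logistic = fit_logistic(X, y),
         pcr = fit_pcr(X, y, spec$n_components),
         pls = fit_pls(X, y, spec$n_components))
}

new_metabosig_model <- function(family, k, feature_names, center, scale,
                                projection, coef, converged, separation_flag) {
  structure(list(family = family, k = k, feature_names = feature_names,
                 center = center, scale = scale, projection = projection,
                 coef = coef, converged = converged,
                 separation_flag = separation_flag),
            class = "metabosig_model")
}

#' Score new participants with a fitted model
#'
#' Scoring always reuses the training standardization (stored centers and
#' scales) and projection; test-set statistics are never recomputed.
#'
#' @param object a `metabosig_model`.
#' @param newdata numeric matrix containing at least the model's feature
#'   columns.
#' @param ... unused.
#' @return Numeric vector of linear-predictor scores (monotone in the fitted
#'   case probability).
#' @export
predict.metabosig_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata))) {
    missing_f <- setdiff(object$feature_names, colnames(newdata))
    if (length(missing_f) > 0L) {
      stop("newdata lacks feature(s): ", paste(missing_f, collapse = ", "),
           call. = FALSE)
    }
    newdata <- newdata[, object$feature_names, drop = FALSE]
  } else if (ncol(newdata) != length(object$feature_names)) {
    stop("newdata has wrong number of columns", call. = FALSE)
  }
  Z <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, `/`)
  S <- if (is.null(object$projection)) Z else Z %*% object$projection
  drop(object$coef[1L] + S %*% object$coef[-1L])
}

#' @export
print.metabosig_model <- function(x, ...) {
  cat(sprintf("<metabosig_model> %s (k=%d, %d features)%s\n",
              x$family, x$k, length(x$feature_names),
              if (x$separation_flag) " [separation]" else ""))
  invisible(x)
}

standardize <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  if (any(scl == 0)) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[scl == 0], collapse = ", "), call. = FALSE)
  }
  list(Z = sweep(sweep(X, 2L, ctr), 2L, scl, `/`), center = ctr, scale = scl)
}

# Deterministic sign convention for loading vectors: the largest-magnitude
# entry of each axis is positive.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' Aggregate concentrations by lipid class
#'
#' Per participant, raw concentrations are summed within each lipid class
#' over the whole measured panel (not only signature members), then
#' log(x+1)-transformed — the same order as for individual metabolites.
#' Classes with no panel member are omitted with a warning.
#'
#' @param cohort a `cohort` on the raw concentration scale.
#' @return Numeric matrix with columns among `sum_lysoPC`, `sum_PCaa`,
#'   `sum_PCae`.
#' @export
aggregate_by_class <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (isTRUE(attr(cohort, "log_transformed"))) {
    stop("aggregate_by_class expects raw-scale concentrations", call. = FALSE)
  }
  info <- classify_metabolite_name(metabolites(cohort))
  x <- cohort_matrix(cohort)
  cols <- list()
  for (cl in c("lysoPC", "PCaa", "PCae")) {
    members <- info$name[info$lipid_class == cl]
    if (length(members) == 0L) {
      warning("no panel metabolites of class ", cl, "; column omitted",
              call. = FALSE)
      next
    }
    cols[[paste0("sum_", cl)]] <- log1p(rowSums(x[, members, drop = FALSE]))
  }
  out <- do.call(cbind, cols)
  rownames(out) <- cohort$subject_id
  out
}
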