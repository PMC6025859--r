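#' Area under the ROC curve (Mann-Whitney probability)
#'
#' Computed as the Mann-Whitney U statistic with midrank tie handling:
#' the probability that a random case scores above a random control, with
#' ties counted half.  Equals the trapezoidal area under the empirical ROC
#' curve.
#'
#' @param scores numeric vector of classifier scores (higher = more
#'   case-like).
#' @param labels binary vector (0 = control, 1 = case), or a factor whose
#'   second level is the case.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(1, 2, 3, 4), c(0, 0, 1, 1))  # 1
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) return(as.integer(labels == levels(labels)[2L]))
  if (is.logical(labels)) return(as.integer(labels))
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 (or a two-level factor)", call. = FALSE)
  }
  y
}

# Univariate logistic regression by Newton-Raphson; returns c(intercept,
# slope).  Used inside the bootstrap where ~10^5 fits occur: only the fitted
# linear predictor is consumed (its order decides the AUC), so divergence
# under complete separation is benign — iterations are capped and the
# direction is already correct.
logistic_uni <- function(x, y, maxit = 50L, tol = 1e-8) {
  b0 <- 0; b1 <- 0
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- b0 + b1 * x
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    g0 <- sum(y - p); g1 <- sum((y - p) * x)
    h00 <- sum(w); h01 <- sum(w * x); h11 <- sum(w * x^2)
    det <- h00 * h11 - h01^2
    if (!is.finite(det) || det < 1e-12) break
    b0 <- b0 + (h11 * g0 - h01 * g1) / det
    b1 <- b1 + (h00 * g1 - h01 * g0) / det
    dev <- -2 * sum(y * log(pmax(p, 1e-12)) +
                      (1 - y) * log(pmax(1 - p, 1e-12)))
    if (abs(dev_old - dev) < tol) break
    dev_old <- dev
  }
  c(b0, b1)
}
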