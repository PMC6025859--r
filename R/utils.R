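# Shared numerical helpers.

# One fixed quantile estimator everywhere selection or reporting touches a
# bootstrap distribution: linear interpolation of order statistics
# (stats::quantile type 7).  Selection is threshold-sensitive, so the
# estimator must not drift between call sites.
boot_quantiles <- function(x, probs = c(0.025, 0.5, 0.975)) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

#' Derive a reproducible child seed from a master seed and string labels
#'
#' Bootstrap stages seed their RNG per (stratum, metabolite) or per
#' (stratum, model) so results do not depend on the order in which panels or
#' model lists are traversed.  A small multiplicative string hash folds the
#' labels into the master seed; the result stays below 2^31.
#'
#' @param master integer master seed.
#' @param ... character labels identifying the unit of work.
#' @return integer seed in `[1, 2147483628]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L)
  mod <- 2147483629  # prime < 2^31
  h <- as.double(master) %% mod
  for (lab in as.character(c(...))) {
    for (ci in utf8ToInt(lab)) h <- (h * 131 + ci) %% mod
  }
  as.integer(h %% (mod - 2) + 1)
}

# Inverse-CDF draw from a normal truncated to (lower, upper).
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}
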