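test_that("separable data flags separation but still ranks perfectly", {
  y <- rep(c(0, 1), each = 10)
  X <- matrix(y + rnorm(20, sd = 1e-6), ncol = 1,
              dimnames = list(NULL, "x1"))
  m <- fit_logistic(X, y)
  expect_true(m$separation_flag)
  expect_equal(auc(predict(m, X), y), 1)
})

test_that("logistic coefficients recover the generating model within 3 SE", {
  set.seed(29)
  n <- 200
  X <- cbind(a = rnorm(n), b = rnorm(n))
  beta_true <- c(-0.3, 0.9, -0.6)
  y <- rbinom(n, 1, plogis(beta_true[1] + X %*% beta_true[-1]))
  m <- fit_logistic(X, y)
  ref <- stats::glm(y ~ X, family = binomial())
  se <- sqrt(diag(stats::vcov(ref)))
  expect_true(all(abs(m$coef - beta_true) < 3 * se))
  # same ML optimum as the formula interface
  expect_equal(unname(m$coef), unname(coef(ref)), tolerance = 1e-6)
})

test_that("feature order does not change predictions", {
  set.seed(31)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  perm <- c(3, 1, 4, 2)
  for (fit in list(fit_logistic, function(X, y) fit_pcr(X, y, 2),
                   function(X, y) fit_pls(X, y, 2))) {
    m1 <- fit(X, y)
    m2 <- fit(X[, perm], y)
    expect_equal(predict(m1, X), predict(m2, X[, perm]), tolerance = 1e-8)
  }
})

test_that("full-rank PCR ranks identically to plain logistic on standardized data", {
  set.seed(37)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, plogis(X[, 1] - X[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  m_pcr <- fit_pcr(X, y, k = 4)
  m_log <- fit_logistic(scale(X), y)
  expect_equal(auc(predict(m_pcr, X), y), auc(predict(m_log, scale(X)), y),
               tolerance = 1e-8)
})

test_that("single-feature components reduce to the univariate AUC", {
  set.seed(41)
  x <- matrix(rnorm(80), ncol = 1, dimnames = list(NULL, "m"))
  y <- rbinom(80, 1, plogis(1.2 * x))
  a_uni <- auc(x[, 1], y)
  a_pcr <- auc(predict(fit_pcr(x, y, 1), x), y)
  a_pls <- auc(predict(fit_pls(x, y, 1), x), y)
  expect_true(isTRUE(all.equal(a_pcr, a_uni)) ||
                isTRUE(all.equal(a_pcr, 1 - a_uni)))
  expect_equal(a_pls, a_uni)
})

test_that("axis sign conventions do not affect the AUC", {
  set.seed(43)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, plogis(rowSums(X[, 1:2])))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  a1 <- auc(predict(fit_pcr(X, y, 1), X), y)
  a2 <- auc(predict(fit_pcr(-X, y, 1), -X), y)
  expect_equal(a1, a2, tolerance = 1e-8)
})

test_that("first PLS weight vector is proportional to the feature-label correlations", {
  set.seed(47)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, letters[1:5]))
  y <- rbinom(60, 1, plogis(X[, 1] + 0.5 * X[, 3]))
  m <- fit_pls(X, y, 1)
  w <- m$projection[, 1]
  r <- apply(X, 2, function(col) cor(col, y))
  expect_equal(w / sqrt(sum(w^2)), r / sqrt(sum(r^2)), tolerance = 1e-8)
})

test_that("one supervised PLS component competes with the best single feature", {
  set.seed(53)
  hits <- 0L
  for (s in 1:10) {
    n <- 100; p <- 6
    latent <- rnorm(n)
    X <- sapply(1:p, function(j) latent * 0.7 + rnorm(n) * 0.7)
    colnames(X) <- paste0("m", 1:p)
    y <- rbinom(n, 1, plogis(latent))
    if (length(unique(y)) < 2) next
    a_pls <- auc(predict(fit_pls(X, y, 1), X), y)
    best_single <- max(sapply(1:p, function(j) max(auc(X[, j], y),
                                                   1 - auc(X[, j], y))))
    if (a_pls >= best_single - 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("scoring reuses training standardization on shifted test data", {
  set.seed(59)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, letters[1:4]))
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  m <- fit_pcr(X, y, 2)
  shift <- c(10, -5, 2, 0)
  Xs <- sweep(X, 2L, shift, `+`)
  # expected score change from stored center/scale and projection
  delta <- drop((shift / m$scale) %*% m$projection %*% m$coef[-1])
  expect_equal(predict(m, Xs) - predict(m, X), rep(delta, 50),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("class aggregates sum raw concentrations then log-transform", {
  df <- tiny_cohort_df(3L, metab = c("PCaaC32:3", "PCaaC36:0", "PCaeC38:0"))
  df[["PCaaC32:3"]] <- c(1, 5, 0)
  df[["PCaaC36:0"]] <- c(2, 5, 0)
  df[["PCaeC38:0"]] <- c(7, 1, 2)
  ch <- as_cohort(df)
  expect_warning(agg <- aggregate_by_class(ch), "lysoPC")
  expect_equal(unname(agg[, "sum_PCaa"]), log1p(c(3, 10, 0)))
  expect_equal(unname(agg[, "sum_PCae"]), log1p(c(7, 1, 2)))
  expect_false("sum_lysoPC" %in% colnames(agg))
  # commutes with participant reordering
  ch_rev <- as_cohort(df[3:1, ])
  expect_warning(agg_rev <- aggregate_by_class(ch_rev), "lysoPC")
  expect_equal(agg_rev, agg[3:1, ])
})
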