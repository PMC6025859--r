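test_that("null PCR is honest: chance-level test AUC, mild optimism", {
  set.seed(61)
  X <- matrix(rnorm(500), 100, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- rep(c(0, 1), each = 50)
  s <- bootstrap_model_auc(X, y, model_spec("pcr", 1), B = 300, seed = 67)
  expect_equal(unname(s$test_quantiles["q50"]), 0.5, tolerance = 0.05)
  expect_gt(unname(s$train_quantiles["q50"]), unname(s$test_quantiles["q50"]))
  s2 <- bootstrap_model_auc(X, y, model_spec("pcr", 1), B = 300, seed = 67)
  expect_identical(s$replicates, s2$replicates)
})

test_that("component selection prefers the single dominant direction", {
  expect_error(select_components(matrix(1:10), 1:10, "pcr", integer(0), seed = 1),
               "empty")
  set.seed(71)
  X1 <- matrix(rnorm(60), ncol = 1, dimnames = list(NULL, "m"))
  y1 <- rbinom(60, 1, plogis(X1)); y1[1:2] <- c(0, 1)
  expect_equal(as.integer(select_components(X1, y1, "pcr", 1L, B = 100,
                                            seed = 3)), 1L)
  hits <- 0L
  for (s in 1:10) {
    n <- 80; p <- 10
    latent <- rnorm(n)
    X <- sapply(1:p, function(j) 0.8 * latent + 0.6 * rnorm(n))
    colnames(X) <- paste0("m", 1:p)
    y <- rbinom(n, 1, plogis(1.5 * latent))
    if (length(unique(y)) < 2) next
    k <- select_components(X, y, "pcr", 1:3, B = 100, seed = 100 + s)
    if (as.integer(k) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})

test_that("on noise, increasing components only adds overfit (tie-break at k=1)", {
  set.seed(73)
  hits <- 0L
  for (s in 1:5) {
    X <- matrix(rnorm(80 * 8), 80, 8, dimnames = list(NULL, paste0("m", 1:8)))
    y <- rep(c(0, 1), each = 40)
    k <- select_components(X, y, "pcr", 1:5, B = 100, seed = 200 + s)
    if (as.integer(k) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})

test_that("the printed consistency grid reproduces its own arithmetic", {
  cells <- table3_cells()
  # printed difference equals printed train - test (rounding-boundary cells
  # may differ by one unit in the third decimal)
  expect_true(all(abs(cells$difference - (cells$train - cells$test))
                  <= 0.001 + 1e-9))
  # recomputed mean absolute differences match the printed mad columns
  ct <- consistency_table(cells)
  t3 <- load_fixture("table3")
  printed_q <- t3[c("model", "quantile", "mad_quantile")]
  merged <- merge(ct$mad_quantile, printed_q, by = c("model", "quantile"))
  expect_true(all(abs(merged$mad - merged$mad_quantile) <= 0.001 + 1e-9))
  printed_all <- t3[!is.na(t3$mad_all), c("model", "mad_all")]
  merged_all <- merge(ct$mad_all, printed_all, by = "model")
  expect_true(all(abs(merged_all$mad - merged_all$mad_all) <= 0.001 + 1e-9))
})

test_that("recomputed consistency ranks the families pcr < pls < log", {
  ct <- consistency_table(table3_cells(c("pcr", "pls", "log")))
  mad <- setNames(ct$mad_all$mad, ct$mad_all$model)
  expect_lt(mad["pcr"], mad["pls"])
  expect_lt(mad["pls"], mad["log"])
})

test_that("a family with train == test collapses to zero everywhere", {
  cells <- data.frame(model = "x", quantile = rep(c(0.025, 0.5, 0.975), 2),
                      stratum = rep(c("a", "b"), each = 3),
                      train = runif(6, 0.6, 0.8))
  cells$test <- cells$train
  ct <- consistency_table(cells)
  expect_true(all(ct$cells$difference == 0))
  expect_true(all(ct$mad_quantile$mad == 0))
  expect_true(all(ct$mad_all$mad == 0))
})

test_that("mismatched strata across models are rejected", {
  cells <- data.frame(model = c("a", "a", "b"), quantile = 0.5,
                      stratum = c("s1", "s2", "s1"),
                      train = 0.7, test = 0.6)
  expect_error(consistency_table(cells), "identical strata")
})

test_that("signature set algebra matches the printed stratum overlaps", {
  sigs <- list(
    bmi_hi = fixture_signature("age_gt50_bmi_ge30"),
    bmi_lo = fixture_signature("age_gt50_bmi_lt30"),
    males50 = fixture_signature("males_age_gt50")
  )
  cmp <- signature_set_ops(sigs)
  not_in_males <- setdiff(union(cmp$sets$bmi_hi, cmp$sets$bmi_lo),
                          cmp$sets$males50)
  expect_setequal(not_in_males, c("lysoPCaC16:0", "PCaeC38:3"))
  # the single older-female metabolite sits inside the older-male signature
  fem <- fixture_signature("females_age_gt50")
  expect_equal(fem, "PCaaC32:3")
  expect_true(fem %in% cmp$sets$males50)
  # identities
  cmp2 <- signature_set_ops(list(a = fem, b = fem))
  expect_equal(cmp2$differences[["a \\ b"]], character(0))
  a <- cmp$sets$bmi_hi; b <- cmp$sets$bmi_lo
  expect_equal(length(union(a, b)),
               length(a) + length(b) - length(intersect(a, b)))
  # venn regions partition the union
  expect_equal(sum(cmp$venn_regions), length(cmp$union))
})

test_that("ROC bands: perfect classifiers give the unit step with zero width", {
  x <- c(rnorm(40, 0, 0.05), rnorm(40, 5, 0.05))
  y <- rep(c(0, 1), each = 40)
  s <- bootstrap_model_auc(matrix(x, dimnames = list(NULL, "m")), y,
                           model_spec("logistic"), B = 50, seed = 79,
                           keep_scores = TRUE)
  band <- roc_band_export(s, grid = c(0, 0.5, 1))
  expect_equal(band$tpr_mean, c(1, 1, 1))
  expect_equal(band$tpr_hi - band$tpr_lo, c(0, 0, 0))
  expect_error(roc_band_export(s, grid = c(-0.1, 0.5)), "grid")
})

test_that("ROC bands: null classifiers hug the diagonal and integrate to the AUC", {
  # a genuinely null classifier: replicate scores independent of the labels
  # (refitting a model on resamples of one finite cohort is *not* null —
  # the fit aligns with that cohort's accidental direction)
  set.seed(83)
  grid <- seq(0, 1, 0.05)
  null_summary <- local({
    reps <- lapply(1:500, function(b) {
      y <- rep(c(0L, 1L), each = 50)
      list(train = rnorm(100), train_labels = y,
           test = rnorm(100), test_labels = y)
    })
    aucs <- vapply(reps, function(r) auc(r$test, r$test_labels), numeric(1))
    structure(list(stratum = "null", spec = model_spec("logistic"),
                   train_quantiles = c(q025 = 0.4, q50 = 0.5, q975 = 0.6),
                   test_quantiles = c(q025 = unname(quantile(aucs, 0.025)),
                                      q50 = unname(quantile(aucs, 0.5)),
                                      q975 = unname(quantile(aucs, 0.975))),
                   replicates = data.frame(train = aucs, test = aucs),
                   scores = reps, n_valid = 500L, n_discarded = 0L,
                   B = 500L, seed = 83),
              class = "model_bootstrap_summary")
  })
  band <- roc_band_export(null_summary, grid = grid)
  expect_lt(max(abs(band$tpr_mean - band$fpr)), 0.05)
  # internal consistency on a bootstrap-evaluated cohort: the exported mean
  # curve integrates to the summary's median test AUC
  X <- matrix(rnorm(270), dimnames = list(NULL, "m"))
  y <- rep(c(0, 1), length.out = 270)
  s <- bootstrap_model_auc(X, y, model_spec("logistic"), B = 300, seed = 89,
                           keep_scores = TRUE)
  b2 <- roc_band_export(s, grid = grid)
  area <- sum(diff(b2$fpr) * (head(b2$tpr_mean, -1) + tail(b2$tpr_mean, -1)) / 2)
  expect_equal(area, unname(s$test_quantiles["q50"]), tolerance = 0.02)
})
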