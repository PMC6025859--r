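test_that("Yates-corrected sex-ratio chi-square reproduces the printed p-values", {
  # male counts derived from the printed totals and female counts
  expect_equal(round(sex_ratio_chisq(75, 77, 84, 110), 3), 0.312)
  expect_equal(round(sex_ratio_chisq(72, 76, 50, 52), 3), 1.000)
  expect_equal(round(sex_ratio_chisq(33, 30, 52, 59), 3), 0.586)
  # proportional table: zero statistic
  expect_equal(sex_ratio_chisq(10, 10, 20, 20), 1.0)
  expect_error(sex_ratio_chisq(0, 0, 5, 5), "marginal")
  # without the correction the 'All' row p drops to ~0.263
  expect_equal(round(sex_ratio_chisq(75, 77, 84, 110, correct = FALSE), 3),
               0.263)
})

test_that("the Yates correction is conservative relative to the exact test", {
  # on all tabulated strata the corrected p bounds the Fisher exact p from
  # above while the uncorrected Pearson p bounds it from below
  t1 <- load_fixture("table1")
  rows <- t1[!is.na(t1$n_females), ]
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    tab <- matrix(c(r$n_oa - r$n_females_oa, r$n_females_oa,
                    r$n_hv - r$n_females_hv, r$n_females_hv), 2)
    p_yates <- sex_ratio_chisq(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2])
    p_plain <- sex_ratio_chisq(tab[1, 1], tab[2, 1], tab[1, 2], tab[2, 2],
                               correct = FALSE)
    p_exact <- fisher.test(tab)$p.value
    expect_gte(p_yates, p_exact - 1e-9)
    expect_lte(p_plain, p_exact + 1e-9)
  }
})

test_that("Welch test from summary moments matches the raw-data test", {
  expect_equal(welch_t_from_summary(5, 1, 30, 5, 1, 30)$p_value, 1)
  # published stratum moments give the printed significance bound
  expect_lte(welch_t_from_summary(62.9, 5.9, 89, 58.6, 6.7, 42)$p_value, 0.001)
  # oracle: construct samples with exactly these moments and run t.test
  set.seed(97)
  mk <- function(n, m, s) {
    v <- rnorm(n)
    m + s * (v - mean(v)) / sd(v)
  }
  x <- mk(25, 10.2, 2.1); y <- mk(40, 9.1, 3.3)
  ref <- t.test(x, y)
  got <- welch_t_from_summary(10.2, 2.1, 25, 9.1, 3.3, 40)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-8)
})

test_that("the demographics table of a default synthetic cohort matches the design", {
  ch <- simulate_cohort(default_study_config(103))
  demo <- demographics_table(ch)
  t1 <- load_fixture("table1")
  m <- merge(demo, t1, by = "stratum", suffixes = c("", ".printed"))
  expect_equal(nrow(m), 10L)
  expect_equal(m$n_total, m$n_total.printed)
  expect_equal(m$n_oa, m$n_oa.printed)
  expect_equal(m$n_hv, m$n_hv.printed)
  # generated group age means sit within 2 SE of the configured moments
  for (i in seq_len(nrow(m))) {
    se <- m$age_oa_sd.printed[i] / sqrt(m$n_oa[i])
    expect_lt(abs(m$age_oa_mean[i] - m$age_oa_mean.printed[i]),
              2.5 * se + 0.5)  # truncation shifts the mean slightly
  }
})

test_that("DM screening flags at the nominal rate under the null", {
  panel <- sprintf("PCaaC%d:%d", rep(30:69, each = 5), 0:4)
  cfg <- flat_sim_config(107, 1000, 1000, panel, dm_prevalence = 0.3,
                         rho_within_class = 0, n_batches = 1)
  pre <- log1p_transform(simulate_cohort(cfg))
  dists_dummy <- stratum_spec("all")
  sig <- structure(list(
    stratum = dists_dummy,
    entries = data.frame(metabolite = panel[1:5], q025 = 0.55, q50 = 0.6,
                         q975 = 0.7, n_valid = 100L),
    rule = selection_rule()), class = "signature")
  res <- dm_sensitivity(pre, sig, alpha = 0.05)
  rate <- mean(res$tests$p_value < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("an injected DM shift is flagged and removed from the signature", {
  flagged_runs <- 0L
  for (s in 1:5) {
    cfg <- flat_sim_config(300 + s, 200, 200,
                           c("PCaaC32:3", "PCaeC38:0", "lysoPCaC16:0"),
                           dm_prevalence = 0.3, rho_within_class = 0,
                           n_batches = 1,
                           dm_effects = c("PCaaC32:3" = 1))
    pre <- log1p_transform(simulate_cohort(cfg))
    sig <- structure(list(
      stratum = stratum_spec("all"),
      entries = data.frame(metabolite = c("PCaaC32:3", "PCaeC38:0"),
                           q025 = 0.55, q50 = 0.6, q975 = 0.7,
                           n_valid = 100L),
      rule = selection_rule()), class = "signature")
    res <- dm_sensitivity(pre, sig)
    if ("PCaaC32:3" %in% res$flagged$metabolite &&
        !"PCaaC32:3" %in% signature_metabolites(res$reduced)) {
      flagged_runs <- flagged_runs + 1L
    }
  }
  expect_gte(flagged_runs, 5L * 0.9)
  # untouched signatures pass through unchanged
  cfg0 <- flat_sim_config(99, 50, 50, c("PCaaC32:3", "PCaeC38:0"),
                          dm_prevalence = 0.4, n_batches = 1)
  pre0 <- log1p_transform(simulate_cohort(cfg0))
  sig0 <- structure(list(
    stratum = stratum_spec("all"),
    entries = data.frame(metabolite = character(0), q025 = numeric(0),
                         q50 = numeric(0), q975 = numeric(0),
                         n_valid = integer(0)),
    rule = selection_rule()), class = "signature")
  res0 <- dm_sensitivity(pre0, sig0)
  expect_equal(nrow(res0$flagged), 0L)
  expect_equal(nrow(res0$reduced$entries), 0L)
})
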