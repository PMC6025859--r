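# Small cohorts and matrices built in code for the unit tests.

# Minimal hand-built cohort data.frame (raw scale).
tiny_cohort_df <- function(n = 6L, metab = c("PCaaC32:3", "lysoPCaC28:1")) {
  set.seed(42)
  df <- data.frame(
    subject_id = sprintf("P%02d", seq_len(n)),
    group = rep(c("OA", "HV"), length.out = n),
    age = seq(40, 70, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    bmi = seq(22, 36, length.out = n),
    batch = rep(c("b1", "b2"), each = ceiling(n / 2))[seq_len(n)],
    dm_status = "no",
    stringsAsFactors = FALSE, check.names = FALSE
  )
  for (m in metab) df[[m]] <- round(stats::runif(n, 1, 100), 3)
  df
}

# Simulation config with a single demographic cell per group: quickest way
# to a cohort with chosen sizes and metabolite effects.
flat_sim_config <- function(seed, n_case, n_control, panel, effects = NULL,
                            ...) {
  cells <- data.frame(
    group = c("OA", "HV"), sex = "male", age_band = "gt50",
    n = c(n_case, n_control),
    n_obese = c(round(n_case / 2), round(n_control / 2)),
    age_mean = 62, age_sd = 6, stringsAsFactors = FALSE
  )
  bmi_moments <- data.frame(
    group = rep(c("OA", "HV"), each = 2), obese = c(TRUE, FALSE),
    mean = c(34, 27, 33, 26), sd = c(3, 2, 3, 2), stringsAsFactors = FALSE
  )
  simulation_config(seed = seed, cells = cells, bmi_moments = bmi_moments,
                    panel = panel, effects = effects, ...)
}

# O(n^2) pair-counting AUC oracle with half-credit ties.
auc_bruteforce <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in ctrls) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(cases) * length(ctrls))
}
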