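#' Convert a target univariate AUC to a standardized mean difference
#'
#' Under the binormal equal-variance model the AUC of a single marker equals
#' `pnorm(d / sqrt(2))` where `d` is the standardized difference between the
#' case and control means.  The simulator injects effects on the log scale at
#' `d = sqrt(2) * qnorm(auc)`, so the empirical univariate AUC of a simulated
#' metabolite converges to its configured target.
#'
#' @param auc target AUC in `[0.5, 1)`.
#' @return standardized mean difference `d >= 0`.
#' @seealso [effect_to_auc()]
#' @export
auc_to_effect <- function(auc) {
  stopifnot(is.numeric(auc), all(auc >= 0.5), all(auc < 1))
  sqrt(2) * stats::qnorm(auc)
}

#' Convert a standardized mean difference to its binormal AUC
#' @param d standardized mean difference `>= 0`.
#' @return AUC in `[0.5, 1)`.
#' @export
effect_to_auc <- function(d) {
  stopifnot(is.numeric(d), all(d >= 0))
  stats::pnorm(d / sqrt(2))
}

#' Configure a synthetic case-control cohort
#'
#' The simulator draws a cohort with the statistical structure the analysis
#' assumes: exact demographic cell counts (group x sex x age-band x obesity),
#' truncated-normal age and BMI within cells, and log-normal metabolite
#' concentrations with block-exchangeable correlation within each lipid
#' class, per-metabolite case shifts calibrated to target univariate AUCs,
#' and additive per-batch log-scale shifts.
#'
#' @param seed integer RNG seed; the same seed reproduces the same cohort.
#' @param cells data.frame of demographic cells with columns `group`
#'   (`OA`/`HV`), `sex` (`male`/`female`), `age_band` (`gt50`/`le50`), `n`,
#'   `n_obese` (participants with BMI >= 30), `age_mean`, `age_sd`.
#' @param bmi_moments data.frame with columns `group`, `obese` (logical),
#'   `mean`, `sd` giving truncated-normal BMI parameters per group and
#'   obesity status.
#' @param panel character vector of metabolite names (either dialect).
#' @param effects named numeric vector of target univariate AUCs in
#'   `[0.5, 1)` for a subset of the panel; unnamed metabolites default to
#'   0.5 (no effect).
#' @param effect_modifiers list of `list(spec = stratum_spec, multiplier =
#'   m)`: the case shift of participants matching `spec` is multiplied by
#'   `m`, e.g. to concentrate signal in older males.
#' @param rho_within_class exchangeable correlation within each lipid class,
#'   in `[0, 1)`; classes are mutually independent.
#' @param n_batches number of measurement batches (assigned near-balanced at
#'   random).
#' @param batch_sd SD of the additive per-(batch, metabolite) log-scale
#'   shift.
#' @param base_log_mean,base_log_sd baseline log-concentration location and
#'   scale, scalar or per-metabolite.
#' @param dm_prevalence probability a participant is flagged diabetic
#'   (`dm_status = "yes"`).
#' @param dm_effects named numeric vector of log-SD-scale shifts applied to
#'   diabetic participants, for sensitivity analyses.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              cells,
                              bmi_moments,
                              panel,
                              effects = NULL,
                              effect_modifiers = list(),
                              rho_within_class = 0.5,
                              n_batches = 4,
                              batch_sd = 0.2,
                              base_log_mean = 4,
                              base_log_sd = 0.4,
                              dm_prevalence = 0,
                              dm_effects = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  req <- c("group", "sex", "age_band", "n", "n_obese", "age_mean", "age_sd")
  stopifnot(is.data.frame(cells), all(req %in% names(cells)))
  if (any(cells$n < 0) || any(cells$n_obese < 0) ||
      any(cells$n_obese > cells$n)) {
    stop("infeasible demographic cell counts", call. = FALSE)
  }
  if (sum(cells$n) < 2) stop("cohort must have >= 2 participants", call. = FALSE)
  panel_info <- classify_metabolite_name(panel)
  if (anyDuplicated(panel_info$name)) {
    stop("duplicate metabolites in panel", call. = FALSE)
  }
  eff <- stats::setNames(rep(0.5, nrow(panel_info)), panel_info$name)
  if (!is.null(effects)) {
    nm <- canonical_metabolite_name(names(effects))
    if (!all(nm %in% panel_info$name)) {
      stop("effects name metabolites outside the panel", call. = FALSE)
    }
    stopifnot(all(effects >= 0.5), all(effects < 1))
    eff[nm] <- unname(effects)
  }
  stopifnot(rho_within_class >= 0, rho_within_class < 1,
            n_batches >= 1, batch_sd >= 0,
            dm_prevalence >= 0, dm_prevalence <= 1)
  structure(list(
    seed = as.integer(seed), cells = cells, bmi_moments = bmi_moments,
    panel = panel_info, effects = eff, effect_modifiers = effect_modifiers,
    rho_within_class = rho_within_class, n_batches = as.integer(n_batches),
    batch_sd = batch_sd,
    base_log_mean = rep_len(base_log_mean, nrow(panel_info)),
    base_log_sd = rep_len(base_log_sd, nrow(panel_info)),
    dm_prevalence = dm_prevalence, dm_effects = dm_effects
  ), class = "simulation_config")
}

#' Default configuration reproducing the study cohort's demographics
#'
#' The printed stratum marginals pin down the full group x sex x age-band x
#' obesity cell table exactly (346 participants: 152 OA / 194 HV, 159 male /
#' 187 female, 250 over age 50 of whom 122 are male).  Ages and BMI are
#' truncated normals with the printed per-stratum moments; the small
#' age <= 50 bands use means derived from the printed mixture moments.  The
#' default panel is the 39 tabulated lysoPC/PC metabolites with signal
#' concentrated in the older-male stratum.
#'
#' @param seed integer RNG seed.
#' @param effects named target-AUC vector; default gives the tabulated
#'   older-male signature metabolites their printed median AUC (applied to
#'   cases cohort-wide, attenuated outside the older-male stratum).
#' @param ... further overrides passed to [simulation_config()].
#' @return A `simulation_config`.
#' @export
default_study_config <- function(seed, effects = NULL, ...) {
  cells <- data.frame(
    group    = rep(c("OA", "HV"), each = 4),
    sex      = rep(c("male", "male", "female", "female"), 2),
    age_band = rep(c("gt50", "le50"), 4),
    n        = c(72, 3, 76, 1, 50, 34, 52, 58),
    n_obese  = c(42, 0, 47, 0, 19, 13, 23, 28),
    age_mean = c(64.5, 42.0, 64.3, 48.9, 59.8, 39.8, 59.9, 38.7),
    age_sd   = c(6.5, 5.0, 6.9, 5.0, 6.8, 7.0, 5.6, 7.0),
    stringsAsFactors = FALSE
  )
  bmi_moments <- data.frame(
    group = c("OA", "OA", "HV", "HV"),
    obese = c(TRUE, FALSE, TRUE, FALSE),
    mean  = c(35.0, 27.4, 33.0, 25.3),
    sd    = c(5.0, 2.4, 2.7, 3.3),
    stringsAsFactors = FALSE
  )
  t2 <- load_fixture("table2")
  panel <- t2$metabolite
  if (is.null(effects)) {
    sel <- !is.na(t2$males_age_gt50)
    effects <- stats::setNames(t2$males_age_gt50[sel], t2$metabolite[sel])
  }
  args <- list(seed = seed, cells = cells, bmi_moments = bmi_moments,
               panel = panel, effects = effects,
               effect_modifiers = list(
                 list(spec = stratum_spec("older_males", age = "gt50",
                                          sex = "male"),
                      multiplier = 1),
                 list(spec = stratum_spec("younger", age = "le50"),
                      multiplier = 0.5),
                 list(spec = stratum_spec("older_females", age = "gt50",
                                          sex = "female"),
                      multiplier = 0.6)
               ))
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

#' Simulate a case-control cohort
#'
#' Deterministic given `config$seed`.  Demographic cell counts are matched
#' exactly; ages and BMI honor their band boundaries via truncation
#' (age > 50 strictly in the `gt50` band, BMI >= 30 iff obese).
#' Log-concentrations are multivariate normal with exchangeable correlation
#' within each lipid class; case means are shifted by
#' `auc_to_effect(target) * base_log_sd` (times any matching effect
#' modifier); per-(batch, metabolite) additive shifts emulate batch effects.
#' Concentrations are returned on the natural scale via exponentiation, so
#' all values are strictly positive.
#'
#' @param config a [simulation_config()].
#' @return A `cohort` object.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  cells <- config$cells
  n <- sum(cells$n)
  demo <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ci <- cells[i, ]
    if (ci$n == 0) return(NULL)
    lo <- if (ci$age_band == "gt50") 50 else 19
    hi <- if (ci$age_band == "gt50") 90 else 50
    age <- rtruncnorm(ci$n, ci$age_mean, ci$age_sd, lo, hi)
    if (ci$age_band == "gt50") age <- pmax(age, 50 + 1e-6)
    obese <- sample(rep(c(TRUE, FALSE), c(ci$n_obese, ci$n - ci$n_obese)))
    bm <- config$bmi_moments
    bmi <- numeric(ci$n)
    for (ob in unique(obese)) {
      row <- bm[bm$group == ci$group & bm$obese == ob, ]
      if (nrow(row) != 1L) stop("missing BMI moments for cell", call. = FALSE)
      idx <- which(obese == ob)
      bmi[idx] <- if (ob) rtruncnorm(length(idx), row$mean, row$sd, 30, 65)
                  else    rtruncnorm(length(idx), row$mean, row$sd, 15, 30 - 1e-6)
    }
    data.frame(group = ci$group, sex = ci$sex, age = age, bmi = bmi,
               stringsAsFactors = FALSE)
  }))
  demo$subject_id <- sprintf("S%04d", seq_len(n))
  demo$batch <- paste0("B", rep_len(seq_len(config$n_batches), n)[sample.int(n)])
  demo$dm_status <- ifelse(stats::runif(n) < config$dm_prevalence, "yes", "no")

  p <- nrow(config$panel)
  cls <- as.character(config$panel$lipid_class)
  rho <- config$rho_within_class
  z <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    for (cl in unique(cls)) {
      j <- which(cls == cl)
      common <- stats::rnorm(n)
      z[, j] <- sqrt(rho) * common + sqrt(1 - rho) * z[, j]
    }
  }
  d <- auc_to_effect(config$effects)              # per-metabolite, sd units
  mult <- rep(1, n)
  for (mod in config$effect_modifiers) {
    keep <- stratum_mask(demo, mod$spec)
    mult[keep] <- mult[keep] * mod$multiplier
  }
  shift <- outer((demo$group == "OA") * mult, d)   # n x p, sd units
  if (!is.null(config$dm_effects)) {
    nm <- canonical_metabolite_name(names(config$dm_effects))
    jdx <- match(nm, config$panel$name)
    stopifnot(!anyNA(jdx))
    dmrow <- demo$dm_status == "yes"
    for (k in seq_along(jdx)) {
      shift[dmrow, jdx[k]] <- shift[dmrow, jdx[k]] + config$dm_effects[k]
    }
  }
  batch_shift <- matrix(stats::rnorm(config$n_batches * p, 0, config$batch_sd),
                        config$n_batches, p)
  bi <- as.integer(factor(demo$batch, levels = paste0("B", seq_len(config$n_batches))))
  logconc <- sweep(z + shift, 2, config$base_log_sd, `*`)
  logconc <- sweep(logconc, 2, config$base_log_mean, `+`)
  logconc <- logconc + batch_shift[bi, , drop = FALSE]
  conc <- exp(logconc)
  colnames(conc) <- config$panel$name

  df <- cbind(demo[c("subject_id", "group", "age", "sex", "bmi", "batch",
                     "dm_status")],
              as.data.frame(conc, check.names = FALSE))
  as_cohort(df)
}

# Row mask of a bare demographics data.frame for a stratum spec (cohort
# objects also work since they carry the same columns).
stratum_mask <- function(df, spec) {
  keep <- rep(TRUE, nrow(df))
  keep <- keep & switch(spec$age, all = TRUE, gt50 = df$age > 50,
                        le50 = df$age <= 50)
  keep <- keep & switch(spec$bmi, all = TRUE, ge30 = df$bmi >= 30,
                        lt30 = df$bmi < 30)
  keep <- keep & switch(spec$sex, all = TRUE, male = df$sex == "male",
                        female = df$sex == "female")
  keep
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
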