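#' Chi-square test of the sex ratio between cases and controls
#'
#' 2x2 chi-square with Yates continuity correction (1 df) on the male/female
#' counts of the OA and HV groups; the correction shrinks `|O - E|` by up to
#' 0.5, so perfectly (or near) proportional tables give p = 1.
#'
#' @param n_oa_male,n_oa_female,n_hv_male,n_hv_female cell counts.
#' @param correct apply the Yates correction (default `TRUE`).
#' @return Two-sided p-value.
#' @examples
#' sex_ratio_chisq(75, 77, 84, 110)  # 0.312
#' @export
sex_ratio_chisq <- function(n_oa_male, n_oa_female, n_hv_male, n_hv_female,
                            correct = TRUE) {
  counts <- c(n_oa_male, n_oa_female, n_hv_male, n_hv_female)
  stopifnot(all(counts >= 0))
  tab <- matrix(counts, nrow = 2L,
                dimnames = list(sex = c("male", "female"),
                                group = c("OA", "HV")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal: test undefined", call. = FALSE)
  }
  suppressWarnings(stats::chisq.test(tab, correct = correct))$p.value
}

#' Welch's t-test from summary moments
#'
#' Unequal-variance two-sample t with Satterthwaite degrees of freedom,
#' computed directly from group means, SDs and sizes — usable on published
#' summary rows where raw data are unavailable.
#'
#' @param mean1,sd1,n1 first group moments and size.
#' @param mean2,sd2,n2 second group moments and size.
#' @return List with `statistic`, `df`, `p_value` (two-sided).
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tstat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(statistic = tstat, df = df,
       p_value = 2 * stats::pt(-abs(tstat), df))
}

#' Demographic comparison table across the study strata
#'
#' For each stratum: participant counts by group and sex, age and BMI means
#' and SDs per group, and the OA-vs-HV comparison p-values (Yates-corrected
#' chi-square for the sex ratio, Welch t for age and BMI).
#'
#' @param cohort a `cohort`.
#' @param strata named list of [stratum_spec()]s (default [study_strata()]).
#' @return data.frame, one row per stratum.
#' @export
demographics_table <- function(cohort, strata = study_strata()) {
  rows <- lapply(strata, function(sp) {
    sub <- suppressWarnings(stratify(cohort, sp))
    oa <- sub$group == "OA"
    fem <- sub$sex == "female"
    p_sex <- tryCatch(
      sex_ratio_chisq(sum(oa & !fem), sum(oa & fem),
                      sum(!oa & !fem), sum(!oa & fem)),
      error = function(e) NA_real_)
    wt <- function(v) {
      if (sum(oa) < 2 || sum(!oa) < 2) return(NA_real_)
      stats::t.test(v[oa], v[!oa])$p.value
    }
    data.frame(
      stratum = sp$name, n_total = nrow(sub), n_oa = sum(oa),
      n_hv = sum(!oa), n_females = sum(fem),
      n_females_oa = sum(fem & oa), n_females_hv = sum(fem & !oa),
      p_sex_ratio = p_sex,
      age_oa_mean = mean(sub$age[oa]), age_oa_sd = stats::sd(sub$age[oa]),
      age_hv_mean = mean(sub$age[!oa]), age_hv_sd = stats::sd(sub$age[!oa]),
      p_age = wt(sub$age),
      bmi_oa_mean = mean(sub$bmi[oa]), bmi_oa_sd = stats::sd(sub$bmi[oa]),
      bmi_hv_mean = mean(sub$bmi[!oa]), bmi_hv_sd = stats::sd(sub$bmi[!oa]),
      p_bmi = wt(sub$bmi),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Diabetes-mellitus sensitivity screen of a signature
#'
#' Within the signature's stratum, separately inside the OA and HV groups,
#' each metabolite's (transformed) values are compared between diabetic and
#' non-diabetic participants by a two-sided Welch t-test.  Signature
#' metabolites significant at `alpha` in either group are flagged; the
#' reduced signature removes them so the classifier can be refit without
#' DM-associated features.
#'
#' @param cohort a preprocessed `cohort` with informative `dm_status`.
#' @param signature a `signature` object.
#' @param alpha flagging threshold on the unadjusted p-value.
#' @return List with `flagged` (data.frame metabolite, group, p_value),
#'   `reduced` (the signature minus flagged metabolites) and `tests`
#'   (all per-metabolite p-values).
#' @export
dm_sensitivity <- function(cohort, signature, alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort"), inherits(signature, "signature"))
  sub <- stratify(cohort, signature$stratum)
  known <- sub$dm_status %in% c("yes", "no")
  if (!any(known)) stop("no participants with known dm_status", call. = FALSE)
  sub <- cohort_like(as.data.frame(sub)[known, , drop = FALSE], sub)
  x <- cohort_matrix(sub)
  tests <- list()
  for (grp in c("OA", "HV")) {
    rows <- sub$group == grp
    dm <- sub$dm_status[rows] == "yes"
    if (sum(dm) < 2L || sum(!dm) < 2L) {
      warning("group ", grp, " lacks >= 2 participants per DM status; skipped",
              call. = FALSE)
      next
    }
    for (m in metabolites(sub)) {
      v <- x[rows, m]
      p <- tryCatch(stats::t.test(v[dm], v[!dm])$p.value,
                    error = function(e) NA_real_)
      tests[[length(tests) + 1L]] <-
        data.frame(metabolite = m, group = grp, p_value = p,
                   stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, tests)
  sig_mets <- signature_metabolites(signature)
  flagged <- tests[!is.na(tests$p_value) & tests$p_value < alpha &
                     tests$metabolite %in% sig_mets, , drop = FALSE]
  reduced <- signature
  reduced$entries <- signature$entries[
    !signature$entries$metabolite %in% flagged$metabolite, , drop = FALSE]
  list(flagged = flagged, reduced = reduced, tests = tests)
}
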