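#' Define a demographic stratum
#'
#' Strata are conjunctions of up to three rules: age (`all`, `gt50` for
#' strictly > 50 years, `le50` for <= 50), BMI (`all`, `ge30` for >= 30
#' kg/m2 — the WHO obesity threshold — inclusive, `lt30` for < 30) and sex
#' (`all`, `male`, `female`).  Boundary semantics follow the study design:
#' age 50 belongs to the `le50` stratum, BMI 30.0 to the `ge30` stratum.
#'
#' @param name stratum label.
#' @param age one of `"all"`, `"gt50"`, `"le50"`.
#' @param bmi one of `"all"`, `"ge30"`, `"lt30"`.
#' @param sex one of `"all"`, `"male"`, `"female"`.
#' @return An object of class `stratum_spec`.
#' @export
stratum_spec <- function(name, age = "all", bmi = "all", sex = "all") {
  age <- match.arg(age, c("all", "gt50", "le50"))
  bmi <- match.arg(bmi, c("all", "ge30", "lt30"))
  sex <- match.arg(sex, c("all", "male", "female"))
  structure(list(name = name, age = age, bmi = bmi, sex = sex),
            class = "stratum_spec")
}

#' @export
print.stratum_spec <- function(x, ...) {
  cat(sprintf("<stratum> %s (age=%s, bmi=%s, sex=%s)\n",
              x$name, x$age, x$bmi, x$sex))
  invisible(x)
}

#' The ten study strata
#'
#' The full cohort plus single- and two-factor strata on age (> 50 / <= 50
#' years), obesity (BMI >= 30 / < 30 kg/m2) and sex, as tabulated in the
#' study design.
#'
#' @return Named list of [stratum_spec()] objects.
#' @export
study_strata <- function() {
  list(
    all               = stratum_spec("all"),
    males             = stratum_spec("males", sex = "male"),
    females           = stratum_spec("females", sex = "female"),
    bmi_ge30          = stratum_spec("bmi_ge30", bmi = "ge30"),
    bmi_lt30          = stratum_spec("bmi_lt30", bmi = "lt30"),
    age_gt50          = stratum_spec("age_gt50", age = "gt50"),
    males_age_gt50    = stratum_spec("males_age_gt50", age = "gt50", sex = "male"),
    females_age_gt50  = stratum_spec("females_age_gt50", age = "gt50", sex = "female"),
    age_gt50_bmi_ge30 = stratum_spec("age_gt50_bmi_ge30", age = "gt50", bmi = "ge30"),
    age_gt50_bmi_lt30 = stratum_spec("age_gt50_bmi_lt30", age = "gt50", bmi = "lt30")
  )
}

#' The six strata with non-empty signatures used for model comparison
#' @return Named list of [stratum_spec()] objects.
#' @export
model_strata <- function() {
  study_strata()[c("all", "age_gt50", "males", "males_age_gt50",
                   "age_gt50_bmi_ge30", "age_gt50_bmi_lt30")]
}

#' Restrict a cohort to a demographic stratum
#'
#' Rules apply conjunctively with strict/inclusive boundaries as in
#' [stratum_spec()].  An empty result is returned with a warning, not an
#' error (some strata legitimately select nobody in small cohorts).
#'
#' @param cohort a `cohort` object.
#' @param spec a [stratum_spec()].
#' @return The stratified `cohort`.
#' @export
stratify <- function(cohort, spec) {
  stopifnot(inherits(cohort, "cohort"), inherits(spec, "stratum_spec"))
  keep <- rep(TRUE, nrow(cohort))
  keep <- keep & switch(spec$age, all = TRUE, gt50 = cohort$age > 50,
                        le50 = cohort$age <= 50)
  keep <- keep & switch(spec$bmi, all = TRUE, ge30 = cohort$bmi >= 30,
                        lt30 = cohort$bmi < 30)
  keep <- keep & switch(spec$sex, all = TRUE, male = cohort$sex == "male",
                        female = cohort$sex == "female")
  if (!any(keep)) {
    warning("stratum '", spec$name, "' selected no participants",
            call. = FALSE)
  }
  cohort_like(as.data.frame(cohort)[keep, , drop = FALSE], cohort)
}
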