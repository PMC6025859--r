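#' Configure a full signature-discovery and model-comparison run
#'
#' @param input path to a cohort CSV, or a [simulation_config()] to generate
#'   one.
#' @param strata named list of [stratum_spec()]s to analyse (default the six
#'   model-comparison strata).
#' @param B bootstrap replicates per stage (>= 100).
#' @param seed master seed; every stage derives its own seed from it, so
#'   stages are independently reproducible.
#' @param rule a [selection_rule()].
#' @param families model families to compare.
#' @param k_range candidate component counts for `pcr`/`pls`.
#' @param out_dir output directory for report files (created if needed);
#'   `NULL` to skip writing.
#' @param batch_method passed to [adjust_batch()].
#' @return A `run_config` list.
#' @export
run_config <- function(input, strata = model_strata(), B = 1000L, seed,
                       rule = selection_rule(),
                       families = c("pcr", "pls", "logistic"),
                       k_range = 1L, out_dir = NULL,
                       batch_method = "median-ratio") {
  if (missing(seed) || is.null(seed)) {
    stop("a master seed is mandatory", call. = FALSE)
  }
  stopifnot(B >= 100L)
  families <- match.arg(families, c("pcr", "pls", "logistic"),
                        several.ok = TRUE)
  structure(list(input = input, strata = strata, B = as.integer(B),
                 seed = as.integer(seed), rule = rule, families = families,
                 k_range = as.integer(k_range), out_dir = out_dir,
                 batch_method = batch_method),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Recognized fields mirror [run_config()]; `input` may be a cohort CSV path
#' or a `simulation` block with [default_study_config()] overrides
#' (`sim_seed`, `effects` as a name->AUC map, `rho_within_class`,
#' `n_batches`, `batch_sd`).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$seed)) stop("config must set a seed", call. = FALSE)
  input <- if (!is.null(raw$cohort_csv)) {
    raw$cohort_csv
  } else {
    sim <- raw$simulation
    if (is.null(sim)) stop("config needs cohort_csv or simulation", call. = FALSE)
    args <- list(seed = sim$seed %||% raw$seed)
    if (!is.null(sim$effects)) args$effects <- unlist(sim$effects)
    for (f in c("rho_within_class", "n_batches", "batch_sd",
                "dm_prevalence")) {
      if (!is.null(sim[[f]])) args[[f]] <- sim[[f]]
    }
    do.call(default_study_config, args)
  }
  strata <- if (is.null(raw$strata)) model_strata()
            else study_strata()[unlist(raw$strata)]
  run_config(input = input, strata = strata,
             B = raw$B %||% 1000L, seed = raw$seed,
             families = raw$families %||% c("pcr", "pls", "logistic"),
             k_range = raw$k_range %||% 1L,
             out_dir = raw$out_dir,
             batch_method = raw$batch_method %||% "median-ratio")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full stepwise workflow
#'
#' Preprocess (batch adjustment, log(x+1)) -> dispersion homogeneity check
#' (age-band x group) -> per-stratum bootstrap signature selection ->
#' per-stratum model comparison on signature and aggregate inputs ->
#' signature set algebra, writing TSV/CSV report files and a JSON manifest
#' when `out_dir` is set.  Two runs with the same configuration produce
#' identical numbers.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `cohort`, `preprocessed`, `demographics`,
#'   `dispersion` (pairwise Tukey table), `signatures`, `summaries`,
#'   `consistency`, `set_ops`, `roc_bands` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (inherits(config$input, "simulation_config")) {
    simulate_cohort(config$input)
  } else {
    read_cohort_csv(config$input)
  }
  pre <- preprocess_cohort(cohort, batch_method = config$batch_method)

  demo <- demographics_table(cohort)

  disp_groups <- interaction(
    ifelse(cohort$age > 50, "age_gt50", "age_le50"), cohort$group, drop = TRUE)
  disp <- group_dispersion(cohort_matrix(pre), disp_groups)
  disp_pairs <- tukey_dispersion_test(disp)

  signatures <- list()
  dists <- list()
  for (nm in names(config$strata)) {
    res <- stratum_signature(pre, config$strata[[nm]], B = config$B,
                             seed = config$seed, rule = config$rule)
    signatures[[nm]] <- res$signature
    dists[[nm]] <- res$dists
  }

  agg_raw <- aggregate_by_class(adjust_batch(cohort,
                                             method = config$batch_method))
  summaries <- list()
  roc_bands <- list()
  cells <- list()
  for (nm in names(config$strata)) {
    sig <- signatures[[nm]]
    mets <- signature_metabolites(sig)
    sub <- stratify(pre, config$strata[[nm]])
    y <- cohort_labels(sub)
    agg_sub <- agg_raw[sub$subject_id, , drop = FALSE]
    for (fam in config$families) {
      fam_label <- unname(c(pcr = "pcr", pls = "pls", logistic = "log")[fam])
      k <- 1L
      if (fam %in% c("pcr", "pls") && length(config$k_range) > 1L &&
          length(mets) > 0L) {
        k <- as.integer(select_components(
          cohort_matrix(sub, mets), y, fam,
          k_range = config$k_range[config$k_range <= length(mets)],
          B = config$B, seed = derive_seed(config$seed, nm, fam, "ksel")))
      }
      if (length(mets) > 0L) {
        s <- bootstrap_model_auc(
          cohort_matrix(sub, mets), y, model_spec(fam, k, "signature"),
          B = config$B, seed = derive_seed(config$seed, nm, fam, "signature"),
          stratum_name = nm, keep_scores = (fam == "pcr"))
        summaries[[paste(nm, fam_label, sep = ".")]] <- s
        if (fam == "pcr") {
          roc_bands[[nm]] <- list(test = roc_band_export(s, which = "test"),
                                  train = roc_band_export(s, which = "train"))
          s$scores <- NULL
        }
        cells[[length(cells) + 1L]] <- summary_cells(s, fam_label)
      }
      sa <- bootstrap_model_auc(
        agg_sub, y, model_spec(fam, min(k, ncol(agg_sub)), "aggregate"),
        B = config$B, seed = derive_seed(config$seed, nm, fam, "aggregate"),
        stratum_name = nm)
      summaries[[paste(nm, paste0("sum_", fam_label), sep = ".")]] <- sa
      cells[[length(cells) + 1L]] <- summary_cells(sa, paste0("sum_", fam_label))
    }
  }
  cells <- do.call(rbind, cells)
  # consistency grids are assembled per input type over strata every family covered
  consistency <- tryCatch(consistency_table(cells), error = function(e) {
    warning("consistency grid not assembled: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })

  nonempty <- names(signatures)[vapply(signatures, function(s)
    nrow(s$entries) > 0L, TRUE)]
  set_ops <- if (length(nonempty) >= 2L) {
    signature_set_ops(signatures[nonempty[seq_len(min(3L, length(nonempty)))]])
  } else NULL

  manifest <- list(
    seed = config$seed, B = config$B,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("metabosig")),
    discarded_selection = lapply(dists, function(dl)
      vapply(dl, function(d) d$n_discarded, integer(1L))),
    discarded_models = lapply(summaries, function(s) s$n_discarded)
  )

  out <- list(cohort = cohort, preprocessed = pre, demographics = demo,
              dispersion = disp_pairs, signatures = signatures,
              summaries = summaries, consistency = consistency,
              set_ops = set_ops, roc_bands = roc_bands, manifest = manifest)
  if (!is.null(config$out_dir)) write_report(out, config$out_dir)
  invisible(out)
}

summary_cells <- function(s, model_label) {
  data.frame(model = model_label, quantile = c(0.025, 0.5, 0.975),
             stratum = s$stratum,
             train = unname(s$train_quantiles),
             test = unname(s$test_quantiles),
             stringsAsFactors = FALSE)
}

write_report <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) utils::write.table(
    df, file.path(dir, file), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(out$demographics, "demographics.tsv")
  wt(out$dispersion, "dispersion_pairs.tsv")
  detail <- do.call(rbind, lapply(names(out$signatures), function(nm) {
    e <- out$signatures[[nm]]$entries
    if (nrow(e) == 0L) return(NULL)
    cbind(stratum = nm, e)
  }))
  if (!is.null(detail)) {
    wt(detail, "signatures.tsv")
    wide <- stats::reshape(
      detail[c("stratum", "metabolite", "q50")], direction = "wide",
      idvar = "metabolite", timevar = "stratum")
    names(wide) <- sub("^q50\\.", "", names(wide))
    wt(wide[order(wide$metabolite), ], "signature_grid.tsv")
  }
  if (!is.null(out$consistency)) {
    wt(out$consistency$cells, "consistency_cells.tsv")
    wt(out$consistency$mad_quantile, "consistency_mad_quantile.tsv")
    wt(out$consistency$mad_all, "consistency_mad_all.tsv")
  }
  if (!is.null(out$set_ops) && !is.null(out$set_ops$venn_regions)) {
    wt(data.frame(region = names(out$set_ops$venn_regions),
                  count = as.integer(out$set_ops$venn_regions)),
       "venn_regions.tsv")
  }
  for (nm in names(out$roc_bands)) {
    utils::write.csv(out$roc_bands[[nm]]$test,
                     file.path(dir, paste0("roc_test_", nm, ".csv")),
                     row.names = FALSE)
    utils::write.csv(out$roc_bands[[nm]]$train,
                     file.path(dir, paste0("roc_train_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
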