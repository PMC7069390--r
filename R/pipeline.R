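# Orchestration: simulate -> ingest -> QC -> summarize -> phenotype ->
# report, with a flow ledger, stratified analyses and sensitivity toggles.

#' Analysis configuration
#'
#' @param thresholds list of [threshold_pair()]s, or a string such as
#'   `"130/80,135/85,140/90"` (the default three international cutoffs).
#' @param reference reference standard for the primary analysis: `"24h"`
#'   (time-weighted 24-h mean >= 130/80) or `"daytime"` (daytime mean >=
#'   135/85).
#' @param exclude_medicated drop subjects who report antihypertensive
#'   medication (default `TRUE`; the primary analysis).
#' @param include_qc_failures keep records that fail the completeness
#'   criteria (default `FALSE`; the sensitivity analysis).
#' @param strata covariate keys for stratified validity tables; subset of
#'   `"sex"`, `"age_group"`, `"site"`, `"bmi_category"`.
#' @param ci_method passed to [proportion_ci()].
#' @param weighting_mode passed to [weighted_24h_mean()].
#' @param seed optional integer recorded in the report (the analysis itself
#'   is deterministic).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(thresholds = default_thresholds(),
                            reference = c("24h", "daytime"),
                            exclude_medicated = TRUE,
                            include_qc_failures = FALSE,
                            strata = character(),
                            ci_method = "wilson",
                            weighting_mode = "interval",
                            seed = NULL) {
  if (is.character(thresholds)) thresholds <- parse_thresholds(thresholds)
  stopifnot(length(thresholds) >= 1,
            all(vapply(thresholds, inherits, TRUE, "threshold_pair")))
  reference <- match.arg(reference)
  known <- c("sex", "age_group", "site", "bmi_category")
  if (!all(strata %in% known)) {
    stop("unknown strata: ", paste(setdiff(strata, known), collapse = ", "),
         call. = FALSE)
  }
  structure(list(thresholds = thresholds, reference = reference,
                 exclude_medicated = isTRUE(exclude_medicated),
                 include_qc_failures = isTRUE(include_qc_failures),
                 strata = strata, ci_method = ci_method,
                 weighting_mode = weighting_mode, seed = seed),
            class = "analysis_config")
}

#' Partition subjects into analysis strata
#'
#' Keys: `sex` and `site` as given; `age_group` in decade bands (18-29,
#' 30-39, ..., 60-69, 70+); `bmi_category` as underweight (<18.5), normal
#' (18.5-24.9), overweight (25-29.9), obese (>=30 kg/m2). A missing
#' covariate maps to an explicit `"missing"` stratum.
#'
#' @param subjects data frame with the covariate columns.
#' @param key one of `"sex"`, `"age_group"`, `"site"`, `"bmi_category"`.
#' @return character vector of stratum labels, one per subject.
#' @export
stratify <- function(subjects, key) {
  lab <- switch(key,
    sex = as.character(subjects$sex),
    site = as.character(subjects$site),
    age_group = {
      a <- subjects$age
      ifelse(a < 30, "18-29",
             ifelse(a < 40, "30-39",
                    ifelse(a < 50, "40-49",
                           ifelse(a < 60, "50-59",
                                  ifelse(a < 70, "60-69", "70+")))))
    },
    bmi_category = {
      b <- subjects$bmi
      ifelse(b < 18.5, "underweight",
             ifelse(b < 25, "normal",
                    ifelse(b < 30, "overweight", "obese")))
    },
    stop("unknown stratification key: ", key, call. = FALSE))
  ifelse(is.na(lab), "missing", lab)
}

threshold_block <- function(scr, ref, mean_sbp, mean_dbp, th, ci_method) {
  ct <- confusion_table(scr, ref)
  ph <- table(phenotype(scr, ref))
  # signed margin to the cutoff pair: positive iff screen-positive, so the
  # empirical AUC of this score is threshold-consistent
  score <- pmax(mean_sbp - th$sbp_cut, mean_dbp - th$dbp_cut)
  auc_emp <- tryCatch(auc_empirical(score, ref), error = function(e) NULL)
  list(threshold = th$label,
       n = ct$n,
       screen_positive = ct$tp + ct$fp,
       screen_positive_pct = 100 * (ct$tp + ct$fp) / ct$n,
       confusion = ct[c("tp", "fp", "fn", "tn")],
       phenotype_counts = as.list(ph),
       validity = validity_metrics(ct, ci_method),
       likelihood_ratios = likelihood_ratios(ct),
       auc_binary = auc_point(ct),
       auc_empirical = auc_emp)
}

paired_block <- function(x, y, label) {
  ok <- !is.na(x) & !is.na(y)
  tt <- stats::t.test(x[ok], y[ok], paired = TRUE)
  ba <- bland_altman(x[ok], y[ok])
  list(comparison = label,
       n = sum(ok),
       mean_diff = unname(tt$estimate),
       diff_ci = unname(tt$conf.int),
       t_p = tt$p.value,
       pearson_r = stats::cor(x[ok], y[ok]),
       loa = c(ba$loa_low, ba$loa_high),
       pitman_r = ba$pitman_r,
       pitman_p = ba$pitman_p)
}

#' Run the full screening-validation analysis
#'
#' Ingests the three raw files, applies completeness QC and the medication
#' exclusion, and produces the report bundle: a subject flow ledger,
#' per-threshold validity tables (confusion cells, sensitivity,
#' specificity, predictive values, likelihood ratios, both AUROC forms,
#' phenotype counts), the agreement block (paired t, correlation,
#' Bland-Altman with Pitman test, for office vs 24-h and office vs daytime,
#' systolic and diastolic), dipping counts, stratified validity tables and
#' the covariate regression on device differences. Identical inputs and
#' config produce identical reports.
#'
#' @param config an [analysis_config()].
#' @param readings_file,office_file,subjects_file paths to the raw CSVs
#'   (formats as written by [write_cohort_files()]).
#' @return object of class `abpm_report` (a nested list; serialize with
#'   [write_report()]).
#' @export
run_pipeline <- function(config, readings_file, office_file,
                         subjects_file) {
  stopifnot(inherits(config, "analysis_config"))
  records <- parse_readings(readings_file)
  summaries <- summarize_abpm(records,
                              weighting_mode = config$weighting_mode)
  office <- read_office_sessions(office_file)
  subjects <- read_subjects(subjects_file)

  # flow ledger: each parsed subject lands in exactly one terminal bin
  subjects$has_abpm <- subjects$subject_id %in% summaries$subject_id
  qc_ok <- summaries$qc_pass[match(subjects$subject_id,
                                   summaries$subject_id)]
  qc_ok[is.na(qc_ok)] <- FALSE
  if (config$include_qc_failures) qc_ok <- qc_ok | subjects$has_abpm
  off_ok <- office$usable[match(subjects$subject_id, office$subject_id)]
  off_ok[is.na(off_ok)] <- FALSE
  med <- subjects$on_medication
  bin <- ifelse(!subjects$has_abpm, "no_abpm_record",
         ifelse(!qc_ok, "qc_failed",
         ifelse(config$exclude_medicated & med, "medicated_excluded",
         ifelse(!off_ok, "office_insufficient", "analyzed"))))
  flow <- list(parsed = nrow(subjects),
               no_abpm_record = sum(bin == "no_abpm_record"),
               qc_failed = sum(bin == "qc_failed"),
               medicated_excluded = sum(bin == "medicated_excluded"),
               office_insufficient = sum(bin == "office_insufficient"),
               analyzed = sum(bin == "analyzed"))

  ids <- subjects$subject_id[bin == "analyzed"]
  s <- summaries[match(ids, summaries$subject_id), ]
  o <- office[match(ids, office$subject_id), ]
  cov <- subjects[match(ids, subjects$subject_id), ]

  ref <- reference_status(s, config$reference,
                          allow_qc_failures = config$include_qc_failures)
  prev <- proportion_ci(sum(ref, na.rm = TRUE), sum(!is.na(ref)),
                        config$ci_method)

  blocks <- lapply(config$thresholds, function(th) {
    scr <- screen_status(o$mean_sbp, o$mean_dbp, th)
    threshold_block(scr, ref, o$mean_sbp, o$mean_dbp, th, config$ci_method)
  })
  names(blocks) <- vapply(config$thresholds, `[[`, "", "label")

  agreement <- list(
    sbp_24h = paired_block(o$mean_sbp, s$wt24_sbp, "office vs 24h SBP"),
    sbp_day = paired_block(o$mean_sbp, s$day_sbp, "office vs daytime SBP"),
    dbp_24h = paired_block(o$mean_dbp, s$wt24_dbp, "office vs 24h DBP"),
    dbp_day = paired_block(o$mean_dbp, s$day_dbp, "office vs daytime DBP"))

  dip <- dipping_status(s$night_sbp, s$day_sbp)
  strata <- lapply(config$strata, function(key) {
    labels <- stratify(cov, key)
    per <- lapply(sort(unique(labels)), function(lv) {
      i <- labels == lv
      lapply(config$thresholds, function(th) {
        scr <- screen_status(o$mean_sbp[i], o$mean_dbp[i], th)
        threshold_block(scr, ref[i], o$mean_sbp[i], o$mean_dbp[i], th,
                        config$ci_method)
      })
    })
    names(per) <- sort(unique(labels))
    per
  })
  names(strata) <- config$strata

  covariates <- data.frame(age = cov$age, sex = factor(cov$sex),
                           site = factor(cov$site), bmi = cov$bmi,
                           diabetes = cov$diabetes, smoker = cov$smoker)
  # constant covariates (e.g. no diabetics in a small cohort) carry no
  # information and would only make the design rank deficient
  covariates <- covariates[, vapply(covariates,
                                    function(x) length(unique(x)) > 1,
                                    TRUE), drop = FALSE]
  regression <- list(
    sbp = difference_regression(o$mean_sbp - s$wt24_sbp, covariates),
    dbp = difference_regression(o$mean_dbp - s$wt24_dbp, covariates))

  structure(list(
    config = list(thresholds = names(blocks), reference = config$reference,
                  exclude_medicated = config$exclude_medicated,
                  include_qc_failures = config$include_qc_failures,
                  ci_method = config$ci_method,
                  weighting_mode = config$weighting_mode,
                  seed = config$seed),
    flow = flow,
    prevalence = list(n_confirmed = sum(ref, na.rm = TRUE),
                      n_analyzed = sum(!is.na(ref)),
                      pct = 100 * prev$estimate,
                      ci_pct = c(100 * prev$ci_low, 100 * prev$ci_high)),
    thresholds = blocks,
    agreement = agreement,
    dipping = as.list(table(dip)),
    strata = strata,
    regression = regression),
    class = "abpm_report")
}

#' @export
print.abpm_report <- function(x, ...) {
  cat(sprintf("<abpm_report: %d analyzed of %d parsed; reference %s>\n",
              x$flow$analyzed, x$flow$parsed, x$config$reference))
  cat(sprintf(" confirmed hypertension: %d/%d (%.0f%%)\n",
              x$prevalence$n_confirmed, x$prevalence$n_analyzed,
              x$prevalence$pct))
  for (b in x$thresholds) {
    v <- b$validity
    g <- function(m) v$estimate[v$metric == m] * 100
    cat(sprintf(
      " %7s: screen+ %2.0f%%  sens %2.0f%%  spec %2.0f%%  ppv %2.0f%%  npv %2.0f%%  auc %.2f\n",
      b$threshold, b$screen_positive_pct, g("sensitivity"),
      g("specificity"), g("ppv"), g("npv"), b$auc_binary))
  }
  invisible(x)
}

#' Serialize a report to JSON (machine-readable, full precision)
#'
#' @param report an `abpm_report` (or any list).
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       na = "null")
  invisible(path)
}

#' Side-by-side sensitivity analyses
#'
#' Reruns the pipeline with the medication exclusion lifted and with
#' QC-failing records included, and reports per-threshold deltas in
#' sensitivity and specificity against the base run.
#'
#' @param config base [analysis_config()].
#' @param readings_file,office_file,subjects_file raw file paths.
#' @return list with the base report and one delta block per toggle; each
#'   delta block holds the toggled report plus `deltas` (threshold,
#'   d_sensitivity, d_specificity, d_n).
#' @export
sensitivity_analyses <- function(config, readings_file, office_file,
                                 subjects_file) {
  base <- run_pipeline(config, readings_file, office_file, subjects_file)
  toggle <- function(field, value) {
    cfg <- config
    cfg[[field]] <- value
    run_pipeline(cfg, readings_file, office_file, subjects_file)
  }
  delta <- function(alt) {
    rows <- lapply(names(base$thresholds), function(lab) {
      gv <- function(rep) {
        v <- rep$thresholds[[lab]]$validity
        c(sens = v$estimate[v$metric == "sensitivity"],
          spec = v$estimate[v$metric == "specificity"],
          n = rep$thresholds[[lab]]$n)
      }
      b <- gv(base)
      a <- gv(alt)
      data.frame(threshold = lab,
                 d_sensitivity = a[["sens"]] - b[["sens"]],
                 d_specificity = a[["spec"]] - b[["spec"]],
                 d_n = a[["n"]] - b[["n"]],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  inc_med <- toggle("exclude_medicated", FALSE)
  inc_qc <- toggle("include_qc_failures", TRUE)
  list(base = base,
       include_medicated = list(report = inc_med, deltas = delta(inc_med)),
       include_qc_failures = list(report = inc_qc, deltas = delta(inc_qc)))
}
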