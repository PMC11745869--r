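#' Pipeline configuration
#'
#' Settings for the end-to-end analysis: individual PK estimation from the
#' sparse samples, genetic screening with false-discovery-rate control,
#' repeated cross-validated LASSO selection, the 60/40 train/test split, the
#' final Cox model, nomogram and calibration.
#'
#' @param fdr_threshold FDR threshold for the univariate screen
#'   (default 0.05).
#' @param train_fraction Training fraction of the split (default 0.6).
#' @param n_repeats,k,n_iterations,alpha,lambda_rule Passed to
#'   [selection_frequency()].
#' @param epsilon,patience Passed to [progressive_addition()].
#' @param horizon Risk horizon in minutes (default 90).
#' @param n_bins,n_boot Calibration-curve settings.
#' @param seed Master seed for all randomized stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr_threshold = 0.05, train_fraction = 0.6,
                            n_repeats = 100, k = 5, n_iterations = 10000,
                            alpha = 1, lambda_rule = "min",
                            epsilon = 0.005, patience = 2, horizon = 90,
                            n_bins = 10, n_boot = 200, seed = 1L) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(fdr_threshold = fdr_threshold,
                 train_fraction = train_fraction, n_repeats = n_repeats,
                 k = k, n_iterations = n_iterations, alpha = alpha,
                 lambda_rule = lambda_rule, epsilon = epsilon,
                 patience = patience, horizon = horizon, n_bins = n_bins,
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Validate pipeline input files
#'
#' Schema and plausibility checks on the CSV inputs: required columns,
#' plausible units (weights 1-150 kg, non-negative times, ng/mL-magnitude
#' concentrations), genotype domain 0/1/2/NA, and subject-id
#' cross-referencing across tables.
#'
#' @param dir Directory holding `covariates.csv`, `genotypes.csv` and
#'   `concentrations.csv` (the dialect written by [write_cohort()]).
#' @return A character vector of issues (empty when all checks pass);
#'   attribute `"severity"` marks each as `"error"` or `"warning"`.
#' @export
validate_inputs <- function(dir) {
  files <- file.path(dir, c("covariates.csv", "genotypes.csv",
                            "concentrations.csv"))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  issues <- character(0)
  sev <- character(0)
  note <- function(msg, s = "error") {
    issues <<- c(issues, msg); sev <<- c(sev, s)
  }
  cov <- utils::read.csv(files[1])
  need <- c("id", "weight", "pma", "event_time", "status", "censor_time")
  lack <- setdiff(need, names(cov))
  if (length(lack))
    note(paste("covariates.csv: missing column(s)",
               paste(lack, collapse = ", ")))
  if ("weight" %in% names(cov) &&
      any(cov$weight < 1 | cov$weight > 150, na.rm = TRUE))
    note("covariates.csv: weight outside 1-150 kg", "warning")
  if ("event_time" %in% names(cov) && any(cov$event_time < 0, na.rm = TRUE))
    note("covariates.csv: negative event_time")
  gen <- utils::read.csv(files[2], check.names = FALSE)
  gmat <- as.matrix(gen[, -1, drop = FALSE])
  if (!all(is.na(gmat) | gmat %in% 0:2))
    note("genotypes.csv: entries outside {0, 1, 2, NA}")
  con <- utils::read.csv(files[3])
  cneed <- c("subject_id", "time_h", "conc_ng_ml")
  clack <- setdiff(cneed, names(con))
  if (length(clack))
    note(paste("concentrations.csv: missing column(s)",
               paste(clack, collapse = ", ")))
  if ("time_h" %in% names(con) && any(con$time_h < 0, na.rm = TRUE))
    note("concentrations.csv: negative time")
  if ("conc_ng_ml" %in% names(con) &&
      stats::median(con$conc_ng_ml, na.rm = TRUE) > 100)
    note("concentrations.csv: concentration magnitude suggests ug/mL, expected ng/mL",
         "warning")
  if ("id" %in% names(cov)) {
    if (!all(gen[[1]] %in% cov$id))
      note("genotypes.csv: subject(s) absent from covariates.csv")
    if ("subject_id" %in% names(con) && !all(con$subject_id %in% cov$id))
      note("concentrations.csv: subject(s) absent from covariates.csv")
  }
  attr(issues, "severity") <- sev
  issues
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages in order: MAP estimation of individual PK from the
#' 60-min samples; genotype summary (MAF, Hardy-Weinberg); univariate Cox
#' screening of all candidate covariates with Benjamini-Hochberg FDR;
#' 60/40 train/test split; repeated cross-validated LASSO selection
#' frequencies and progressive addition on the FDR-passing candidates;
#' final multivariable Cox fit; nomogram with Youden threshold from the
#' training ROC; calibration curve on the test cohort. Per-stage tables are
#' returned and, when `output_dir` is given, written as CSVs together with a
#' machine-readable JSON summary and a run log.
#'
#' @param cohort A [generate_cohort()] result (or a cohort read back from
#'   [write_cohort()] files via [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for per-stage artifacts.
#' @return A list of class `pipeline_result` with elements `pk`,
#'   `genetics`, `univariate`, `split`, `selection`, `progressive`,
#'   `final_fit`, `nomogram`, `roc` (train/test AuROC and threshold),
#'   `calibration`, `summary`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(config, "pipeline_config"))
  cv <- cohort$covariates
  if (sum(cv$status) == 0)
    stop("no hemodynamic-instability events in the cohort; ",
         "screening and modelling stages cannot run")
  log_lines <- c(sprintf("pipeline seed: %d", config$seed),
                 sprintf("cohort seed: %d, n = %d", cohort$seed, nrow(cv)))

  # -- stage 1: individual PK (MAP from the single 60-min sample) ----------
  m <- cohort$config$pk_model
  pk <- do.call(rbind, lapply(seq_len(nrow(cv)), function(i) {
    obs <- cohort$conc_obs[cohort$conc_obs$id == cv$id[i], ]
    fit <- map_estimate(m, obs$time_h, obs$conc, cv$dose[i],
                        cv$weight[i], cv$pma[i])
    met <- derive_metrics(fit, cv$dose[i])
    data.frame(id = cv$id[i], eta_cl = fit$eta[["cl"]],
               eta_v = fit$eta[["v"]], eta_ka = fit$eta[["ka"]],
               cl = fit$cl, v = fit$v, ka = fit$ka,
               cl_per_kg = met$cl_per_kg, v_per_kg = met$v_per_kg,
               cmax = met$cmax, tmax = met$tmax, t_half = met$t_half,
               auc_inf = met$auc_inf, converged = fit$converged)
  }))
  if (!all(pk$converged))
    log_lines <- c(log_lines, sprintf("MAP non-convergence for %d subject(s)",
                                      sum(!pk$converged)))

  # -- stage 2: genetics ---------------------------------------------------
  genetics <- genotype_summary(cohort$genotypes)

  # -- stage 3: survival dataset + univariate screen -----------------------
  sdat <- cohort_survival_data(cohort, cl = pk$cl)
  cand <- covariate_names(sdat)
  uni <- do.call(rbind, lapply(cand, function(v) {
    fit <- tryCatch(suppressWarnings(cox_fit(sdat, v)),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(covariate = v, coef = NA, hr = NA, lower95 = NA,
                        upper95 = NA, p_value = NA))
    fit$hr[, c("covariate", "coef", "hr", "lower95", "upper95", "p_value")]
  }))
  uni$q_value <- fdr_adjust(uni$p_value)
  keep <- uni$covariate[!is.na(uni$q_value) &
                          uni$q_value < config$fdr_threshold]
  if (length(keep) < 2) {
    log_lines <- c(log_lines,
                   "fewer than 2 covariates pass the FDR screen; using all candidates")
    keep <- cand
  }

  # -- stage 4: split + LASSO selection ------------------------------------
  split <- split_cohort(sdat, config$train_fraction, seed = config$seed)
  train <- subset_subjects(sdat, split$train_ids)
  test <- subset_subjects(sdat, split$test_ids)
  sel <- selection_frequency(train, keep, n_repeats = config$n_repeats,
                             k = config$k,
                             n_iterations = config$n_iterations,
                             alpha = config$alpha,
                             lambda_rule = config$lambda_rule,
                             seed = config$seed)
  prog <- progressive_addition(sel$ranked, train, test,
                               epsilon = config$epsilon,
                               patience = config$patience)

  # -- stage 5: final model, nomogram, ROC, calibration --------------------
  final_fit <- cox_fit(train, prog$chosen)
  nom <- build_nomogram(final_fit, train, horizon = config$horizon)
  subj_train <- .subject_level(train, prog$chosen)
  subj_test <- .subject_level(test, prog$chosen)
  risk_train <- nomogram_risk(nom, nomogram_points(nom, subj_train)$total)
  risk_test <- nomogram_risk(nom, nomogram_points(nom, subj_test)$total)
  yj <- youden_threshold(risk_train, subj_train$event)
  nom$threshold <- yj$threshold
  roc <- list(auc_train = roc_auc(risk_train, subj_train$event),
              auc_test = roc_auc(risk_test, subj_test$event),
              threshold = yj$threshold, sensitivity = yj$sensitivity,
              specificity = yj$specificity)
  calib <- calibration_curve(nom, test, n_bins = min(config$n_bins,
                                                     nrow(subj_test) %/% 5),
                             n_boot = config$n_boot, seed = config$seed)

  summary <- list(
    n = nrow(cv), n_events = sum(cv$status),
    median_cl = stats::median(pk$cl),
    n_candidates = length(cand), n_screened = length(keep),
    chosen = prog$chosen,
    auc_train = roc$auc_train, auc_test = roc$auc_test,
    threshold = yj$threshold,
    calibration_slope = calibration_slope(calib),
    seed = config$seed)
  out <- structure(list(pk = pk, genetics = genetics, univariate = uni,
                        split = split, selection = sel,
                        progressive = prog, final_fit = final_fit,
                        nomogram = nom, roc = roc, calibration = calib,
                        summary = summary, log = log_lines),
                   class = "pipeline_result")
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pk, file.path(output_dir, "individual_pk.csv"),
                     row.names = FALSE)
    utils::write.csv(genetics, file.path(output_dir, "genetics.csv"),
                     row.names = FALSE)
    utils::write.csv(uni, file.path(output_dir, "univariate.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(covariate = names(sel$frequency),
                                frequency = unname(sel$frequency)),
                     file.path(output_dir, "selection_frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(final_fit$hr, file.path(output_dir, "final_model.csv"),
                     row.names = FALSE)
    utils::write.csv(nom$points_table,
                     file.path(output_dir, "nomogram.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(calib),
                     file.path(output_dir, "calibration.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(output_dir, "run_log.txt"))
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result\n")
  cat(sprintf("  cohort: n = %d, events = %d\n", x$summary$n,
              x$summary$n_events))
  cat(sprintf("  chosen model: %s\n", paste(x$summary$chosen, collapse = ", ")))
  cat(sprintf("  AuROC train %.3f / test %.3f; Youden risk threshold %.3f\n",
              x$summary$auc_train, x$summary$auc_test, x$summary$threshold))
  cat(sprintf("  calibration slope %.2f\n", x$summary$calibration_slope))
  invisible(x)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory holding the cohort CSVs.
#' @param config The [cohort_config()] that generated the cohort (PK model
#'   and standardization constants are needed downstream); defaults to the
#'   package default.
#' @return A `synthetic_cohort`.
#' @export
read_cohort <- function(dir, config = cohort_config()) {
  issues <- validate_inputs(dir)
  sev <- attr(issues, "severity")
  if (any(sev == "error"))
    stop("invalid inputs:\n  ", paste(issues[sev == "error"],
                                      collapse = "\n  "))
  for (w in issues[sev == "warning"]) warning(w)
  cv <- utils::read.csv(file.path(dir, "covariates.csv"))
  gen <- utils::read.csv(file.path(dir, "genotypes.csv"),
                         check.names = FALSE)
  con <- utils::read.csv(file.path(dir, "concentrations.csv"))
  info_path <- file.path(dir, "snp_info.csv")
  info <- if (file.exists(info_path)) {
    utils::read.csv(info_path, stringsAsFactors = FALSE)
  } else NULL
  gmat <- as.matrix(gen[, -1, drop = FALSE])
  mode(gmat) <- "integer"
  rownames(gmat) <- gen[[1]]
  tp_path <- file.path(dir, "true_pk.csv")
  structure(list(covariates = cv,
                 genotypes = genotype_matrix(gmat, info),
                 conc_obs = data.frame(id = con$subject_id,
                                       time_h = con$time_h,
                                       conc = con$conc_ng_ml),
                 true_pk = if (file.exists(tp_path))
                   utils::read.csv(tp_path) else NULL,
                 config = config, seed = NA_integer_),
            class = "synthetic_cohort")
}
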