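#' Default SNP panel of the synthetic generator
#'
#' Six candidate variants in drug-metabolism, drug-target and calcium-channel
#' genes, with minor allele frequencies and binary genetic-model contrasts
#' matching the pharmacogenetic screen this package implements, and true
#' hazard ratios used as simulation ground truth. For the two
#' heterozygote-vs-homozygote contrasts the homozygote group is the at-risk
#' side (`exposed = "ref"`).
#'
#' @return A data.frame with columns `rsid`, `gene`, `chrom`,
#'   `major_allele`, `minor_allele`, `maf`, `model`, `exposed`, `hr`.
#' @export
default_snp_panel <- function() {
  data.frame(
    rsid = c("rs1841042", "rs8192733", "rs3813662", "rs2236957",
             "rs3814057", "rs10764319"),
    gene = c("UGT2B10", "CYP2A6", "ADRA2B", "CACNA2D2", "NR1I2", "CACNB2"),
    chrom = c("4", "19", "2", "3", "3", "10"),
    major_allele = c("A", "G", "A", "A", "C", "C"),
    minor_allele = c("G", "C", "C", "G", "A", "T"),
    maf = c(0.19, 0.48, 0.14, 0.49, 0.49, 0.49),
    model = c("dominant", "dominant", "overdominant", "dominant",
              "dominant", "overdominant"),
    exposed = c("alt", "alt", "ref", "alt", "alt", "ref"),
    hr = c(1.41, 0.28, 1.39, 1.46, 0.64, 1.40),
    stringsAsFactors = FALSE)
}

# Piecewise-constant baseline hazard calibrated (see calibrate_baseline) so
# the marginal cohort reproduces the landmark incidences 8.2% at 22 min and
# 16.3% at 90 min, a 35-min median first-event time among observed events,
# and a 52/270 affected-subject fraction. Units: events per minute; segments
# [0,16), [16,35), [35,90), [90, Inf).
.default_hazard_knots <- c(16, 35, 90)
.default_hazard_levels <- c(0.0053080759, 0.0007658518, 0.0009265992,
                            0.0045346947)

#' Configuration of the synthetic cohort generator
#'
#' Encodes the study conditions the generator emulates: the demographic
#' distribution of a pediatric interventional-surgery cohort (median age 22
#' months, median weight 11 kg), intranasal dexmedetomidine at 3 ug/kg, one
#' plasma sample at 60 min, propofol induction at a median of 16 min
#' (IQR 12-22), a piecewise-constant baseline hazard for the composite
#' hemodynamic-instability endpoint, censoring at operation completion
#' (uniform 60-120 min), and the SNP panel with its true hazard ratios.
#'
#' Clinical/PK effects act on the log hazard through standardized log weight
#' and standardized true log clearance plus a time-dependent
#' post-propofol-induction indicator; their default hazard ratios (1.30 per
#' SD log weight, 0.70 per SD log CL/F, 2.00 for propofol) are generator
#' ground truth, configurable here.
#'
#' @param n Number of subjects (default 270).
#' @param age_meanlog,age_sdlog Log-normal postnatal age (months) parameters;
#'   ages truncated to `age_range`.
#' @param age_range Admissible age range in months (default c(3, 72)).
#' @param weight_cv Log-scale SD of weight around the age-indexed growth
#'   curve.
#' @param p_female Probability of female sex.
#' @param snp_panel SNP metadata + true hazard ratios
#'   (default [default_snp_panel()]).
#' @param pk_model A [poppk_model()] for the true individual PK.
#' @param dose_per_kg Intranasal dose, ug per kg (default 3).
#' @param conc_time_h Sampling time of the single plasma level, hours
#'   (default 1).
#' @param tprop_meanlog,tprop_sdlog Log-normal propofol-induction time
#'   (minutes after dexmedetomidine) parameters (median 16, IQR approx
#'   12-22).
#' @param hr_weight,hr_cl,hr_propofol True hazard ratios of the clinical/PK
#'   effects.
#' @param weight_z_ref,cl_z_ref Numeric c(meanlog, sdlog) standardization
#'   constants for log weight and log clearance (population constants, so
#'   the true effects do not drift with cohort size).
#' @param hazard_knots,hazard_levels Baseline hazard: levels (per minute) on
#'   the segments delimited by the knots, with the last level continuing
#'   beyond the final knot. Defaults are the calibrated package values.
#' @param censor_range Operation-completion (censoring) window, minutes.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 270,
                          age_meanlog = 3.43994, age_sdlog = 1.25,
                          age_range = c(3, 72), weight_cv = 0.12,
                          p_female = 146 / 270,
                          snp_panel = default_snp_panel(),
                          pk_model = poppk_model(),
                          dose_per_kg = 3, conc_time_h = 1,
                          tprop_meanlog = log(16),
                          tprop_sdlog = log(22 / 12) / (2 * stats::qnorm(0.75)),
                          hr_weight = 1.30, hr_cl = 0.70,
                          hr_propofol = 2.00,
                          weight_z_ref = c(2.458, 0.310),
                          cl_z_ref = c(2.544, 0.479),
                          hazard_knots = .default_hazard_knots,
                          hazard_levels = .default_hazard_levels,
                          censor_range = c(60, 120)) {
  stopifnot(n > 0, all(hazard_levels >= 0),
            length(hazard_levels) == length(hazard_knots) + 1,
            all(snp_panel$maf > 0), all(snp_panel$maf <= 0.5))
  structure(list(n = n, age_meanlog = age_meanlog, age_sdlog = age_sdlog,
                 age_range = age_range, weight_cv = weight_cv,
                 p_female = p_female, snp_panel = snp_panel,
                 pk_model = pk_model, dose_per_kg = dose_per_kg,
                 conc_time_h = conc_time_h,
                 tprop_meanlog = tprop_meanlog, tprop_sdlog = tprop_sdlog,
                 hr_weight = hr_weight, hr_cl = hr_cl,
                 hr_propofol = hr_propofol,
                 weight_z_ref = weight_z_ref, cl_z_ref = cl_z_ref,
                 hazard_knots = hazard_knots,
                 hazard_levels = hazard_levels,
                 censor_range = censor_range),
            class = "cohort_config")
}

#' Ground-truth hazard ratios of the generator
#'
#' @param config A [cohort_config()].
#' @return A data.frame (`covariate`, `hr`, `beta`) with one row per SNP and
#'   per clinical/PK effect; `beta = log(hr)` elementwise. Empty panel gives
#'   only the clinical rows; an empty panel and zeroed clinical effects give
#'   an empty table.
#' @export
true_effect_table <- function(config) {
  panel <- config$snp_panel
  out <- data.frame(
    covariate = c(panel$rsid, "weight_z", "cl_z", "propofol"),
    gene = c(panel$gene, NA, NA, NA),
    hr = c(panel$hr, config$hr_weight, config$hr_cl, config$hr_propofol),
    stringsAsFactors = FALSE)
  out$beta <- log(out$hr)
  out[out$hr != 1, , drop = FALSE]
}

# pediatric weight-for-age curve (kg): (m + 9)/2 for infants up to 12
# months, then 2 * years + 8; crude norms adequate for cohort simulation
.weight_for_age <- function(age_months) {
  ifelse(age_months <= 12, (age_months + 9) / 2, 2 * age_months / 12 + 8)
}

# baseline cumulative hazard at times t for piecewise-constant levels
.base_cumhaz <- function(t, knots, levels) {
  bounds <- c(0, knots)
  seg_len <- diff(c(bounds, Inf))
  cum_at_knot <- c(0, cumsum(levels[-length(levels)] *
                               seg_len[-length(seg_len)]))
  i <- findInterval(t, bounds)
  cum_at_knot[i] + (t - bounds[i]) * levels[i]
}

# inverse of .base_cumhaz (H >= 0); returns Inf where the hazard has been
# exhausted (only possible if the terminal level is 0)
.base_cumhaz_inv <- function(H, knots, levels) {
  bounds <- c(0, knots)
  seg_len <- diff(c(bounds, Inf))
  cum_at_knot <- c(0, cumsum(levels[-length(levels)] *
                               seg_len[-length(seg_len)]))
  i <- findInterval(H, cum_at_knot)
  # skip zero-level segments: advance to the next knot where hazard resumes
  out <- rep(Inf, length(H))
  ok <- levels[i] > 0 | H == cum_at_knot[i]
  pos <- which(levels[i] > 0)
  out[pos] <- bounds[i[pos]] + (H[pos] - cum_at_knot[i[pos]]) / levels[i[pos]]
  zero <- which(levels[i] == 0 & H <= cum_at_knot[i] + 1e-12)
  out[zero] <- bounds[i[zero]]
  out
}

# event times for subjects with pre/post-propofol multipliers m0, m1,
# propofol onset tp and standard-exponential draws e
.sample_event_times <- function(e, m0, m1, tp, knots, levels) {
  H_tp <- .base_cumhaz(tp, knots, levels)
  e_at_tp <- m0 * H_tp
  early <- e <= e_at_tp
  T <- numeric(length(e))
  T[early] <- .base_cumhaz_inv(e[early] / m0[early], knots, levels)
  late <- !early
  T[late] <- .base_cumhaz_inv(H_tp[late] + (e[late] - e_at_tp[late]) /
                                m1[late], knots, levels)
  T
}

# covariate draw shared by generate_cohort and calibrate_baseline
.draw_population <- function(config, n) {
  age <- exp(stats::rnorm(n, config$age_meanlog, config$age_sdlog))
  while (any(bad <- age < config$age_range[1] | age > config$age_range[2]))
    age[bad] <- exp(stats::rnorm(sum(bad), config$age_meanlog,
                                 config$age_sdlog))
  weight <- .weight_for_age(age) * exp(stats::rnorm(n, 0, config$weight_cv))
  sex <- stats::rbinom(n, 1, config$p_female)  # 1 = female
  pma <- pma_from_age(age)
  panel <- config$snp_panel
  geno <- matrix(0L, n, nrow(panel), dimnames = list(NULL, panel$rsid))
  for (j in seq_len(nrow(panel)))
    geno[, j] <- stats::rbinom(n, 2L, panel$maf[j])
  m <- config$pk_model
  tv <- typical_params(m, weight, pma)
  eta_cl <- stats::rnorm(n, 0, m$omega[["cl"]])
  eta_v <- stats::rnorm(n, 0, m$omega[["v"]])
  eta_ka <- stats::rnorm(n, 0, m$omega[["ka"]])
  cl <- tv$cl * exp(eta_cl)
  tprop <- exp(stats::rnorm(n, config$tprop_meanlog, config$tprop_sdlog))
  censor <- stats::runif(n, config$censor_range[1], config$censor_range[2])
  weight_z <- (log(weight) - config$weight_z_ref[1]) / config$weight_z_ref[2]
  cl_z <- (log(cl) - config$cl_z_ref[1]) / config$cl_z_ref[2]
  enc <- matrix(0, n, nrow(panel), dimnames = list(NULL, panel$rsid))
  for (j in seq_len(nrow(panel)))
    enc[, j] <- encode_genotype(geno[, j], panel$model[j], panel$exposed[j])
  beta_snp <- log(panel$hr)
  lp0 <- drop(enc %*% beta_snp) + log(config$hr_weight) * weight_z +
    log(config$hr_cl) * cl_z
  list(age = age, weight = weight, sex = sex, pma = pma, geno = geno,
       enc = enc, eta_cl = eta_cl, eta_v = eta_v, eta_ka = eta_ka,
       cl = cl, tv = tv, tprop = tprop, censor = censor,
       weight_z = weight_z, cl_z = cl_z,
       m0 = exp(lp0), m1 = exp(lp0 + log(config$hr_propofol)))
}

#' Generate a synthetic cohort
#'
#' Draws demographics (log-normal age with an age-indexed growth curve for
#' weight), genotypes at Hardy-Weinberg proportions, true individual PK
#' parameters from the population model times `exp(eta)`, one plasma
#' concentration at 60 min with log-normal residual error, first
#' hemodynamic-instability event times from the proportional-hazards model
#' `h(t|x) = h0(t) exp(beta'x(t))` with propofol as a time-dependent switch
#' at the subject's induction time, and censoring at operation completion.
#' Fully reproducible given the seed.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_cohort` with elements `covariates`
#'   (data.frame: id, age_months, sex, weight, pma, dose, tprop,
#'   censor_time, event_time, status, weight_z, cl_z_true), `genotypes` (a
#'   [genotype_matrix()]), `conc_obs` (id, time_h, conc), `true_pk` (true
#'   individual parameters and etas), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (all(config$hazard_levels == 0))
    stop("infeasible config: all baseline hazard levels are zero")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n <- config$n
  pop <- .draw_population(config, n)
  e <- stats::rexp(n)
  T <- .sample_event_times(e, pop$m0, pop$m1, pop$tprop,
                           config$hazard_knots, config$hazard_levels)
  status <- as.integer(T <= pop$censor)
  time <- pmin(T, pop$censor)
  dose <- config$dose_per_kg * pop$weight
  m <- config$pk_model
  conc <- vapply(seq_len(n), function(i) {
    ind <- individual_pk(m, pop$weight[i], pop$pma[i],
                         c(cl = pop$eta_cl[i], v = pop$eta_v[i],
                           ka = pop$eta_ka[i]))
    simulate_concentration(ind, dose[i], config$conc_time_h)
  }, numeric(1))
  conc_obs <- conc * exp(stats::rnorm(n, 0, m$sigma))
  panel <- config$snp_panel
  info <- do.call(rbind, lapply(seq_len(nrow(panel)), function(j)
    snp_info(rsid = panel$rsid[j], gene = panel$gene[j],
             chrom = panel$chrom[j],
             major_allele = panel$major_allele[j],
             minor_allele = panel$minor_allele[j], maf = panel$maf[j],
             model = panel$model[j], exposed = panel$exposed[j])))
  covariates <- data.frame(
    id = seq_len(n), age_months = pop$age, sex = pop$sex,
    weight = pop$weight, pma = pop$pma, dose = dose, tprop = pop$tprop,
    censor_time = pop$censor, event_time = time, status = status,
    weight_z = pop$weight_z, cl_z_true = pop$cl_z)
  true_pk <- data.frame(
    id = seq_len(n), eta_cl = pop$eta_cl, eta_v = pop$eta_v,
    eta_ka = pop$eta_ka, cl = pop$cl, v = pop$tv$v * exp(pop$eta_v),
    q = pop$tv$q, v2 = pop$tv$v2, ka = pop$tv$ka * exp(pop$eta_ka),
    conc_true_60min = conc)
  structure(list(covariates = covariates,
                 genotypes = genotype_matrix(pop$geno, info),
                 conc_obs = data.frame(id = seq_len(n),
                                       time_h = config$conc_time_h,
                                       conc = conc_obs),
                 true_pk = true_pk, config = config, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cv <- x$covariates
  cat(sprintf("Synthetic cohort: n = %d (seed %d); %d events (%.1f%%); median weight %.1f kg\n",
              nrow(cv), x$seed, sum(cv$status), 100 * mean(cv$status),
              stats::median(cv$weight)))
  invisible(x)
}

#' Counting-process survival dataset from a synthetic cohort
#'
#' Builds the (start, stop] dataset used by the screening, selection and
#' risk-model stages: standardized log weight, standardized log clearance
#' (true or externally estimated), the encoded SNP covariates and the
#' time-dependent propofol indicator (0 before the subject's induction time,
#' 1 after).
#'
#' @param cohort A [generate_cohort()] result.
#' @param cl Either `"true"` (default; the generator's clearance) or a
#'   numeric vector of per-subject clearance estimates (L/h), e.g. MAP
#'   estimates, standardized with the config's reference constants.
#' @return A [survival_data()].
#' @export
cohort_survival_data <- function(cohort, cl = "true") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cv <- cohort$covariates
  cl_z <- if (identical(cl, "true")) {
    cv$cl_z_true
  } else {
    (log(cl) - cohort$config$cl_z_ref[1]) / cohort$config$cl_z_ref[2]
  }
  enc <- encode_all(cohort$genotypes)
  n <- nrow(cv)
  split_row <- cv$tprop < cv$event_time
  mk <- function(i, start, stop, status, prop) {
    cbind(data.frame(id = cv$id[i], start = start, stop = stop,
                     status = status),
          data.frame(weight_z = cv$weight_z[i], cl_z = cl_z[i]),
          as.data.frame(enc[i, , drop = FALSE]),
          data.frame(propofol = prop))
  }
  pre <- mk(which(split_row), 0, cv$tprop[split_row], 0L, 0)
  post <- mk(which(split_row), cv$tprop[split_row],
             cv$event_time[split_row], cv$status[split_row], 1)
  whole <- mk(which(!split_row), 0, cv$event_time[!split_row],
              cv$status[!split_row], 0)
  df <- rbind(pre, post, whole)
  df <- df[order(df$id, df$stop), , drop = FALSE]
  survival_data(id = df$id, start = df$start, stop = df$stop,
                status = df$status,
                covariates = df[, c("weight_z", "cl_z",
                                    colnames(enc), "propofol")])
}

#' Calibrate the baseline hazard to the cohort landmarks
#'
#' Monte-Carlo root-finding for the piecewise-constant baseline hazard
#' levels so that, over the configured covariate distribution, the marginal
#' cohort reproduces four landmarks: cumulative incidence 8.2% at 22 min and
#' 16.3% at 90 min, a 35-min median time to first event among subjects with
#' an observed event, and an affected-subject fraction of 52/270. A fixed
#' Monte-Carlo population (covariates and exponential quantile draws) is
#' reused across hazard evaluations, making each statistic a smooth,
#' monotone function of the level being solved for; the four one-dimensional
#' root solves are iterated Gauss-Seidel style until all residuals fall
#' within tolerance.
#'
#' The median condition is equivalent to requiring the incidence at 35 min
#' to equal half the affected fraction (no censoring can occur before 60
#' min), which is how it is solved.
#'
#' @param config A [cohort_config()]; its hazard levels serve as the
#'   starting point.
#' @param targets Named numeric vector: `cuminc22`, `cuminc90`,
#'   `median_event` (min), `event_fraction`.
#' @param n_mc Monte-Carlo population size (default 120000).
#' @param seed Seed for the Monte-Carlo population.
#' @param tol Tolerance on the incidence/fraction residuals (default 0.005);
#'   the median residual tolerance is `tol_median` minutes.
#' @param tol_median Tolerance on the median landmark, minutes (default 2).
#' @param max_iter Maximum Gauss-Seidel sweeps.
#' @return A `cohort_config` equal to `config` but with calibrated
#'   `hazard_levels`, plus attributes `achieved` (the landmark values at the
#'   solution) and `trajectory` (per-sweep levels).
#' @export
calibrate_baseline <- function(config = cohort_config(),
                               targets = c(cuminc22 = 0.082,
                                           cuminc90 = 0.163,
                                           median_event = 35,
                                           event_fraction = 52 / 270),
                               n_mc = 120000, seed = 1L, tol = 0.005,
                               tol_median = 2, max_iter = 10) {
  stopifnot(inherits(config, "cohort_config"))
  if (targets["cuminc22"] >= targets["cuminc90"])
    stop("infeasible targets: cumulative incidence must increase")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pop <- .draw_population(config, n_mc)
  e <- stats::rexp(n_mc)
  knots <- config$hazard_knots
  f35_target <- unname(targets["event_fraction"] / 2)
  stats_at <- function(levels) {
    T <- .sample_event_times(e, pop$m0, pop$m1, pop$tprop, knots, levels)
    obs <- T <= pop$censor
    c(cuminc22 = mean(T <= 22), cuminc35 = mean(T <= 35),
      cuminc90 = mean(T <= 90), event_fraction = mean(obs),
      median_event = stats::median(T[obs]))
  }
  solve_level <- function(levels, i, stat, target, lower = 1e-9,
                          upper = 0.2) {
    g <- function(h) {
      levels[i] <- h
      stats_at(levels)[stat] - target
    }
    if (g(lower) > 0) { levels[i] <- lower; return(levels) }
    if (g(upper) < 0) { levels[i] <- upper; return(levels) }
    levels[i] <- stats::uniroot(g, c(lower, upper), tol = 1e-9)$root
    levels
  }
  levels <- config$hazard_levels
  traj <- list()
  for (it in seq_len(max_iter)) {
    levels <- solve_level(levels, 1, "cuminc22",
                          unname(targets["cuminc22"]))
    levels <- solve_level(levels, 2, "cuminc35", f35_target)
    levels <- solve_level(levels, 3, "cuminc90",
                          unname(targets["cuminc90"]))
    levels <- solve_level(levels, 4, "event_fraction",
                          unname(targets["event_fraction"]))
    traj[[it]] <- levels
    ach <- stats_at(levels)
    ok <- abs(ach["cuminc22"] - targets["cuminc22"]) < tol &&
      abs(ach["cuminc90"] - targets["cuminc90"]) < tol &&
      abs(ach["event_fraction"] - targets["event_fraction"]) < tol &&
      abs(ach["median_event"] - targets["median_event"]) < tol_median
    if (ok) break
  }
  if (!ok) {
    stop("baseline-hazard calibration did not converge; trajectory: ",
         paste(vapply(traj, function(l) paste(signif(l, 4), collapse = "/"),
                      character(1)), collapse = " -> "))
  }
  out <- config
  out$hazard_levels <- levels
  attr(out, "achieved") <- ach
  attr(out, "trajectory") <- traj
  out
}

#' Write a synthetic cohort to CSV files
#'
#' Writes the covariate table, genotype matrix, concentration observations
#' and a ground-truth sidecar (true PK parameters and the true effect table)
#' in the same dialects the pipeline reads.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("covariates.csv", "genotypes.csv",
                            "concentrations.csv", "snp_info.csv",
                            "true_pk.csv", "true_effects.csv"))
  utils::write.csv(cohort$covariates, paths[1], row.names = FALSE)
  gm <- cohort$genotypes
  utils::write.csv(cbind(data.frame(id = cohort$covariates$id),
                         as.data.frame(gm$genotypes)),
                   paths[2], row.names = FALSE)
  co <- cohort$conc_obs
  utils::write.csv(data.frame(subject_id = co$id, time_h = co$time_h,
                              conc_ng_ml = co$conc, bql_flag = 0L),
                   paths[3], row.names = FALSE)
  utils::write.csv(gm$info, paths[4], row.names = FALSE)
  utils::write.csv(cohort$true_pk, paths[5], row.names = FALSE)
  utils::write.csv(true_effect_table(cohort$config), paths[6],
                   row.names = FALSE)
  invisible(paths)
}
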