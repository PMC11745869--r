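#' Population pharmacokinetic model for intranasal dexmedetomidine
#'
#' Defines the fixed-effect (typical-value) covariate model of an
#' allometrically scaled two-compartment disposition model with first-order
#' absorption, together with log-normal inter-individual variability and a
#' log-scale residual error. All disposition parameters are *apparent*
#' (CL/F-style): bioavailability is folded in, as is standard after
#' extravascular dosing. Typical clearance matures with postmenstrual age
#' (PMA) through a Hill function:
#' \deqn{CL/F = CL_{ref} (W/70)^{0.75} \frac{PMA^{h}}{PMA^{h} + PMA_{50}^{h}}}
#' while volumes scale linearly with weight and the intercompartmental
#' clearance scales with exponent 0.75.
#'
#' @param cl_ref Typical apparent central clearance at 70 kg, full maturation
#'   (L/h). Default 53.0.
#' @param v_ref Typical apparent central volume at 70 kg (L). Default 57.5.
#' @param q_ref Typical apparent intercompartmental clearance at 70 kg (L/h).
#'   Default 243.8.
#' @param v2_ref Typical apparent peripheral volume at 70 kg (L). Default 71.8.
#' @param cl_exponent,q_exponent Allometric exponents for the clearances
#'   (default 0.75).
#' @param v_exponent,v2_exponent Allometric exponents for the volumes
#'   (default 1).
#' @param hill Hill coefficient of the clearance maturation function
#'   (default 3.0).
#' @param pma50 PMA at half-maximal clearance maturation, weeks (default 44.7).
#' @param ka_typical Typical first-order absorption rate constant, 1/h
#'   (default 0.38; not covariate-modelled).
#' @param omega Named numeric vector of log-normal inter-individual SDs for
#'   `cl`, `v`, `q`, `v2`, `ka` (log scale). Entries of 0 fix a parameter at
#'   its typical value.
#' @param sigma Residual error SD on the log-concentration scale.
#' @return An object of class `poppk_model`.
#' @examples
#' m <- poppk_model()
#' typical_params(m, weight = 70, pma = 1e6)$cl  # 53.0
#' @export
poppk_model <- function(cl_ref = 53.0, v_ref = 57.5, q_ref = 243.8,
                        v2_ref = 71.8,
                        cl_exponent = 0.75, q_exponent = 0.75,
                        v_exponent = 1, v2_exponent = 1,
                        hill = 3.0, pma50 = 44.7, ka_typical = 0.38,
                        omega = c(cl = 0.35, v = 0.35, q = 0, v2 = 0,
                                  ka = 0.5),
                        sigma = 0.20) {
  refs <- c(cl_ref, v_ref, q_ref, v2_ref, hill, pma50, ka_typical)
  if (any(!is.finite(refs)) || any(refs <= 0))
    stop("all reference parameters, hill and pma50 must be positive")
  om <- c(cl = 0, v = 0, q = 0, v2 = 0, ka = 0)
  om[names(omega)] <- omega
  if (any(om < 0) || sigma < 0)
    stop("omega and sigma must be non-negative")
  structure(list(cl_ref = cl_ref, v_ref = v_ref, q_ref = q_ref,
                 v2_ref = v2_ref,
                 cl_exponent = cl_exponent, q_exponent = q_exponent,
                 v_exponent = v_exponent, v2_exponent = v2_exponent,
                 hill = hill, pma50 = pma50, ka_typical = ka_typical,
                 omega = om, sigma = sigma),
            class = "poppk_model")
}

#' @export
print.poppk_model <- function(x, ...) {
  cat("Population PK model (2-compartment, first-order absorption, apparent parameters)\n")
  cat(sprintf("  CL/F = %.1f * (W/70)^%.2f * PMA^%.1f / (PMA^%.1f + %.1f^%.1f)  [L/h]\n",
              x$cl_ref, x$cl_exponent, x$hill, x$hill, x$pma50, x$hill))
  cat(sprintf("  V/F  = %.1f * (W/70)^%g [L];  Q/F = %.1f * (W/70)^%.2f [L/h];  V2/F = %.1f * (W/70)^%g [L]\n",
              x$v_ref, x$v_exponent, x$q_ref, x$q_exponent, x$v2_ref, x$v2_exponent))
  cat(sprintf("  ka (typical) = %.3g 1/h; omega = [%s]; sigma = %.3g (log scale)\n",
              x$ka_typical,
              paste(sprintf("%s %.2f", names(x$omega), x$omega), collapse = ", "),
              x$sigma))
  invisible(x)
}

#' Postmenstrual age from postnatal age
#'
#' PMA in weeks is gestational plus postnatal age. When gestational age is
#' unknown a term birth (40 weeks) is assumed.
#'
#' @param age_months Postnatal age in months.
#' @param gestational_weeks Gestational age at birth, weeks (default 40).
#' @return PMA in weeks (1 month = 365.25/84 weeks).
#' @export
pma_from_age <- function(age_months, gestational_weeks = 40) {
  gestational_weeks + age_months * 365.25 / 12 / 7
}

#' Typical (population) PK parameters for a set of covariates
#'
#' Evaluates the covariate model at a subject's weight and PMA. The
#' maturation fraction \eqn{PMA^h / (PMA^h + PMA_{50}^h)} lies in (0, 1) and
#' equals 1/2 at `pma50`.
#'
#' @param model A [poppk_model()].
#' @param weight Body weight, kg (> 0). Vectorised.
#' @param pma Postmenstrual age, weeks (> 0). Vectorised.
#' @return A list with components `cl`, `v`, `q`, `v2` (apparent, L or L/h),
#'   `ka` (1/h) and `fmat` (maturation fraction).
#' @export
typical_params <- function(model, weight, pma) {
  stopifnot(inherits(model, "poppk_model"))
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("weight must be positive")
  if (any(!is.finite(pma)) || any(pma <= 0))
    stop("pma must be positive")
  w <- weight / 70
  # PMA^h overflows for extreme PMA; compute the Hill fraction on a stable form
  fmat <- 1 / (1 + (model$pma50 / pma)^model$hill)
  list(cl = model$cl_ref * w^model$cl_exponent * fmat,
       v  = model$v_ref  * w^model$v_exponent,
       q  = model$q_ref  * w^model$q_exponent,
       v2 = model$v2_ref * w^model$v2_exponent,
       ka = rep_len(model$ka_typical, length(w)),
       fmat = fmat)
}

#' Subject-level PK parameters
#'
#' Combines typical values with log-scale deviations `eta`:
#' `cl = typical_cl * exp(eta["cl"])`, and analogously for `v`, `q`, `v2`,
#' `ka`.
#'
#' @param model A [poppk_model()].
#' @param weight,pma Subject covariates (scalars).
#' @param eta Named numeric vector of log-scale deviations; missing names are
#'   taken as 0.
#' @return An object of class `individual_pk` with fields `cl`, `v`, `q`,
#'   `v2`, `ka`, `eta`, `weight`, `pma`.
#' @export
individual_pk <- function(model, weight, pma,
                          eta = c(cl = 0, v = 0, q = 0, v2 = 0, ka = 0)) {
  tv <- typical_params(model, weight, pma)
  e <- c(cl = 0, v = 0, q = 0, v2 = 0, ka = 0)
  e[names(eta)] <- eta
  structure(list(cl = tv$cl * exp(e[["cl"]]),
                 v  = tv$v  * exp(e[["v"]]),
                 q  = tv$q  * exp(e[["q"]]),
                 v2 = tv$v2 * exp(e[["v2"]]),
                 ka = tv$ka * exp(e[["ka"]]),
                 eta = e, weight = weight, pma = pma),
            class = "individual_pk")
}

#' @export
print.individual_pk <- function(x, ...) {
  cat(sprintf("Individual PK: CL/F %.3g L/h, V/F %.3g L, Q/F %.3g L/h, V2/F %.3g L, ka %.3g 1/h\n",
              x$cl, x$v, x$q, x$v2, x$ka))
  invisible(x)
}

# Macro-constant decomposition of the analytic solution.
# Returns lambda (3 rate constants: lam1, lam2, ka) and amplitudes A such
# that C(t) = sum_i A_i exp(-lambda_i t). Near-coincident rates are
# perturbed by 1e-6 relative to avoid catastrophic cancellation.
macro_constants <- function(ind, dose) {
  cl <- ind$cl; v <- ind$v; q <- ind$q; v2 <- ind$v2; ka <- ind$ka
  if (any(c(cl, v, ka) <= 0) || q < 0 || v2 < 0)
    stop("non-positive PK parameters")
  k10 <- cl / v
  k12 <- if (v > 0) q / v else 0
  k21 <- if (v2 > 0) q / v2 else 0
  s <- k10 + k12 + k21
  disc <- sqrt(max(s * s - 4 * k10 * k21, 0))
  lam1 <- (s + disc) / 2
  lam2 <- (s - disc) / 2
  lam <- c(lam1, lam2, ka)
  # perturb coincident rates (|li - lj| < 1e-8 * li)
  for (i in 2:3) for (j in 1:(i - 1)) {
    if (abs(lam[i] - lam[j]) < 1e-8 * max(lam[i], lam[j], 1e-300))
      lam[i] <- lam[i] * (1 + 1e-6 * i)
  }
  A <- numeric(3)
  scale <- ka * dose / v
  A[1] <- scale * (k21 - lam[1]) / ((lam[3] - lam[1]) * (lam[2] - lam[1]))
  A[2] <- scale * (k21 - lam[2]) / ((lam[3] - lam[2]) * (lam[1] - lam[2]))
  A[3] <- scale * (k21 - lam[3]) / ((lam[1] - lam[3]) * (lam[2] - lam[3]))
  list(lambda = lam, A = A)
}

#' Simulate the concentration-time curve
#'
#' Analytic solution of the linear two-compartment model with first-order
#' absorption into the central compartment after a single extravascular dose
#' at time 0: a sum of three exponentials whose macro rate constants derive
#' from CL, V, Q, V2 and ka. `C(0) = 0`.
#'
#' @param ind An [individual_pk()].
#' @param dose Dose in micrograms (> 0); with apparent (CL/F) parameters the
#'   administered dose is used directly.
#' @param times Times post-dose, hours (>= 0). Vectorised.
#' @return Concentrations in ug/L (= ng/mL), same length as `times`.
#' @export
simulate_concentration <- function(ind, dose, times) {
  stopifnot(inherits(ind, "individual_pk"))
  if (!is.finite(dose) || dose <= 0) stop("dose must be positive")
  if (any(times < 0)) stop("times must be non-negative")
  mc <- macro_constants(ind, dose)
  out <- drop(exp(-outer(times, mc$lambda)) %*% mc$A)
  # the three amplitudes cancel exactly at t = 0; clamp the round-off
  out[times == 0] <- 0
  pmax(out, 0)
}

# log-posterior (negative) over eta for MAP estimation
.map_objective <- function(eta_free, free, model, weight, pma,
                           obs_time, obs_conc, dose) {
  eta <- c(cl = 0, v = 0, q = 0, v2 = 0, ka = 0)
  eta[free] <- eta_free
  ind <- individual_pk(model, weight, pma, eta)
  pred <- simulate_concentration(ind, dose, obs_time)
  if (any(pred <= 0)) return(1e10)
  r <- log(obs_conc) - log(pred)
  0.5 * sum(r^2) / model$sigma^2 +
    0.5 * sum((eta[free] / model$omega[free])^2)
}

#' MAP (empirical-Bayes) estimation of individual PK parameters
#'
#' Maximizes the log-posterior combining the log-normal population prior on
#' the individual deviations `eta` with a log-normal residual likelihood for
#' the observed concentrations:
#' \deqn{-\tfrac12 \sum_{obs} (\log c_{obs} - \log c_{pred})^2/\sigma^2
#'       - \tfrac12 \sum_{par} \eta^2/\omega^2.}
#' Only parameters with `omega > 0` are estimated; with all `omega = 0` the
#' typical values are returned. Optimization is quasi-Newton (BFGS) from a
#' fixed set of five start points, making the result deterministic.
#'
#' @param model A [poppk_model()].
#' @param obs_time,obs_conc Quantifiable observations: times (h, post-dose)
#'   and concentrations (ug/L). Pre-dose (time 0) samples only verify drug
#'   absence and are dropped from the likelihood.
#' @param dose Dose, ug.
#' @param weight,pma Subject covariates.
#' @return An `individual_pk` with extra fields `objective`, `converged`,
#'   `n_obs` and `starts` (objective value per start, diagnostics).
#' @export
map_estimate <- function(model, obs_time, obs_conc, dose, weight, pma) {
  stopifnot(inherits(model, "poppk_model"))
  keep <- obs_time > 0 & is.finite(obs_conc) & obs_conc > 0
  obs_time <- obs_time[keep]; obs_conc <- obs_conc[keep]
  if (length(obs_time) < 1)
    stop("at least one quantifiable post-dose observation is required")
  free <- names(model$omega)[model$omega > 0]
  if (length(free) == 0) {
    out <- individual_pk(model, weight, pma)
    out$objective <- .map_objective(numeric(0), character(0), model,
                                    weight, pma, obs_time, obs_conc, dose)
    out$converged <- TRUE
    out$n_obs <- length(obs_time)
    return(out)
  }
  starts <- c(0, 0.3, -0.3, 0.6, -0.6)  # applied to every free eta
  best <- NULL
  diag_obj <- numeric(length(starts))
  for (s in seq_along(starts)) {
    fit <- stats::optim(rep(starts[s], length(free)), .map_objective,
                        free = free, model = model, weight = weight,
                        pma = pma, obs_time = obs_time, obs_conc = obs_conc,
                        dose = dose, method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 1000))
    diag_obj[s] <- fit$value
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  eta <- stats::setNames(best$par, free)
  out <- individual_pk(model, weight, pma, eta)
  out$objective <- best$value
  out$converged <- best$convergence == 0
  if (!out$converged)
    warning("MAP optimizer did not converge (optim code ",
            best$convergence, ")")
  out$n_obs <- length(obs_time)
  out$starts <- diag_obj
  out
}

#' Derived exposure metrics from an individual PK curve
#'
#' Computes the peak (`cmax`, `tmax`) by bracketed 1-D maximization of the
#' analytic curve, the terminal half-life from the smallest macro rate
#' constant (including `ka`, so flip-flop kinetics report the absorption
#' slope as a non-compartmental terminal fit would), partial AUCs by
#' closed-form exponential integration, and `auc_inf = dose / cl`.
#'
#' @param ind An [individual_pk()].
#' @param dose Dose, ug.
#' @return A list with `cmax` (ug/L), `tmax` (h), `t_half` (h),
#'   `auc_0_0p5`, `auc_0_1`, `auc_0_2`, `auc_inf` (ug*h/L), `cl` (L/h),
#'   `v` (L), and per-kg versions `cl_per_kg`, `v_per_kg`.
#' @export
derive_metrics <- function(ind, dose) {
  stopifnot(inherits(ind, "individual_pk"))
  mc <- macro_constants(ind, dose)
  lam_min <- min(mc$lambda)
  t_half <- log(2) / lam_min
  cfun <- function(t) drop(exp(-outer(t, mc$lambda)) %*% mc$A)
  # bracket the peak on a coarse grid, then refine
  grid <- exp(seq(log(1e-3), log(12 * t_half), length.out = 400))
  cg <- cfun(grid)
  i <- which.max(cg)
  lo <- grid[max(i - 1, 1)]; hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(cfun, c(lo, hi), maximum = TRUE, tol = 1e-9)
  auc_t <- function(t) sum(mc$A * (1 - exp(-mc$lambda * t)) / mc$lambda)
  list(cmax = opt$objective, tmax = opt$maximum, t_half = t_half,
       auc_0_0p5 = auc_t(0.5), auc_0_1 = auc_t(1), auc_0_2 = auc_t(2),
       auc_inf = dose / ind$cl,
       cl = ind$cl, v = ind$v,
       cl_per_kg = ind$cl / ind$weight, v_per_kg = ind$v / ind$weight)
}
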