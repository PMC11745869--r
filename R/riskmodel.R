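#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' `AuROC = (sum of positive-class ranks - n1(n1+1)/2) / (n1 * n0)` with
#' midranks, which applies the standard tie correction.
#'
#' @param scores Numeric risk scores (higher = more at risk).
#' @param labels Binary outcome labels (0/1 or logical).
#' @return The AuROC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-optimal classification threshold
#'
#' Scans the midpoints between adjacent distinct scores and returns the
#' threshold maximizing Youden's J = sensitivity + specificity - 1, with
#' subjects classified positive when `score >= threshold`. Ties in J are
#' broken toward the higher threshold (higher specificity).
#'
#' @inheritParams roc_auc
#' @return A list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  sens <- vapply(cand, function(th) mean(scores[labels == 1] >= th),
                 numeric(1))
  spec <- vapply(cand, function(th) mean(scores[labels == 0] < th),
                 numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[length(best)]  # highest threshold among ties
  list(threshold = cand[pick], sensitivity = sens[pick],
       specificity = spec[pick], youden = j[pick])
}

#' Breslow baseline cumulative hazard of a fitted Cox model
#'
#' `H0(t) = sum over event times up to t of d_k / S0_k(beta-hat)`, the
#' standard profile estimator accompanying the partial likelihood; the
#' baseline corresponds to all covariates at zero.
#'
#' @param fit A [cox_fit()].
#' @param data The [survival_data()] used for the fit.
#' @return A data.frame (`time`, `hazard`, `cumhaz`) of class
#'   `breslow_hazard`.
#' @export
breslow_basehaz <- function(fit, data) {
  stopifnot(inherits(fit, "cox_fit"), inherits(data, "survival_data"))
  prep <- .cox_prep(data, fit$covariates)
  r <- exp(drop(prep$X %*% fit$coefficients))
  S0 <- .risk_sums(prep, r)[, 1]
  f <- as.integer(factor(prep$stop[prep$ev], levels = prep$et))
  dk <- tabulate(f, nbins = length(prep$et))
  out <- data.frame(time = prep$et, hazard = dk / S0,
                    cumhaz = cumsum(dk / S0))
  class(out) <- c("breslow_hazard", "data.frame")
  out
}

# step-function evaluation of the cumulative hazard
.cumhaz_at <- function(bh, times) {
  idx <- findInterval(times, bh$time)
  c(0, bh$cumhaz)[idx + 1]
}

#' Build a nomogram from a fitted Cox model
#'
#' Assigns each covariate a linear point scale anchored at its least-risk
#' observed value (the covariate value minimizing `beta * x` over the
#' observed range contributes 0 points) and scaled so the covariate with the
#' largest absolute contribution `|beta * range|` spans exactly 0-100
#' points. Total points map affinely back to the linear predictor, and the
#' event probability by a time horizon follows from the Breslow baseline:
#' `risk(t) = 1 - S0(t)^exp(lp)`.
#'
#' @param fit A converged [cox_fit()].
#' @param data The [survival_data()] used for the fit (supplies observed
#'   covariate ranges and the baseline hazard).
#' @param horizon Risk horizon in the dataset's time unit (default 90, the
#'   usual minutes-scale reporting horizon here).
#' @return An object of class `nomogram`: `points_table` (per covariate:
#'   beta, observed range, reference value, points per unit),
#'   `points_per_lp` (scale), `lp_ref`, `basehaz`, `horizon`, `threshold`
#'   (NULL until set).
#' @export
build_nomogram <- function(fit, data, horizon = 90) {
  stopifnot(inherits(fit, "cox_fit"))
  if (!fit$converged) stop("build_nomogram requires a converged fit")
  X <- as.matrix(as.data.frame(data)[, fit$covariates, drop = FALSE])
  beta <- fit$coefficients
  rng <- apply(X, 2, range)
  span <- abs(beta * (rng[2, ] - rng[1, ]))
  keep <- span > 0
  if (!all(keep)) {
    warning("zero-range covariate(s) excluded from the nomogram: ",
            paste(fit$covariates[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no covariate with a nonzero point span")
  scale <- max(span[keep])
  ref <- ifelse(beta >= 0, rng[1, ], rng[2, ])  # value minimizing beta*x
  tab <- data.frame(covariate = fit$covariates, beta = unname(beta),
                    min = rng[1, ], max = rng[2, ], ref = unname(ref),
                    points_per_unit = unname(100 * beta / scale),
                    max_points = unname(100 * span / scale))[keep, ]
  rownames(tab) <- NULL
  structure(list(points_table = tab,
                 points_per_lp = 100 / scale,
                 lp_ref = sum(beta[keep] * ref[keep]),
                 excluded = fit$covariates[!keep],
                 basehaz = breslow_basehaz(fit, data),
                 horizon = horizon, threshold = NULL,
                 covariates = fit$covariates[keep]),
            class = "nomogram")
}

#' @export
print.nomogram <- function(x, ...) {
  cat(sprintf("Cox-derived nomogram (risk horizon %g):\n", x$horizon))
  print(format(x$points_table, digits = 3), row.names = FALSE)
  if (!is.null(x$threshold))
    cat(sprintf("decision threshold (Youden): risk %.3f\n", x$threshold))
  invisible(x)
}

#' Nomogram points for new subjects
#'
#' @param nomogram A [build_nomogram()] result.
#' @param newdata data.frame with the nomogram covariates.
#' @return A list with `points` (matrix, per covariate) and `total`.
#' @export
nomogram_points <- function(nomogram, newdata) {
  tab <- nomogram$points_table
  X <- as.matrix(as.data.frame(newdata)[, tab$covariate, drop = FALSE])
  pts <- sweep(X, 2, tab$ref) %*% diag(tab$points_per_unit,
                                       nrow = nrow(tab))
  colnames(pts) <- tab$covariate
  list(points = pts, total = rowSums(pts))
}

#' Predicted event risk by the horizon
#'
#' Maps total nomogram points back to the linear predictor and through the
#' Breslow baseline survival: `risk = 1 - exp(-H0(t))^exp(lp)`, a strictly
#' increasing function of total points.
#'
#' @param nomogram A [build_nomogram()] result.
#' @param total_points Numeric vector of total points (from
#'   [nomogram_points()]).
#' @param horizon Risk horizon; defaults to the nomogram's.
#' @return Event probabilities in \[0, 1\].
#' @export
nomogram_risk <- function(nomogram, total_points, horizon = nomogram$horizon) {
  lp <- total_points / nomogram$points_per_lp + nomogram$lp_ref
  H0 <- .cumhaz_at(nomogram$basehaz, horizon)
  1 - exp(-H0 * exp(lp))
}

#' Calibration curve of nomogram-predicted risk
#'
#' Bins subjects by predicted-risk quantiles and compares the mean predicted
#' risk per bin with the Kaplan-Meier observed risk (1 - KM survival at the
#' horizon, which accommodates censoring) plus a bootstrap percentile CI.
#' Bins collapsing to fewer than two distinct predictions are merged with
#' their neighbor.
#'
#' @param nomogram A [build_nomogram()] result.
#' @param data A [survival_data()] to calibrate on.
#' @param horizon Risk horizon (defaults to the nomogram's).
#' @param n_bins Number of quantile bins (default 10).
#' @param n_boot Bootstrap replicates for the CI (default 200).
#' @param seed Seed for the bootstrap.
#' @return A data.frame of class `calibration_curve` with one row per bin:
#'   `n`, `predicted` (mean), `observed` (KM risk), `lower`, `upper`.
#' @export
calibration_curve <- function(nomogram, data, horizon = nomogram$horizon,
                              n_bins = 10, n_boot = 200, seed = 1L) {
  subj <- .subject_level(data, nomogram$points_table$covariate)
  if (nrow(subj) < n_bins * 5)
    stop("need at least ", n_bins * 5, " subjects for ", n_bins, " bins")
  pred <- nomogram_risk(nomogram,
                        nomogram_points(nomogram, subj)$total, horizon)
  br <- unique(stats::quantile(pred, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 3) {
    bin <- rep(1L, length(pred))  # degenerate: all predictions equal
  } else {
    bin <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km_risk <- function(time, event) {
    sd <- survival_data(id = seq_along(time), stop = time, status = event)
    km_at(km_estimate(sd), horizon, "cuminc")
  }
  rows <- lapply(sort(unique(bin)), function(b) {
    i <- which(bin == b)
    obs <- km_risk(subj$time[i], subj$event[i])
    boots <- vapply(seq_len(n_boot), function(r) {
      j <- sample(i, length(i), replace = TRUE)
      km_risk(subj$time[j], subj$event[j])
    }, numeric(1))
    data.frame(bin = b, n = length(i), predicted = mean(pred[i]),
               observed = obs,
               lower = unname(stats::quantile(boots, 0.025)),
               upper = unname(stats::quantile(boots, 0.975)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_curve", "data.frame")
  out
}

#' Calibration slope across bins
#'
#' Least-squares slope of observed on predicted bin risks; 1 indicates
#' perfect calibration-in-the-large alongside an intercept near 0.
#'
#' @param curve A [calibration_curve()].
#' @return Numeric slope.
#' @export
calibration_slope <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  unname(stats::coef(stats::lm(observed ~ predicted, data = curve))[2])
}
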