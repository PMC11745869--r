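test_that("rank-formula AuROC equals the all-pairs brute force", {
  set.seed(3)
  scores <- round(rnorm(50), 1)  # rounding forces ties
  labels <- rbinom(50, 1, 0.4)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(roc_auc(scores, labels), mean(pairs))
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(exp(scores), labels), roc_auc(scores, labels))
  expect_equal(roc_auc(rank(scores), labels), roc_auc(scores, labels))
  # null scores give AuROC near 1/2
  set.seed(4)
  s <- rnorm(1000); l <- rbinom(1000, 1, 0.5)
  expect_lt(abs(roc_auc(s, l) - 0.5), 0.05)
  expect_error(roc_auc(s, rep(1, 1000)), "both")
})

test_that("Youden threshold maximizes J over the midpoint set", {
  set.seed(8)
  scores <- rnorm(80)
  labels <- rbinom(80, 1, plogis(2 * scores))
  yt <- youden_threshold(scores, labels)
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(th)
    mean(scores[labels == 1] >= th) + mean(scores[labels == 0] < th) - 1,
    numeric(1))
  expect_equal(yt$youden, max(j))
  # tie-break toward higher specificity = higher threshold
  best <- cand[j >= max(j) - 1e-12]
  expect_equal(yt$threshold, max(best))
  # perfect separation
  yp <- youden_threshold(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1))
  expect_equal(yp$youden, 1)
  expect_true(yp$threshold > 3 && yp$threshold < 10)
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
})

test_that("nomogram anchors, scaling and proportional-hazards property hold", {
  co <- generate_cohort(cohort_config(n = 400), seed = 21)
  d <- cohort_survival_data(co)
  fit <- cox_fit(d, c("weight_z", "cl_z", "rs8192733"))
  nom <- build_nomogram(fit, d, horizon = 90)
  tab <- nom$points_table
  # covariate at its reference value contributes 0 points
  ref_row <- as.data.frame(as.list(setNames(tab$ref, tab$covariate)))
  expect_equal(unname(nomogram_points(nom, ref_row)$total), 0)
  # the widest-contribution covariate spans exactly 100 points
  expect_equal(max(tab$max_points), 100)
  expect_true(all(tab$max_points <= 100 + 1e-9))
  # risk is strictly increasing in total points (monotone bijection)
  tp <- seq(0, sum(tab$max_points), length.out = 50)
  risk <- nomogram_risk(nom, tp)
  expect_true(all(diff(risk) > 0))
  expect_true(all(risk >= 0 & risk <= 1))
  # PH property: a binary covariate with beta = ln 2 doubles the
  # cumulative hazard
  fit2 <- fit
  fit2$coefficients["rs8192733"] <- log(2)
  nom2 <- build_nomogram(fit2, d, horizon = 90)
  sub0 <- data.frame(weight_z = 0, cl_z = 0, rs8192733 = 0)
  sub1 <- data.frame(weight_z = 0, cl_z = 0, rs8192733 = 1)
  H <- function(s) -log(1 - nomogram_risk(nom2,
                                          nomogram_points(nom2, s)$total))
  expect_equal(H(sub1) / H(sub0), 2, tolerance = 1e-9)
})

test_that("well-specified data calibrate on the identity", {
  # simulate survival from the model the nomogram encodes, then check the
  # calibration slope across bins is ~1
  co <- generate_cohort(cohort_config(n = 500), seed = 77)
  d <- cohort_survival_data(co)
  fit <- cox_fit(d, c("weight_z", "cl_z", "rs8192733", "rs10764319"))
  nom <- build_nomogram(fit, d, horizon = 90)
  bh <- nom$basehaz
  set.seed(42)
  df0 <- dexhdi:::.subject_level(d, fit$covariates)
  df <- df0[rep(seq_len(nrow(df0)), 3), ]  # 3 draws per covariate profile
  df$id <- seq_len(nrow(df))
  lp <- as.matrix(df[, fit$covariates]) %*% fit$coefficients
  e <- rexp(nrow(df)) / exp(lp)
  # invert the Breslow step cumulative hazard
  idx <- findInterval(e, c(0, bh$cumhaz), left.open = FALSE)
  t_new <- c(bh$time, Inf)[pmax(idx, 1)]
  cens <- runif(nrow(df), 95, 150)
  sim <- survival_data(df$id, stop = pmin(t_new, cens, 200),
                       status = as.integer(t_new <= cens),
                       covariates = df[, fit$covariates])
  curve <- calibration_curve(nom, sim, n_bins = 10, n_boot = 50, seed = 1)
  expect_equal(calibration_slope(curve), 1, tolerance = 0.15)
  expect_true(all(curve$lower <= curve$upper))
})

test_that("degenerate calibration inputs collapse to the marginal risk", {
  co <- generate_cohort(cohort_config(n = 300), seed = 31)
  d <- cohort_survival_data(co)
  fit <- cox_fit(d, c("weight_z", "cl_z"))
  nom <- build_nomogram(fit, d, horizon = 90)
  # constant predictions: a single bin whose observed risk is the marginal KM
  nom0 <- nom
  nom0$points_table$points_per_unit <- 0
  nom0$points_per_lp <- 1e9  # flat map: all subjects get the same risk
  curve <- calibration_curve(nom0, d, n_bins = 10, n_boot = 20, seed = 2)
  expect_equal(nrow(curve), 1)
  subj <- dexhdi:::.subject_level(d, character(0))
  km <- km_estimate(survival_data(subj$id, stop = subj$time,
                                  status = subj$event))
  expect_equal(curve$observed, km_at(km, 90, "cuminc"))
  # shifting every linear predictor upward inflates predicted risk but,
  # since the quantile bins are shift-invariant, leaves observed risk alone
  curve1 <- calibration_curve(nom, d, n_bins = 5, n_boot = 20, seed = 3)
  nom_hi <- nom
  nom_hi$lp_ref <- nom$lp_ref + 0.7
  curve2 <- calibration_curve(nom_hi, d, n_bins = 5, n_boot = 20, seed = 3)
  expect_equal(curve2$observed, curve1$observed)
  expect_true(all(curve2$predicted > curve1$predicted))
})
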