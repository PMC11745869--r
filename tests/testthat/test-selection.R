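test_that("60/40 split is exact, disjoint, exhaustive and reproducible", {
  co <- generate_cohort(cohort_config(), seed = 101)
  d <- cohort_survival_data(co)
  sp <- split_cohort(d, 0.6, seed = 5)
  expect_length(sp$train_ids, 162)
  expect_length(sp$test_ids, 108)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), co$covariates$id)
  expect_identical(sp, split_cohort(d, 0.6, seed = 5))
  expect_false(identical(sp, split_cohort(d, 0.6, seed = 6)))
  # stratification keeps event fractions close
  ev <- co$covariates$status
  f_tr <- mean(ev[co$covariates$id %in% sp$train_ids])
  f_te <- mean(ev[co$covariates$id %in% sp$test_ids])
  expect_lt(abs(f_tr - f_te), 0.02)
})

test_that("penalty dominates at lambda_max: the first path solution is null", {
  co <- generate_cohort(cohort_config(n = 200), seed = 7)
  d <- cohort_rc_data(co)
  p <- lasso_cox_path(d)
  expect_true(all(p$beta[, 1] == 0))
  expect_true(any(p$beta[, length(p$lambda)] != 0))
  # an explicit lambda above lambda_max keeps every coefficient at zero
  p2 <- lasso_cox_path(d, lambda = c(2 * max(p$lambda), max(p$lambda)))
  expect_true(all(p2$beta == 0))
})

test_that("the penalized path approaches the unpenalized fit as lambda -> 0", {
  set.seed(31)
  n <- 600
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  t <- rexp(n, 0.1 * exp(x %*% c(0.6, -0.5, 0.3, 0)))
  c0 <- runif(n, 3, 25)
  d <- survival_data(1:n, stop = pmin(t, c0),
                     status = as.integer(t <= c0),
                     covariates = as.data.frame(x))
  f <- cox_fit(d, ties = "breslow")
  p <- lasso_cox_path(d, lambda = c(0.05, 0.001, 1e-6), thresh = 1e-14)
  expect_equal(unname(p$beta[, 3]), unname(f$coefficients),
               tolerance = 0.01)
})

test_that("a strong predictor enters the path before noise covariates", {
  set.seed(17)
  wins <- 0
  for (r in 1:50) {
    n <- 500
    x <- matrix(rnorm(n * 21), n, 21,
                dimnames = list(NULL, c("true", paste0("n", 1:20))))
    t <- rexp(n, 0.1 * exp(log(3) * x[, 1]))
    c0 <- runif(n, 2, 20)
    d <- survival_data(1:n, stop = pmin(t, c0),
                       status = as.integer(t <= c0),
                       covariates = as.data.frame(x))
    p <- lasso_cox_path(d, nlambda = 60)
    entry <- apply(p$beta != 0, 1, function(row)
      if (any(row)) which(row)[1] else Inf)
    wins <- wins + (which.min(entry) == 1 &&
                      entry[1] < min(entry[-1]))
  }
  expect_gte(wins, 45)  # >= 90% of datasets
})

test_that("selection frequencies are reproducible, bounded and rank signal over noise", {
  set.seed(23)
  n <- 300
  x <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("sig", paste0("noise", 1:5))))
  t <- rexp(n, 0.1 * exp(log(2) * x[, 1]))
  c0 <- runif(n, 2, 25)
  d <- survival_data(1:n, stop = pmin(t, c0),
                     status = as.integer(t <= c0),
                     covariates = as.data.frame(x))
  s1 <- selection_frequency(d, n_repeats = 10, seed = 44)
  s2 <- selection_frequency(d, n_repeats = 10, seed = 44)
  expect_identical(s1$frequency, s2$frequency)
  expect_true(all(s1$frequency >= 0 & s1$frequency <= 1))
  expect_equal(s1$ranked[1], "sig")
  expect_true(all(s1$frequency["sig"] >= s1$frequency[-1]))
  # the iteration budget caps contributing fits
  s3 <- selection_frequency(d, n_repeats = 10, k = 5, n_iterations = 12,
                            seed = 44)
  expect_lte(s3$n_iterations, 12)
})

test_that("duplicating a variable does not lose its selection signal", {
  set.seed(29)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, c("sig", paste0("noise", 1:3))))
  t <- rexp(n, 0.1 * exp(log(2.5) * x[, 1]))
  c0 <- runif(n, 2, 25)
  base <- survival_data(1:n, stop = pmin(t, c0),
                        status = as.integer(t <= c0),
                        covariates = as.data.frame(x))
  f_base <- selection_frequency(base, n_repeats = 8, seed = 3)$frequency
  xx <- cbind(x, sig_copy = x[, "sig"])
  dup <- survival_data(1:n, stop = pmin(t, c0),
                       status = as.integer(t <= c0),
                       covariates = as.data.frame(xx))
  f_dup <- selection_frequency(dup, n_repeats = 8, seed = 3)$frequency
  expect_gte(f_dup[["sig"]] + f_dup[["sig_copy"]], f_base[["sig"]] - 1e-9)
})

test_that("progressive addition finds the informative variable and stops", {
  set.seed(37)
  hits <- 0
  for (r in 1:50) {
    n <- 408
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, c("sig", paste0("noise", 1:4))))
    t <- rexp(n, 0.08 * exp(log(3) * x[, 1]))
    c0 <- runif(n, 2, 25)
    d <- survival_data(1:n, stop = pmin(t, c0),
                       status = as.integer(t <= c0),
                       covariates = as.data.frame(x))
    sp <- split_cohort(d, 0.6, seed = r)
    pr <- progressive_addition(c("sig", paste0("noise", 1:4)),
                               subset_subjects(d, sp$train_ids),
                               subset_subjects(d, sp$test_ids))
    hits <- hits + identical(pr$chosen, "sig")
    expect_lte(length(pr$auroc), 5)  # trajectory bounded by candidates
  }
  expect_gt(hits, 25)  # majority of simulations
})

test_that("the whole selection procedure is a pure function of data and seed", {
  co <- generate_cohort(cohort_config(n = 150), seed = 55)
  d <- cohort_rc_data(co)
  r1 <- selection_frequency(d, n_repeats = 3, seed = 9)
  r2 <- selection_frequency(d, n_repeats = 3, seed = 9)
  expect_identical(r1$ranked, r2$ranked)
  expect_identical(r1$lambda_chosen, r2$lambda_chosen)
})
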