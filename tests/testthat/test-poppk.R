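test_that("typical-value covariate model reproduces its reference points", {
  m <- poppk_model()
  # full maturation at the 70-kg reference returns the reference parameters
  tp <- typical_params(m, weight = 70, pma = 1e6)
  expect_equal(tp$cl, 53.0, tolerance = 1e-9)
  expect_equal(tp$q, 243.8)
  expect_equal(tp$v, 57.5)
  expect_equal(tp$v2, 71.8)
  # Hill midpoint: maturation fraction is exactly 1/2 at pma50
  mid <- typical_params(m, weight = 70, pma = 44.7)
  expect_equal(mid$fmat, 0.5)
  expect_equal(mid$cl, 26.5)
  expect_error(typical_params(m, -1, 50), "weight")
  expect_error(typical_params(m, 10, 0), "pma")
})

test_that("clearance increases in weight and PMA; volumes in weight", {
  m <- poppk_model()
  set.seed(1)
  for (i in 1:50) {
    w <- runif(1, 3, 60); pma <- runif(1, 30, 300)
    a <- typical_params(m, w, pma)
    b <- typical_params(m, w * 1.1, pma)
    cc <- typical_params(m, w, pma * 1.1)
    expect_gt(b$cl, a$cl); expect_gt(cc$cl, a$cl)
    expect_gt(b$v, a$v); expect_gt(b$q, a$q); expect_gt(b$v2, a$v2)
    expect_true(a$fmat > 0 && a$fmat < 1)
  }
})

test_that("analytic two-compartment solution matches a high-accuracy ODE", {
  ind <- oracle_individual()
  times <- c(0.1, 0.25, 0.5, 1, 2, 4, 8)
  expect_equal(simulate_concentration(ind, 33, times),
               ode_concentration(ind, 33, times), tolerance = 1e-6)
  expect_identical(simulate_concentration(ind, 33, 0), 0)
  # property: agreement over random parameter draws
  m <- poppk_model()
  set.seed(42)
  for (i in 1:40) {
    ind <- individual_pk(m, runif(1, 5, 40), runif(1, 45, 200),
                         eta = c(cl = rnorm(1, 0, 0.4), v = rnorm(1, 0, 0.4),
                                 ka = rnorm(1, 0, 0.5)))
    ind$q <- ind$q * exp(rnorm(1, 0, 0.4))
    ind$v2 <- ind$v2 * exp(rnorm(1, 0, 0.4))
    dose <- runif(1, 10, 200)
    ana <- simulate_concentration(ind, dose, times)
    ode <- ode_concentration(ind, dose, times)
    expect_equal(ana, ode, tolerance = 1e-6)
  }
})

test_that("degenerate no-peripheral limit reduces to the one-compartment form", {
  m <- poppk_model()
  ind <- individual_pk(m, 11, 130)
  ind$cl <- 10; ind$v <- 8; ind$q <- 0; ind$v2 <- 1e-9; ind$ka <- 0.38
  ke <- ind$cl / ind$v
  t <- c(0.5, 1, 3)
  one_cpt <- (ind$ka * 33 / ind$v) / (ind$ka - ke) *
    (exp(-ke * t) - exp(-ind$ka * t))
  expect_equal(simulate_concentration(ind, 33, t), one_cpt,
               tolerance = 1e-6)
})

test_that("derived exposure metrics match closed forms and grid oracles", {
  ind <- oracle_individual()
  ind$cl <- 11
  met <- derive_metrics(ind, 33)
  expect_equal(met$auc_inf, 3.0)  # dose / CL
  expect_true(met$auc_0_0p5 <= met$auc_0_1)
  expect_true(met$auc_0_1 <= met$auc_0_2)
  expect_true(met$auc_0_2 < met$auc_inf)
  # tmax against a dense grid
  grid <- seq(1e-4, 20, length.out = 1e5)
  cg <- simulate_concentration(ind, 33, grid)
  expect_lt(abs(met$tmax - grid[which.max(cg)]), 0.01)
  expect_gte(met$cmax, max(cg))
  # AUC_inf closed form vs numeric integration far into the tail
  num <- stats::integrate(function(t) simulate_concentration(ind, 33, t),
                          0, 200 * met$t_half, rel.tol = 1e-9,
                          subdivisions = 2000)$value
  expect_equal(met$auc_inf, num, tolerance = 1e-3)
  # terminal slope from the smallest macro constant (flip-flop aware)
  mc <- dexhdi:::macro_constants(ind, 33)
  expect_equal(met$t_half, log(2) / min(mc$lambda))
})

test_that("MAP estimation collapses to typical values with zero-width priors", {
  m0 <- poppk_model(omega = c(cl = 0, v = 0, q = 0, v2 = 0, ka = 0))
  tv <- typical_params(m0, 11, 130)
  fit <- map_estimate(m0, obs_time = 1, obs_conc = 0.5, dose = 33,
                      weight = 11, pma = 130)
  expect_identical(unname(fit$cl), unname(tv$cl))
  expect_identical(unname(fit$eta), rep(0, 5))
})

test_that("MAP solution matches a dense 1-D grid search of the posterior", {
  # single observation 20% above the typical prediction, only omega_cl free
  m <- poppk_model(omega = c(cl = 0.35, v = 0, q = 0, v2 = 0, ka = 0))
  tv_ind <- individual_pk(m, 11, 130)
  c_typ <- simulate_concentration(tv_ind, 33, 1)
  obs <- 1.2 * c_typ
  fit <- map_estimate(m, 1, obs, 33, 11, 130)
  # higher-than-typical concentration implies lower-than-typical clearance
  expect_lt(fit$cl, tv_ind$cl)
  obj <- function(eta_cl) {
    ind <- individual_pk(m, 11, 130, c(cl = eta_cl))
    pred <- simulate_concentration(ind, 33, 1)
    0.5 * (log(obs) - log(pred))^2 / m$sigma^2 +
      0.5 * eta_cl^2 / m$omega[["cl"]]^2
  }
  grid <- seq(-1.5, 1.5, by = 1e-4)
  vals <- vapply(grid, obj, numeric(1))
  expect_lt(abs(fit$eta[["cl"]] - grid[which.min(vals)]), 1e-4)
  expect_lte(fit$objective, min(vals) + 1e-8)
  # objective at the optimum is below random nearby perturbations
  set.seed(7)
  nearby <- fit$eta[["cl"]] + rnorm(1000, 0, 0.05)
  expect_true(all(fit$objective <= vapply(nearby, obj, numeric(1)) + 1e-10))
})

test_that("MAP recovers clearance with shrinkage toward typical values", {
  m <- poppk_model(omega = c(cl = 0.35, v = 0, q = 0, v2 = 0, ka = 0),
                   sigma = 0.10)
  set.seed(99)
  n <- 200
  eta_true <- rnorm(n, 0, 0.35)
  w <- runif(n, 6, 25); pma <- runif(n, 50, 300)
  est <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    ind <- individual_pk(m, w[i], pma[i], c(cl = eta_true[i]))
    cobs <- simulate_concentration(ind, 3 * w[i], 1) *
      exp(rnorm(1, 0, m$sigma))
    fit <- map_estimate(m, 1, cobs, 3 * w[i], w[i], pma[i])
    est[i, ] <- c(ind$cl, fit$cl)
  }
  # MAP clearance tracks the simulated truth
  slope <- coef(lm(log(est[, 2]) ~ log(est[, 1])))[2]
  expect_gt(slope, 0.2)
  # larger residual noise shrinks eta harder toward zero
  m_noisy <- poppk_model(omega = c(cl = 0.35, v = 0, q = 0, v2 = 0, ka = 0),
                         sigma = 0.60)
  ind <- individual_pk(m, 11, 130, c(cl = 0.5))
  cobs <- simulate_concentration(ind, 33, 1)
  eta_tight <- map_estimate(m, 1, cobs, 33, 11, 130)$eta[["cl"]]
  eta_loose <- map_estimate(m_noisy, 1, cobs, 33, 11, 130)$eta[["cl"]]
  expect_lt(abs(eta_loose), abs(eta_tight))
})
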