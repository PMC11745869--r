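test_that("Kaplan-Meier reproduces the hand product-limit computation", {
  d <- survival_data(1:4, stop = c(10, 15, 20, 30),
                     status = c(1, 0, 1, 0))
  km <- km_estimate(d)
  # S(10) = 3/4; at t=20 two at risk, one event: S(20) = 0.75 * 0.5
  expect_equal(km_at(km, 10), 0.75)
  expect_equal(km_at(km, 20), 0.375)
  expect_equal(km_at(km, 20, "cuminc"), 0.625)
  # all censored: cumulative incidence identically zero
  d0 <- survival_data(1:4, stop = c(10, 15, 20, 30), status = rep(0, 4))
  expect_equal(km_at(km_estimate(d0), c(5, 50), "cuminc"), c(0, 0))
  # no censoring: survivor complement of the ECDF
  set.seed(5)
  t <- rexp(60, 0.2)
  dn <- survival_data(1:60, stop = t, status = rep(1, 60))
  kmn <- km_estimate(dn)
  at <- c(1, 3, 7)
  expect_equal(km_at(kmn, at), 1 - ecdf(t)(at))
})

test_that("Cox Newton solution matches a dense 1-D partial-likelihood grid", {
  d <- survival_data(1:6, stop = c(1, 2, 3, 4, 5, 6),
                     status = c(1, 1, 0, 1, 1, 0),
                     covariates = data.frame(x = c(1, 0, 1, 0, 1, 0)))
  fit <- cox_fit(d, "x")
  grid <- seq(-3, 3, by = 1e-4)
  ll <- cox_loglik(d, "x", matrix(grid, nrow = 1), ties = "efron")
  expect_lt(abs(fit$coefficients[["x"]] - grid[which.max(ll)]), 1e-4)
  expect_lt(fit$score_norm, 1e-6)  # first-order condition at the optimum
})

test_that("Cox solver agrees with the survival package on untied and tied data", {
  d <- make_rc_data(300, seed = 42)
  f <- cox_fit(d)
  g <- survival::coxph(survival::Surv(stop, status) ~ x + z,
                       data = as.data.frame(d), ties = "efron")
  expect_equal(unname(f$coefficients), unname(coef(g)), tolerance = 1e-7)
  expect_equal(unname(diag(f$var)), unname(diag(vcov(g))), tolerance = 1e-6)
  # tied, time-dependent (start, stop] data, both tie corrections
  set.seed(7)
  n <- 150
  x <- rnorm(n); tp <- runif(n, 1, 4)
  t <- ceiling(rexp(n, 0.1 * exp(0.4 * x)))
  c0 <- ceiling(runif(n, 5, 20))
  time <- pmin(t, c0); status <- as.integer(t <= c0)
  sp <- tp < time
  df <- rbind(
    data.frame(id = which(sp), start = 0, stop = tp[sp], status = 0L,
               x = x[sp], z = 0),
    data.frame(id = which(sp), start = tp[sp], stop = time[sp],
               status = status[sp], x = x[sp], z = 1),
    data.frame(id = which(!sp), start = 0, stop = time[!sp],
               status = status[!sp], x = x[!sp], z = 0))
  d2 <- survival_data(df$id, df$start, df$stop, df$status,
                      df[, c("x", "z")])
  for (ties in c("efron", "breslow")) {
    f2 <- cox_fit(d2, ties = ties)
    g2 <- survival::coxph(survival::Surv(start, stop, status) ~ x + z,
                          data = as.data.frame(d2), ties = ties)
    expect_equal(unname(f2$coefficients), unname(coef(g2)),
                 tolerance = 1e-7)
  }
})

test_that("Efron and Breslow agree exactly without ties; duplication is invariant", {
  d <- make_rc_data(120, seed = 9)
  fe <- cox_fit(d, ties = "efron")
  fb <- cox_fit(d, ties = "breslow")
  expect_equal(fe$coefficients, fb$coefficients, tolerance = 1e-9)
  # duplicating every row scales the Breslow likelihood but not its argmax
  # (under Efron the duplicates form tied pairs, changing the correction)
  df <- as.data.frame(d)
  dd <- survival_data(c(df$id, df$id + 1000), stop = rep(df$stop, 2),
                      status = rep(df$status, 2),
                      covariates = rbind(df[, c("x", "z")],
                                         df[, c("x", "z")]))
  fd <- cox_fit(dd, ties = "breslow")
  expect_equal(fd$coefficients, fb$coefficients, tolerance = 1e-6)
})

test_that("Cox fit recovers a known hazard ratio of 2", {
  set.seed(11)
  n <- 4000
  g <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(log(2) * g))
  c0 <- rexp(n, 0.1)  # ~50% events
  d <- survival_data(1:n, stop = pmin(t, c0), status = as.integer(t <= c0),
                     covariates = data.frame(g = g))
  f <- cox_fit(d)
  expect_equal(exp(f$coefficients[["g"]]), 2, tolerance = 0.1)
})

test_that("degenerate Cox inputs are flagged rather than silently wrong", {
  d <- make_rc_data(50, seed = 2)
  df <- as.data.frame(d)
  df$c1 <- 1
  dc <- survival_data(df$id, stop = df$stop, status = df$status,
                      covariates = df[, c("x", "c1")])
  expect_error(cox_fit(dc), "constant")
  # collinear copies are reported by name
  df$x2 <- df$x
  dx <- survival_data(df$id, stop = df$stop, status = df$status,
                      covariates = df[, c("x", "x2")])
  expect_error(cox_fit(dx), "collinear|singular")
  # perfect separation flags monotone likelihood
  ds <- survival_data(1:20, stop = c(1:10, 101:110),
                      status = rep(1, 20),
                      covariates = data.frame(s = rep(c(1, 0), each = 10)))
  expect_warning(fs <- cox_fit(ds, "s"), "monotone|separation")
  expect_false(fs$converged)
  expect_true(fs$flagged)
})

test_that("proportional-hazards diagnostic is invariant to affine rescaling", {
  d <- make_rc_data(200, seed = 13)
  f <- cox_fit(d)
  z1 <- ph_test(f, d)
  df <- as.data.frame(d)
  df$x <- 10 * df$x + 3
  d2 <- survival_data(df$id, stop = df$stop, status = df$status,
                      covariates = df[, c("x", "z")])
  z2 <- ph_test(cox_fit(d2), d2)
  expect_equal(z1$chisq, z2$chisq, tolerance = 1e-6)
})

test_that("Benjamini-Hochberg adjustment follows the step-up arithmetic", {
  expect_equal(fdr_adjust(0.01), 0.01)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  p <- runif(20)
  expect_true(all(fdr_adjust(p) >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("event detection applies the strict 20%-drop composite rule", {
  vit <- data.frame(time = c(10, 20, 30, 40),
                    hr = c(100, 95, 87, 90),
                    sbp = c(95, 94, 93, 92), dbp = c(55, 54, 53, 52))
  base <- c(hr = 110, sbp = 95, dbp = 55)
  ev <- detect_events(vit, base, follow_up = 60)
  # HR 87 < 0.8 * 110 = 88 at t = 30
  expect_equal(ev$time, 30)
  expect_equal(ev$event, 1L)
  expect_equal(ev$type, "bradycardia")
  # all vitals within 20%: censored at follow-up
  vit2 <- vit; vit2$hr <- c(100, 95, 92, 90)
  expect_equal(detect_events(vit2, base, 60),
               list(time = 60, event = 0L, type = NA_character_))
  # exact 20% drop is not an event (strict inequality)
  vit3 <- data.frame(time = 10, hr = 88)
  expect_equal(detect_events(vit3, c(hr = 110), 60)$event, 0L)
  # composite takes the earliest component
  vit4 <- data.frame(time = c(25, 40), sbp = c(70, 95), hr = c(110, 80))
  ev4 <- detect_events(vit4, c(sbp = 95, hr = 110), 60)
  expect_equal(ev4$time, 25)
  expect_equal(ev4$type, "hypotension")
})
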