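# shared fixtures built in code

# simple right-censored dataset with one binary and one continuous covariate
make_rc_data <- function(n, beta = c(x = 0.5, z = -0.7), rate0 = 0.1,
                         cens = c(5, 15), seed = 1) {
  set.seed(seed)
  x <- stats::rnorm(n)
  z <- stats::rbinom(n, 1, 0.4)
  t <- stats::rexp(n, rate0 * exp(beta[["x"]] * x + beta[["z"]] * z))
  c0 <- stats::runif(n, cens[1], cens[2])
  survival_data(seq_len(n), stop = pmin(t, c0),
                status = as.integer(t <= c0),
                covariates = data.frame(x = x, z = z))
}

# subject-level right-censored view of a generated cohort
cohort_rc_data <- function(cohort) {
  sdat <- cohort_survival_data(cohort)
  subj <- dexhdi:::.subject_level(sdat)
  covs <- setdiff(names(subj), c("id", "time", "event"))
  survival_data(subj$id, stop = subj$time, status = subj$event,
                covariates = subj[, covs])
}

# an individual with the reference parameters used by several oracles
oracle_individual <- function() {
  ind <- individual_pk(poppk_model(), weight = 11, pma = pma_from_age(22))
  ind$cl <- 12; ind$v <- 9; ind$q <- 60; ind$v2 <- 11; ind$ka <- 0.38
  ind
}

# numeric ODE solution of the two-compartment first-order-absorption system
ode_concentration <- function(ind, dose, times) {
  rhs <- function(t, y, p) {
    with(as.list(p), list(c(
      -ka * y[1],
      ka * y[1] - (cl / v) * y[2] - (q / v) * y[2] + (q / v2) * y[3],
      (q / v) * y[2] - (q / v2) * y[3])))
  }
  p <- c(ka = ind$ka, cl = ind$cl, v = ind$v, q = ind$q, v2 = ind$v2)
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::ode(c(dose, 0, 0), tt, rhs, p, rtol = 1e-10, atol = 1e-12)
  (sol[match(times, sol[, 1]), 3]) / ind$v
}
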