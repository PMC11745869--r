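# ---- internal machinery for the Cox partial likelihood --------------------

# Prepares sorted structures reused across Newton iterations.
.cox_prep <- function(data, covariates) {
  X <- as.matrix(data[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X)) stop("missing values in covariates")
  ev <- data$status == 1
  if (!any(ev)) stop("at least one event is required")
  et <- sort(unique(data$stop[ev]))
  list(X = X, start = data$start, stop = data$stop, status = data$status,
       n = nrow(X), p = ncol(X),
       ord_start = order(data$start), ord_stop = order(data$stop),
       start_sorted = sort(data$start), stop_sorted = sort(data$stop),
       et = et, ev = ev)
}

# Risk-set sums at the event times via two prefix-cumsum passes:
# sum over rows with (start < t <= stop) of w equals
# (prefix over start < t) - (prefix over stop < t), since stop > start.
.risk_sums <- function(prep, w) {
  w <- as.matrix(w)
  cs_start <- apply(w[prep$ord_start, , drop = FALSE], 2, cumsum)
  cs_stop <- apply(w[prep$ord_stop, , drop = FALSE], 2, cumsum)
  cs_start <- rbind(0, as.matrix(cs_start))
  cs_stop <- rbind(0, as.matrix(cs_stop))
  i_start <- findInterval(prep$et, prep$start_sorted, left.open = TRUE)
  i_stop <- findInterval(prep$et, prep$stop_sorted, left.open = TRUE)
  cs_start[i_start + 1, , drop = FALSE] - cs_stop[i_stop + 1, , drop = FALSE]
}

# Log partial likelihood, score and information at beta.
# ties: "efron" or "breslow". Returns list(loglik, U, I).
.cox_lgh <- function(prep, beta, ties = "efron") {
  X <- prep$X; p <- prep$p
  lp <- drop(X %*% beta)
  r <- exp(lp)
  rX <- r * X
  # upper-triangle pairs for the p x p second-moment sums
  ut <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  rXX <- rX[, ut[, 1], drop = FALSE] * X[, ut[, 2], drop = FALSE]
  S0 <- .risk_sums(prep, r)[, 1]
  S1 <- .risk_sums(prep, rX)
  S2 <- .risk_sums(prep, rXX)
  # tied-event aggregates per event time
  ev <- prep$ev
  f <- as.integer(factor(prep$stop[ev], levels = prep$et))
  dk <- tabulate(f, nbins = length(prep$et))
  D0 <- rowsum(r[ev], f)[, 1]
  D1 <- rowsum(rX[ev, , drop = FALSE], f)
  D2 <- rowsum(rXX[ev, , drop = FALSE], f)
  sum_lp_d <- rowsum(lp[ev], f)[, 1]
  sum_X_d <- rowsum(X[ev, , drop = FALSE], f)

  unpack <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(ut[, 1], ut[, 2])] <- v
    M[cbind(ut[, 2], ut[, 1])] <- v
    M
  }
  loglik <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  for (k in seq_along(prep$et)) {
    d <- dk[k]
    loglik <- loglik + sum_lp_d[k]
    U <- U + sum_X_d[k, ]
    if (ties == "breslow" || d == 1) {
      frac <- 0
      reps <- d
    } else {
      frac <- (seq_len(d) - 1) / d
      reps <- 1
    }
    for (fr in frac) {
      s0 <- S0[k] - fr * D0[k]
      s1 <- S1[k, ] - fr * D1[k, ]
      s2 <- unpack(S2[k, ] - fr * D2[k, ])
      v <- s1 / s0
      loglik <- loglik - reps * log(s0)
      U <- U - reps * v
      I <- I + reps * (s2 / s0 - tcrossprod(v))
    }
  }
  list(loglik = unname(loglik), U = unname(U), I = I)
}

# ---- public API -----------------------------------------------------------

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson maximization of the log partial likelihood with step
#' halving, Efron tie correction by default, and time-dependent covariates
#' via `(start, stop]` risk-set membership. Convergence requires the score
#' norm (max absolute component) to fall below `tol`.
#'
#' @param data A [survival_data()].
#' @param covariates Character vector of covariate column names; defaults to
#'   all covariate columns of `data`.
#' @param ties `"efron"` (default, matching the R survival package) or
#'   `"breslow"`.
#' @param ridge Optional L2 penalty coefficient added to the negative log
#'   partial likelihood (default 0, i.e. unpenalized).
#' @param init Starting coefficient vector (default all zero).
#' @param tol Convergence tolerance on the score norm (default 1e-8).
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `cox_fit` with elements `coefficients`, `var`
#'   (inverse information), `loglik` (c(null, final)), `hr` (a data.frame of
#'   hazard ratios with Wald 95% CIs and p-values), `score_norm`, `iter`,
#'   `converged`, `flagged` (TRUE on suspected monotone likelihood /
#'   separation), `n`, `n_event`, `ties`, `covariates`.
#' @export
cox_fit <- function(data, covariates = covariate_names(data),
                    ties = c("efron", "breslow"), ridge = 0,
                    init = NULL, tol = 1e-8, max_iter = 30) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "survival_data"))
  prep <- .cox_prep(data, covariates)
  p <- prep$p
  # constant columns across all risk sets cannot be estimated
  sds <- apply(prep$X, 2, stats::sd)
  if (any(sds == 0))
    stop("covariate(s) constant across the dataset: ",
         paste(covariates[sds == 0], collapse = ", "))
  beta <- if (is.null(init)) numeric(p) else as.numeric(init)
  cur <- .cox_lgh(prep, beta, ties)
  ll <- cur$loglik - 0.5 * ridge * sum(beta^2)
  null_ll <- .cox_lgh(prep, numeric(p), ties)$loglik
  converged <- FALSE
  flagged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    U <- cur$U - ridge * beta
    I <- cur$I + diag(ridge, p)
    step <- tryCatch(solve(I, U), error = function(e) {
      qx <- qr(prep$X)
      bad <- covariates[-seq_len(qx$rank)]
      stop("singular information matrix; collinear covariate(s): ",
           paste(if (length(bad)) bad else covariates, collapse = ", "),
           call. = FALSE)
    })
    halve <- 0
    repeat {
      cand <- beta + step / 2^halve
      new <- .cox_lgh(prep, cand, ties)
      new_ll <- new$loglik - 0.5 * ridge * sum(cand^2)
      if (is.finite(new_ll) && new_ll >= ll - 1e-12) break
      halve <- halve + 1
      if (halve > 20) break
    }
    beta <- cand; cur <- new; ll <- new_ll
    score_norm <- max(abs(cur$U - ridge * beta))
    if (score_norm < tol) { converged <- TRUE; break }
    # step-halving exhausted: the quadratic model cannot improve further;
    # accept if the score is small relative to the likelihood magnitude
    if (halve > 20 && score_norm < 1e-6 * max(1, abs(ll))) {
      converged <- TRUE; break
    }
    if (iter >= max_iter) break
  }
  if (max(abs(beta)) > 15) {
    flagged <- TRUE
    converged <- FALSE
    warning("suspected monotone partial likelihood (separation): ",
            "coefficients diverging")
  }
  if (!converged && !flagged)
    warning("Newton-Raphson did not reach score tolerance ", tol,
            " in ", max_iter, " iterations (score norm ",
            format(max(abs(cur$U))), ")")
  V <- solve(cur$I + diag(ridge, p))
  se <- sqrt(diag(V))
  z <- beta / se
  hr <- data.frame(covariate = covariates, coef = beta, se = se,
                   hr = exp(beta),
                   lower95 = exp(beta - 1.96 * se),
                   upper95 = exp(beta + 1.96 * se),
                   z = z, p_value = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = stats::setNames(beta, covariates),
                 var = V, loglik = c(null = null_ll, final = cur$loglik),
                 hr = hr, score_norm = max(abs(cur$U - ridge * beta)),
                 iter = iter, converged = converged, flagged = flagged,
                 n = prep$n, n_event = sum(prep$ev), ties = ties,
                 ridge = ridge, covariates = covariates),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_event))
  print(format(x$hr, digits = digits), row.names = FALSE)
  cat(sprintf("log partial likelihood: null %.3f, final %.3f; %s in %d iterations\n",
              x$loglik["null"], x$loglik["final"],
              if (x$converged) "converged" else "NOT converged", x$iter))
  invisible(x)
}

#' Log partial likelihood at given coefficients
#'
#' Evaluates the (Breslow- or Efron-tie) log partial likelihood at one or
#' more coefficient vectors without fitting. Used for cross-validated
#' deviance and for oracle checks.
#'
#' @param data A [survival_data()].
#' @param covariates Covariate names.
#' @param beta Numeric vector (length p) or matrix (p x L) of coefficient
#'   vectors.
#' @param ties `"breslow"` (default here, matching penalized-path software)
#'   or `"efron"`.
#' @return Numeric vector of log partial likelihoods, length L.
#' @export
cox_loglik <- function(data, covariates, beta,
                       ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  prep <- .cox_prep(data, covariates)
  B <- as.matrix(beta)
  if (nrow(B) != prep$p) stop("beta must have one row per covariate")
  if (ties == "efron") {
    return(vapply(seq_len(ncol(B)), function(j)
      .cox_lgh(prep, B[, j], "efron")$loglik, numeric(1)))
  }
  LP <- prep$X %*% B                      # n x L
  R <- exp(LP)
  S0 <- .risk_sums(prep, R)               # E x L
  ev <- prep$ev
  f <- as.integer(factor(prep$stop[ev], levels = prep$et))
  dk <- tabulate(f, nbins = length(prep$et))
  sum_lp_d <- rowsum(LP[ev, , drop = FALSE], f)  # E x L
  colSums(sum_lp_d) - colSums(dk * log(S0))
}

#' Score (gradient) of the Breslow log partial likelihood
#'
#' Gradient of the log partial likelihood at `beta`; used for
#' Karush-Kuhn-Tucker verification of penalized paths.
#'
#' @inheritParams cox_loglik
#' @param beta Numeric coefficient vector.
#' @param ties Tie handling.
#' @return Numeric gradient vector, length p.
#' @export
cox_score <- function(data, covariates, beta, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  prep <- .cox_prep(data, covariates)
  .cox_lgh(prep, as.numeric(beta), ties)$U
}

#' Proportional-hazards diagnostic (scaled Schoenfeld residuals)
#'
#' Score test for a linear association of the scaled Schoenfeld residuals
#' with a transform of event time (default: the Kaplan-Meier transform).
#' Backed by [survival::cox.zph()] on an internal [survival::coxph()] refit
#' of the same model.
#'
#' @param fit A [cox_fit()].
#' @param data The [survival_data()] the model was fitted on.
#' @param transform Time transform passed to `cox.zph` (default `"km"`).
#' @return A data.frame with one row per covariate plus a `GLOBAL` row:
#'   `chisq`, `df`, `p_value`.
#' @export
ph_test <- function(fit, data, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"), inherits(data, "survival_data"))
  if (!fit$converged && fit$flagged)
    stop("ph_test requires a converged fit")
  if (fit$n_event < 2) stop("proportional-hazards test undefined with < 2 events")
  fml <- stats::as.formula(paste(
    "survival::Surv(start, stop, status) ~",
    paste(fit$covariates, collapse = " + ")))
  cph <- survival::coxph(fml, data = as.data.frame(data), ties = fit$ties)
  zph <- survival::cox.zph(cph, transform = transform)
  tab <- as.data.frame(zph$table)
  data.frame(term = rownames(tab), chisq = tab$chisq, df = tab$df,
             p_value = tab$p, row.names = NULL)
}
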