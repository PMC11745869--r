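# Subject-level view of a counting-process dataset: one row per id with the
# covariates of the last interval, overall event indicator and final time.
.subject_level <- function(data, covariates = covariate_names(data)) {
  df <- as.data.frame(data)
  ord <- order(df$id, df$stop)
  df <- df[ord, , drop = FALSE]
  last <- !duplicated(df$id, fromLast = TRUE)
  out <- df[last, c("id", covariates), drop = FALSE]
  out$time <- df$stop[last]
  out$event <- as.integer(tapply(df$status, df$id, max)[as.character(out$id)])
  rownames(out) <- NULL
  out
}

#' Split a cohort into training and test sets
#'
#' Random 60/40 (by default) split of subjects, stratified by the
#' subject-level event indicator so event counts stay balanced; the
#' per-stratum training sizes are allocated by largest remainder so the
#' total training size is exactly `round(n * train_fraction)` (270 subjects
#' at 0.6 give 162/108). Falls back to an unstratified split, with a
#' warning, when a stratum has fewer than 2 members.
#'
#' @param data A [survival_data()].
#' @param train_fraction Fraction of subjects assigned to training (0-1).
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return A list with `train_ids` and `test_ids` (disjoint, exhaustive).
#' @export
split_cohort <- function(data, train_fraction = 0.6, seed = 1L) {
  stopifnot(inherits(data, "survival_data"),
            train_fraction > 0, train_fraction < 1)
  subj <- .subject_level(data, character(0))
  n <- nrow(subj)
  if (n < 10) stop("at least 10 subjects are required to split")
  n_train <- round(n * train_fraction)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  strata <- split(subj$id, subj$event)
  if (any(lengths(strata) < 2)) {
    warning("a stratum has fewer than 2 members; using an unstratified split")
    train <- sample(subj$id, n_train)
  } else {
    raw <- lengths(strata) * train_fraction
    base <- floor(raw)
    rem <- n_train - sum(base)
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
    train <- unlist(mapply(function(ids, m) sample(ids, m),
                           strata, base, SIMPLIFY = FALSE))
  }
  list(train_ids = sort(unname(train)),
       test_ids = sort(setdiff(subj$id, train)))
}

# save/restore the global RNG state so seeded helpers are side-effect free
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Subset a survival dataset by subject ids
#' @param data A [survival_data()].
#' @param ids Subject ids to keep.
#' @export
subset_subjects <- function(data, ids) {
  out <- data[data$id %in% ids, , drop = FALSE]
  attr(out, "covariates") <- covariate_names(data)
  class(out) <- class(data)
  out
}

#' Elastic-net penalized Cox coefficient path
#'
#' Coordinate-descent solution of the elastic-net-penalized Cox partial
#' likelihood (via \pkg{glmnet}) over a log-spaced lambda grid running from
#' the smallest lambda giving the all-zero solution down three decades (100
#' points by default). Covariates are standardized internally; coefficients
#' are returned on the original scale.
#'
#' @param data A [survival_data()].
#' @param covariates Covariate names (default: all).
#' @param alpha Elastic-net mixing parameter in \[0, 1\]: 1 = LASSO
#'   (default), 0 = ridge.
#' @param nlambda Number of lambda grid points.
#' @param lambda_min_ratio Smallest lambda as a fraction of `lambda_max`.
#' @param lambda Optional explicit lambda sequence (overrides the grid).
#' @param thresh Coordinate-descent convergence threshold.
#' @return A list of class `lasso_path`: `lambda`, `beta` (p x nlambda matrix,
#'   original scale), `alpha`, `covariates`, and the underlying `glmnet` fit.
#' @export
lasso_cox_path <- function(data, covariates = covariate_names(data),
                           alpha = 1, nlambda = 100,
                           lambda_min_ratio = 0.001, lambda = NULL,
                           thresh = 1e-10) {
  stopifnot(inherits(data, "survival_data"))
  x <- as.matrix(as.data.frame(data)[, covariates, drop = FALSE])
  # right-censored data take glmnet's fast path; (start, stop] data need
  # the counting-process response
  y <- if (all(data$start == 0))
    survival::Surv(data$stop, data$status)
  else
    survival::Surv(data$start, data$stop, data$status)
  flags <- character(0)
  fit <- withCallingHandlers(
    glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                   nlambda = nlambda,
                   lambda.min.ratio = lambda_min_ratio,
                   lambda = lambda, standardize = TRUE,
                   thresh = thresh),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- as.matrix(fit$beta)
  structure(list(lambda = fit$lambda, beta = beta, alpha = alpha,
                 covariates = covariates, glmnet_fit = fit,
                 flags = flags),
            class = "lasso_path")
}

# Cross-validated deviance for one fold-omission fit, Verweij-Van Houwelingen
# style: dev_f(lambda) = -2 * [ ll_all(beta_f) - ll_without_f(beta_f) ].
.cv_fold_deviance <- function(data, covariates, fold_fit, full_lambda,
                              fold_ids) {
  beta <- as.matrix(glmnet::coef.glmnet(fold_fit$glmnet_fit,
                                        s = full_lambda, exact = FALSE))
  ll_all <- cox_loglik(data, covariates, beta, ties = "breslow")
  train_minus <- subset_subjects(data, setdiff(unique(data$id), fold_ids))
  ll_minus <- cox_loglik(train_minus, covariates, beta, ties = "breslow")
  list(dev = -2 * (ll_all - ll_minus), beta = beta)
}

#' Selection frequency from repeated cross-validated LASSO
#'
#' Repeats k-fold cross-validated elastic-net Cox regression with a fresh
#' fold assignment per repeat. Within each repeat, the lambda sequence is
#' taken from a fit on the full training data, each fold-omission model is
#' fitted along that sequence, the cross-validated partial-likelihood
#' deviance is accumulated, and lambda is chosen at its minimum (or by the
#' one-standard-error rule). Every fold-omission fit, evaluated at the
#' repeat's chosen lambda, contributes one iteration: a variable counts as
#' selected in an iteration if its coefficient there is nonzero, and its
#' frequency is selections divided by iterations. The iteration budget caps
#' the total number of contributing fits.
#'
#' @param data A [survival_data()] (training cohort).
#' @param covariates Candidate covariate names.
#' @param n_repeats Number of cross-validation repeats (default 100).
#' @param k Folds per repeat (default 5).
#' @param n_iterations Budget on the total number of contributing fits
#'   (default 10000; with the defaults, 100 repeats x 5 folds = 500 fits are
#'   run and the budget is not binding).
#' @param alpha Elastic-net mixing parameter (default 1, pure LASSO).
#' @param lambda_rule `"min"` (cross-validated deviance minimizer, default)
#'   or `"1se"`.
#' @param seed Integer seed; the whole procedure is a pure function of
#'   (data, seed).
#' @return A list of class `selection_result`: `frequency` (named, in
#'   \[0,1\]), `ranked` (covariates by decreasing frequency; ties broken by
#'   mean absolute coefficient, then name), `n_iterations` (fits used),
#'   `lambda_chosen` (per repeat), `seed`.
#' @export
selection_frequency <- function(data, covariates = covariate_names(data),
                                n_repeats = 100, k = 5,
                                n_iterations = 10000, alpha = 1,
                                lambda_rule = c("min", "1se"), seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  stopifnot(inherits(data, "survival_data"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- unique(data$id)
  n <- length(ids)
  p <- length(covariates)
  selected <- stats::setNames(numeric(p), covariates)
  coef_mass <- stats::setNames(numeric(p), covariates)
  iter_done <- 0L
  lambda_chosen <- numeric(0)
  # the lambda sequence depends only on the full training data
  master <- lasso_cox_path(data, covariates, alpha = alpha, thresh = 1e-8)
  lam <- master$lambda
  for (rep_i in seq_len(n_repeats)) {
    if (iter_done >= n_iterations) break
    foldid <- sample(rep(seq_len(k), length.out = n))
    folds <- vector("list", k)
    dev <- matrix(NA_real_, k, length(lam))
    for (f in seq_len(k)) {
      fold_ids <- ids[foldid == f]
      tr <- subset_subjects(data, setdiff(ids, fold_ids))
      ffit <- tryCatch(
        lasso_cox_path(tr, covariates, alpha = alpha, lambda = lam,
                       thresh = 1e-8),
        error = function(e) NULL)
      if (is.null(ffit)) next  # flagged non-convergence; path continues
      cvf <- .cv_fold_deviance(data, covariates, ffit, lam, fold_ids)
      dev[f, ] <- cvf$dev
      folds[[f]] <- cvf$beta
    }
    ok <- !is.na(dev[, 1])
    if (!any(ok)) next
    cvm <- colMeans(dev[ok, , drop = FALSE])
    if (lambda_rule == "min") {
      j <- which.min(cvm)
    } else {
      cvsd <- apply(dev[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok))
      jmin <- which.min(cvm)
      j <- min(which(cvm <= cvm[jmin] + cvsd[jmin]))
    }
    lambda_chosen <- c(lambda_chosen, lam[j])
    for (f in which(ok)) {
      if (iter_done >= n_iterations) break
      b <- folds[[f]][, j]
      selected <- selected + (b != 0)
      coef_mass <- coef_mass + abs(b)
      iter_done <- iter_done + 1L
    }
  }
  if (iter_done == 0) stop("no successful cross-validation fits")
  freq <- selected / iter_done
  ord <- order(-freq, -coef_mass, covariates)
  structure(list(frequency = freq, ranked = covariates[ord],
                 n_iterations = iter_done, lambda_chosen = lambda_chosen,
                 seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("LASSO selection frequencies over %d iterations:\n",
              x$n_iterations))
  print(round(sort(x$frequency, decreasing = TRUE), 3))
  invisible(x)
}

#' Progressive addition of ranked variables with AuROC stopping
#'
#' Adds frequency-ranked variables one at a time to a Cox model fitted on
#' the training cohort, scoring the test cohort by the linear predictor
#' against the subject-level any-event indicator. Addition stops when the
#' AuROC improvement falls below `epsilon` for `patience` consecutive
#' additions; the chosen subset is the prefix before the stall.
#'
#' @param ranked Character vector of candidate variables, best first.
#' @param train,test [survival_data()] cohorts.
#' @param epsilon Minimum AuROC improvement counted as progress
#'   (default 0.005).
#' @param patience Consecutive below-epsilon additions tolerated before
#'   stopping (default 2).
#' @return A list of class `progressive_addition`: `chosen` (variable
#'   subset), `auroc` (trajectory, one entry per model size actually fitted),
#'   `sizes`, `stopped_early`.
#' @export
progressive_addition <- function(ranked, train, test, epsilon = 0.005,
                                 patience = 2) {
  stopifnot(length(ranked) >= 1)
  subj_test <- .subject_level(test, ranked)
  labels <- subj_test$event
  auroc <- numeric(0)
  sizes <- integer(0)
  stall <- 0
  best_k <- 1L
  last_auc <- NA_real_
  for (k in seq_along(ranked)) {
    fit <- tryCatch(
      suppressWarnings(cox_fit(train, ranked[seq_len(k)])),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      warning("Cox fit failed or did not converge at model size ", k,
              "; skipped")
      next
    }
    scores <- as.matrix(subj_test[, ranked[seq_len(k)], drop = FALSE]) %*%
      fit$coefficients
    auc <- roc_auc(drop(scores), labels)
    auroc <- c(auroc, auc)
    sizes <- c(sizes, k)
    if (!is.na(last_auc)) {
      if (auc - last_auc < epsilon) stall <- stall + 1 else stall <- 0
      if (stall >= patience) {
        best_k <- sizes[length(sizes) - patience]
        return(structure(list(chosen = ranked[seq_len(best_k)],
                              auroc = auroc, sizes = sizes,
                              stopped_early = TRUE),
                         class = "progressive_addition"))
      }
    }
    last_auc <- auc
    best_k <- k
  }
  structure(list(chosen = ranked[seq_len(best_k)], auroc = auroc,
                 sizes = sizes, stopped_early = FALSE),
            class = "progressive_addition")
}
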