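# Survival analysis: L1-penalized Cox feature selection with nested
# leave-one-out cross-validation, median-split Kaplan-Meier / log-rank
# stratification, multivariable Cox with a time-dependent transplant
# covariate, Fisher exact tests and Benjamini-Hochberg adjustment.

#' Breslow Cox partial log-likelihood for a matrix of linear predictors
#'
#' @param lp n x m matrix of linear predictors (one column per model).
#' @param time,event survival outcome.
#' @return length-m vector of partial log-likelihoods.
#' @noRd
cox_loglik <- function(lp, time, event) {
  lp <- as.matrix(lp)
  o <- order(-time)          # decreasing time: risk set = prefix
  lp <- lp[o, , drop = FALSE]
  time <- time[o]
  event <- event[o]
  # for tied times, the risk sum must cover the whole tie group
  elp <- exp(lp)
  cum <- apply(elp, 2, cumsum)
  last_of_tie <- rev(!duplicated(rev(time)))  # last index of each tie group
  # tie_end[i] = largest index sharing time[i] (prefix sums include ties)
  tie_end <- rev(cummin(rev(ifelse(last_of_tie, seq_along(time), Inf))))
  risk <- cum[tie_end, , drop = FALSE]
  ev <- event == 1
  colSums(lp[ev, , drop = FALSE]) - colSums(log(risk[ev, , drop = FALSE]))
}

#' Largest penalty with an all-zero solution
#'
#' Computed from the null-model score (Breslow martingale residuals):
#' `max_j |x_j' r| / n`, the glmnet-scale lambda at which every coefficient
#' enters at zero.
#' @noRd
lambda_max_cox <- function(X, time, event) {
  o <- order(time)
  n <- length(time)
  tj <- time[o]; dj <- event[o]
  # Breslow cumulative hazard under the null (lp = 0)
  risk_size <- n - seq_len(n) + 1
  # events at each time / risk size, accumulated; ties share the risk set
  first_of_tie <- !duplicated(tj)
  grp <- cumsum(first_of_tie)
  d_at <- tapply(dj, grp, sum)
  r_at <- tapply(risk_size, grp, max)   # risk set size at tie group start
  h_inc <- as.numeric(d_at / r_at)
  H <- cumsum(h_inc)[grp]
  r <- dj - H
  resid <- numeric(n)
  resid[o] <- r
  max(abs(crossprod(X, resid))) / n
}

#' L1-penalized Cox regression path
#'
#' Fits the lasso-penalized Cox partial-likelihood path by cyclic
#' coordinate descent (via glmnet) with Breslow tie handling. Columns are
#' z-scored first so coefficients are log hazard ratios per standard
#' deviation of each feature.
#'
#' @param X numeric feature matrix (patients x features), complete.
#' @param time,event survival outcome (>= 2 events required).
#' @param lambda decreasing penalty sequence; default: `nlambda` log-spaced
#'   values from the computed lambda-max down to
#'   `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio path grid controls.
#' @param standardize z-score columns before fitting (default TRUE).
#' @param tol coordinate-descent convergence tolerance.
#' @return object of class `lasso_cox`: `lambda`, `beta` (features x
#'   lambda, on the standardized scale), `lambda_max`, `center`, `scale`.
#' @export
fit_lasso_cox <- function(X, time, event, lambda = NULL, nlambda = 30,
                          lambda_min_ratio = 0.05, standardize = TRUE,
                          tol = 1e-7) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix", call. = FALSE)
  if (sum(event) < 2) stop("need at least 2 events", call. = FALSE)
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- scale(X, center = ctr, scale = scl)
  }
  lmax <- lambda_max_cox(X, time, event)
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  y <- survival::Surv(time, event)
  one_col <- ncol(X) == 1
  Xfit <- if (one_col) cbind(X, .pad = 0) else X  # glmnet needs >= 2 columns
  fit <- glmnet::glmnet(Xfit, y, family = "cox", lambda = lambda,
                        standardize = FALSE, thresh = tol)
  beta <- as.matrix(fit$beta)
  if (one_col) beta <- beta[1, , drop = FALSE]
  # glmnet may drop trailing path points on convergence trouble; pad with
  # the last available solution so the grid stays aligned
  if (ncol(beta) < length(lambda)) {
    pad <- matrix(beta[, ncol(beta)], nrow(beta),
                  length(lambda) - ncol(beta))
    beta <- cbind(beta, pad)
  }
  colnames(beta) <- NULL
  structure(list(lambda = lambda, beta = beta, lambda_max = lmax,
                 center = ctr, scale = scl, features = colnames(X)),
            class = "lasso_cox")
}

#' @export
print.lasso_cox <- function(x, ...) {
  nz <- colSums(x$beta != 0)
  cat(sprintf("<lasso_cox> %d features, %d lambda values (max %.4g); df range %d-%d\n",
              nrow(x$beta), length(x$lambda), x$lambda_max, min(nz), max(nz)))
  invisible(x)
}

# inner leave-one-out lambda selection on an index subset:
# Verweij-van Houwelingen cross-validated partial-likelihood deviance
#' @noRd
inner_loo_lambda <- function(X, time, event, idx, lambda, tol = 1e-7,
                             rule = "1se") {
  contrib <- matrix(NA_real_, length(idx), length(lambda))
  for (j in seq_along(idx)) {
    tr <- idx[-j]
    if (sum(event[tr]) < 2) {
      warning("training fold with fewer than 2 events skipped")
      next
    }
    fit <- glmnet::glmnet(X[tr, , drop = FALSE],
                          survival::Surv(time[tr], event[tr]),
                          family = "cox", lambda = lambda,
                          standardize = FALSE, thresh = tol)
    beta <- as.matrix(fit$beta)
    if (ncol(beta) < length(lambda)) {
      beta <- cbind(beta, matrix(beta[, ncol(beta)], nrow(beta),
                                 length(lambda) - ncol(beta)))
    }
    lp_all <- X[idx, , drop = FALSE] %*% beta
    lp_tr <- X[tr, , drop = FALSE] %*% beta
    pl_all <- cox_loglik(lp_all, time[idx], event[idx])
    pl_tr <- cox_loglik(lp_tr, time[tr], event[tr])
    contrib[j, ] <- (-2) * (pl_all - pl_tr)
  }
  contrib <- contrib[stats::complete.cases(contrib), , drop = FALSE]
  if (nrow(contrib) == 0L) stop("no usable inner folds", call. = FALSE)
  dev <- colSums(contrib)
  best <- which.min(dev)
  if (rule == "min") return(lambda[best])
  # parsimony: largest lambda whose total deviance is within one standard
  # error of the minimum (standard error of the fold-contribution sum)
  se <- sd(contrib[, best]) * sqrt(nrow(contrib))
  lambda[which(dev <= dev[best] + se)[1]]
}

#' Nested leave-one-out LASSO-Cox feature selection
#'
#' Outer loop: each patient is left out in turn; an inner leave-one-out
#' loop on the remaining patients picks the penalty minimizing the
#' cross-validated partial-likelihood deviance, and the per-fold model
#' (fit on the outer training set at that penalty) records which features
#' it selects. The final model refits on all patients at the penalty chosen
#' by inner cross-validation on the full cohort. For each finally selected
#' feature the log hazard ratio comes from an unpenalized Cox refit on the
#' selected set (per standard deviation of the feature), with Wald p-values
#' adjusted by Benjamini-Hochberg; a raw univariate Cox p-value is reported
#' alongside, since penalized fits carry no natural p-value.
#'
#' The procedure is deterministic for fixed inputs: leave-one-out folds
#' involve no random resampling.
#'
#' @inheritParams fit_lasso_cox
#' @param nlambda,lambda_min_ratio penalty grid (shared by all folds, so
#'   selection frequencies are comparable).
#' @param lambda_rule `"1se"` (default): the sparsest penalty whose
#'   cross-validated deviance lies within one standard error of the
#'   minimum -- the usual parsimony rule, which keeps pure-noise cohorts
#'   from selecting anything; `"min"`: the exact deviance minimizer.
#' @return object of class `loocv_cox`: `selected` (data frame: feature,
#'   log_hr, p, p_adj, p_univariate, selection_frequency), `lambda_chosen`,
#'   `lambda`, `selection_frequency` (all features), `fold_selected`.
#' @export
nested_loocv_select <- function(X, time, event, nlambda = 20,
                                lambda_min_ratio = 0.08, tol = 1e-7,
                                lambda_rule = c("1se", "min")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop("need at least 10 patients", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite values in feature matrix", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  lmax <- lambda_max_cox(Xs, time, event)
  lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                    length.out = nlambda))

  p <- ncol(Xs)
  sel_count <- numeric(p)
  fold_selected <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    lam_i <- inner_loo_lambda(Xs, time, event, tr, lambda, tol, lambda_rule)
    fit <- glmnet::glmnet(Xs[tr, , drop = FALSE],
                          survival::Surv(time[tr], event[tr]),
                          family = "cox", lambda = lambda,
                          standardize = FALSE, thresh = tol)
    b <- as.matrix(fit$beta)
    col <- min(which.min(abs(fit$lambda - lam_i)), ncol(b))
    nz <- which(b[, col] != 0)
    sel_count[nz] <- sel_count[nz] + 1
    fold_selected[[i]] <- colnames(Xs)[nz]
  }
  sel_freq <- setNames(sel_count / n, colnames(Xs))

  lam_final <- inner_loo_lambda(Xs, time, event, seq_len(n), lambda, tol,
                                lambda_rule)
  path <- fit_lasso_cox(Xs, time, event, lambda = lambda,
                        standardize = FALSE, tol = tol)
  col <- which.min(abs(lambda - lam_final))
  final_beta <- path$beta[, col]
  selected <- colnames(Xs)[final_beta != 0]

  if (length(selected) > 0) {
    df <- data.frame(Xs[, selected, drop = FALSE])
    names(df) <- selected
    df$.time <- time; df$.event <- event
    refit <- survival::coxph(
      survival::Surv(.time, .event) ~ .,
      data = df, ties = "breslow")
    sm <- summary(refit)$coefficients
    uni_p <- vapply(selected, function(f) {
      u <- survival::coxph(survival::Surv(time, event) ~ Xs[, f],
                           ties = "breslow")
      summary(u)$coefficients[1, "Pr(>|z|)"]
    }, numeric(1))
    sel_df <- data.frame(feature = selected,
                         log_hr = sm[, "coef"],
                         p = sm[, "Pr(>|z|)"],
                         p_adj = bh_adjust(sm[, "Pr(>|z|)"]),
                         p_univariate = uni_p,
                         selection_frequency = sel_freq[selected],
                         row.names = NULL, stringsAsFactors = FALSE)
    sel_df <- sel_df[order(sel_df$p), ]
  } else {
    sel_df <- data.frame(feature = character(0), log_hr = numeric(0),
                         p = numeric(0), p_adj = numeric(0),
                         p_univariate = numeric(0),
                         selection_frequency = numeric(0))
  }
  structure(list(selected = sel_df, lambda_chosen = lam_final,
                 lambda = lambda, selection_frequency = sel_freq,
                 fold_selected = fold_selected, n = n,
                 final_beta = setNames(final_beta, colnames(Xs))),
            class = "loocv_cox")
}

#' @export
print.loocv_cox <- function(x, ...) {
  cat(sprintf("<loocv_cox> n=%d, lambda=%.4g, %d features selected\n",
              x$n, x$lambda_chosen, nrow(x$selected)))
  if (nrow(x$selected) > 0) {
    print(head(x$selected, 10), digits = 3)
  }
  invisible(x)
}

#' @export
summary.loocv_cox <- function(object, ...) {
  top <- sort(object$selection_frequency, decreasing = TRUE)
  cat("Top features by leave-one-out selection frequency:\n")
  print(head(top[top > 0], 10), digits = 3)
  invisible(object)
}

#' Median split of a patient-level feature
#'
#' Values at or below the median go to `"low"`, above to `"high"`; with an
#' even number of distinct values the split is equal.
#'
#' @param values named numeric vector (>= 2 patients).
#' @return factor with levels `low`, `high`.
#' @export
median_split <- function(values) {
  if (length(values) < 2) stop("need at least 2 patients", call. = FALSE)
  if (max(values) == min(values)) {
    stop("all values identical: degenerate median split", call. = FALSE)
  }
  m <- median(values)
  factor(ifelse(values <= m, "low", "high"), levels = c("low", "high"))
}

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator; censored subjects leave the risk set after
#' their time; S(0) = 1.
#'
#' @param time,event survival outcome.
#' @param groups factor of group labels (all groups non-empty).
#' @return named list (per group) of data frames with `time`, `n_risk`,
#'   `n_event`, `surv`; attribute `fit` holds the underlying
#'   [survival::survfit()] object.
#' @export
km_estimate <- function(time, event, groups) {
  groups <- as.factor(groups)
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ groups)
  sm <- summary(fit, censored = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(groups)[1], length(sm$time)) else
    sub("^groups=", "", as.character(sm$strata))
  out <- lapply(levels(groups), function(g) {
    i <- strata == g
    data.frame(time = sm$time[i], n_risk = sm$n.risk[i],
               n_event = sm$n.event[i], surv = sm$surv[i])
  })
  names(out) <- levels(groups)
  attr(out, "fit") <- fit
  out
}

#' Two-group log-rank (Mantel-Cox) test with log-rank hazard ratio
#'
#' Chi-square with 1 df from the per-event-time observed-minus-expected
#' sums; the hazard ratio of group 1 versus group 2 is `(O1/E1)/(O2/E2)`
#' with confidence interval `exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2))`.
#' Optionally the p-value is computed by permutation of group labels
#' (exhaustive when the number of label arrangements is at most
#' `max_permutations`, otherwise sampled).
#'
#' @param time,event survival outcome.
#' @param groups two-level factor, both groups non-empty.
#' @param p_method `"asymptotic"` (chi-square) or `"permutation"`.
#' @param max_permutations cap for exhaustive enumeration.
#' @param seed seed for sampled permutations.
#' @return object of class `logrank_test`: `chisq`, `p`, `hr`, `hr_ci`,
#'   `observed`, `expected`, `group_sizes`.
#' @export
logrank_test <- function(time, event, groups,
                         p_method = c("asymptotic", "permutation"),
                         max_permutations = 20000, seed = 1) {
  p_method <- match.arg(p_method)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2 || any(table(groups) == 0)) {
    stop("need exactly two non-empty groups", call. = FALSE)
  }
  if (sum(event) == 0) stop("no events", call. = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ groups)
  O <- sd_$obs; E <- sd_$exp
  chisq <- sd_$chisq
  hr <- (O[1] / E[1]) / (O[2] / E[2])
  ci <- exp(log(hr) + c(-1, 1) * 1.96 * sqrt(1 / E[1] + 1 / E[2]))
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  if (p_method == "permutation") {
    n <- length(groups)
    n1 <- sum(groups == levels(groups)[1])
    stat_for <- function(g) {
      s <- survival::survdiff(survival::Surv(time, event) ~ g)
      s$chisq
    }
    n_comb <- choose(n, n1)
    if (n_comb <= max_permutations) {
      combs <- utils::combn(n, n1)
      stats_all <- apply(combs, 2, function(idx) {
        g <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
        stat_for(g)
      })
      p <- mean(stats_all >= chisq - 1e-12)
    } else {
      stats_all <- withr::with_seed(seed, {
        replicate(max_permutations, stat_for(sample(groups)))
      })
      p <- (sum(stats_all >= chisq - 1e-12) + 1) / (max_permutations + 1)
    }
  }
  structure(list(chisq = unname(chisq), p = unname(p), hr = unname(hr),
                 hr_ci = unname(ci), observed = unname(O),
                 expected = unname(E),
                 group_sizes = as.vector(table(groups)),
                 groups = levels(groups), p_method = p_method),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chisq = %.4g, p = %.4g (%s)\n",
              x$chisq, x$p, x$p_method))
  cat(sprintf("HR %s/%s = %.4g (95%% CI %.4g-%.4g); n = %s\n",
              x$groups[1], x$groups[2], x$hr, x$hr_ci[1], x$hr_ci[2],
              paste(x$group_sizes, collapse = "/")))
  invisible(x)
}

#' Multivariable Cox model with transplant as a time-dependent covariate
#'
#' Each transplanted patient's follow-up is split at the transplant day
#' into a pre-transplant episode (covariate 0) and a post-transplant
#' episode (covariate 1), in counting-process form; total follow-up time is
#' conserved exactly. Covariates that are constant are dropped from the fit
#' and reported as such.
#'
#' @param time,event survival outcome (days).
#' @param covariates data frame of fixed covariates (one row per patient).
#' @param transplant_day per-patient transplant day (`NA` = no transplant);
#'   must be strictly before the patient's observed time.
#' @return list with `fit` (the [survival::coxph()] object), `coefficients`
#'   (data frame: term, log_hr, p), `dropped` (constant covariates).
#' @export
fit_cox_td <- function(time, event, covariates, transplant_day = NULL) {
  n <- length(time)
  covariates <- as.data.frame(covariates)
  if (is.null(transplant_day)) transplant_day <- rep(NA_real_, n)
  bad <- !is.na(transplant_day) & transplant_day >= time
  if (any(bad)) {
    stop(sprintf("transplant at/after observed time for record(s) %s",
                 paste(which(bad), collapse = ", ")), call. = FALSE)
  }
  keep <- vapply(covariates, function(v) length(unique(v)) > 1, logical(1))
  dropped <- names(covariates)[!keep]
  covariates <- covariates[, keep, drop = FALSE]

  rows <- lapply(seq_len(n), function(i) {
    if (is.na(transplant_day[i])) {
      data.frame(start = 0, stop = time[i], ev = event[i], transplant = 0,
                 covariates[i, , drop = FALSE], row.names = NULL)
    } else {
      rbind(
        data.frame(start = 0, stop = transplant_day[i], ev = 0, transplant = 0,
                   covariates[i, , drop = FALSE], row.names = NULL),
        data.frame(start = transplant_day[i], stop = time[i], ev = event[i],
                   transplant = 1, covariates[i, , drop = FALSE],
                   row.names = NULL))
    }
  })
  df <- do.call(rbind, rows)
  if (all(df$transplant == 0)) {
    dropped <- c(dropped, "transplant")
    df$transplant <- NULL
  }
  terms <- setdiff(names(df), c("start", "stop", "ev"))
  fml <- stats::as.formula(paste("survival::Surv(start, stop, ev) ~",
                                 paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "breslow")
  sm <- summary(fit)$coefficients
  list(fit = fit,
       coefficients = data.frame(term = rownames(sm), log_hr = sm[, "coef"],
                                 p = sm[, "Pr(>|z|)"], row.names = NULL,
                                 stringsAsFactors = FALSE),
       dropped = dropped, episodes = df)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p: the sum of hypergeometric probabilities of all tables (with
#' the observed margins) whose probability does not exceed that of the
#' observed table, within a relative tolerance of 1e-7.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  validate_that(all(dim(table) == 2), "table", "must be 2x2")
  validate_that(all(table >= 0) && all(table == round(table)), "table",
                "counts must be non-negative integers")
  fisher.test(table)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' capped at 1.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvals) {
  validate_that(all(pvals >= 0 & pvals <= 1, na.rm = TRUE), "pvals",
                "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Administrative censoring at a horizon
#'
#' @param time,event survival outcome in days.
#' @param horizon `"2y"` (730 days), `"5y"` (1826 days) or a number of days.
#' @return list with capped `time` and `event`.
#' @export
censor_at_horizon <- function(time, event, horizon = "5y") {
  days <- switch(as.character(horizon), "2y" = 730, "5y" = 1826,
                 as.numeric(horizon))
  capped <- pmin(time, days)
  list(time = capped, event = ifelse(time > days, 0L, as.integer(event)))
}
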