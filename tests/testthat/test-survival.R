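# small reproducible survival dataset generator (patient level)
surv_data <- function(n = 20, p = 2, beta = c(0.8, rep(0, 1)), seed = 1,
                      cens = 0.25) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(paste0("P", 1:n), paste0("f", 1:p)))
    lp <- X %*% c(beta, rep(0, p - length(beta)))
    time <- rexp(n, 0.002 * exp(lp))
    censored <- rbinom(n, 1, cens) == 1
    time[censored] <- time[censored] * runif(sum(censored))
    list(X = X, time = as.numeric(time), event = as.integer(!censored))
  })
}

test_that("the penalty ceiling zeroes every coefficient", {
  d <- surv_data(n = 30, p = 8, beta = c(1, -0.5), seed = 3)
  fit <- fit_lasso_cox(d$X, d$time, d$event)
  expect_equal(unname(fit$beta[, 1]), rep(0, 8))
  # explicitly at and above the computed lambda-max
  fit2 <- fit_lasso_cox(d$X, d$time, d$event,
                        lambda = c(fit$lambda_max * 2, fit$lambda_max))
  expect_true(all(fit2$beta == 0))
  # and strictly below it, something enters
  fit3 <- fit_lasso_cox(d$X, d$time, d$event,
                        lambda = fit$lambda_max * c(1, 0.5, 0.1))
  expect_gt(sum(fit3$beta[, 3] != 0), 0)
})

test_that("the unpenalized end of the path matches a Newton oracle", {
  d <- surv_data(n = 20, p = 2, beta = c(0.8, -0.4), seed = 7)
  Xs <- scale(d$X)
  fit <- fit_lasso_cox(Xs, d$time, d$event, standardize = FALSE,
                       lambda = c(0.5, 0.1, 0.01, 0), tol = 1e-12)
  oracle <- oracle_newton_cox(Xs, d$time, d$event)
  expect_equal(unname(fit$beta[, 4]), unname(oracle), tolerance = 1e-4)
})

test_that("duplicated columns share the collapsed-design solution", {
  d <- surv_data(n = 40, p = 1, beta = 1, seed = 9)
  Xs <- scale(d$X)
  Xdup <- cbind(Xs, Xs)
  colnames(Xdup) <- c("a", "b")
  lam <- 0.02
  fit <- fit_lasso_cox(Xdup, d$time, d$event, standardize = FALSE,
                       lambda = c(0.5, lam), tol = 1e-12)
  single <- fit_lasso_cox(Xs, d$time, d$event, standardize = FALSE,
                          lambda = c(0.5, lam), tol = 1e-12)
  expect_equal(sum(fit$beta[, 2]), unname(single$beta[1, 2]),
               tolerance = 1e-4)
})

test_that("the number of active features shrinks as the penalty grows", {
  for (s in 1:3) {
    d <- surv_data(n = 35, p = 10, beta = c(1, -0.8, 0.5), seed = s)
    fit <- fit_lasso_cox(d$X, d$time, d$event, nlambda = 12)
    nz <- colSums(fit$beta != 0)
    # lambda decreases along the path: active counts grow, up to transient
    # single-feature swaps at the coordinate-descent tolerance
    expect_equal(unname(nz[1]), 0)
    expect_true(all(diff(nz) >= -1))
    expect_gte(nz[length(nz)], nz[1])
  }
})

test_that("nested LOOCV finds a strong causal feature among noise", {
  hits <- 0
  for (s in 1:6) {
    d <- surv_data(n = 40, p = 25, beta = c(2), seed = 100 + s, cens = 0.2)
    sel <- nested_loocv_select(d$X, d$time, d$event)
    top <- names(sort(sel$selection_frequency, decreasing = TRUE))[1]
    if (top == "f1") hits <- hits + 1
    if (nrow(sel$selected) > 0 && "f1" %in% sel$selected$feature) {
      expect_gt(sel$selected$log_hr[sel$selected$feature == "f1"], 0)
    }
  }
  expect_gte(hits, 5)
})

test_that("nested LOOCV is deterministic and mostly empty under the null", {
  d <- surv_data(n = 25, p = 15, beta = c(0), seed = 55, cens = 0.3)
  s1 <- nested_loocv_select(d$X, d$time, d$event)
  s2 <- nested_loocv_select(d$X, d$time, d$event)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$selection_frequency, s2$selection_frequency)
  empty <- 0
  for (s in 1:9) {
    d <- surv_data(n = 25, p = 15, beta = c(0), seed = 200 + s, cens = 0.3)
    sel <- nested_loocv_select(d$X, d$time, d$event)
    if (nrow(sel$selected) == 0) empty <- empty + 1
  }
  expect_gte(empty, 5)  # majority of null cohorts select nothing
})

test_that("median split follows the at-or-below rule", {
  v <- setNames(sample(1:32), paste0("P", 1:32))
  g <- median_split(v)
  expect_equal(as.vector(table(g)), c(16, 16))
  v5 <- setNames(c(10, 20, 30, 40, 50), paste0("P", 1:5))
  g5 <- median_split(v5)
  expect_equal(as.vector(table(g5)), c(3, 2))
  expect_equal(unname(g5[3]), factor("low", levels = c("low", "high"))[1])
  expect_error(median_split(rep(2, 5)), "identical")
  expect_error(median_split(3), "2 patients")
})

test_that("Kaplan-Meier estimates match hand-computed product limits", {
  # all censored: S stays 1
  km <- km_estimate(c(5, 8, 12), c(0, 0, 0), factor(rep("a", 3)))
  expect_true(all(km$a$surv == 1))
  # n=2, events at 1 and 2
  km2 <- km_estimate(c(1, 2), c(1, 1), factor(rep("a", 2)))
  expect_equal(km2$a$surv, c(0.5, 0))
  # n=5: event 1, censored 2, event 3, censored 4, event 5
  # S(1)=4/5, S(3)=4/5*2/3=8/15, S(5)=0
  km5 <- km_estimate(1:5, c(1, 0, 1, 0, 1), factor(rep("a", 5)))
  s <- km5$a
  expect_equal(s$surv[s$time == 1], 4 / 5)
  expect_equal(s$surv[s$time == 3], 8 / 15, tolerance = 1e-12)
  expect_equal(s$surv[s$time == 5], 0)
  expect_error(km_estimate(1, 1, factor("a", levels = c("a", "b"))), "empty")
})

test_that("log-rank matches hand tabulation and symmetry", {
  # identical groups: chi-square 0, HR 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- logrank_test(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$hr, 1, tolerance = 1e-12)
  # A events at 1,2; B events at 3,4: E_A = 1/2 + 1/3 = 0.8333,
  # HR(A/B) = (2/0.8333)/(2/3.1667) = 3.80
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1),
                     factor(c("A", "A", "B", "B")))
  expect_equal(lr$expected[1], 5 / 6, tolerance = 1e-4)
  expect_equal(lr$hr, 3.80, tolerance = 0.01)
  expect_error(logrank_test(1:4, rep(0, 4), rep(c("a", "b"), 2)), "events")
})

test_that("permutation log-rank p equals exhaustive enumeration", {
  withr::local_seed(12)
  time <- c(2, 4, 5, 7, 9, 12, 14, 20)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  groups <- factor(rep(c("a", "b"), 4))
  lr <- logrank_test(time, event, groups, p_method = "permutation")
  expect_equal(lr$p, oracle_permutation_logrank(time, event, groups),
               tolerance = 1e-12)
  # sampled permutations approximate the exhaustive answer
  lrs <- logrank_test(time, event, groups, p_method = "permutation",
                      max_permutations = 30, seed = 3)
  expect_lt(abs(lrs$p - lr$p), 0.35)
})

test_that("time-dependent Cox reduces to ordinary Cox without transplants", {
  d <- surv_data(n = 40, p = 2, beta = c(0.7, -0.3), seed = 17)
  cov <- data.frame(x1 = d$X[, 1], x2 = d$X[, 2])
  td <- fit_cox_td(d$time, d$event, cov)
  plain <- survival::coxph(survival::Surv(d$time, d$event) ~ x1 + x2,
                           data = cov, ties = "breslow")
  expect_equal(td$coefficients$log_hr[td$coefficients$term %in% c("x1", "x2")],
               unname(coef(plain)), tolerance = 1e-6)
  expect_true("transplant" %in% td$dropped)
})

test_that("episode splitting conserves follow-up and validates timing", {
  d <- surv_data(n = 30, p = 1, beta = 0.5, seed = 23)
  tx <- rep(NA_real_, 30)
  tx[1:10] <- d$time[1:10] * 0.5
  td <- fit_cox_td(d$time, d$event, data.frame(x1 = d$X[, 1]), tx)
  ep <- td$episodes
  tot <- tapply(ep$stop - ep$start, rep(seq_len(30), ifelse(is.na(tx), 1, 2)), sum)
  expect_equal(as.numeric(tot), d$time, tolerance = 1e-12)
  expect_true("transplant" %in% td$coefficients$term)
  bad_tx <- tx; bad_tx[2] <- d$time[2] + 1
  expect_error(fit_cox_td(d$time, d$event, data.frame(x1 = d$X[, 1]), bad_tx),
               "transplant")
  # constant covariate reported as dropped
  td2 <- fit_cox_td(d$time, d$event, data.frame(x1 = d$X[, 1], z = 1), tx)
  expect_true("z" %in% td2$dropped)
})

test_that("Fisher exact matches hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(1, 0, 0, 1), 2)), 1.0)
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2)), 1.0)  # zero margin
  tab <- matrix(c(6, 3, 10, 13), 2)
  expect_equal(fisher_exact(tab), 0.4331, tolerance = 1e-3)
  expect_equal(fisher_exact(tab), oracle_fisher_2x2(tab), tolerance = 1e-7)
  expect_error(fisher_exact(matrix(c(-1, 0, 0, 1), 2)), "counts")
  # random small-margin tables against the enumeration oracle
  withr::local_seed(31)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 4), 2)
    expect_equal(fisher_exact(t2), oracle_fisher_2x2(t2), tolerance = 1e-7)
  }
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "pvals")
})

test_that("administrative censoring caps time and events", {
  cens <- censor_at_horizon(c(100, 800, 2000), c(1, 1, 1), "2y")
  expect_equal(cens$time, c(100, 730, 730))
  expect_equal(cens$event, c(1L, 0L, 0L))
  cens5 <- censor_at_horizon(c(2000), c(1), "5y")
  expect_equal(cens5$time, 1826)
})
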