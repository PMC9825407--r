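# Independent oracles used across tests. These deliberately avoid the code
# paths they check: plain Newton-Raphson for the Cox partial likelihood,
# exhaustive enumeration for permutation and hypergeometric p-values, and
# brute-force nearest-neighbor search.

# Newton-Raphson maximizer of the (unpenalized) Breslow Cox partial
# likelihood.
oracle_newton_cox <- function(X, time, event, tol = 1e-10, max_iter = 100) {
  X <- as.matrix(X)
  p <- ncol(X)
  beta <- rep(0, p)
  ev_times <- sort(unique(time[event == 1]))
  for (it in seq_len(max_iter)) {
    g <- rep(0, p)
    H <- matrix(0, p, p)
    for (t in ev_times) {
      risk <- which(time >= t)
      d <- which(time == t & event == 1)
      w <- exp(X[risk, , drop = FALSE] %*% beta)
      sw <- sum(w)
      xbar <- colSums(X[risk, , drop = FALSE] * as.vector(w)) / sw
      g <- g + colSums(X[d, , drop = FALSE]) - length(d) * xbar
      xc <- sweep(X[risk, , drop = FALSE], 2, xbar)
      H <- H + length(d) * crossprod(xc * as.vector(w), xc) / sw
    }
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# two-sided Fisher p by full hypergeometric enumeration over one margin
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(ks, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive permutation p-value for the two-group log-rank chi-square
oracle_permutation_logrank <- function(time, event, groups) {
  groups <- as.factor(groups)
  n <- length(groups)
  n1 <- sum(groups == levels(groups)[1])
  obs <- survival::survdiff(survival::Surv(time, event) ~ groups)$chisq
  combs <- utils::combn(n, n1)
  stats_all <- apply(combs, 2, function(idx) {
    g <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
    survival::survdiff(survival::Surv(time, event) ~ g)$chisq
  })
  mean(stats_all >= obs - 1e-12)
}

# brute-force nearest-row search (ties -> lowest index)
oracle_nearest <- function(data, centers) {
  apply(data, 1, function(x) {
    d <- colSums((t(centers) - x)^2)
    which.min(d)
  })
}

# adjusted Rand index between two labelings (independent of the package)
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
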