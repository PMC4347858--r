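# Independent oracles used to check the package implementation.

# Interior equilibrium of the recursion for F = 1, H = 1, w > 0:
# (1 - mu)(1 + w(1 - p(1 - mu))) = 1  =>  closed form below.
oracle_neutral_equilibrium <- function(mu, w) {
  (1 - mu / (w * (1 - mu))) / (1 - mu)
}

# Interior fixed points for w = 0: cancelling p in k(p) = p leaves
# a*p^2 + b*p + c = 0 with the coefficients below (s_f = 1 - F, s_h = 1 - H).
oracle_w0_quadratic <- function(mu, F_rel, H) {
  s_f <- 1 - F_rel; s_h <- 1 - H
  a <- s_h * (1 - mu * (1 - s_f))
  b <- -(s_f + s_h)
  cc <- 1 - (1 - mu) * (1 - s_f)
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  r <- sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
  r[r > 0 & r < 1]
}

# Binomial log-likelihood ratio between per-group and pooled MLEs.
oracle_binomial_lrt <- function(infected, total, group) {
  ll <- function(x, n, p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(x * log(p) + (n - x) * log(1 - p))
  }
  p_group <- tapply(infected, group, sum) / tapply(total, group, sum)
  ll_full <- ll(infected, total, p_group[as.character(group)])
  ll_null <- ll(infected, total, sum(infected) / sum(total))
  2 * (ll_full - ll_null)
}

# Direct maximisation of the binomial-regression log-likelihood (intercept
# and slope on time), with analytic gradient; independent of glm's IRLS.
oracle_logistic_fit <- function(infected, total, time) {
  nll <- function(beta) {
    eta <- beta[1] + beta[2] * time
    -sum(infected * eta - total * log1p(exp(eta)))
  }
  grad <- function(beta) {
    mu <- stats::plogis(beta[1] + beta[2] * time)
    r <- infected - total * mu
    -c(sum(r), sum(r * time))
  }
  fit <- stats::optim(c(0, 0), nll, grad, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 1000))
  # Newton-polish on the analytic score to the exact root, then read the
  # observed information H = X' diag(n mu (1-mu)) X at the maximum
  beta <- fit$par
  X <- cbind(1, time)
  for (i in 1:50) {
    mu <- stats::plogis(X %*% beta)[, 1]
    score <- c(crossprod(X, infected - total * mu))
    H <- t(X) %*% ((total * mu * (1 - mu)) * X)
    delta <- solve(H, score)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-13) break
  }
  mu <- stats::plogis(X %*% beta)[, 1]
  H <- t(X) %*% ((total * mu * (1 - mu)) * X)
  se <- unname(sqrt(diag(solve(H))))
  list(coef = unname(beta), se = se)
}
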