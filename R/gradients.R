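# Objective/gradient pairs for the quadrature-based fitters. The gradient of
# the marginal log-likelihood follows the Fisher identity: the score of the
# complete-data log-likelihood averaged over the posterior of the random
# effects, evaluated with the same adaptive Gauss-Hermite nodes as the
# objective (node positions are treated as fixed; the residual error is of
# the order of the quadrature error). Objective and gradient are computed in
# one pass and memoized on the parameter vector, since nlminb requests them
# separately.

# ---- node-level pieces -----------------------------------------------------

agh_parts_1d <- function(fam, eta, pid, m, tau, rule, cache = NULL) {
  b_init <- if (!is.null(cache) && !is.null(cache$b1d) &&
                length(cache$b1d) == m) cache$b1d
  md <- agh_mode_1d(fam, eta, pid, m, tau, b_init = b_init)
  if (!is.null(cache)) cache$b1d <- md$mode
  s_hat <- 1 / sqrt(md$curv)
  B <- md$mode + sqrt(2) * s_hat %o% rule$x
  ETA <- eta + B[pid, , drop = FALSE]
  hk <- rowsum(ll_matrix(fam, ETA), pid, reorder = TRUE) +
    dnorm(B, 0, tau, log = TRUE) +
    matrix(rule$logw, m, length(rule$x), byrow = TRUE)
  ll <- lse_rows(hk) + log(sqrt(2) * s_hat)
  W <- exp(hk - ll + log(sqrt(2) * s_hat))   # posterior node weights, rows sum to 1
  W <- W / rowSums(W)
  list(ll = ll, W = W, ETA = ETA, B = B)
}

agh_parts_2d <- function(fam, eta, tpre, pid, m, tau0, tau1, rule,
                         cache = NULL) {
  tau0 <- max(tau0, 1e-5); tau1 <- max(tau1, 1e-5)
  b_init <- if (!is.null(cache) && !is.null(cache$b2d) &&
                length(cache$b2d$b0) == m) cache$b2d
  md <- agh_mode_2d(fam, eta, tpre, pid, m, tau0, tau1, b_init = b_init)
  if (!is.null(cache)) cache$b2d <- md[c("b0", "b1")]
  l11 <- sqrt(md$p11)
  l21 <- md$p12 / l11
  l22 <- sqrt(pmax(md$p22 - l21^2, 1e-12))
  K <- length(rule$x)
  xa <- rep(rule$x, each = K); xb <- rep(rule$x, times = K)
  lw <- rep(rule$logw, each = K) + rep(rule$logw, times = K)
  B0 <- md$b0 + sqrt(2) * (outer(1 / l11, xa) - outer(l21 / (l11 * l22), xb))
  B1 <- md$b1 + sqrt(2) * outer(1 / l22, xb)
  ETA <- eta + B0[pid, , drop = FALSE] + B1[pid, , drop = FALSE] * tpre
  hk <- rowsum(ll_matrix(fam, ETA), pid, reorder = TRUE) +
    dnorm(B0, 0, tau0, log = TRUE) + dnorm(B1, 0, tau1, log = TRUE) +
    matrix(lw, m, K * K, byrow = TRUE)
  ll <- lse_rows(hk) + log(2) - log(l11) - log(l22)
  W <- exp(hk - ll)
  W <- W / rowSums(W)
  list(ll = ll, W = W, ETA = ETA, B0 = B0, B1 = B1)
}

# ---- memoized objective factories -----------------------------------------

# Mixed beta regression of compressed decrements (optional random slope).
# Parameters: beta (p), log phi, log tau0, [log tau1].
make_beta_objective <- function(mf, y_star, re_slope, rule) {
  p <- ncol(mf$X)
  ly <- log(y_star); l1y <- log1p(-y_star)
  cache <- new.env(parent = emptyenv())
  memo <- new.env(parent = emptyenv())
  compute <- function(th) {
    beta <- th[seq_len(p)]
    phi <- exp(th[p + 1]); tau0 <- exp(th[p + 2])
    tau1 <- if (re_slope) exp(th[p + 3]) else 0
    fam <- fam_beta(y_star, phi)
    eta <- as.numeric(mf$X %*% beta)
    parts <- if (re_slope) {
      agh_parts_2d(fam, eta, mf$tpre, mf$pid, mf$m, tau0, tau1, rule, cache)
    } else {
      agh_parts_1d(fam, eta, mf$pid, mf$m, tau0, rule, cache)
    }
    val <- -sum(parts$ll)
    if (!is.finite(val)) {
      return(list(value = 1e10, grad = rep(0, length(th))))
    }
    Wobs <- parts$W[mf$pid, , drop = FALSE]
    D1 <- fam$d1(parts$ETA); dim(D1) <- dim(parts$ETA)
    g_beta <- as.numeric(crossprod(mf$X, rowSums(D1 * Wobs)))
    mu <- pmin(pmax(plogis(parts$ETA), 1e-10), 1 - 1e-10)
    dphi <- mu * ly + (1 - mu) * l1y + digamma(phi) -
      mu * digamma(mu * phi) - (1 - mu) * digamma((1 - mu) * phi)
    g_logphi <- sum(Wobs * dphi) * phi
    if (re_slope) {
      g_t0 <- sum(parts$W * (parts$B0^2 / tau0^2 - 1))
      g_t1 <- sum(parts$W * (parts$B1^2 / tau1^2 - 1))
      grad <- -c(g_beta, g_logphi, g_t0, g_t1)
    } else {
      g_t0 <- sum(parts$W * (parts$B^2 / tau0^2 - 1))
      grad <- -c(g_beta, g_logphi, g_t0)
    }
    list(value = val, grad = grad)
  }
  get <- function(th) {
    if (!identical(memo$th, th)) {
      memo$th <- th
      memo$res <- compute(th)
    }
    memo$res
  }
  list(fn = function(th) get(th)$value,
       gr = function(th) get(th)$grad)
}

# Mixed logistic regression of the ceiling indicator (random intercept).
# Parameters: gamma (p), log tau.
make_bernoulli_objective <- function(mf, z, rule) {
  p <- ncol(mf$X)
  fam <- fam_bernoulli(z)
  cache <- new.env(parent = emptyenv())
  memo <- new.env(parent = emptyenv())
  compute <- function(th) {
    tau <- exp(th[p + 1])
    eta <- as.numeric(mf$X %*% th[seq_len(p)])
    parts <- agh_parts_1d(fam, eta, mf$pid, mf$m, tau, rule, cache)
    val <- -sum(parts$ll)
    if (!is.finite(val)) {
      return(list(value = 1e10, grad = rep(0, length(th))))
    }
    Wobs <- parts$W[mf$pid, , drop = FALSE]
    D1 <- z - plogis(parts$ETA); dim(D1) <- dim(parts$ETA)
    g_beta <- as.numeric(crossprod(mf$X, rowSums(D1 * Wobs)))
    g_tau <- sum(parts$W * (parts$B^2 / tau^2 - 1))
    list(value = val, grad = -c(g_beta, g_tau))
  }
  get <- function(th) {
    if (!identical(memo$th, th)) {
      memo$th <- th
      memo$res <- compute(th)
    }
    memo$res
  }
  list(fn = function(th) get(th)$value,
       gr = function(th) get(th)$grad)
}
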