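# Adaptive Gauss-Hermite quadrature engines for marginal likelihoods with
# one- and two-dimensional patient-level random effects. Both engines locate
# the per-patient posterior mode of h(b) = sum_j log f(y_ij | eta_ij + b) +
# log phi(b; 0, D) by damped Newton iterations vectorized across patients,
# then integrate exp(h) with Gauss-Hermite nodes rescaled by the curvature
# at the mode. All node evaluations run as one matrix pass (observations x
# nodes) followed by a single grouped rowsum. An optional cache environment
# warm-starts the modes between successive objective evaluations, which cuts
# the Newton work to one or two steps during optimization.

gh_rule <- function(nodes) {
  if (nodes < 5) {
    abort("Quadrature requires at least 5 nodes per dimension.",
          class = "hsuv_config_error")
  }
  gh <- pracma::gaussHermite(as.integer(nodes))
  list(x = gh$x, logw = log(gh$w) + gh$x^2)
}

# single-node rule: adaptive quadrature collapses to a Laplace
# approximation, used as a cheap first optimization stage
laplace_rule <- function() list(x = 0, logw = log(sqrt(pi)))

# numeric first/second derivative fallback for kernels without analytic ones
numeric_derivs <- function(ll, delta = 1e-4) {
  list(
    ll = ll,
    d1 = function(eta) (ll(eta + delta) - ll(eta - delta)) / (2 * delta),
    d2 = function(eta) {
      (ll(eta + delta) - 2 * ll(eta) + ll(eta - delta)) / delta^2
    }
  )
}

ll_matrix <- function(fam, ETA) {
  LL <- fam$ll(ETA)
  dim(LL) <- dim(ETA)
  LL
}

# Damped Newton ascent on per-patient h for a scalar random intercept.
agh_mode_1d <- function(fam, eta, pid, m, tau, b_init = NULL,
                        max_iter = 25L, tol = 1e-6) {
  b <- b_init %||% numeric(m)
  h_at <- function(b) {
    as.numeric(rowsum(fam$ll(eta + b[pid]), pid, reorder = TRUE)) -
      b^2 / (2 * tau^2)
  }
  h_cur <- h_at(b)
  if (any(!is.finite(h_cur))) {     # stale warm start: restart from zero
    b <- numeric(m)
    h_cur <- h_at(b)
  }
  for (it in seq_len(max_iter)) {
    ebp <- eta + b[pid]
    g1 <- as.numeric(rowsum(fam$d1(ebp), pid, reorder = TRUE)) - b / tau^2
    g2 <- as.numeric(rowsum(fam$d2(ebp), pid, reorder = TRUE)) - 1 / tau^2
    g2 <- pmin(g2, -1e-10)
    step <- pmax(pmin(-g1 / g2, 4 * tau), -4 * tau)
    b_new <- b + step
    h_new <- h_at(b_new)
    for (k in 1:4) {   # vectorized backtracking where the step overshot
      worse <- !is.finite(h_new) | h_new < h_cur - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
      b_new <- b + step
      h_new <- h_at(b_new)
    }
    keep <- is.finite(h_new) & h_new >= h_cur
    b[keep] <- b_new[keep]
    h_cur[keep] <- h_new[keep]
    if (!any(keep) || max(abs(step[keep])) < tol) break
  }
  ebp <- eta + b[pid]
  g2 <- as.numeric(rowsum(fam$d2(ebp), pid, reorder = TRUE)) - 1 / tau^2
  list(mode = b, curv = pmax(-g2, 1e-10))
}

# Marginal log-likelihood contributions (one per patient) for a model with a
# single Gaussian random intercept, via adaptive Gauss-Hermite quadrature.
agh_loglik_1d <- function(fam, eta, pid, m, tau, rule, cache = NULL) {
  if (tau < 1e-6) {   # point-mass limit: no integration needed
    return(as.numeric(rowsum(fam$ll(eta), pid, reorder = TRUE)))
  }
  b_init <- if (!is.null(cache) && !is.null(cache$b1d) &&
                length(cache$b1d) == m) cache$b1d
  md <- agh_mode_1d(fam, eta, pid, m, tau, b_init = b_init)
  if (!is.null(cache)) cache$b1d <- md$mode
  s_hat <- 1 / sqrt(md$curv)
  B <- md$mode + sqrt(2) * s_hat %o% rule$x        # m x K node locations
  ETA <- eta + B[pid, , drop = FALSE]
  hk <- rowsum(ll_matrix(fam, ETA), pid, reorder = TRUE) +
    dnorm(B, 0, tau, log = TRUE) +
    matrix(rule$logw, m, length(rule$x), byrow = TRUE)
  lse_rows(hk) + log(sqrt(2) * s_hat)
}

# 2-D engine: random effect (b0, b1) with independent N(0, tau0^2),
# N(0, tau1^2) priors entering the linear predictor as b0 + b1 * t_pre.
agh_mode_2d <- function(fam, eta, tpre, pid, m, tau0, tau1, b_init = NULL,
                        max_iter = 25L, tol = 1e-6) {
  b0 <- b_init$b0 %||% numeric(m)
  b1 <- b_init$b1 %||% numeric(m)
  h_at <- function(b0, b1) {
    as.numeric(rowsum(fam$ll(eta + b0[pid] + b1[pid] * tpre), pid,
                      reorder = TRUE)) -
      b0^2 / (2 * tau0^2) - b1^2 / (2 * tau1^2)
  }
  h_cur <- h_at(b0, b1)
  if (any(!is.finite(h_cur))) {
    b0 <- numeric(m); b1 <- numeric(m)
    h_cur <- h_at(b0, b1)
  }
  for (it in seq_len(max_iter)) {
    ebp <- eta + b0[pid] + b1[pid] * tpre
    d1 <- fam$d1(ebp); d2 <- fam$d2(ebp)
    g1a <- as.numeric(rowsum(d1, pid, reorder = TRUE)) - b0 / tau0^2
    g1b <- as.numeric(rowsum(d1 * tpre, pid, reorder = TRUE)) - b1 / tau1^2
    h11 <- as.numeric(rowsum(d2, pid, reorder = TRUE)) - 1 / tau0^2
    h12 <- as.numeric(rowsum(d2 * tpre, pid, reorder = TRUE))
    h22 <- as.numeric(rowsum(d2 * tpre^2, pid, reorder = TRUE)) - 1 / tau1^2
    det <- h11 * h22 - h12^2
    det <- ifelse(det < 1e-12, pmax(det, 1e-12), det)
    s0 <- -( h22 * g1a - h12 * g1b) / det
    s1 <- -(-h12 * g1a + h11 * g1b) / det
    s0 <- pmax(pmin(s0, 4 * tau0), -4 * tau0)
    s1 <- pmax(pmin(s1, 4 * tau1), -4 * tau1)
    nb0 <- b0 + s0; nb1 <- b1 + s1
    h_new <- h_at(nb0, nb1)
    for (k in 1:4) {
      worse <- !is.finite(h_new) | h_new < h_cur - 1e-12
      if (!any(worse)) break
      s0[worse] <- s0[worse] / 2; s1[worse] <- s1[worse] / 2
      nb0 <- b0 + s0; nb1 <- b1 + s1
      h_new <- h_at(nb0, nb1)
    }
    keep <- is.finite(h_new) & h_new >= h_cur
    b0[keep] <- nb0[keep]; b1[keep] <- nb1[keep]
    h_cur[keep] <- h_new[keep]
    if (!any(keep) || max(abs(c(s0[keep], s1[keep]))) < tol) break
  }
  ebp <- eta + b0[pid] + b1[pid] * tpre
  d2 <- fam$d2(ebp)
  p11 <- -(as.numeric(rowsum(d2, pid, reorder = TRUE)) - 1 / tau0^2)
  p12 <- -as.numeric(rowsum(d2 * tpre, pid, reorder = TRUE))
  p22 <- -(as.numeric(rowsum(d2 * tpre^2, pid, reorder = TRUE)) - 1 / tau1^2)
  p11 <- pmax(p11, 1e-10); p22 <- pmax(p22, 1e-10)
  list(b0 = b0, b1 = b1, p11 = p11, p12 = p12, p22 = p22)
}

agh_loglik_2d <- function(fam, eta, tpre, pid, m, tau0, tau1, rule,
                          cache = NULL) {
  if (tau0 < 1e-6 && tau1 < 1e-6) {
    return(as.numeric(rowsum(fam$ll(eta), pid, reorder = TRUE)))
  }
  if (tau1 < 1e-6) {
    return(agh_loglik_1d(fam, eta, pid, m, tau0, rule, cache = cache))
  }
  tau0 <- max(tau0, 1e-6)
  b_init <- if (!is.null(cache) && !is.null(cache$b2d) &&
                length(cache$b2d$b0) == m) cache$b2d
  md <- agh_mode_2d(fam, eta, tpre, pid, m, tau0, tau1, b_init = b_init)
  if (!is.null(cache)) cache$b2d <- md[c("b0", "b1")]
  # Cholesky of the per-patient precision P = [[p11, p12], [p12, p22]]; node
  # offsets use the inverse-transpose factor so they have covariance P^{-1}.
  l11 <- sqrt(md$p11)
  l21 <- md$p12 / l11
  l22 <- sqrt(pmax(md$p22 - l21^2, 1e-12))
  K <- length(rule$x)
  xa <- rep(rule$x, each = K); xb <- rep(rule$x, times = K)
  lw <- rep(rule$logw, each = K) + rep(rule$logw, times = K)
  # L'^{-1} = [[1/l11, -l21/(l11*l22)], [0, 1/l22]]
  B0 <- md$b0 + sqrt(2) * (outer(1 / l11, xa) -
                             outer(l21 / (l11 * l22), xb))
  B1 <- md$b1 + sqrt(2) * outer(1 / l22, xb)
  ETA <- eta + B0[pid, , drop = FALSE] + B1[pid, , drop = FALSE] * tpre
  hk <- rowsum(ll_matrix(fam, ETA), pid, reorder = TRUE) +
    dnorm(B0, 0, tau0, log = TRUE) + dnorm(B1, 0, tau1, log = TRUE) +
    matrix(lw, m, K * K, byrow = TRUE)
  lse_rows(hk) + log(2) - log(l11) - log(l22)
}
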