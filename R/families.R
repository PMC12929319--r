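# Per-observation conditional log-densities and their first two derivatives
# with respect to the linear predictor. These are the building blocks shared
# by the marginal-likelihood quadrature engines and the exported likelihood
# operations. Derivatives are analytic for the Bernoulli, beta and Gaussian
# kernels; the ALDVMM mixture kernel exposes only the log-density and the
# quadrature engine differentiates it numerically.

log1p_exp <- function(x) ifelse(x > 33, x, log1p(exp(x)))

fam_bernoulli <- function(z) {
  # z: 0/1 indicator of the zero (ceiling) state
  list(
    ll = function(eta) z * eta - log1p_exp(eta),
    d1 = function(eta) z - plogis(eta),
    d2 = function(eta) {
      p <- plogis(eta)
      -p * (1 - p)
    }
  )
}

fam_beta <- function(y_star, phi) {
  # y_star: compressed decrements strictly in (0,1); phi: precision.
  # mu is kept off the exact boundary so the digamma terms stay finite when
  # the optimizer proposes extreme linear predictors.
  ly <- log(y_star); l1y <- log1p(-y_star)
  Ly <- ly - l1y
  lg_phi <- lgamma(phi)
  clamp_mu <- function(eta) pmin(pmax(plogis(eta), 1e-10), 1 - 1e-10)
  list(
    ll = function(eta) {
      # beta log-density written out with the data terms precomputed;
      # markedly faster than dbeta() over the observations x nodes matrix
      a <- clamp_mu(eta) * phi
      b <- phi - a
      (a - 1) * ly + (b - 1) * l1y + lg_phi - lgamma(a) - lgamma(b)
    },
    d1 = function(eta) {
      mu <- clamp_mu(eta)
      mu * (1 - mu) * phi * (Ly - digamma(mu * phi) + digamma((1 - mu) * phi))
    },
    d2 = function(eta) {
      mu <- clamp_mu(eta)
      dmu <- mu * (1 - mu)
      resid <- Ly - digamma(mu * phi) + digamma((1 - mu) * phi)
      dmu * (1 - 2 * mu) * phi * resid -
        phi^2 * dmu^2 * (trigamma(mu * phi) + trigamma((1 - mu) * phi))
    }
  )
}

fam_gaussian <- function(u, sigma) {
  list(
    ll = function(eta) dnorm(u, eta, sigma, log = TRUE),
    d1 = function(eta) (u - eta) / sigma^2,
    d2 = function(eta) rep(-1 / sigma^2, length(eta))
  )
}

# ALDVMM observation kernel: finite mixture of normals on the utility scale
# with censoring-induced point masses at the boundaries. Latent component
# values above psi1 are observed as u_max, below u_min as u_min. `eta` is an
# n x K matrix of component means (before the shared random intercept).
aldvmm_obs_ll <- function(u, eta, pi_c, sigma_c, psi1, u_min, u_max,
                          tol = 1e-8) {
  n <- length(u)
  K <- length(pi_c)
  at_max <- abs(u - u_max) < tol
  at_min <- abs(u - u_min) < tol
  comp <- matrix(NA_real_, n, K)
  for (c in seq_len(K)) {
    m <- eta[, c]
    lc <- numeric(n)
    if (any(at_max)) {
      lc[at_max] <- pnorm((psi1 - m[at_max]) / sigma_c[c],
                          lower.tail = FALSE, log.p = TRUE)
    }
    if (any(at_min)) {
      lc[at_min] <- pnorm((u_min - m[at_min]) / sigma_c[c], log.p = TRUE)
    }
    mid <- !at_max & !at_min
    if (any(mid)) {
      lc[mid] <- dnorm(u[mid], m[mid], sigma_c[c], log = TRUE)
    }
    comp[, c] <- lc + log(pi_c[c])
  }
  lse_rows(comp)
}

# row-wise log-sum-exp
lse_rows <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}
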