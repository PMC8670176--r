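# Independent integration oracles, deliberately written as direct probability
# sums over dense grids -- no shared code with the package's quadrature path.

# Bernoulli cluster probability at a fixed random-effect value.
# y1, y2: 0/1/NA per delivery; eta1/eta2: fixed linear predictors.
bern_cluster_prob <- function(y1, y2, eta1, eta2, b1, b2) {
  p <- 1
  for (k in seq_along(y1)) {
    if (!is.na(y1[k])) {
      p1 <- 1 / (1 + exp(-(eta1[k] + b1)))
      p <- p * ifelse(y1[k] == 1, p1, 1 - p1)
    }
    if (!is.na(y2[k])) {
      p2 <- 1 / (1 + exp(-(eta2[k] + b2)))
      p <- p * ifelse(y2[k] == 1, p2, 1 - p2)
    }
  }
  p
}

# trapezoid oracle for the shared bivariate cluster log-integral (d = 1)
oracle_biv_shared <- function(y1, y2, eta1, eta2, sigma, n_grid = 20001, span = 10) {
  b <- seq(-span * max(sigma, 0.5), span * max(sigma, 0.5), length.out = n_grid)
  f <- vapply(b, function(bb) {
    bern_cluster_prob(y1, y2, eta1, eta2, bb, bb) * dnorm(bb, 0, sigma)
  }, numeric(1))
  log(trapz_int(b, f))
}

# 2-d grid oracle for the correlated bivariate cluster (d = 2)
oracle_biv_corr <- function(y1, y2, eta1, eta2, D, n_grid = 401, span = 8) {
  sds <- sqrt(diag(D))
  g1 <- seq(-span * sds[1], span * sds[1], length.out = n_grid)
  g2 <- seq(-span * sds[2], span * sds[2], length.out = n_grid)
  Di <- solve(D)
  cst <- 1 / (2 * pi * sqrt(det(D)))
  tot <- 0
  for (b1 in g1) {
    dens <- cst * exp(-0.5 * (Di[1, 1] * b1^2 + 2 * Di[1, 2] * b1 * g2 +
                                Di[2, 2] * g2^2))
    lik <- vapply(g2, function(b2) {
      bern_cluster_prob(y1, y2, eta1, eta2, b1, b2)
    }, numeric(1))
    tot <- tot + sum(lik * dens)
  }
  log(tot * (g1[2] - g1[1]) * (g2[2] - g2[1]))
}

# multinomial cluster probability at a fixed 3-vector of random effects
multi_cluster_prob <- function(ycat, eta0, b) {
  p <- 1
  for (k in seq_along(ycat)) {
    e <- eta0[k, ] + b
    den <- 1 + sum(exp(e))
    p <- p * if (ycat[k] == 0) 1 / den else exp(e[ycat[k]]) / den
  }
  p
}

# trapezoid oracle for the shared multinomial cluster (d = 1)
oracle_multi_shared <- function(ycat, eta0, sigma, n_grid = 20001, span = 10) {
  b <- seq(-span * max(sigma, 0.5), span * max(sigma, 0.5), length.out = n_grid)
  f <- vapply(b, function(bb) {
    multi_cluster_prob(ycat, eta0, rep(bb, 3)) * dnorm(bb, 0, sigma)
  }, numeric(1))
  log(trapz_int(b, f))
}

# 3-d grid oracle for the separate-correlated multinomial cluster (d = 3)
oracle_multi_sep <- function(ycat, eta0, D, n_grid = 41, span = 8) {
  sds <- sqrt(diag(D))
  gs <- lapply(sds, function(s) seq(-span * s, span * s, length.out = n_grid))
  Di <- solve(D)
  cst <- 1 / sqrt((2 * pi)^3 * det(D))
  h <- vapply(gs, function(g) g[2] - g[1], numeric(1))
  tot <- 0
  b3v <- gs[[3]]
  for (b1 in gs[[1]]) {
    for (b2 in gs[[2]]) {
      dens <- cst * exp(-0.5 * (Di[1, 1] * b1^2 + Di[2, 2] * b2^2 +
                                  Di[3, 3] * b3v^2 + 2 * Di[1, 2] * b1 * b2 +
                                  2 * Di[1, 3] * b1 * b3v + 2 * Di[2, 3] * b2 * b3v))
      lik <- rep(1, length(b3v))
      for (k in seq_along(ycat)) {
        e1 <- eta0[k, 1] + b1
        e2 <- eta0[k, 2] + b2
        e3 <- eta0[k, 3] + b3v
        den <- 1 + exp(e1) + exp(e2) + exp(e3)
        lik <- lik * switch(as.character(ycat[k]),
                            "0" = 1 / den, "1" = exp(e1) / den,
                            "2" = exp(e2) / den, "3" = exp(e3) / den)
      }
      tot <- tot + sum(lik * dens)
    }
  }
  log(tot * prod(h))
}

trapz_int <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

# direct fixed-effects log-likelihoods (degenerate variance limits)
direct_bern_loglik <- function(y, eta) {
  sum(ifelse(y == 1, eta, 0) - log1p(exp(eta)), na.rm = TRUE)
}

direct_multi_loglik <- function(ycat, eta0) {
  ll <- 0
  for (k in seq_along(ycat)) {
    den <- log(1 + sum(exp(eta0[k, ])))
    ll <- ll + (if (ycat[k] == 0) 0 else eta0[k, ycat[k]]) - den
  }
  ll
}
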