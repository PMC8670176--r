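# small data factories shared across test files

small_registry <- function(n_mothers = 300, seed = 1, sigma2 = 0.4) {
  simulate_registry(registry_config(
    n_mothers = n_mothers, seed = seed,
    random = list(structure = "shared", sigma2 = sigma2)
  ))
}

# random small-cluster data + parameters for one oracle-equivalence case
random_cluster_case <- function(variant, seed) {
  withr::with_seed(seed, {
    K <- sample(1:5, 1)
    x <- round(rnorm(K), 2)
    if (variant %in% c("biv_shared", "biv_corr")) {
      y1 <- sample(c(0L, 1L, NA), K, replace = TRUE, prob = c(0.45, 0.45, 0.1))
      y2 <- sample(c(0L, 1L, NA), K, replace = TRUE, prob = c(0.45, 0.45, 0.1))
      if (all(is.na(y1)) && all(is.na(y2))) y1[1] <- 1L
      b1 <- round(rnorm(2, sd = 0.6), 2)
      b2 <- round(rnorm(2, sd = 0.6), 2)
      dat <- tibble::tibble(mother_id = "m", preterm = y1,
                            perinatal_death = y2, x = x)
      if (variant == "biv_shared") {
        theta <- list(beta_preterm = b1, beta_death = b2,
                      sigma2 = round(runif(1, 0.2, 1.5), 2))
      } else {
        A <- matrix(rnorm(4, sd = 0.5), 2)
        D <- A %*% t(A) + diag(0.25, 2)
        theta <- list(beta_preterm = b1, beta_death = b2, D = D)
      }
      list(data = dat, theta = theta)
    } else {
      ycat <- sample(0:3, K, replace = TRUE)
      B <- matrix(round(rnorm(6, sd = 0.5), 2), 2, 3)
      dat <- tibble::tibble(mother_id = "m",
                            cooccurrence = factor(ycat, levels = 0:3), x = x)
      if (variant == "multi_shared") {
        theta <- list(beta = B, sigma2 = round(runif(1, 0.2, 1.5), 2))
      } else {
        A <- matrix(rnorm(9, sd = 0.35), 3)
        D <- A %*% t(A) + diag(0.3, 3)
        theta <- list(beta = B, D = D)
      }
      list(data = dat, theta = theta)
    }
  })
}

# fixed predictors for a given case (design is ~ x for both outcomes)
case_etas <- function(case) {
  X <- cbind(1, case$data$x)
  if (!is.null(case$theta$beta)) {
    list(eta0 = X %*% case$theta$beta)
  } else {
    list(eta1 = drop(X %*% case$theta$beta_preterm),
         eta2 = drop(X %*% case$theta$beta_death))
  }
}
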