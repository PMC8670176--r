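biv_spec <- function(random = "shared") {
  joint_model_spec("bivariate", random, formula_preterm = ~x, formula_death = ~x)
}
multi_spec <- function(random = "shared") {
  joint_model_spec("multinomial", random, formula = ~x)
}

test_that("vanishing variance reduces the bivariate model to independent logits", {
  reg <- small_registry(n_mothers = 150, seed = 10)
  reg$x <- withr::with_seed(1, rnorm(nrow(reg)))
  theta <- list(beta_preterm = c(-1.5, 0.4), beta_death = c(-2.5, -0.2),
                psi = -20) # sigma ~ 2e-9
  ll <- loglik_bivariate(theta, reg, biv_spec("shared"))
  eta1 <- -1.5 + 0.4 * reg$x
  eta2 <- -2.5 - 0.2 * reg$x
  direct <- direct_bern_loglik(reg$preterm, eta1) +
    direct_bern_loglik(reg$perinatal_death, eta2)
  expect_equal(as.numeric(ll), direct, tolerance = 1e-8)
})

test_that("perfect correlation in D recovers the shared-parameter likelihood", {
  reg <- small_registry(n_mothers = 120, seed = 12)
  reg$x <- withr::with_seed(2, rnorm(nrow(reg)))
  s2 <- 0.6
  th_sh <- list(beta_preterm = c(-1.2, 0.3), beta_death = c(-2, 0.1), sigma2 = s2)
  th_co <- list(beta_preterm = c(-1.2, 0.3), beta_death = c(-2, 0.1),
                D = s2 * matrix(1, 2, 2))
  ll_sh <- loglik_bivariate(th_sh, reg, biv_spec("shared"))
  ll_co <- loglik_bivariate(th_co, reg, biv_spec("correlated"))
  expect_equal(as.numeric(ll_co), as.numeric(ll_sh), tolerance = 1e-6)
})

test_that("a two-category co-occurrence outcome collapses to a binary logit", {
  withr::with_seed(3, {
    n <- 60
    cl <- rep(1:20, each = 3)
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.4)
  })
  # multinomial with categories {0, 3} ("neither" vs "preterm only")
  datm <- tibble::tibble(mother_id = as.character(cl),
                         cooccurrence = ifelse(y == 1, 3L, 0L), x = x)
  # same records as a bivariate model where only preterm is observed
  datb <- tibble::tibble(mother_id = as.character(cl), preterm = as.integer(y),
                         perinatal_death = NA_integer_, x = x)
  th_m <- list(beta = matrix(c(-0.5, 0.7), 2, 1), sigma2 = 0.5)
  th_b <- list(beta_preterm = c(-0.5, 0.7), beta_death = c(0, 0), sigma2 = 0.5)
  ll_m <- loglik_multinomial(th_m, datm, multi_spec("shared"))
  ll_b <- loglik_bivariate(th_b, datb, biv_spec("shared"))
  expect_equal(as.numeric(ll_m), as.numeric(ll_b), tolerance = 1e-10)
})

test_that("vanishing variance reduces the multinomial model to ordinary multinomial logit", {
  withr::with_seed(4, {
    n <- 90
    cl <- rep(1:30, each = 3)
    x <- rnorm(n)
    ycat <- sample(0:3, n, replace = TRUE)
  })
  dat <- tibble::tibble(mother_id = as.character(cl),
                        cooccurrence = factor(ycat, levels = 0:3), x = x)
  B <- matrix(c(-1, 0.2, -0.6, -0.1, 0.3, 0.4), 2, 3)
  ll <- loglik_multinomial(list(beta = B, psi = -20), dat, multi_spec("shared"))
  direct <- direct_multi_loglik(ycat, cbind(1, x) %*% B)
  expect_equal(as.numeric(ll), direct, tolerance = 1e-8)
})

test_that("records missing one outcome contribute exactly one Bernoulli factor", {
  # one mother, one delivery with only preterm observed: the marginal
  # likelihood is the integral of a single logistic factor
  dat <- tibble::tibble(mother_id = "m", preterm = 1L,
                        perinatal_death = NA_integer_)
  sp <- joint_model_spec("bivariate", "shared")
  th <- list(beta_preterm = 0.4, beta_death = -1, sigma2 = 0.9)
  ll <- loglik_bivariate(th, dat, sp)
  b <- seq(-10, 10, length.out = 40001)
  truth <- log(trapz_int(b, plogis(0.4 + b) * dnorm(b, 0, sqrt(0.9))))
  expect_equal(as.numeric(ll), truth, tolerance = 1e-6)
  # complete-case mode drops the record entirely
  expect_error(loglik_bivariate(th, dat, sp, complete_case = TRUE),
               "empty cluster set")
})

test_that("likelihood errors are informative", {
  sp <- joint_model_spec("bivariate", "shared")
  empty <- tibble::tibble(mother_id = character(), preterm = integer(),
                          perinatal_death = integer())
  th <- list(beta_preterm = 0, beta_death = 0, sigma2 = 1)
  expect_error(loglik_bivariate(th, empty, sp), "empty cluster set")
  dat <- tibble::tibble(mother_id = "m7", preterm = 1L, perinatal_death = 0L)
  expect_error(
    loglik_bivariate(list(beta_preterm = Inf, beta_death = 0, sigma2 = 1), dat, sp),
    "non-finite linear predictor.*m7"
  )
})

test_that("the covariance encoding round-trips", {
  set.seed(5)
  for (d in 2:3) {
    A <- matrix(rnorm(d * d), d)
    D <- A %*% t(A) + diag(0.1, d)
    expect_equal(theta_decode_re(theta_encode_re(D), d), D, tolerance = 1e-10)
  }
  expect_equal(theta_decode_re(0.5 * log(0.7), 1)[1, 1], 0.7, tolerance = 1e-12)
})

test_that("adaptive and non-adaptive quadrature agree at moderate variance", {
  reg <- small_registry(n_mothers = 80, seed = 14)
  th <- list(beta_preterm = -1.5, beta_death = -2.5, sigma2 = 0.3)
  sp <- joint_model_spec("bivariate", "shared")
  ll_ad <- loglik_bivariate(th, reg, sp, rule = gh_rule(10), adaptive = TRUE)
  ll_na <- loglik_bivariate(th, reg, sp, rule = gh_rule(30), adaptive = FALSE)
  expect_equal(as.numeric(ll_ad), as.numeric(ll_na), tolerance = 1e-7)
})
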