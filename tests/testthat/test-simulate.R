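test_that("the generator is reproducible and validated", {
  cfg <- registry_config(n_mothers = 200, seed = 99)
  a <- simulate_registry(cfg)
  b <- simulate_registry(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_silent(validate_registry(a))
  # birth_index contiguous per mother by construction
  expect_true(all(vapply(
    split(a$birth_index, a$mother_id),
    function(k) identical(as.integer(sort(k)), seq_along(k)), logical(1)
  )))
})

test_that("config validation rejects malformed probability vectors and D", {
  expect_error(registry_config(births_per_mother = c(0.5, 0.6)), "summing to 1")
  expect_error(registry_config(covariates = list(x = c(a = 0.5, b = 0.4))),
               "summing to 1")
  expect_error(
    registry_config(random = list(structure = "correlated",
                                  D = matrix(c(1, 2, 2, 1), 2))),
    "positive semi-definite"
  )
  expect_error(registry_config(random = list(structure = "shared", sigma2 = -1)),
               "sigma2")
})

test_that("zero-variance, zero-coefficient generator gives 50% prevalence", {
  cfg <- registry_config(
    n_mothers = 7500, seed = 21,
    covariates = list(), covariate_sampler = NULL,
    beta_preterm = c("(Intercept)" = 0), beta_death = c("(Intercept)" = 0),
    beta_year = c(preterm = 0, death = 0),
    random = list(structure = "shared", sigma2 = 0),
    missingness = c(preterm = 0, death = 0)
  )
  reg <- simulate_registry(cfg)
  n <- nrow(reg)
  expect_gt(n, 9000) # ~1.34 deliveries per mother
  mc3 <- 3 * sqrt(0.25 / n)
  expect_lt(abs(mean(reg$preterm) - 0.5), mc3)
  expect_lt(abs(mean(reg$perinatal_death) - 0.5), mc3)
})

test_that("marginal prevalence under a shared intercept matches the quadrature integral", {
  cfg <- registry_config(
    n_mothers = 37500, seed = 8,
    covariates = list(),
    beta_preterm = c("(Intercept)" = -2), beta_death = c("(Intercept)" = -2),
    beta_year = c(preterm = 0, death = 0),
    random = list(structure = "shared", sigma2 = 1),
    missingness = c(preterm = 0, death = 0)
  )
  reg <- simulate_registry(cfg)
  n <- nrow(reg)
  expect_gt(n, 49000)
  p_theory <- theoretical_marginal_prevalence(-2, 1, Q = 200)
  # clustered binomial: inflate the 3-SE band by the design effect of
  # within-mother duplication (conservative upper bound: all K_i equal 4)
  mc3 <- 3 * sqrt(4 * p_theory * (1 - p_theory) / n)
  expect_lt(abs(mean(reg$preterm) - p_theory), mc3)
})

test_that("theoretical marginal prevalence matches closed forms and trapezoid", {
  expect_equal(theoretical_marginal_prevalence(0, 0), 0.5)
  expect_equal(theoretical_marginal_prevalence(-2, 0), plogis(-2))
  expect_equal(round(theoretical_marginal_prevalence(-2, 0), 4), 0.1192)
  b <- seq(-8, 8, length.out = 400001)
  truth <- trapz_int(b, plogis(-2 + b) * dnorm(b, 0, 1))
  expect_equal(theoretical_marginal_prevalence(-2, 1), truth, tolerance = 1e-8)
})

test_that("covariate frequencies converge to the configured marginals", {
  cfg <- registry_config(n_mothers = 37500, seed = 13,
                         missingness = c(preterm = 0, death = 0))
  reg <- simulate_registry(cfg)
  for (nm in names(cfg$covariates)) {
    obs <- table(reg[[nm]])
    p <- cfg$covariates[[nm]]
    gof <- chisq.test(as.vector(obs), p = p[names(obs)])
    expect_gt(gof$p.value, 0.001)
  }
})

test_that("positive covariance in D raises the within-mother outcome odds ratio", {
  or_at <- function(cov, seed) {
    D <- matrix(c(0.8, cov, cov, 0.8), 2)
    cfg <- registry_config(
      n_mothers = 15000, seed = seed,
      covariates = list(),
      beta_preterm = c("(Intercept)" = -1.5),
      beta_death = c("(Intercept)" = -1.5),
      beta_year = c(preterm = 0, death = 0),
      random = list(structure = "correlated", D = D),
      missingness = c(preterm = 0, death = 0)
    )
    reg <- simulate_registry(cfg)
    tab <- table(reg$preterm, reg$perinatal_death)
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  ors <- c(or_at(-0.2, 31), or_at(0, 31), or_at(0.3, 31))
  expect_true(all(diff(ors) > 0))
  # diagonal D with no covariates: outcomes independent, OR near 1
  expect_lt(abs(log(ors[2])), 0.15)
})

test_that("missingness produces the unbalanced per-outcome denominators", {
  reg <- simulate_registry(registry_config(n_mothers = 3000, seed = 5))
  n1 <- sum(!is.na(reg$preterm))
  n2 <- sum(!is.na(reg$perinatal_death))
  expect_lt(n1, n2) # gestational age is missing far more often
  expect_true(all(is.na(reg$gestational_age_weeks[is.na(reg$preterm)])))
  # preterm indicator always agrees with the synthesized gestational age
  ok <- !is.na(reg$preterm)
  expect_identical(reg$preterm[ok],
                   encode_preterm(reg$gestational_age_weeks[ok]))
})

test_that("generator truth sidecar round-trips through JSON", {
  reg <- small_registry(n_mothers = 30, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_generator_truth(reg, path)
  truth <- jsonlite::read_json(path)
  expect_equal(truth$structure, "shared")
  expect_equal(truth$n_mothers, 30)
  expect_equal(truth$beta_preterm[["anc_visits<4"]],
               unname(attr(reg, "config")$beta_preterm["anc_visits<4"]))
})

test_that("the co-occurrence generator follows the multinomial probabilities", {
  B <- matrix(c(-2.5, -2.2, -1.3), 1, 3,
              dimnames = list("(Intercept)", NULL))
  reg <- simulate_cooccurrence_registry(
    20000, B, random = list(structure = "shared", sigma2 = 0), seed = 4
  )
  p_obs <- as.vector(prop.table(table(reg$cooccurrence)))
  p_true <- c(1, exp(B)) / (1 + sum(exp(B)))
  expect_lt(max(abs(p_obs - p_true)), 3 * sqrt(max(p_true) / nrow(reg)) + 0.005)
  expect_identical(
    as.data.frame(simulate_cooccurrence_registry(200, B, seed = 9)),
    as.data.frame(simulate_cooccurrence_registry(200, B, seed = 9))
  )
})
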