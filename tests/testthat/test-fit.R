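fit_registry <- function(n_mothers = 400, seed = 20, sigma2 = 0.5) {
  simulate_registry(registry_config(
    n_mothers = n_mothers, seed = seed,
    random = list(structure = "shared", sigma2 = sigma2)
  ))
}

biv_formula_spec <- joint_model_spec(
  "bivariate", "shared",
  formula_preterm = ~ anc_visits + referral,
  formula_death = ~ anc_visits + referral
)

test_that("fitting is deterministic and matches an independent mixed-model fit", {
  skip_if_not_installed("lme4")
  reg <- fit_registry(n_mothers = 500, seed = 25)
  f1 <- fit_joint(reg, biv_formula_spec, vcov = "model")
  f2 <- fit_joint(reg, biv_formula_spec, vcov = "model")
  expect_identical(f1$par, f2$par)
  expect_identical(f1$loglik, f2$loglik)
  expect_true(f1$converged)

  # independent route: lme4 on the stacked binary responses with a common
  # mother-level intercept, same 10-point adaptive quadrature
  long <- tidyr::pivot_longer(reg, c("preterm", "perinatal_death"),
                              names_to = "oc", values_to = "y")
  long <- long[!is.na(long$y), ]
  gf <- lme4::glmer(y ~ 0 + oc + oc:anc_visits + oc:referral + (1 | mother_id),
                    data = long, family = binomial, nAGQ = 10)
  expect_equal(f1$loglik, as.numeric(stats::logLik(gf)), tolerance = 1e-6)
  expect_equal(unname(f1$coefficients$sigma2),
               unname(as.numeric(lme4::VarCorr(gf)$mother_id[1])),
               tolerance = 1e-3)
  fe <- lme4::fixef(gf)
  expect_equal(unname(f1$coefficients$beta_preterm["(Intercept)"]),
               unname(fe["ocpreterm"]), tolerance = 1e-4)
  expect_equal(unname(f1$coefficients$beta_death["anc_visits<4"]),
               unname(fe["ocperinatal_death:anc_visits<4"]), tolerance = 1e-3)
})

test_that("zero-variance multinomial fit agrees with an independent multinomial logit", {
  skip_if_not_installed("nnet")
  reg <- fit_registry(n_mothers = 400, seed = 26, sigma2 = 0.3)
  spm <- joint_model_spec("multinomial", "shared", formula = ~anc_visits)
  # evaluate our marginal likelihood at nnet's fixed-effects optimum with the
  # variance pinned near zero: must equal nnet's maximized log-likelihood
  reg$cooc <- encode_cooccurrence(reg$preterm, reg$perinatal_death)
  cc <- !is.na(reg$cooc)
  mn <- nnet::multinom(factor(cooc) ~ anc_visits, data = reg[cc, ], trace = FALSE)
  B <- t(stats::coef(mn))
  ll <- loglik_multinomial(list(beta = B, psi = -20), reg, spm)
  expect_equal(as.numeric(ll), -mn$value, tolerance = 1e-6)
})

test_that("finite-difference score and information behave like likelihood theory says", {
  reg <- fit_registry(n_mothers = 120, seed = 27)
  sp <- joint_model_spec("bivariate", "shared",
                         formula_preterm = ~anc_visits, formula_death = ~1)
  fit <- fit_joint(reg, sp, vcov = "model")
  si <- score_and_information(fit)
  # first-order condition at the maximum
  expect_lt(max(abs(si$gradient)), 1e-4)
  # information at the maximum is positive semi-definite
  ev <- eigen(si$information, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-6 * max(ev))

  # away from the maximum the FD gradient matches its definition
  theta <- list(beta_preterm = c(-1.2, 0.5), beta_death = -2.2, sigma2 = 0.4)
  si2 <- score_and_information(theta, reg, sp)
  par <- c(-1.2, 0.5, -2.2, 0.5 * log(0.4))
  f <- function(p) {
    th <- list(beta_preterm = p[1:2], beta_death = p[3], psi = p[4])
    as.numeric(loglik_bivariate(th, reg, sp))
  }
  for (i in seq_along(par)) {
    h <- 1e-5 * max(1, abs(par[i]))
    e <- numeric(4); e[i] <- h
    expect_equal(unname(si2$gradient[i]), (f(par + e) - f(par - e)) / (2 * h),
                 tolerance = 1e-6)
  }
})

test_that("model-based and robust covariances are close under correct specification", {
  reg <- fit_registry(n_mothers = 900, seed = 28)
  sp <- joint_model_spec("bivariate", "shared",
                         formula_preterm = ~anc_visits, formula_death = ~anc_visits)
  fit <- fit_joint(reg, sp, vcov = "both")
  se_m <- sqrt(diag(vcov(fit, "model")))
  se_r <- sqrt(diag(vcov(fit, "robust")))
  # fixed effects: sandwich and inverse-information agree to ~15% here
  nb <- 4
  expect_lt(max(abs(se_r[1:nb] / se_m[1:nb] - 1)), 0.15)
})

test_that("correlated bivariate fit recovers the generating covariance", {
  D_true <- matrix(c(0.6, 0.3, 0.3, 0.5), 2)
  cfg <- registry_config(
    n_mothers = 1500, seed = 29,
    covariates = list(anc_visits = c("4+" = 0.7, "<4" = 0.3)),
    beta_preterm = c("(Intercept)" = -1.5, "anc_visits<4" = 0.8),
    beta_death = c("(Intercept)" = -1.8, "anc_visits<4" = 0.4),
    beta_year = c(preterm = 0, death = 0),
    random = list(structure = "correlated", D = D_true),
    missingness = c(preterm = 0, death = 0)
  )
  reg <- simulate_registry(cfg)
  sp <- joint_model_spec("bivariate", "correlated",
                         formula_preterm = ~anc_visits, formula_death = ~anc_visits)
  fit <- fit_joint(reg, sp, vcov = "model")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$coefficients$D - D_true)), 0.35)
  se <- sqrt(diag(vcov(fit, "model")))[1:4]
  est <- fit$par[1:4]
  truth <- c(-1.5, 0.8, -1.8, 0.4)
  expect_true(all(abs(est - truth) < 3.5 * se))
})

test_that("constrained D equal to sigma2*J reproduces the shared fit", {
  reg <- fit_registry(n_mothers = 400, seed = 30)
  sp_sh <- joint_model_spec("bivariate", "shared",
                            formula_preterm = ~anc_visits, formula_death = ~anc_visits)
  fit_sh <- fit_joint(reg, sp_sh, vcov = "none")
  th_co <- list(
    beta_preterm = fit_sh$coefficients$beta_preterm,
    beta_death = fit_sh$coefficients$beta_death,
    D = fit_sh$coefficients$sigma2 * matrix(1, 2, 2)
  )
  sp_co <- joint_model_spec("bivariate", "correlated",
                            formula_preterm = ~anc_visits, formula_death = ~anc_visits)
  ll <- loglik_bivariate(th_co, reg, sp_co)
  expect_equal(as.numeric(ll), fit_sh$loglik, tolerance = 1e-5)
})

test_that("non-convergence is flagged, not hidden", {
  reg <- fit_registry(n_mothers = 150, seed = 31)
  sp <- joint_model_spec("bivariate", "shared",
                         formula_preterm = ~anc_visits, formula_death = ~1)
  expect_warning(
    fit <- fit_joint(reg, sp, vcov = "none",
                     control = list(max_outer = 1, inner_maxit = 2)),
    "did not converge"
  )
  expect_false(fit$converged)
  expect_error(odds_ratio_table(fit), "did not converge")
})
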