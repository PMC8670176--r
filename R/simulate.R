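#' Configuration for the synthetic mother-clustered registry generator
#'
#' Bundles and validates every parameter of the synthetic data-generating
#' process: the number of mothers, the distribution of deliveries per mother,
#' categorical covariate marginals, true logistic coefficients for each
#' outcome, a linear secular year trend on the logit scale, the random-effects
#' structure (one scalar intercept shared by both outcomes, or a correlated
#' bivariate intercept), per-outcome missingness rates, and the seed.
#'
#' Defaults emulate the structure of a large East-African referral-hospital
#' birth registry: about 1.34 deliveries per mother on support 1--4, an
#' inadequate-ANC prevalence near 31%, referral near 24%, outcome marginals
#' near 13% (preterm) and 4% (perinatal death), a random-intercept variance of
#' 0.18, gestational age missing for about 12% of deliveries and perinatal
#' status for 0.3%. True coefficients follow the direction and rough size of
#' effects reported for such registries (for example a strong positive
#' inadequate-ANC effect on preterm birth) but are round preset values, not
#' estimates from any particular data set.
#'
#' @param n_mothers Number of mothers (clusters).
#' @param births_per_mother Probability vector over 1..K_max deliveries.
#' @param covariates Named list: each element a named probability vector over
#'   that covariate's categories (first category = reference).
#' @param beta_preterm,beta_death Named coefficient vectors on the logit
#'   scale. Names are `"(Intercept)"` and `paste0(covariate, level)` for
#'   non-reference levels, as produced by treatment-coded [model.matrix()].
#' @param year_range Integer vector of calendar years sampled uniformly.
#' @param beta_year Length-2 named vector `c(preterm = , death = )`: logit
#'   change per year since the first year.
#' @param random Either `list(structure = "shared", sigma2 = )` or
#'   `list(structure = "correlated", D = )` with `D` a symmetric positive
#'   semi-definite 2 x 2 matrix.
#' @param missingness Named rates `c(preterm = , death = )`: each outcome is
#'   set missing independently with this probability (gestational age is
#'   blanked when the preterm outcome is missing).
#' @param covariate_sampler Optional function `(n, config)` returning a data
#'   frame of covariate columns for `n` deliveries, replacing the default
#'   independent-marginals draw for realism studies.
#' @param seed Integer seed governing all draws.
#' @return A validated list of class `registry_config`.
#' @export
registry_config <- function(
    n_mothers = 2000,
    births_per_mother = c(0.72, 0.23, 0.04, 0.01),
    covariates = list(
      anc_visits = c("4+" = 0.686, "<4" = 0.314),
      referral = c(no = 0.763, yes = 0.237),
      preeclampsia = c(no = 0.958, yes = 0.042),
      child_sex = c(female = 0.485, male = 0.515)
    ),
    beta_preterm = c("(Intercept)" = -2.9, "anc_visits<4" = 1.0,
                     referralyes = 0.3, preeclampsiayes = 0.6,
                     child_sexmale = 0.1),
    beta_death = c("(Intercept)" = -3.0, "anc_visits<4" = 0.3,
                   referralyes = 0.3, preeclampsiayes = 0.1,
                   child_sexmale = -0.2),
    year_range = 2000:2017,
    beta_year = c(preterm = 0.04, death = -0.03),
    random = list(structure = "shared", sigma2 = 0.18),
    missingness = c(preterm = 0.12, death = 0.003),
    covariate_sampler = NULL,
    seed = 1L) {
  check_prob_vector <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-12) {
      abort(sprintf("%s must be a non-negative probability vector summing to 1", what))
    }
  }
  check_prob_vector(births_per_mother, "births_per_mother")
  for (nm in names(covariates)) {
    check_prob_vector(covariates[[nm]], sprintf("covariate marginal '%s'", nm))
    if (is.null(names(covariates[[nm]]))) {
      abort(sprintf("covariate marginal '%s' must have category names", nm))
    }
  }
  random$structure <- match.arg(random$structure, c("shared", "correlated"))
  if (random$structure == "shared") {
    if (is.null(random$sigma2) || random$sigma2 < 0) {
      abort("shared random-effects structure requires sigma2 >= 0")
    }
  } else {
    D <- random$D
    if (is.null(D) || !all(dim(as.matrix(D)) == 2L)) {
      abort("correlated random-effects structure requires a 2 x 2 matrix D")
    }
    D <- as.matrix(D)
    if (max(abs(D - t(D))) > 1e-10 || any(eigen(D, symmetric = TRUE,
                                                only.values = TRUE)$values < -1e-10)) {
      abort("D must be symmetric positive semi-definite")
    }
    random$D <- D
  }
  stopifnot(all(missingness >= 0), all(missingness <= 1))
  structure(
    list(n_mothers = as.integer(n_mothers),
         births_per_mother = births_per_mother,
         covariates = covariates,
         beta_preterm = beta_preterm, beta_death = beta_death,
         year_range = as.integer(year_range), beta_year = beta_year,
         random = random, missingness = missingness,
         covariate_sampler = covariate_sampler,
         seed = as.integer(seed)),
    class = "registry_config"
  )
}

#' Simulate a mother-clustered synthetic birth registry
#'
#' Generates delivery-level records with the statistical structure the joint
#' models assume: for each mother a latent random intercept (shared scalar or
#' correlated bivariate) is drawn, each of her deliveries receives covariates
#' and a calendar year, the two outcomes are Bernoulli draws from
#' inverse-logit linear predictors including the random effect and year trend,
#' and missingness is applied per outcome. A gestational age consistent with
#' the preterm indicator is synthesized so that records round-trip through the
#' schema layer.
#'
#' Draws are consumed from one stream seeded by `config$seed` in a fixed
#' order -- deliveries per mother, random effects, years, outcome uniforms,
#' missingness, gestational-age noise, then covariates -- so changing the
#' covariate block never reshuffles the outcomes.
#'
#' @param config A [registry_config()].
#' @return A tibble of delivery records (one row per singleton delivery) with
#'   the generating configuration attached as attribute `"config"` and the
#'   per-mother random effects as attribute `"random_effects"`.
#' @examples
#' reg <- simulate_registry(registry_config(n_mothers = 50, seed = 7))
#' head(reg)
#' @export
simulate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  withr::with_seed(config$seed, simulate_registry_impl(config))
}

simulate_registry_impl <- function(config) {
  n_m <- config$n_mothers
  kmax <- length(config$births_per_mother)

  # (1) deliveries per mother
  K <- sample.int(kmax, n_m, replace = TRUE, prob = config$births_per_mother)
  n <- sum(K)
  cl <- rep(seq_len(n_m), K)

  # (2) mother-level random intercepts
  if (config$random$structure == "shared") {
    b <- matrix(rnorm(n_m, sd = sqrt(config$random$sigma2)), ncol = 1L)
    b1 <- b[cl, 1L]
    b2 <- b[cl, 1L]
  } else {
    L <- t(chol(config$random$D + diag(1e-12, 2L)))
    b <- matrix(rnorm(2L * n_m), ncol = 2L) %*% t(L)
    b1 <- b[cl, 1L]
    b2 <- b[cl, 2L]
  }

  # (3) calendar year per delivery
  year <- sample(config$year_range, n, replace = TRUE)
  year_c <- year - min(config$year_range)

  # (4) outcome uniforms (drawn before covariates, compared after)
  u1 <- runif(n)
  u2 <- runif(n)

  # (5) missingness uniforms
  m1 <- runif(n)
  m2 <- runif(n)

  # (6) gestational-age noise
  v <- runif(n)

  # (7) covariates
  covs <- if (is.null(config$covariate_sampler)) {
    tibble::as_tibble(purrr::map(config$covariates, function(p) {
      factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
    }))
  } else {
    tibble::as_tibble(config$covariate_sampler(n, config))
  }

  X <- if (ncol(covs)) {
    model.matrix(~., data = covs)
  } else {
    matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  }
  lp_fixed <- function(beta, which_year) {
    miss <- setdiff(names(beta), colnames(X))
    if (length(miss)) {
      abort(sprintf("coefficients not matched by covariate design: %s",
                    paste(miss, collapse = ", ")))
    }
    drop(X[, names(beta), drop = FALSE] %*% beta) +
      config$beta_year[[which_year]] * year_c
  }
  eta1 <- lp_fixed(config$beta_preterm, "preterm") + b1
  eta2 <- lp_fixed(config$beta_death, "death") + b2

  preterm <- as.integer(u1 < plogis(eta1))
  death <- as.integer(u2 < plogis(eta2))

  preterm[m1 < config$missingness[["preterm"]]] <- NA_integer_
  death[m2 < config$missingness[["death"]]] <- NA_integer_

  ga <- ifelse(preterm == 1L, 27 + 9.9 * v, 37 + 5.5 * v)
  ga <- round(ga, 1L)
  ga[is.na(preterm)] <- NA_real_

  out <- tibble::tibble(
    mother_id = sprintf("M%06d", cl),
    birth_index = unlist(lapply(K, seq_len)),
    year = year,
    plurality = "singleton",
    gestational_age_weeks = ga,
    preterm = preterm,
    perinatal_death = death
  )
  if (ncol(covs)) out <- dplyr::bind_cols(out, covs)
  attr(out, "config") <- config
  attr(out, "random_effects") <- b
  out
}

#' Write the true generating parameters of a simulated registry as JSON
#'
#' Sidecar companion to [write_registry()] for parameter-recovery studies.
#'
#' @param records A tibble from [simulate_registry()].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_generator_truth <- function(records, path) {
  config <- attr(records, "config")
  if (is.null(config)) abort("records carry no generator config attribute")
  truth <- list(
    beta_preterm = as.list(config$beta_preterm),
    beta_death = as.list(config$beta_death),
    beta_year = as.list(config$beta_year),
    random = config$random[setdiff(names(config$random), "structure")],
    structure = config$random$structure,
    n_mothers = config$n_mothers,
    seed = config$seed
  )
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate mother-clustered co-occurrence outcomes from a random-effects
#' multinomial model
#'
#' Generates delivery-level records whose four-category co-occurrence outcome
#' (0 = neither event, 1 = both, 2 = death only, 3 = preterm only) follows the
#' mixed multinomial logit directly: per mother a random intercept is drawn
#' (scalar shared across the three non-reference logits, or a correlated
#' 3-vector), each delivery receives covariates, and the category is sampled
#' from the softmax probabilities. This is the generating process for
#' model-comparison studies between the shared and separate-but-correlated
#' multinomial variants.
#'
#' @param n_mothers Number of mothers.
#' @param beta Coefficient matrix, terms x 3 non-reference categories; row
#'   names must match the treatment-coded design columns of the covariates
#'   (`"(Intercept)"` first).
#' @param covariates Named list of category probability vectors as in
#'   [registry_config()] (may be empty for an intercept-only model).
#' @param births_per_mother Probability vector over 1..K_max deliveries.
#' @param random `list(structure = "shared", sigma2 = )` or
#'   `list(structure = "correlated", D = )` with `D` 3 x 3 PSD.
#' @param seed Integer seed.
#' @return Tibble with `mother_id`, `birth_index`, `cooccurrence` (factor with
#'   levels 0--3) and covariate columns; the generating parameters are
#'   attached as attribute `"truth"`.
#' @export
simulate_cooccurrence_registry <- function(n_mothers, beta, covariates = list(),
                                           births_per_mother = c(0.72, 0.23, 0.04, 0.01),
                                           random = list(structure = "shared", sigma2 = 0.3),
                                           seed = 1L) {
  beta <- as.matrix(beta)
  stopifnot(ncol(beta) == 3L)
  random$structure <- match.arg(random$structure, c("shared", "correlated"))
  withr::with_seed(as.integer(seed), {
    K <- sample.int(length(births_per_mother), n_mothers, replace = TRUE,
                    prob = births_per_mother)
    n <- sum(K)
    cl <- rep(seq_len(n_mothers), K)
    if (random$structure == "shared") {
      b <- matrix(rnorm(n_mothers, sd = sqrt(random$sigma2)), ncol = 1L)
      Bc <- b[cl, c(1L, 1L, 1L)]
    } else {
      D <- as.matrix(random$D)
      stopifnot(all(dim(D) == 3L))
      L <- t(chol(D + diag(1e-12, 3L)))
      b <- matrix(rnorm(3L * n_mothers), ncol = 3L) %*% t(L)
      Bc <- b[cl, , drop = FALSE]
    }
    covs <- tibble::as_tibble(purrr::map(covariates, function(p) {
      factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
    }))
    X <- if (ncol(covs)) model.matrix(~., data = covs) else
      matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
    stopifnot(all(rownames(beta) %in% colnames(X)))
    eta <- X[, rownames(beta), drop = FALSE] %*% beta + Bc
    expeta <- exp(eta)
    den <- 1 + rowSums(expeta)
    P <- cbind(1 / den, expeta / den)
    u <- runif(n)
    c1 <- P[, 1L]
    c2 <- c1 + P[, 2L]
    c3 <- c2 + P[, 3L]
    ycat <- (u > c1) + (u > c2) + (u > c3)
    out <- tibble::tibble(
      mother_id = sprintf("M%06d", cl),
      birth_index = unlist(lapply(K, seq_len)),
      cooccurrence = factor(ycat, levels = 0:3)
    )
    if (ncol(covs)) out <- dplyr::bind_cols(out, covs)
    attr(out, "truth") <- list(beta = beta, random = random, seed = seed)
    out
  })
}

#' Marginal outcome prevalence implied by a random-intercept logit model
#'
#' Integrates the inverse-logit of `intercept + b` over `b ~ N(0, variance)`
#' by high-order Gauss--Hermite quadrature; with `variance = 0` this is just
#' `plogis(intercept)`. Used to calibrate generator intercepts against target
#' marginal prevalences.
#'
#' @param intercept Linear-predictor intercept on the logit scale.
#' @param variance Random-intercept variance (>= 0).
#' @param Q Quadrature order (default 200).
#' @return Probability in (0, 1).
#' @examples
#' theoretical_marginal_prevalence(-2, 0) # plogis(-2)
#' theoretical_marginal_prevalence(-2, 1)
#' @export
theoretical_marginal_prevalence <- function(intercept, variance, Q = 200) {
  stopifnot(variance >= 0)
  if (variance == 0) return(plogis(intercept))
  r <- gh_rule(Q)
  sum(r$weights * plogis(intercept + sqrt(variance) * r$nodes[, 1L]))
}
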