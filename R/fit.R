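#' Fit a joint random-effects model by adaptive Gauss--Hermite ML
#'
#' Maximizes the marginal likelihood of the chosen model variant (see
#' [joint_model_spec()]) over the fixed effects and the log-Cholesky-encoded
#' random-effects covariance. Estimation alternates an outer step that
#' refreshes each mother's adaptive quadrature nodes (posterior mode and
#' curvature of her random-effect integrand) with an inner quasi-Newton (BFGS)
#' maximization of the fixed-node approximate log-likelihood, for which the
#' analytic score is exact; the outer loop stops when the refreshed
#' log-likelihood changes by less than `1e-8` (relative). Initial fixed
#' effects come from outcome-wise (or category-wise) ordinary logistic fits
#' and variance parameters start at log-SD `log(0.3)`, so the fit is
#' deterministic given data and options.
#'
#' @param data Delivery-level data frame with `mother_id`, outcomes and the
#'   covariates named in the spec's formulas.
#' @param spec A [joint_model_spec()].
#' @param quad_points Gauss--Hermite points per random-effect dimension
#'   (default 10). Three-dimensional correlated multinomial fits use the full
#'   tensor grid (`quad_points^3` nodes); lowering `quad_points` to 4--5 is a
#'   documented speed option there, with adaptivity preserving accuracy.
#' @param adaptive Use adaptive (mode-centred) quadrature (default `TRUE`).
#' @param vcov Which covariance estimates to compute: `"both"` (default:
#'   model-based inverse observed information and cluster-robust sandwich),
#'   `"model"`, `"robust"`, or `"none"` (fastest; for likelihood-only uses
#'   such as BIC comparison).
#' @param complete_case Restrict the bivariate model to deliveries with both
#'   outcomes observed (default `FALSE`: partially observed deliveries
#'   contribute their observed outcome's likelihood factor).
#' @param control Optional list: `max_outer` (default 30), `inner_maxit`
#'   (default 100), `reltol` (outer relative log-likelihood tolerance,
#'   default 1e-8), `fd_step` (relative finite-difference step for the
#'   information, default 1e-5), `init` (packed starting values, e.g. mapped
#'   over from a simpler nested fit; replaces the default deterministic
#'   initialization).
#' @return An object of class `joint_fit`: estimates (`coefficients`, decoded
#'   `sigma2` or `D`), `loglik`, `BIC` (with N = number of delivery records in
#'   the fit), covariance matrices, convergence diagnostics, and counts.
#' @examples
#' reg <- simulate_registry(registry_config(n_mothers = 300, seed = 1))
#' sp <- joint_model_spec("bivariate", "shared",
#'                        formula_preterm = ~ anc_visits,
#'                        formula_death = ~ anc_visits)
#' fit <- fit_joint(reg, sp, vcov = "model")
#' fit
#' @export
fit_joint <- function(data, spec, quad_points = 10, adaptive = TRUE,
                      vcov = c("both", "model", "robust", "none"),
                      complete_case = FALSE, control = list()) {
  vcov <- match.arg(vcov)
  ctrl <- utils::modifyList(
    list(max_outer = 30L, inner_maxit = 100L, reltol = 1e-8, fd_step = 1e-5),
    control
  )
  ws <- build_workspace(data, spec, complete_case = complete_case)
  if (ws$G < 2L) abort("at least 2 clusters (mothers) are required")
  Q <- as.integer(quad_points)

  par <- if (!is.null(ctrl$init)) {
    stopifnot(length(ctrl$init) == ws$n_par)
    as.numeric(ctrl$init)
  } else {
    init_par(ws)
  }
  ll_old <- -Inf
  ll_new <- NA_real_
  warm <- NULL
  converged <- FALSE
  inner_counts <- 0L
  outer <- 0L
  modes <- NULL
  repeat {
    outer <- outer + 1L
    pp <- unpack_par(par, ws)
    modes <- if (adaptive) find_modes(pp, ws, U0 = warm) else identity_modes(ws)
    warm <- modes$U
    # BFGS asks for fn and gr at the same point back-to-back; one shared
    # evaluation (loglik + analytic score, nodes fixed) serves both
    memo <- new.env(parent = emptyenv())
    eval_at <- function(p) {
      key <- paste(p, collapse = ",")
      if (!identical(memo$key, key)) {
        memo$val <- agq_eval(p, ws, Q = Q, cache = modes, want_score = TRUE)
        memo$key <- key
      }
      memo$val
    }
    opt <- stats::optim(
      par,
      fn = function(p) eval_at(p)$loglik,
      gr = function(p) eval_at(p)$score,
      method = "BFGS",
      control = list(fnscale = -1, maxit = ctrl$inner_maxit, reltol = 1e-12)
    )
    par <- opt$par
    inner_counts <- inner_counts + opt$counts[["function"]]
    ev <- agq_eval(par, ws, Q = Q, adaptive = adaptive, warm = warm)
    ll_new <- ev$loglik
    if (abs(ll_new - ll_old) < ctrl$reltol * (abs(ll_new) + 1)) {
      converged <- TRUE
      modes <- ev$modes
      break
    }
    ll_old <- ll_new
    if (!adaptive || outer >= ctrl$max_outer) {
      converged <- !adaptive
      modes <- ev$modes
      break
    }
  }
  if (!converged) {
    warn(sprintf("fit did not converge within %d outer iterations", ctrl$max_outer))
  }

  sc <- agq_eval(par, ws, Q = Q, cache = modes, want_score = TRUE)
  grad_norm <- max(abs(sc$score))

  big <- which(abs(par[seq_len(ws$n_par - re_npar(ws$d))]) > 15)
  if (length(big)) {
    warn(sprintf("possible separation: |estimate| > 15 for %s",
                 paste(ws$par_names[big], collapse = ", ")))
  }

  names(par) <- ws$par_names
  fit <- structure(
    list(
      spec = spec, par = par, ws = ws,
      coefficients = decode_par(par, ws),
      loglik = ll_new,
      np = ws$n_par,
      nobs = ws$n_records,
      BIC = -2 * ll_new + ws$n_par * log(ws$n_records),
      n_mothers = ws$G,
      n_preterm = ws$n_preterm %||% NA_integer_,
      n_death = ws$n_death %||% NA_integer_,
      converged = converged,
      outer_iterations = outer,
      inner_evaluations = inner_counts,
      grad_norm = grad_norm,
      quad = list(points = Q, adaptive = adaptive),
      complete_case = complete_case,
      vcov_model = NULL, vcov_robust = NULL,
      fingerprint = c(n_records = ws$n_records, n_mothers = ws$G)
    ),
    class = "joint_fit"
  )

  if (vcov != "none") {
    info <- fd_information(par, ws, Q, adaptive, ctrl$fd_step)
    Vm <- tryCatch(chol2inv(chol(info)), error = function(e) {
      warn("observed information not positive definite; using pseudo-inverse")
      MASS_ginv(info)
    })
    dimnames(Vm) <- list(ws$par_names, ws$par_names)
    if (vcov %in% c("both", "model")) fit$vcov_model <- Vm
    if (vcov %in% c("both", "robust")) {
      Scl <- fd_cluster_scores(par, ws, Q, adaptive, ctrl$fd_step)
      B <- crossprod(Scl)
      Vr <- Vm %*% B %*% Vm * ws$G / (ws$G - 1)
      Vr <- (Vr + t(Vr)) / 2
      dimnames(Vr) <- dimnames(Vm)
      fit$vcov_robust <- Vr
    }
  }
  fit
}

# Moore-Penrose fallback without adding a MASS dependency
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

init_par <- function(ws) {
  logistic_init <- function(X, y) {
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial()))
    b <- coef(fit)
    b[!is.finite(b)] <- 0
    pmin(pmax(b, -10), 10)
  }
  if (ws$type == "bern") {
    beta <- c(logistic_init(ws$X1, ws$y[ws$i1]),
              logistic_init(ws$X2, ws$y[ws$i2]))
  } else {
    beta <- as.vector(vapply(seq_len(ws$C - 1L), function(c) {
      sel <- ws$ycat %in% c(0L, c)
      logistic_init(ws$X[sel, , drop = FALSE], as.numeric(ws$ycat[sel] == c))
    }, numeric(ws$p)))
  }
  psi <- numeric(re_npar(ws$d))
  i <- 1L
  for (k in seq_len(ws$d)) {
    for (j in k:ws$d) {
      psi[i] <- if (j == k) log(0.3) else 0
      i <- i + 1L
    }
  }
  c(beta, psi)
}

decode_par <- function(par, ws) {
  d <- ws$d
  psi <- par[ws$n_par - re_npar(d) + seq_len(re_npar(d))]
  L <- re_unpack(psi, d)
  D <- L %*% t(L)
  out <- if (ws$type == "bern") {
    list(
      beta_preterm = setNames(par[seq_len(ws$p1)], colnames(ws$X1)),
      beta_death = setNames(par[ws$p1 + seq_len(ws$p2)], colnames(ws$X2))
    )
  } else {
    B <- matrix(par[seq_len(ws$p * (ws$C - 1L))], ws$p, ws$C - 1L,
                dimnames = list(colnames(ws$X), ws$categories[-1]))
    list(beta = B)
  }
  if (d == 1L) {
    out$sigma2 <- D[1L, 1L]
  } else {
    out$D <- D
  }
  out$psi <- setNames(psi, psi_names(d))
  out
}

# ---- finite-difference inference (likelihood-theory covariance) -------------

fd_steps <- function(par, rel_step) rel_step * pmax(abs(par), 1)

fd_information <- function(par, ws, Q, adaptive, rel_step = 1e-5) {
  f <- function(p) agq_eval(p, ws, Q = Q, adaptive = adaptive)$loglik
  p <- length(par)
  h <- fd_steps(par, rel_step)
  f0 <- f(par)
  fp <- fm <- numeric(p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- h[i]
    fp[i] <- f(par + e)
    fm[i] <- f(par - e)
  }
  H <- matrix(0, p, p)
  diag(H) <- (fp + fm - 2 * f0) / h^2
  if (p > 1) {
    for (i in seq_len(p - 1)) {
      for (j in (i + 1):p) {
        ei <- numeric(p); ei[i] <- h[i]
        ej <- numeric(p); ej[j] <- h[j]
        H[i, j] <- H[j, i] <-
          (f(par + ei + ej) - f(par + ei - ej) -
             f(par - ei + ej) + f(par - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  if (any(!is.finite(H))) abort("non-finite entries in the observed information")
  info <- -(H + t(H)) / 2
  dimnames(info) <- list(ws$par_names, ws$par_names)
  info
}

fd_cluster_scores <- function(par, ws, Q, adaptive, rel_step = 1e-5) {
  p <- length(par)
  h <- fd_steps(par, rel_step)
  S <- matrix(0, ws$G, p)
  for (i in seq_len(p)) {
    e <- numeric(p); e[i] <- h[i]
    lp <- agq_eval(par + e, ws, Q = Q, adaptive = adaptive)$per_cluster
    lm <- agq_eval(par - e, ws, Q = Q, adaptive = adaptive)$per_cluster
    S[, i] <- (lp - lm) / (2 * h[i])
  }
  S
}

#' Score vector and observed information by central finite differences
#'
#' Differentiates the (adaptive Gauss--Hermite) log-likelihood numerically:
#' central first differences for the score and central second differences for
#' the Hessian, with relative step `rel_step`; the information is the
#' symmetrized negative Hessian. A Richardson extrapolation option refines the
#' score.
#'
#' @param theta Either a fitted [fit_joint()] object (evaluated at its
#'   estimate) or a natural-parameter list as in [loglik_bivariate()] /
#'   [loglik_multinomial()], with `data` and `spec` supplied.
#' @param data,spec Ignored when `theta` is a `joint_fit`.
#' @param quad_points,adaptive,complete_case Quadrature options as in
#'   [fit_joint()].
#' @param rel_step Relative finite-difference step (default 1e-5).
#' @param richardson Refine the score by Richardson extrapolation.
#' @return List with `gradient` (named vector) and `information` (matrix).
#' @export
score_and_information <- function(theta, data = NULL, spec = NULL,
                                  quad_points = 10, adaptive = TRUE,
                                  complete_case = FALSE,
                                  rel_step = 1e-5, richardson = FALSE) {
  if (inherits(theta, "joint_fit")) {
    ws <- theta$ws
    par <- theta$par
    quad_points <- theta$quad$points
    adaptive <- theta$quad$adaptive
  } else {
    ws <- build_workspace(data, spec, complete_case = complete_case)
    par <- pack_theta(theta, ws)
  }
  Q <- as.integer(quad_points)
  f <- function(p) agq_eval(p, ws, Q = Q, adaptive = adaptive)$loglik
  grad_at <- function(step) {
    h <- fd_steps(par, step)
    vapply(seq_along(par), function(i) {
      e <- numeric(length(par)); e[i] <- h[i]
      (f(par + e) - f(par - e)) / (2 * h[i])
    }, numeric(1))
  }
  g <- grad_at(rel_step)
  if (richardson) {
    g2 <- grad_at(rel_step / 2)
    g <- (4 * g2 - g) / 3
  }
  if (any(!is.finite(g))) abort("non-finite entries in the score")
  names(g) <- ws$par_names
  list(gradient = g,
       information = fd_information(par, ws, Q, adaptive, rel_step))
}

#' Extract a covariance matrix from a joint fit
#'
#' @param object A `joint_fit`.
#' @param type `"model"` (inverse observed information) or `"robust"`
#'   (cluster-robust sandwich with small-sample factor G/(G-1)).
#' @param ... Unused.
#' @return Covariance matrix of the packed parameter vector.
#' @export
vcov.joint_fit <- function(object, type = c("model", "robust"), ...) {
  type <- match.arg(type)
  V <- if (type == "model") object$vcov_model else object$vcov_robust
  if (is.null(V)) {
    abort(sprintf("fit carries no %s covariance (refit with vcov = \"%s\" or \"both\")",
                  type, type))
  }
  V
}

#' @export
logLik.joint_fit <- function(object, ...) {
  structure(object$loglik, df = object$np, nobs = object$nobs,
            class = "logLik")
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint %s model, %s random intercept(s); adaptive GH with %d point(s)/dim\n",
              x$spec$model, x$spec$random, x$quad$points))
  cat(sprintf("  %d mothers, %d delivery records; logLik %.2f, BIC %.2f%s\n",
              x$n_mothers, x$nobs, x$loglik, x$BIC,
              if (x$converged) "" else " (NOT converged)"))
  if (x$spec$model == "bivariate") {
    cat("  preterm coefficients:\n")
    print(round(x$coefficients$beta_preterm, 4))
    cat("  death coefficients:\n")
    print(round(x$coefficients$beta_death, 4))
  } else {
    cat("  coefficients (columns = non-reference categories):\n")
    print(round(x$coefficients$beta, 4))
  }
  if (!is.null(x$coefficients$sigma2)) {
    cat(sprintf("  random-intercept variance: %.4f\n", x$coefficients$sigma2))
  } else {
    cat("  random-effects covariance D:\n")
    print(round(x$coefficients$D, 4))
  }
  invisible(x)
}
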