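# Marginal likelihood machinery for the joint models.
#
# Every model variant is reduced to one integral per mother over a d-dim
# normal random effect b = L u, u ~ N(0, I), with L the Cholesky factor of
# the random-effects covariance (a scalar SD for shared structures). The
# integral is evaluated in the standardized u-space by (adaptive)
# Gauss-Hermite quadrature: the integrand's per-cluster mode and curvature
# are found by a safeguarded Newton iteration (the curvature L'WL + I is
# positive definite by construction), the node grid is recentred and rescaled
# there, and all weights are carried in log space.

log1pexp <- function(x) {
  pmax(x, 0) + log1p(exp(-abs(x)))
}

# ---- workspace --------------------------------------------------------------

build_workspace <- function(data, spec, complete_case = FALSE) {
  stopifnot(inherits(spec, "joint_model_spec"))
  data <- tibble::as_tibble(data)
  if (!"mother_id" %in% names(data)) {
    abort("data must contain a mother_id column identifying clusters")
  }
  if (!"preterm" %in% names(data) && "gestational_age_weeks" %in% names(data)) {
    data$preterm <- encode_preterm(data$gestational_age_weeks)
  }

  if (spec$model == "bivariate") {
    for (col in c("preterm", "perinatal_death")) {
      if (!col %in% names(data)) abort(sprintf("missing outcome column '%s'", col))
    }
    y1 <- data$preterm
    y2 <- data$perinatal_death
    if (complete_case) {
      cc <- !is.na(y1) & !is.na(y2)
      y1[!cc] <- NA
      y2[!cc] <- NA
    }
    v1 <- all.vars(spec$formula_preterm)
    v2 <- all.vars(spec$formula_death)
    ok1 <- !is.na(y1) & complete.cases(data[, v1, drop = FALSE])
    ok2 <- !is.na(y2) & complete.cases(data[, v2, drop = FALSE])
    used <- ok1 | ok2
    if (!any(used)) abort("no usable delivery records (empty cluster set)")
    mothers <- factor(data$mother_id[used])
    G <- nlevels(mothers)
    cl_of <- function(ok) {
      as.integer(factor(data$mother_id[ok], levels = levels(mothers)))
    }
    X1 <- model.matrix(spec$formula_preterm, data = data[ok1, , drop = FALSE])
    X2 <- model.matrix(spec$formula_death, data = data[ok2, , drop = FALSE])
    d <- if (spec$random == "shared") 1L else 2L
    ecl <- c(cl_of(ok1), cl_of(ok2))
    ecomp <- c(rep(1L, nrow(X1)),
               rep(if (spec$random == "shared") 1L else 2L, nrow(X2)))
    ws <- list(
      type = "bern", spec = spec, d = d,
      shared = spec$random == "shared",
      X1 = X1, X2 = X2,
      p1 = ncol(X1), p2 = ncol(X2),
      y = c(y1[ok1], y2[ok2]),
      ecl = ecl, ecomp = ecomp,
      cl_f = factor(ecl, levels = seq_len(G)),
      gsum = make_grouper(ecl, G),
      comp_mask = lapply(seq_len(d), function(c) as.numeric(ecomp == c)),
      i1 = seq_len(nrow(X1)), i2 = nrow(X1) + seq_len(nrow(X2)),
      G = G, n_records = sum(used),
      n_preterm = sum(ok1), n_death = sum(ok2),
      cluster_levels = levels(mothers),
      xlev = var_levels(data, union(v1, v2)),
      term_names = c(paste0("preterm:", colnames(X1)),
                     paste0("death:", colnames(X2)))
    )
  } else {
    if (!"cooccurrence" %in% names(data)) {
      if (!all(c("preterm", "perinatal_death") %in% names(data))) {
        abort("multinomial model needs a cooccurrence column or both outcomes")
      }
      data$cooccurrence <- encode_cooccurrence(data$preterm, data$perinatal_death)
    }
    yc <- data$cooccurrence
    v <- all.vars(spec$formula)
    ok <- !is.na(yc) & complete.cases(data[, v, drop = FALSE])
    if (!any(ok)) abort("no usable delivery records (empty cluster set)")
    # a factor outcome keeps its declared level set (even if a category is
    # unobserved, e.g. tiny evaluation clusters); other codings use the
    # observed categories
    yf <- if (is.factor(yc)) factor(yc[ok], levels = levels(yc)) else factor(yc[ok])
    C <- nlevels(yf)
    if (C < 2) abort("co-occurrence outcome has fewer than 2 observed categories")
    mothers <- factor(data$mother_id[ok])
    G <- nlevels(mothers)
    cl <- as.integer(mothers)
    X <- model.matrix(spec$formula, data = data[ok, , drop = FALSE])
    ycat <- as.integer(yf) - 1L # 0 = reference
    Y <- matrix(0, sum(ok), C - 1L)
    nz <- ycat > 0L
    Y[cbind(which(nz), ycat[nz])] <- 1
    d <- if (spec$random == "shared") 1L else C - 1L
    ws <- list(
      type = "multi", spec = spec, d = d,
      shared = spec$random == "shared",
      X = X, p = ncol(X), C = C,
      y = Y, ycat = ycat, cl = cl,
      cl_f = factor(cl, levels = seq_len(G)),
      gsum = make_grouper(cl, G),
      G = G, n_records = sum(ok),
      categories = levels(yf),
      cluster_levels = levels(mothers),
      xlev = var_levels(data, v),
      term_names = as.vector(vapply(levels(yf)[-1], function(c) {
        paste0("cat", c, ":", colnames(X))
      }, character(ncol(X))))
    )
  }
  ws$n_par <- n_par(ws)
  ws$par_names <- c(ws$term_names, psi_names(ws$d))
  ws
}

# levels of the categorical variables among `vars`, in model.matrix order
var_levels <- function(data, vars) {
  out <- list()
  for (v in intersect(vars, names(data))) {
    x <- data[[v]]
    if (is.factor(x)) {
      out[[v]] <- levels(x)
    } else if (is.character(x)) {
      out[[v]] <- levels(factor(x))
    }
  }
  out
}

n_par <- function(ws) {
  nb <- if (ws$type == "bern") ws$p1 + ws$p2 else ws$p * (ws$C - 1L)
  nb + re_npar(ws$d)
}

psi_names <- function(d) {
  nm <- character(0)
  for (k in seq_len(d)) {
    for (j in k:d) {
      nm <- c(nm, if (j == k) sprintf("log_sd%d", j) else sprintf("chol%d%d", j, k))
    }
  }
  nm
}

unpack_par <- function(par, ws) {
  if (ws$type == "bern") {
    b1 <- par[seq_len(ws$p1)]
    b2 <- par[ws$p1 + seq_len(ws$p2)]
    psi <- par[ws$p1 + ws$p2 + seq_len(re_npar(ws$d))]
    off <- c(drop(ws$X1 %*% b1), drop(ws$X2 %*% b2))
    list(off = off, L = re_unpack(psi, ws$d), beta = list(b1, b2))
  } else {
    nb <- ws$p * (ws$C - 1L)
    B <- matrix(par[seq_len(nb)], ws$p, ws$C - 1L)
    psi <- par[nb + seq_len(re_npar(ws$d))]
    list(off = ws$X %*% B, L = re_unpack(psi, ws$d), beta = B)
  }
}

check_finite_off <- function(off, ws) {
  bad <- !is.finite(off)
  if (any(bad)) {
    cl <- if (ws$type == "bern") ws$ecl[which(bad)[1]] else ws$cl[which(bad)[1]]
    abort(sprintf("non-finite linear predictor in cluster '%s'",
                  ws$cluster_levels[cl]))
  }
}

# standard tensor node grid: list(Z (nq x d), lw (log product weights), z2half)
node_grid <- function(Q, d) {
  nw <- gh_nodes_weights(Q)
  Z <- as.matrix(expand.grid(rep(list(nw$nodes), d)))
  dimnames(Z) <- NULL
  W <- as.matrix(expand.grid(rep(list(nw$weights), d)))
  list(Z = Z, lw = rowSums(log(W)), z2half = rowSums(Z^2) / 2)
}

# u-space nodes for node q given mode U (G x d) and inverse-curvature
# Cholesky entries Sl (lists of G-vectors); returns G x d matrix
shift_nodes <- function(U, Sl, z, d) {
  if (d == 1L) {
    return(U + cbind(Sl$l11 * z[1L]))
  }
  if (d == 2L) {
    return(cbind(U[, 1L] + Sl$l11 * z[1L],
                 U[, 2L] + Sl$l21 * z[1L] + Sl$l22 * z[2L]))
  }
  cbind(U[, 1L] + Sl$l11 * z[1L],
        U[, 2L] + Sl$l21 * z[1L] + Sl$l22 * z[2L],
        U[, 3L] + Sl$l31 * z[1L] + Sl$l32 * z[2L] + Sl$l33 * z[3L])
}

# A = M' W M + I for per-cluster symmetric W given as d-list-of-lists of
# G-vectors and global dW x d matrix M; returns entry list for batch solvers
batch_quadform <- function(M, W, dW, d) {
  A <- list()
  for (j in seq_len(d)) {
    for (k in seq_len(j)) {
      a <- 0
      for (c1 in seq_len(dW)) {
        for (c2 in seq_len(dW)) {
          a <- a + M[c1, j] * M[c2, k] * W[[max(c1, c2)]][[min(c1, c2)]]
        }
      }
      if (j == k) a <- a + 1
      A[[paste0("a", j, k)]] <- a
    }
  }
  A
}

# ---- Bernoulli (bivariate) engine -------------------------------------------

bern_cond <- function(U, pp, ws) {
  V <- U %*% t(pp$L)
  eta <- pp$off + V[cbind(ws$ecl, ws$ecomp)]
  mu <- plogis(eta)
  ll <- ws$y * eta - log1pexp(eta)
  list(eta = eta, mu = mu, ll = ll)
}

bern_cluster_state <- function(U, pp, ws) {
  cc <- bern_cond(U, pp, ws)
  resid <- ws$y - cc$mu
  wgt <- cc$mu * (1 - cc$mu)
  d <- ws$d
  S <- matrix(0, ws$G, d)
  Wl <- vector("list", d)
  for (c in seq_len(d)) {
    mask <- ws$comp_mask[[c]]
    S[, c] <- ws$gsum(resid * mask)
    Wl[[c]] <- vector("list", c)
    for (k in seq_len(c)) {
      Wl[[c]][[k]] <- if (k == c) ws$gsum(wgt * mask) else 0
    }
  }
  g <- ws$gsum(cc$ll)
  list(g = g, S = S, Wl = Wl)
}

multi_cond <- function(U, pp, ws) {
  if (ws$shared) {
    V <- (U %*% t(pp$L))[, 1L]
    eta <- pp$off + V[ws$cl]
  } else {
    V <- U %*% t(pp$L)
    eta <- pp$off + V[ws$cl, , drop = FALSE]
  }
  m0 <- rep(0, nrow(eta))
  for (c in seq_len(ncol(eta))) m0 <- pmax(m0, eta[, c])
  denom <- m0 + log(exp(-m0) + rowSums(exp(eta - m0)))
  P <- exp(eta - denom)
  sel <- ws$ycat
  lin <- numeric(length(sel))
  nz <- sel > 0L
  lin[nz] <- eta[cbind(which(nz), sel[nz])]
  ll <- lin - denom
  list(eta = eta, P = P, ll = ll)
}

multi_cluster_state <- function(U, pp, ws) {
  cc <- multi_cond(U, pp, ws)
  R <- ws$y - cc$P
  # residual sums and softmax curvature live in the (C-1)-dimensional
  # predictor space regardless of the random-effects structure; the loading
  # matrix M maps them down to the d-dimensional u-space
  dW <- ws$C - 1L
  S <- ws$gsum(R)
  Wl <- vector("list", dW)
  for (j in seq_len(dW)) {
    Wl[[j]] <- vector("list", j)
    for (k in seq_len(j)) {
      v <- if (j == k) cc$P[, j] * (1 - cc$P[, j]) else -cc$P[, j] * cc$P[, k]
      Wl[[j]][[k]] <- ws$gsum(v)
    }
  }
  g <- ws$gsum(cc$ll)
  list(g = g, S = S, Wl = Wl)
}

cluster_state <- function(U, pp, ws) {
  if (ws$type == "bern") bern_cluster_state(U, pp, ws) else multi_cluster_state(U, pp, ws)
}

# Loading matrix M (dW x d): how the standardized random effect enters the
# linear predictors. Shared structures load the scalar L on every predictor.
loading_matrix <- function(pp, ws) {
  if (ws$type == "bern") {
    pp$L
  } else if (ws$shared) {
    matrix(pp$L[1L, 1L], ws$C - 1L, 1L)
  } else {
    pp$L
  }
}

# Safeguarded Newton for the per-cluster posterior mode of u, all clusters at
# once. h_i(u) = g_i(Lu) - |u|^2/2 is strictly concave, so the step with
# curvature M'WM + I always exists; step halving guards overshoot.
find_modes <- function(pp, ws, U0 = NULL, max_iter = 50, tol = 1e-8) {
  d <- ws$d
  G <- ws$G
  U <- if (is.null(U0)) matrix(0, G, d) else U0
  M <- loading_matrix(pp, ws)
  dW <- nrow(M)
  st <- cluster_state(U, pp, ws)
  h <- st$g - rowSums(U^2) / 2
  for (it in seq_len(max_iter)) {
    grad <- st$S %*% M - U
    if (max(abs(grad)) < tol) break
    A <- batch_quadform(M, st$Wl, dW, d)
    step <- batch_spd_solve(A, grad, d)
    lambda <- rep(1, G)
    for (half in 1:25) {
      Unew <- U + step * lambda
      stnew <- cluster_state(Unew, pp, ws)
      hnew <- stnew$g - rowSums(Unew^2) / 2
      bad <- hnew < h - 1e-10
      if (!any(bad)) break
      lambda[bad] <- lambda[bad] / 2
    }
    U <- Unew
    st <- stnew
    h <- hnew
  }
  A <- batch_quadform(M, st$Wl, dW, d)
  list(U = U, Sl = batch_spd_inv_chol(A, d),
       logdetS = -0.5 * batch_spd_logdet(A, d))
}

identity_modes <- function(ws) {
  d <- ws$d
  G <- ws$G
  Sl <- list(l11 = rep(1, G))
  if (d >= 2L) Sl <- c(Sl, list(l21 = rep(0, G), l22 = rep(1, G)))
  if (d >= 3L) Sl <- c(Sl, list(l31 = rep(0, G), l32 = rep(0, G), l33 = rep(1, G)))
  list(U = matrix(0, G, d), Sl = Sl, logdetS = rep(0, G))
}

# Core evaluator. With `cache` supplied the quadrature nodes are held fixed
# (the inner-optimizer regime, where the analytic score is exact); otherwise
# modes are refreshed at the current parameters when adaptive = TRUE.
agq_eval <- function(par, ws, Q = 10, adaptive = TRUE, cache = NULL,
                     want_score = FALSE, warm = NULL) {
  pp <- unpack_par(par, ws)
  check_finite_off(pp$off, ws)
  d <- ws$d
  G <- ws$G
  modes <- if (!is.null(cache)) {
    cache
  } else if (adaptive) {
    find_modes(pp, ws, U0 = warm)
  } else {
    identity_modes(ws)
  }
  grid <- node_grid(Q, d)
  nq <- nrow(grid$Z)
  Tm <- matrix(0, G, nq)
  Ulist <- if (want_score) vector("list", nq) else NULL
  Clist <- if (want_score) vector("list", nq) else NULL
  for (q in seq_len(nq)) {
    Uq <- shift_nodes(modes$U, modes$Sl, grid$Z[q, ], d)
    cc <- if (ws$type == "bern") bern_cond(Uq, pp, ws) else multi_cond(Uq, pp, ws)
    Tm[, q] <- grid$lw[q] + ws$gsum(cc$ll) -
      rowSums(Uq^2) / 2 + grid$z2half[q]
    if (want_score) {
      Ulist[[q]] <- Uq
      Clist[[q]] <- if (ws$type == "bern") cc$mu else cc$P
    }
  }
  percl <- modes$logdetS + row_logsumexp(Tm)
  out <- list(loglik = sum(percl), per_cluster = percl, modes = modes)

  if (want_score) {
    Pi <- exp(Tm - (percl - modes$logdetS)) # softmax over nodes, rows sum to 1
    acc <- matrix(0, d, d)
    M <- loading_matrix(pp, ws)
    if (ws$type == "bern") {
      mubar <- numeric(length(ws$y))
      for (q in seq_len(nq)) {
        mu <- Clist[[q]]
        mubar <- mubar + Pi[ws$ecl, q] * mu
        resid <- ws$y - mu
        Sq <- matrix(0, G, d)
        for (c in seq_len(d)) {
          Sq[, c] <- ws$gsum(resid * ws$comp_mask[[c]])
        }
        acc <- acc + crossprod(Sq * Pi[, q], Ulist[[q]])
      }
      rbar <- ws$y - mubar
      score_beta <- c(drop(crossprod(ws$X1, rbar[ws$i1])),
                      drop(crossprod(ws$X2, rbar[ws$i2])))
    } else {
      Pbar <- matrix(0, nrow(ws$y), ncol(ws$y))
      for (q in seq_len(nq)) {
        P <- Clist[[q]]
        Pbar <- Pbar + Pi[ws$cl, q] * P
        R <- ws$y - P
        Sq <- if (ws$shared) cbind(ws$gsum(rowSums(R))) else ws$gsum(R)
        acc <- acc + crossprod(Sq * Pi[, q], Ulist[[q]])
      }
      score_beta <- as.vector(crossprod(ws$X, ws$y - Pbar))
    }
    # chain rule through the log-Cholesky parameterization; for shared
    # structures acc is 1 x 1 and the diagonal rule applies
    score_psi <- numeric(re_npar(d))
    i <- 1L
    for (k in seq_len(d)) {
      for (j in k:d) {
        score_psi[i] <- if (j == k) acc[j, k] * pp$L[j, j] else acc[j, k]
        i <- i + 1L
      }
    }
    out$score <- c(score_beta, score_psi)
  }
  out
}

# ---- public likelihood surface ----------------------------------------------

pack_theta <- function(theta, ws) {
  d <- ws$d
  if (ws$type == "bern") {
    b1 <- align_beta(theta$beta_preterm, colnames(ws$X1), "beta_preterm")
    b2 <- align_beta(theta$beta_death, colnames(ws$X2), "beta_death")
    beta <- c(b1, b2)
  } else {
    B <- theta$beta
    if (is.list(B) && !is.matrix(B)) B <- do.call(cbind, B)
    B <- as.matrix(B)
    if (!all(dim(B) == c(ws$p, ws$C - 1L))) {
      abort(sprintf("beta must be %d x %d (terms x non-reference categories)",
                    ws$p, ws$C - 1L))
    }
    beta <- as.vector(B)
  }
  psi <- extract_psi(theta, d)
  c(beta, psi)
}

align_beta <- function(b, nms, what) {
  b <- unlist(b)
  if (!is.null(names(b)) && all(nms %in% names(b)) && length(b) == length(nms)) {
    return(unname(b[nms]))
  }
  if (length(b) != length(nms)) {
    abort(sprintf("%s has length %d but the design has %d columns (%s)",
                  what, length(b), length(nms), paste(nms, collapse = ", ")))
  }
  unname(b)
}

extract_psi <- function(theta, d) {
  if (!is.null(theta$psi)) {
    stopifnot(length(theta$psi) == re_npar(d))
    return(theta$psi)
  }
  if (d == 1L) {
    if (is.null(theta$sigma2)) abort("theta needs sigma2 (or psi) for a shared model")
    return(0.5 * log(theta$sigma2))
  }
  if (is.null(theta$D)) abort("theta needs D (or psi) for a correlated model")
  D <- as.matrix(theta$D)
  stopifnot(all(dim(D) == d))
  L <- tryCatch(t(chol(D)), error = function(e) {
    t(chol(D + diag(1e-10 * max(mean(diag(D)), 1e-8), d)))
  })
  re_pack(L)
}

#' Marginal log-likelihood of the bivariate joint logit model
#'
#' Sums over mothers the log of the integral, over the mother-level random
#' intercept(s), of the product of Bernoulli likelihood factors of all her
#' observed outcomes. Deliveries missing one outcome contribute only the
#' observed outcome's factor (set `complete_case = TRUE` to drop them
#' instead). The integral is evaluated by (adaptive) Gauss--Hermite
#' quadrature.
#'
#' @param theta List with `beta_preterm`, `beta_death` (named coefficient
#'   vectors matching the design columns of the spec's formulas) and either
#'   `sigma2` (shared structure), `D` (2 x 2, correlated structure) or the
#'   unconstrained `psi`.
#' @param data Delivery-level data frame (see [simulate_registry()] /
#'   [read_registry()]).
#' @param spec A bivariate [joint_model_spec()].
#' @param rule A one-dimensional [gh_rule()] supplying the base nodes
#'   (default 10 points; tensorized internally for correlated structures).
#' @param adaptive Recenter and rescale nodes at each cluster's posterior
#'   mode/curvature (default `TRUE`).
#' @param complete_case Drop deliveries missing either outcome.
#' @return The log-likelihood (scalar) with per-mother contributions in
#'   attribute `"per_cluster"`.
#' @export
loglik_bivariate <- function(theta, data, spec, rule = gh_rule(10),
                             adaptive = TRUE, complete_case = FALSE) {
  if (spec$model != "bivariate") abort("spec is not a bivariate model spec")
  stopifnot(inherits(rule, "gh_rule"), rule$dim == 1L)
  ws <- build_workspace(data, spec, complete_case = complete_case)
  res <- agq_eval(pack_theta(theta, ws), ws, Q = rule$q, adaptive = adaptive)
  structure(res$loglik,
            per_cluster = setNames(res$per_cluster, ws$cluster_levels))
}

#' Marginal log-likelihood of the random-effects multinomial model
#'
#' Complete-case on the four-category co-occurrence outcome; the reference
#' category ("neither event") has linear predictor zero. The shared structure
#' adds one scalar mother-level intercept to all non-reference logits; the
#' correlated structure gives each logit its own intercept with full
#' covariance.
#'
#' @param theta List with `beta` (matrix, terms x non-reference categories)
#'   and either `sigma2`, `D` ((C-1) x (C-1)) or `psi`.
#' @inheritParams loglik_bivariate
#' @param spec A multinomial [joint_model_spec()].
#' @return The log-likelihood (scalar) with per-mother contributions in
#'   attribute `"per_cluster"`.
#' @export
loglik_multinomial <- function(theta, data, spec, rule = gh_rule(10),
                               adaptive = TRUE, complete_case = FALSE) {
  if (spec$model != "multinomial") abort("spec is not a multinomial model spec")
  stopifnot(inherits(rule, "gh_rule"), rule$dim == 1L)
  ws <- build_workspace(data, spec, complete_case = complete_case)
  res <- agq_eval(pack_theta(theta, ws), ws, Q = rule$q, adaptive = adaptive)
  structure(res$loglik,
            per_cluster = setNames(res$per_cluster, ws$cluster_levels))
}
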