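# Gauss-Hermite machinery for normal random-effects integrals.
#
# All rules are kept in the probabilist normalization: the base weights sum to
# one and integrate polynomials exactly against the standard normal kernel.
# Each rule additionally carries log "Lebesgue" weights so that
# sum(exp(lw) * f(nodes)) approximates the plain integral of f, which is the
# form the likelihood code needs (integrand = conditional likelihood times
# random-effects density).

# nodes/weights of the Q-point probabilist Gauss-Hermite rule via
# Golub-Welsch: eigen decomposition of the symmetric tridiagonal Jacobi
# matrix of the (physicists') Hermite recurrence, then rescaled by sqrt(2).
gh_nodes_weights <- function(Q) {
  if (Q == 1L) {
    return(list(nodes = 0, weights = 1))
  }
  off <- sqrt(seq_len(Q - 1) / 2)
  J <- matrix(0, Q, Q)
  J[cbind(seq_len(Q - 1), seq_len(Q - 1) + 1L)] <- off
  J[cbind(seq_len(Q - 1) + 1L, seq_len(Q - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  nodes <- sqrt(2) * e$values[ord]
  weights <- e$vectors[1L, ord]^2 # already normalized: sum = 1
  # symmetrize against floating-point asymmetry
  nodes <- (nodes - rev(nodes)) / 2
  weights <- (weights + rev(weights)) / 2
  list(nodes = nodes, weights = weights / sum(weights))
}

new_gh_rule <- function(dim, q, zgrid, nodes, weights, log_lebesgue,
                        adaptive = FALSE, mode = NULL, scale = NULL,
                        chol = NULL) {
  structure(
    list(dim = dim, q = q, zgrid = zgrid, nodes = nodes, weights = weights,
         log_lebesgue = log_lebesgue, adaptive = adaptive, mode = mode,
         scale = scale, chol = chol),
    class = "gh_rule"
  )
}

#' One-dimensional Gauss--Hermite quadrature rule
#'
#' Returns the `Q`-point rule in the probabilist normalization: weights sum to
#' one and `sum(w * p(x))` is exact for `E[p(X)]`, `X ~ N(0,1)`, for all
#' polynomials `p` of degree at most `2Q - 1`.
#'
#' @param Q Number of quadrature points (default 10, the order used for
#'   maximum-likelihood fitting of the joint models).
#' @return An object of class `gh_rule` with fields `nodes` (n x d matrix),
#'   `weights` (Gaussian-measure weights) and `log_lebesgue` (log weights for
#'   plain integrals, see [gh_integrate()]).
#' @examples
#' r <- gh_rule(10)
#' sum(r$weights * r$nodes[, 1]^2) # E[X^2] = 1, exact
#' @export
gh_rule <- function(Q = 10) {
  Q <- as.integer(Q)
  if (length(Q) != 1L || is.na(Q) || Q < 1L) {
    abort("Q must be a positive integer")
  }
  nw <- gh_nodes_weights(Q)
  nodes <- matrix(nw$nodes, ncol = 1L)
  lw <- log(nw$weights) - dnorm(nw$nodes, log = TRUE)
  new_gh_rule(1L, Q, zgrid = nodes, nodes = nodes,
              weights = nw$weights, log_lebesgue = lw)
}

#' Tensor-product Gauss--Hermite rule for a multivariate normal
#'
#' Builds the `Q^d`-node product grid from a one-dimensional base rule and
#' transforms it by a lower-triangular Cholesky factor `chol_D` so that the
#' Gaussian-measure weights integrate against `N(0, D)` with `D = L L'`.
#'
#' @param base A one-dimensional [gh_rule()].
#' @param d Dimension (2 or 3 for the correlated random-effects models).
#' @param chol_D Lower-triangular `d x d` scale (defaults to the identity).
#' @return A `gh_rule` of dimension `d` with `Q^d` nodes.
#' @examples
#' r <- tensor_rule(gh_rule(10), 2)
#' sum(r$weights * r$nodes[, 1] * r$nodes[, 2]) # E[X1 X2] = 0
#' @export
tensor_rule <- function(base, d, chol_D = NULL) {
  stopifnot(inherits(base, "gh_rule"), base$dim == 1L)
  d <- as.integer(d)
  if (d < 1L || d > 3L) abort("d must be 1, 2 or 3")
  if (is.null(chol_D)) chol_D <- diag(d)
  chol_D <- as.matrix(chol_D)
  if (!all(dim(chol_D) == d)) abort("chol_D must be d x d")
  if (any(abs(chol_D[upper.tri(chol_D)]) > 0)) {
    abort("chol_D must be lower triangular")
  }
  if (any(!is.finite(chol_D)) || any(diag(chol_D) <= 0)) {
    abort("chol_D must have positive diagonal (D must be positive definite)")
  }
  z1 <- base$zgrid[, 1L]
  grid <- as.matrix(expand.grid(rep(list(z1), d)))
  dimnames(grid) <- NULL
  wgrid <- as.matrix(expand.grid(rep(list(base$weights), d)))
  w <- apply(wgrid, 1L, prod)
  nodes <- grid %*% t(chol_D)
  logdet <- sum(log(diag(chol_D)))
  lw <- log(w) + d / 2 * log(2 * pi) + logdet + rowSums(grid^2) / 2
  new_gh_rule(d, base$q, zgrid = grid, nodes = nodes, weights = w,
              log_lebesgue = lw, chol = chol_D)
}

#' Adaptively recenter and rescale a Gauss--Hermite rule
#'
#' Shifts the standard node grid to `mode` and scales it by the inverse
#' Cholesky factor of `curvature` (the negative Hessian of the log-integrand
#' at its mode), adjusting the Lebesgue weights by the Jacobian and normal
#' density ratio. The estimate of a plain integral is unchanged in exact
#' arithmetic for integrands proportional to a Gaussian with that mode and
#' curvature, and far more accurate for integrands concentrated away from the
#' origin.
#'
#' @param base A `gh_rule` of the target dimension (from [gh_rule()] or
#'   [tensor_rule()]).
#' @param mode Numeric mode vector (length `base$dim`).
#' @param curvature Symmetric positive-definite matrix (the negative Hessian
#'   at the mode). If not positive definite, the base rule is returned with a
#'   warning.
#' @return An adapted `gh_rule`.
#' @examples
#' # mass of a normal density centered at 3: the centered rule is exact
#' r <- adapt_rule(gh_rule(10), mode = 3, curvature = matrix(1))
#' gh_integrate(r, function(x) dnorm(x[, 1] - 3))
#' @export
adapt_rule <- function(base, mode, curvature) {
  stopifnot(inherits(base, "gh_rule"))
  d <- base$dim
  mode <- as.numeric(mode)
  stopifnot(length(mode) == d)
  curvature <- as.matrix(curvature)
  stopifnot(all(dim(curvature) == d))
  if (max(abs(curvature - t(curvature))) > 1e-8 * max(1, max(abs(curvature)))) {
    abort("curvature must be symmetric")
  }
  R <- tryCatch(chol(curvature), error = function(e) NULL)
  if (is.null(R)) {
    warn("curvature not positive definite; falling back to the non-adaptive rule")
    return(base)
  }
  S <- backsolve(R, diag(d)) # S S' = curvature^{-1}
  z <- base$zgrid
  nodes <- sweep(z %*% t(S), 2L, mode, `+`)
  logdetS <- -sum(log(diag(R)))
  lw <- log(base$weights) + d / 2 * log(2 * pi) + logdetS + rowSums(z^2) / 2
  # Gaussian-measure weights re-expressed against the standard normal at the
  # new nodes, so both integral semantics stay available after adaptation
  wg <- exp(lw - d / 2 * log(2 * pi) - rowSums(nodes^2) / 2)
  new_gh_rule(d, base$q, zgrid = z, nodes = nodes, weights = wg,
              log_lebesgue = lw, adaptive = TRUE, mode = mode, scale = S,
              chol = base$chol)
}

#' Estimate an integral with a Gauss--Hermite rule
#'
#' @param rule A `gh_rule`.
#' @param f Vectorized integrand taking an `n x d` node matrix and returning
#'   `n` values.
#' @param type `"lebesgue"` (default) estimates `integral f(x) dx`;
#'   `"gaussian"` estimates `E[f(X)]` under the rule's Gaussian base measure.
#' @return Numeric scalar.
#' @export
gh_integrate <- function(rule, f, type = c("lebesgue", "gaussian")) {
  type <- match.arg(type)
  fx <- f(rule$nodes)
  if (type == "lebesgue") sum(exp(rule$log_lebesgue) * fx) else sum(rule$weights * fx)
}

#' @export
print.gh_rule <- function(x, ...) {
  cat(sprintf("Gauss-Hermite rule: dim %d, %d nodes (%d per dimension)%s\n",
              x$dim, nrow(x$nodes), x$q,
              if (isTRUE(x$adaptive)) ", adaptive" else ""))
  invisible(x)
}
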