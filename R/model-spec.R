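#' Specify a joint model for preterm birth and perinatal death
#'
#' Describes which of the four model variants to fit:
#' * `model = "bivariate"`: the two binary outcomes are modelled jointly with
#'   logit links; `random = "shared"` puts one scalar mother-level intercept
#'   in both linear predictors (the shared-parameter model), while
#'   `random = "correlated"` gives each outcome its own intercept with the
#'   pair drawn from a bivariate normal with free covariance.
#' * `model = "multinomial"`: the four-category co-occurrence outcome
#'   (neither event / both / death only / preterm only, reference "neither")
#'   is modelled by mixed multinomial logit; `random = "shared"` uses a single
#'   scalar intercept common to the three non-reference logits,
#'   `random = "correlated"` gives each logit its own intercept with a full
#'   3 x 3 covariance.
#'
#' @param model `"bivariate"` or `"multinomial"`.
#' @param random `"shared"` or `"correlated"`.
#' @param formula_preterm,formula_death Right-hand-side formulas for the two
#'   linear predictors of the bivariate model (may differ, as covariate sets
#'   retained for each outcome usually do).
#' @param formula Right-hand-side formula for the multinomial model; one
#'   common covariate list is used across the non-reference categories.
#' @return An object of class `joint_model_spec`.
#' @examples
#' joint_model_spec("bivariate", "shared",
#'                  formula_preterm = ~ anc_visits + referral,
#'                  formula_death = ~ anc_visits)
#' @export
joint_model_spec <- function(model = c("bivariate", "multinomial"),
                             random = c("shared", "correlated"),
                             formula_preterm = ~1, formula_death = ~1,
                             formula = ~1) {
  model <- match.arg(model)
  random <- match.arg(random)
  structure(
    list(model = model, random = random,
         formula_preterm = formula_preterm,
         formula_death = formula_death,
         formula = formula),
    class = "joint_model_spec"
  )
}

#' @export
print.joint_model_spec <- function(x, ...) {
  cat(sprintf("Joint model spec: %s outcomes, %s random intercept(s)\n",
              x$model, x$random))
  if (x$model == "bivariate") {
    cat("  preterm: ", deparse(x$formula_preterm), "\n")
    cat("  death:   ", deparse(x$formula_death), "\n")
  } else {
    cat("  co-occurrence: ", deparse(x$formula), "\n")
  }
  invisible(x)
}

# --- random-effects covariance parameterization ------------------------------
# psi holds log standard deviations on the Cholesky diagonal and unconstrained
# off-diagonal Cholesky entries, column by column: for k in 1..d, j in k..d.

re_npar <- function(d) d * (d + 1) / 2

re_unpack <- function(psi, d) {
  L <- matrix(0, d, d)
  i <- 1L
  for (k in seq_len(d)) {
    for (j in k:d) {
      L[j, k] <- if (j == k) exp(psi[i]) else psi[i]
      i <- i + 1L
    }
  }
  L
}

re_pack <- function(L) {
  d <- nrow(L)
  psi <- numeric(re_npar(d))
  i <- 1L
  for (k in seq_len(d)) {
    for (j in k:d) {
      psi[i] <- if (j == k) log(L[j, j]) else L[j, k]
      i <- i + 1L
    }
  }
  psi
}

#' Encode / decode a random-effects covariance matrix
#'
#' The variance parameters are carried unconstrained inside the optimizer as
#' log standard deviations plus free Cholesky off-diagonals (`psi`), so that
#' any real vector decodes to a valid symmetric positive semi-definite `D`.
#'
#' @param D Symmetric positive-definite covariance matrix.
#' @return `theta_encode_re()` returns the unconstrained vector `psi`;
#'   `theta_decode_re()` its inverse.
#' @examples
#' D <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
#' theta_decode_re(theta_encode_re(D), d = 2)
#' @export
theta_encode_re <- function(D) {
  D <- as.matrix(D)
  re_pack(t(chol(D)))
}

#' @param psi Unconstrained parameter vector of length `d (d + 1) / 2`.
#' @param d Random-effects dimension.
#' @rdname theta_encode_re
#' @export
theta_decode_re <- function(psi, d) {
  L <- re_unpack(psi, d)
  L %*% t(L)
}
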