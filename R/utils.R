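#' @importFrom rlang .data abort warn %||%
#' @importFrom stats dnorm qnorm pnorm plogis qlogis rbinom runif rnorm
#'   model.matrix setNames complete.cases chisq.test lm coef vcov pchisq
#' @importFrom utils head
NULL

# log(sum(exp(x))) along rows of a matrix, guarded against underflow
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

logsumexp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Fast per-cluster summation: precomputes the permutation that sorts rows by
# cluster so each call is a subset + cumsum (rowsum() re-builds a factor on
# every call, which dominates profile time in the quadrature node loop).
# Requires every cluster 1..G to be present in cl.
make_grouper <- function(cl, G) {
  ord <- order(cl)
  ends <- cumsum(tabulate(cl, nbins = G))
  lower <- c(0L, ends[-G])
  function(x) {
    if (is.matrix(x)) {
      out <- matrix(0, G, ncol(x))
      for (j in seq_len(ncol(x))) {
        cs <- cumsum(x[ord, j])
        out[, j] <- cs[ends] - c(0, cs[lower[-1L]])
      }
      out
    } else {
      cs <- cumsum(x[ord])
      cs[ends] - c(0, cs[lower[-1L]])
    }
  }
}

# Batched solve of symmetric positive-definite systems of dimension d in
# {1,2,3}: A is a list of column vectors for the unique entries (a11, a21,
# a22, a31, a32, a33), g a matrix with d columns; returns solution matrix.
# Closed-form adjugate solves keep the per-cluster Newton loop vectorized.
batch_spd_solve <- function(A, g, d) {
  if (d == 1L) {
    return(cbind(g[, 1L] / A$a11))
  }
  if (d == 2L) {
    det <- A$a11 * A$a22 - A$a21^2
    x1 <- (A$a22 * g[, 1L] - A$a21 * g[, 2L]) / det
    x2 <- (-A$a21 * g[, 1L] + A$a11 * g[, 2L]) / det
    return(cbind(x1, x2))
  }
  # d == 3: cofactor expansion
  c11 <- A$a22 * A$a33 - A$a32^2
  c12 <- A$a32 * A$a31 - A$a21 * A$a33
  c13 <- A$a21 * A$a32 - A$a22 * A$a31
  c22 <- A$a11 * A$a33 - A$a31^2
  c23 <- A$a21 * A$a31 - A$a11 * A$a32
  c33 <- A$a11 * A$a22 - A$a21^2
  det <- A$a11 * c11 + A$a21 * c12 + A$a31 * c13
  x1 <- (c11 * g[, 1L] + c12 * g[, 2L] + c13 * g[, 3L]) / det
  x2 <- (c12 * g[, 1L] + c22 * g[, 2L] + c23 * g[, 3L]) / det
  x3 <- (c13 * g[, 1L] + c23 * g[, 2L] + c33 * g[, 3L]) / det
  cbind(x1, x2, x3)
}

# Batched log-determinant of the same symmetric structure
batch_spd_logdet <- function(A, d) {
  if (d == 1L) return(log(A$a11))
  if (d == 2L) return(log(A$a11 * A$a22 - A$a21^2))
  c11 <- A$a22 * A$a33 - A$a32^2
  c12 <- A$a32 * A$a31 - A$a21 * A$a33
  c13 <- A$a21 * A$a32 - A$a22 * A$a31
  log(A$a11 * c11 + A$a21 * c12 + A$a31 * c13)
}

# Batched lower Cholesky of the INVERSE of the same structure; returns list of
# column vectors l11, l21, l22, l31, l32, l33 (unused entries absent).
# Inverse first (adjugate), then closed-form Cholesky of the inverse.
batch_spd_inv_chol <- function(A, d) {
  if (d == 1L) {
    return(list(l11 = 1 / sqrt(A$a11)))
  }
  if (d == 2L) {
    det <- A$a11 * A$a22 - A$a21^2
    i11 <- A$a22 / det; i21 <- -A$a21 / det; i22 <- A$a11 / det
    l11 <- sqrt(i11)
    l21 <- i21 / l11
    l22 <- sqrt(i22 - l21^2)
    return(list(l11 = l11, l21 = l21, l22 = l22))
  }
  c11 <- A$a22 * A$a33 - A$a32^2
  c12 <- A$a32 * A$a31 - A$a21 * A$a33
  c13 <- A$a21 * A$a32 - A$a22 * A$a31
  c22 <- A$a11 * A$a33 - A$a31^2
  c23 <- A$a21 * A$a31 - A$a11 * A$a32
  c33 <- A$a11 * A$a22 - A$a21^2
  det <- A$a11 * c11 + A$a21 * c12 + A$a31 * c13
  i11 <- c11 / det; i21 <- c12 / det; i22 <- c22 / det
  i31 <- c13 / det; i32 <- c23 / det; i33 <- c33 / det
  l11 <- sqrt(i11)
  l21 <- i21 / l11
  l31 <- i31 / l11
  l22 <- sqrt(i22 - l21^2)
  l32 <- (i32 - l31 * l21) / l22
  l33 <- sqrt(i33 - l31^2 - l32^2)
  list(l11 = l11, l21 = l21, l22 = l22, l31 = l31, l32 = l32, l33 = l33)
}

# significance stars at the conventional 0.05 / 0.01 / 0.001 thresholds
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

z_crit <- function() qnorm(0.975)

is_binary_or_na <- function(x) {
  all(is.na(x) | x %in% c(0, 1))
}
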