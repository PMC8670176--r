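#' Tidy a joint fit into a coefficient table
#'
#' Broom-style one-row-per-term summary of the fixed effects, with Wald
#' standard errors, confidence intervals and p-values from either the
#' model-based or the cluster-robust covariance. `effects = "ran_pars"`
#' returns the random-effects variance components instead: variances carry
#' log-scale (hence asymmetric) confidence intervals, covariances symmetric
#' normal ones, both by the delta method through the log-Cholesky
#' parameterization.
#'
#' @param x A [fit_joint()] object.
#' @param effects `"fixed"` (default) or `"ran_pars"`.
#' @param exponentiate Report odds ratios `exp(beta)` with exponentiated CI.
#' @param conf.level Confidence level (default 0.95).
#' @param vcov `"model"` or `"robust"`.
#' @param ... Unused.
#' @return A tibble with columns `outcome`, `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `conf.low`, `conf.high`.
#' @method tidy joint_fit
#' @export
tidy.joint_fit <- function(x, effects = c("fixed", "ran_pars"),
                           exponentiate = FALSE, conf.level = 0.95,
                           vcov = c("model", "robust"), ...) {
  effects <- match.arg(effects)
  vcov <- match.arg(vcov)
  V <- vcov.joint_fit(x, type = vcov)
  z <- qnorm(1 - (1 - conf.level) / 2)
  if (effects == "fixed") {
    nb <- x$np - re_npar(x$ws$d)
    idx <- seq_len(nb)
    est <- x$par[idx]
    se <- sqrt(diag(V)[idx])
    stat <- est / se
    out <- tibble::tibble(
      outcome = sub(":.*$", "", names(est)),
      term = sub("^[^:]*:", "", names(est)),
      estimate = unname(est),
      std.error = unname(se),
      statistic = unname(stat),
      p.value = 2 * pnorm(-abs(unname(stat))),
      conf.low = unname(est - z * se),
      conf.high = unname(est + z * se)
    )
    if (exponentiate) {
      out <- dplyr::mutate(out,
        estimate = exp(.data$estimate),
        conf.low = exp(.data$conf.low),
        conf.high = exp(.data$conf.high),
        std.error = NA_real_
      )
    }
    return(out)
  }
  ran_pars_table(x, V, z)
}

# delta-method table for the entries of D = L(psi) L(psi)'
ran_pars_table <- function(x, V, z) {
  d <- x$ws$d
  npsi <- re_npar(d)
  idx <- x$np - npsi + seq_len(npsi)
  psi <- x$par[idx]
  Vp <- V[idx, idx, drop = FALSE]
  entries <- list()
  for (j in seq_len(d)) {
    for (k in seq_len(j)) {
      fn <- local({
        j0 <- j; k0 <- k
        function(p) {
          Dm <- theta_decode_re(p, d)
          Dm[j0, k0]
        }
      })
      val <- fn(psi)
      # numeric jacobian of the entry wrt psi
      jac <- vapply(seq_len(npsi), function(i) {
        h <- 1e-6 * max(abs(psi[i]), 1)
        e <- numeric(npsi); e[i] <- h
        (fn(psi + e) - fn(psi - e)) / (2 * h)
      }, numeric(1))
      se <- sqrt(drop(t(jac) %*% Vp %*% jac))
      if (j == k) {
        # log-scale interval keeps the variance bound positive
        se_log <- if (val > 0) se / val else NA_real_
        lo <- val * exp(-z * se_log)
        hi <- val * exp(z * se_log)
        term <- if (d == 1L) "var" else sprintf("var_%d", j)
      } else {
        lo <- val - z * se
        hi <- val + z * se
        term <- sprintf("cov_%d%d", j, k)
      }
      entries[[length(entries) + 1L]] <- tibble::tibble(
        outcome = "random_effects", term = term, estimate = val,
        std.error = se, statistic = NA_real_, p.value = NA_real_,
        conf.low = lo, conf.high = hi
      )
    }
  }
  dplyr::bind_rows(entries)
}

#' One-row model summary
#'
#' @param x A `joint_fit`.
#' @param ... Unused.
#' @return Tibble with the log-likelihood, parameter count, BIC, counts and
#'   convergence flag.
#' @method glance joint_fit
#' @export
glance.joint_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$model,
    random = x$spec$random,
    logLik = x$loglik,
    BIC = x$BIC,
    np = x$np,
    nobs = x$nobs,
    n_mothers = x$n_mothers,
    sigma2 = x$coefficients$sigma2 %||% NA_real_,
    converged = x$converged
  )
}

#' Forest plot of odds ratios from a joint fit
#'
#' @param object A `joint_fit`.
#' @param vcov `"model"` or `"robust"` covariance for the intervals.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot joint_fit
#' @export
autoplot.joint_fit <- function(object, vcov = "model", ...) {
  tb <- tidy.joint_fit(object, exponentiate = TRUE, vcov = vcov) |>
    dplyr::filter(.data$term != "(Intercept)")
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$outcome)) +
    ggplot2::labs(x = "Odds ratio (log scale)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
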