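#' Odds-ratio table from a joint fit, in registry-report style
#'
#' Formats the fixed effects as odds ratios `exp(beta)` with Wald 95%
#' confidence intervals and significance stars (`*` p < 0.05, `**` p < 0.01,
#' `***` p < 0.001). Reference levels of factor covariates are printed as
#' rows with OR 1.00 and an empty interval, matching how such tables are laid
#' out in the perinatal-epidemiology literature.
#'
#' @param fit A converged [fit_joint()] object.
#' @param vcov_choice `"model"` or `"robust"` covariance for the intervals.
#' @param force Report despite non-convergence (default `FALSE`: refuse).
#' @return Tibble with `outcome`, `term`, `OR`, `conf.low`, `conf.high`,
#'   `p.value`, `stars`, `label` (formatted `OR (low, high)stars` at 2
#'   decimals).
#' @export
odds_ratio_table <- function(fit, vcov_choice = c("model", "robust"),
                             force = FALSE) {
  vcov_choice <- match.arg(vcov_choice)
  stopifnot(inherits(fit, "joint_fit"))
  if (!fit$converged && !force) {
    abort("fit did not converge; pass force = TRUE to tabulate anyway")
  }
  tb <- tidy.joint_fit(fit, exponentiate = TRUE, vcov = vcov_choice) |>
    dplyr::mutate(stars = p_stars(.data$p.value)) |>
    dplyr::select("outcome", "term", OR = "estimate", "conf.low",
                  "conf.high", "p.value", "stars")
  tb <- add_reference_rows(tb, fit)
  dplyr::mutate(tb, label = dplyr::if_else(
    is.na(.data$conf.low),
    sprintf("%.2f", .data$OR),
    sprintf("%.2f (%.2f, %.2f)%s", .data$OR, .data$conf.low,
            .data$conf.high, .data$stars)
  ))
}

add_reference_rows <- function(tb, fit) {
  xlev <- fit$ws$xlev
  if (is.null(xlev) || !length(xlev)) return(tb)
  out <- list()
  for (oc in unique(tb$outcome)) {
    block <- tb[tb$outcome == oc, ]
    rows <- list()
    for (i in seq_len(nrow(block))) {
      rows[[length(rows) + 1L]] <- block[i, ]
      # after the last dummy of a factor, nothing to do; before the first
      # dummy of a factor, insert its reference row
    }
    block2 <- dplyr::bind_rows(rows)
    for (v in names(xlev)) {
      lev <- xlev[[v]]
      first_dummy <- paste0(v, lev[2])
      pos <- match(first_dummy, block2$term)
      if (is.na(pos)) next
      ref_row <- tibble::tibble(
        outcome = oc, term = paste0(v, lev[1]), OR = 1,
        conf.low = NA_real_, conf.high = NA_real_,
        p.value = NA_real_, stars = ""
      )
      block2 <- dplyr::bind_rows(
        block2[seq_len(pos - 1), ], ref_row,
        block2[seq(pos, nrow(block2)), ]
      )
    }
    out[[length(out) + 1L]] <- block2
  }
  dplyr::bind_rows(out)
}

#' Compare fitted joint models by BIC
#'
#' Tabulates log-likelihood, parameter count and BIC
#' (`-2 logLik + p log N`, N = delivery records in the fit) for two or more
#' fits of the same record set, flagging the minimum-BIC model as preferred.
#' Fits on different record sets (checked by a record-count fingerprint) are
#' refused, since their likelihoods are not comparable. Ties break to the
#' first model in input order.
#'
#' @param ... `joint_fit` objects, or a single list of them.
#' @param names Optional model names (defaults to `model/random` labels).
#' @return A tibble of class `model_comparison` with columns `model`,
#'   `logLik`, `np`, `BIC`, `delta_BIC`, `preferred`.
#' @export
compare_models <- function(..., names = NULL) {
  fits <- list(...)
  if (length(fits) == 1L && is.list(fits[[1]]) && !inherits(fits[[1]], "joint_fit")) {
    fits <- fits[[1]]
  }
  if (length(fits) < 2L) abort("need at least 2 fits to compare")
  stopifnot(all(vapply(fits, inherits, logical(1), "joint_fit")))
  fp <- vapply(fits, function(f) paste(f$fingerprint, collapse = "/"), character(1))
  if (length(unique(fp)) != 1L) {
    abort(sprintf("fits are not on the same record set (fingerprints: %s)",
                  paste(unique(fp), collapse = " vs ")))
  }
  if (is.null(names)) {
    names <- vapply(fits, function(f) paste(f$spec$model, f$spec$random, sep = "/"),
                    character(1))
    names <- make.unique(names)
  }
  bic <- vapply(fits, function(f) f$BIC, numeric(1))
  best <- which.min(bic) # which.min takes the first minimum: stable tie-break
  out <- tibble::tibble(
    model = names,
    logLik = vapply(fits, function(f) f$loglik, numeric(1)),
    np = vapply(fits, function(f) f$np, numeric(1)),
    BIC = bic,
    delta_BIC = bic - bic[best],
    preferred = seq_along(fits) == best
  )
  class(out) <- c("model_comparison", class(out))
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison by BIC (N = delivery records; minimum flagged)\n")
  NextMethod()
  invisible(x)
}
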