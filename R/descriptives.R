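resolve_outcome_col <- function(records, outcome) {
  outcome <- match.arg(outcome, c("preterm", "death"))
  col <- if (outcome == "death") "perinatal_death" else "preterm"
  if (!col %in% names(records)) {
    if (outcome == "preterm" && "gestational_age_weeks" %in% names(records)) {
      records$preterm <- encode_preterm(records$gestational_age_weeks)
    } else {
      abort(sprintf("outcome column '%s' not found", col))
    }
  }
  list(records = records, col = col, outcome = outcome)
}

#' Stratified proportion table with a chi-square test
#'
#' Tabulates a binary outcome (preterm birth or perinatal death) by the
#' categories of one stratifier: per-category totals, column percentages,
#' event counts and event percentages, plus a Pearson chi-square test of
#' homogeneity on the category-by-outcome contingency table. The table is
#' complete-case within the outcome: rows with a missing outcome are excluded
#' from this table only, so different outcomes can have different
#' denominators. Rows with a missing stratifier contribute to the grand total
#' but not to the test, mirroring how published registry tables are laid out.
#'
#' The chi-square test deliberately ignores mother-level clustering; the joint
#' model layer is where within-mother correlation is handled.
#'
#' @param records Delivery-level data frame.
#' @param stratifier Name of the covariate column to stratify by.
#' @param outcome `"preterm"` or `"death"`.
#' @param correct Apply the continuity correction (default `FALSE`;
#'   registry tables are large-sample).
#' @return A tibble of class `proportion_table` with one row per category
#'   (columns `category`, `n_total`, `pct_total`, `n_event`, `pct_event`) and
#'   attributes `statistic`, `df`, `p.value`, `n`, `n_event`
#'   (grand totals) accessible via [glance()].
#' @examples
#' reg <- simulate_registry(registry_config(n_mothers = 500, seed = 1))
#' proportion_table(reg, "anc_visits", "preterm")
#' @export
proportion_table <- function(records, stratifier, outcome = c("preterm", "death"),
                             correct = FALSE) {
  records <- tibble::as_tibble(records)
  if (!stratifier %in% names(records)) {
    abort(sprintf("unknown stratifier '%s'; available: %s", stratifier,
                  paste(setdiff(names(records),
                                c("mother_id", "birth_index", "plurality")),
                        collapse = ", ")))
  }
  res <- resolve_outcome_col(records, match.arg(outcome))
  y <- res$records[[res$col]]
  s <- as.character(res$records[[stratifier]])
  keep <- !is.na(y)
  y <- y[keep]
  s <- s[keep]

  tab <- tibble::tibble(category = s, y = y) |>
    dplyr::filter(!is.na(.data$category)) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n_total = dplyr::n(), n_event = sum(.data$y),
                     .groups = "drop")
  lev <- codebook_levels(stratifier)
  if (!is.null(lev)) {
    lev <- union(lev, maternal_age_levels("descriptive"))
    tab <- tab[order(match(tab$category, lev)), ]
  }
  n_all <- length(y)
  tab <- tab |>
    dplyr::mutate(
      pct_total = 100 * .data$n_total / n_all,
      pct_event = 100 * .data$n_event / .data$n_total
    ) |>
    dplyr::select("category", "n_total", "pct_total", "n_event", "pct_event")

  # Pearson chi-square on strata with nonzero totals
  test_tab <- tab[tab$n_total > 0, ]
  if (nrow(test_tab) >= 2) {
    m <- cbind(test_tab$n_event, test_tab$n_total - test_tab$n_event)
    ct <- suppressWarnings(chisq.test(m, correct = correct))
    statistic <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- unname(ct$p.value)
  } else {
    statistic <- df <- p <- NA_real_
  }

  structure(
    tab,
    class = c("proportion_table", class(tab)),
    stratifier = stratifier, outcome = res$outcome,
    statistic = statistic, df = df, p.value = p,
    n = n_all, n_event = sum(y)
  )
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf("Proportion of %s by %s (complete-case N = %d, events = %d, %.1f%%)\n",
              attr(x, "outcome"), attr(x, "stratifier"),
              attr(x, "n"), attr(x, "n_event"),
              100 * attr(x, "n_event") / attr(x, "n")))
  df <- as.data.frame(x)
  df$pct_total <- sprintf("%.1f", df$pct_total)
  df$pct_event <- sprintf("%.1f", df$pct_event)
  print(df, row.names = FALSE)
  if (!is.na(attr(x, "statistic"))) {
    cat(sprintf("Chi-square = %.3f, df = %d, p %s\n",
                attr(x, "statistic"), attr(x, "df"),
                format.pval(attr(x, "p.value"), digits = 3, eps = 0.001)))
  }
  invisible(x)
}

#' @rdname proportion_table
#' @param x A `proportion_table`.
#' @param ... Unused.
#' @return `glance()` returns a one-row tibble with the grand totals, overall
#'   event percentage and the chi-square test.
#' @method glance proportion_table
#' @export
glance.proportion_table <- function(x, ...) {
  tibble::tibble(
    outcome = attr(x, "outcome"),
    stratifier = attr(x, "stratifier"),
    n = attr(x, "n"),
    n_event = attr(x, "n_event"),
    pct_event = 100 * attr(x, "n_event") / attr(x, "n"),
    statistic = attr(x, "statistic"),
    df = attr(x, "df"),
    p.value = attr(x, "p.value")
  )
}

#' Ordinary least-squares annual trend of an outcome proportion
#'
#' Computes the per-year outcome percentage (each calendar year contributing
#' one unweighted point) and regresses it on calendar year by OLS, reporting
#' the slope in percentage points per year with a normal-theory 95% confidence
#' interval and two-sided p-value.
#'
#' @inheritParams proportion_table
#' @return An object of class `annual_trend`: list with `by_year` (tibble of
#'   `year`, `n`, `n_event`, `pct`), `slope`, `se`, `conf.low`, `conf.high`,
#'   `p.value`, `outcome`.
#' @examples
#' reg <- simulate_registry(registry_config(n_mothers = 2000, seed = 1))
#' annual_trend(reg, "preterm")
#' @export
annual_trend <- function(records, outcome = c("preterm", "death")) {
  records <- tibble::as_tibble(records)
  res <- resolve_outcome_col(records, match.arg(outcome))
  y <- res$records[[res$col]]
  yr <- res$records$year
  keep <- !is.na(y) & !is.na(yr)
  by_year <- tibble::tibble(year = yr[keep], y = y[keep]) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(n = dplyr::n(), n_event = sum(.data$y), .groups = "drop") |>
    dplyr::mutate(pct = 100 * .data$n_event / .data$n) |>
    dplyr::arrange(.data$year)
  if (nrow(by_year) < 3) {
    abort("annual trend requires at least 3 distinct years with data")
  }
  fit <- lm(pct ~ year, data = by_year)
  slope <- unname(coef(fit)[2L])
  # suppressed: lm warns on numerically exact lines, handled below
  se <- suppressWarnings(sqrt(vcov(fit)[2L, 2L]))
  z <- z_crit()
  # a numerically exact line has residual SE at rounding level; the z-ratio
  # is then noise, so report the degenerate p directly
  p <- if (se < 1e-10) {
    if (abs(slope) < 1e-8) 1 else 0
  } else {
    2 * pnorm(-abs(slope / se))
  }
  structure(
    list(by_year = by_year, slope = slope, se = se,
         conf.low = slope - z * se, conf.high = slope + z * se,
         p.value = p, outcome = res$outcome),
    class = "annual_trend"
  )
}

#' @export
print.annual_trend <- function(x, ...) {
  cat(sprintf(
    "Annual OLS trend of %s: %+0.2f percentage points/year (95%% CI %0.2f, %0.2f; p %s)\n",
    x$outcome, x$slope, x$conf.low, x$conf.high,
    format.pval(x$p.value, digits = 3, eps = 0.001)
  ))
  invisible(x)
}

#' @rdname annual_trend
#' @param x An `annual_trend`.
#' @param ... Unused.
#' @method tidy annual_trend
#' @export
tidy.annual_trend <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, term = "year",
    estimate = x$slope, std.error = x$se,
    conf.low = x$conf.low, conf.high = x$conf.high,
    p.value = x$p.value
  )
}

#' @rdname annual_trend
#' @param object An `annual_trend`.
#' @method autoplot annual_trend
#' @export
autoplot.annual_trend <- function(object, ...) {
  ggplot2::ggplot(object$by_year, ggplot2::aes(x = .data$year, y = .data$pct)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         linewidth = 0.6) +
    ggplot2::labs(
      x = "Calendar year", y = sprintf("%% %s", object$outcome),
      title = sprintf("Annual %s proportion (%+0.2f pp/year)",
                      object$outcome, object$slope)
    ) +
    ggplot2::theme_minimal()
}
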