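#' Encode gestational age as the binary preterm-birth outcome
#'
#' Preterm birth is any delivery before 37 completed weeks of gestation;
#' 37 weeks and later is term. Missing gestational age propagates to a missing
#' outcome. Values outside the plausibility window (20--45 weeks by default)
#' are treated as registry errors and rejected rather than coerced.
#'
#' @param gestational_age_weeks Numeric vector of gestational ages in
#'   completed weeks (may contain `NA`).
#' @param window Length-2 numeric plausibility window; non-missing values
#'   outside it raise an error naming the offending positions.
#' @return Integer vector of 0/1/`NA`.
#' @examples
#' encode_preterm(c(36, 37, NA))
#' @export
encode_preterm <- function(gestational_age_weeks, window = c(20, 45)) {
  ga <- gestational_age_weeks
  bad <- which(!is.na(ga) & (ga < window[1] | ga > window[2]))
  if (length(bad)) {
    abort(sprintf(
      "gestational_age_weeks outside plausibility window [%g, %g] at record(s): %s",
      window[1], window[2],
      paste(head(bad, 10L), collapse = ", ")
    ))
  }
  as.integer(ifelse(is.na(ga), NA, ga < 37))
}

#' Encode the four-category co-occurrence outcome
#'
#' Combines the two binary outcomes into a single categorical variable:
#' `0` if neither event occurred, `1` if both occurred, `2` if perinatal death
#' only, and `3` if preterm birth only. The category is missing whenever either
#' component is missing, which keeps the multinomial analysis complete-case on
#' the pair.
#'
#' @param preterm,death Vectors of 0/1/`NA` (recycled to common length).
#' @return Integer vector with values in `0:3` or `NA`.
#' @examples
#' encode_cooccurrence(c(1, 0, 1, 0), c(1, 0, 0, 1))
#' @export
encode_cooccurrence <- function(preterm, death) {
  n <- max(length(preterm), length(death))
  preterm <- rep_len(preterm, n)
  death <- rep_len(death, n)
  if (!is_binary_or_na(preterm) || !is_binary_or_na(death)) {
    abort("preterm and death must be 0, 1 or NA")
  }
  out <- rep(NA_integer_, n)
  ok <- !is.na(preterm) & !is.na(death)
  out[ok] <- dplyr::case_when(
    preterm[ok] == 0 & death[ok] == 0 ~ 0L,
    preterm[ok] == 1 & death[ok] == 1 ~ 1L,
    preterm[ok] == 0 & death[ok] == 1 ~ 2L,
    TRUE ~ 3L
  )
  out
}

#' Apply the registry eligibility filters
#'
#' Reproduces the singleton-delivery eligibility flow: records are removed, in
#' order, when (1) the mother identifier is missing (such records cannot be
#' linked across deliveries), (2) the delivery is a multiple gestation (twins
#' and triplets over-represent high-risk pregnancies), and (3) the plurality is
#' unknown. The order of surviving records is preserved.
#'
#' @param records A data frame of delivery records with at least `mother_id`;
#'   a `plurality` column (values `"singleton"`, `"multiple"`, `"unknown"`) is
#'   used for steps 2--3 and, when absent, all records are treated as
#'   singleton.
#' @return A list of class `eligibility_result` with elements
#'   `records` (tibble of survivors), `exclusions` (tibble with `step`,
#'   `reason`, `n_removed`, `n_remaining`), `n_input` and `n_kept`.
#' @examples
#' df <- tibble::tibble(
#'   mother_id = c("a", NA, "b", "c"),
#'   plurality = c("singleton", "singleton", "multiple", "singleton")
#' )
#' apply_eligibility(df)
#' @export
apply_eligibility <- function(records) {
  records <- tibble::as_tibble(records)
  n_input <- nrow(records)
  plurality <- if ("plurality" %in% names(records)) {
    records$plurality
  } else {
    rep("singleton", n_input)
  }

  keep <- rep(TRUE, n_input)
  steps <- character(0)
  removed <- integer(0)
  remaining <- integer(0)

  drop_step <- function(mask, reason) {
    mask <- mask & keep
    keep <<- keep & !mask
    steps <<- c(steps, reason)
    removed <<- c(removed, sum(mask))
    remaining <<- c(remaining, sum(keep))
  }

  drop_step(is.na(records$mother_id) | records$mother_id == "",
            "missing mother identifier")
  drop_step(!is.na(plurality) & plurality == "multiple",
            "multiple gestation")
  drop_step(is.na(plurality) | plurality == "unknown",
            "unknown plurality")

  structure(
    list(
      records = records[keep, , drop = FALSE],
      exclusions = tibble::tibble(
        step = seq_along(steps),
        reason = steps,
        n_removed = removed,
        n_remaining = remaining
      ),
      n_input = n_input,
      n_kept = sum(keep)
    ),
    class = "eligibility_result"
  )
}

#' @export
print.eligibility_result <- function(x, ...) {
  cat(sprintf("Eligibility flow: %d records in, %d kept\n", x$n_input, x$n_kept))
  for (i in seq_len(nrow(x$exclusions))) {
    cat(sprintf("  step %d: removed %d (%s), %d remaining\n",
                x$exclusions$step[i], x$exclusions$n_removed[i],
                x$exclusions$reason[i], x$exclusions$n_remaining[i]))
  }
  invisible(x)
}

#' Write the exclusion tally of an eligibility result as JSON
#'
#' @param x An [apply_eligibility()] result.
#' @param path File path for the JSON report.
#' @return `path`, invisibly.
#' @export
write_eligibility_report <- function(x, path) {
  stopifnot(inherits(x, "eligibility_result"))
  jsonlite::write_json(
    list(
      n_input = x$n_input,
      n_kept = x$n_kept,
      exclusions = x$exclusions
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Validate a delivery-level registry data frame
#'
#' Checks the schema invariants: `birth_index` values within a mother are
#' unique and contiguous from 1; gestational ages are inside the plausibility
#' window; outcome columns are binary; and every covariate column that appears
#' in the code book only contains declared categories (or `NA`).
#'
#' @param records Data frame of delivery records.
#' @param age_scheme Maternal-age partition to validate against
#'   (see [covariate_codebook()]); both partitions are accepted when
#'   `age_scheme = "either"`.
#' @param window Gestational-age plausibility window in weeks.
#' @return `records` as a tibble, invisibly, if valid; otherwise an error
#'   describing the first violated invariant.
#' @export
validate_registry <- function(records, age_scheme = c("either", "model", "descriptive"),
                              window = c(20, 45)) {
  age_scheme <- match.arg(age_scheme)
  records <- tibble::as_tibble(records)

  if (!"mother_id" %in% names(records)) {
    abort("registry must have a mother_id column")
  }

  if ("birth_index" %in% names(records)) {
    bad <- records |>
      dplyr::filter(!is.na(.data$mother_id)) |>
      dplyr::group_by(.data$mother_id) |>
      dplyr::summarise(
        ok = identical(as.integer(sort(.data$birth_index)),
                       seq_along(.data$birth_index)),
        .groups = "drop"
      ) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad)) {
      abort(sprintf(
        "birth_index not unique and contiguous from 1 for mother(s): %s",
        paste(head(bad$mother_id, 5L), collapse = ", ")
      ))
    }
  }

  if ("gestational_age_weeks" %in% names(records)) {
    encode_preterm(records$gestational_age_weeks, window = window)
  }
  for (col in intersect(c("perinatal_death", "preterm"), names(records))) {
    if (!is_binary_or_na(records[[col]])) {
      abort(sprintf("column %s must be 0/1/NA", col))
    }
  }

  cb <- covariate_codebook("model")
  cb_desc <- covariate_codebook("descriptive")
  for (i in seq_len(nrow(cb))) {
    nm <- cb$covariate[i]
    if (!nm %in% names(records)) next
    allowed <- cb$levels[[i]]
    if (nm == "maternal_age") {
      allowed <- switch(age_scheme,
        either = union(allowed, cb_desc$levels[[match(nm, cb_desc$covariate)]]),
        model = allowed,
        descriptive = cb_desc$levels[[match(nm, cb_desc$covariate)]]
      )
    }
    vals <- records[[nm]]
    bad <- setdiff(unique(vals[!is.na(vals)]), allowed)
    if (length(bad)) {
      abort(sprintf(
        "covariate %s has undeclared categories: %s (allowed: %s)",
        nm, paste(bad, collapse = ", "), paste(allowed, collapse = ", ")
      ))
    }
  }
  invisible(records)
}

#' Read / write a delivery-level registry CSV
#'
#' The on-disk format is UTF-8 comma-delimited with a mandatory header, one
#' row per delivery; empty strings are missing values. `read_registry()`
#' validates the result against the schema.
#'
#' @param path CSV file path.
#' @param ... Passed to [validate_registry()].
#' @return A validated tibble of delivery records.
#' @export
read_registry <- function(path, ...) {
  records <- readr::read_csv(
    path,
    na = c("", "NA"),
    col_types = readr::cols(
      mother_id = readr::col_character(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  for (col in intersect(c("birth_index", "year", "preterm", "perinatal_death",
                          "cooccurrence"), names(records))) {
    records[[col]] <- as.integer(records[[col]])
  }
  validate_registry(records, ...)
  records
}

#' @param records Data frame of delivery records.
#' @rdname read_registry
#' @return `write_registry()` returns `path` invisibly.
#' @export
write_registry <- function(records, path) {
  readr::write_csv(tibble::as_tibble(records), path, na = "")
  invisible(path)
}

#' Perinatal mortality rate per 1,000 births
#'
#' @param records Data frame with a `perinatal_death` column (0/1/`NA`);
#'   missing outcomes are excluded from the denominator.
#' @return Deaths per 1,000 births (numeric scalar).
#' @examples
#' perinatal_mortality_rate(tibble::tibble(perinatal_death = c(0, 0, 1, NA)))
#' @export
perinatal_mortality_rate <- function(records) {
  y <- records$perinatal_death
  1000 * mean(y, na.rm = TRUE)
}

#' Expand published stratified counts into delivery-level records
#'
#' Reconstructs a record-level data frame from summary counts of the kind
#' printed in registry reports: for each stratum, `total` records of which
#' `events` have the outcome. When `overall_total`/`overall_events` exceed the
#' stratum sums, the remainder is emitted with a missing stratifier value so
#' that outcome denominators match the published complete-case totals.
#'
#' @param counts Data frame with columns `category`, `total`, `events`.
#' @param stratifier Name for the stratifier column in the output.
#' @param outcome Name for the binary outcome column in the output.
#' @param overall_total,overall_events Optional published complete-case totals
#'   for the outcome; the difference from the stratum sums becomes an
#'   `NA`-stratum remainder.
#' @return Tibble with columns `stratifier`, `outcome` (one row per record).
#' @export
expand_summary_counts <- function(counts, stratifier = "stratum",
                                  outcome = "event",
                                  overall_total = NULL, overall_events = NULL) {
  counts <- tibble::as_tibble(counts)
  stopifnot(all(c("category", "total", "events") %in% names(counts)),
            all(counts$events <= counts$total))
  cats <- counts$category
  tot <- counts$total
  ev <- counts$events
  if (!is.null(overall_total)) {
    extra_tot <- overall_total - sum(tot)
    extra_ev <- (overall_events %||% sum(ev)) - sum(ev)
    stopifnot(extra_tot >= 0, extra_ev >= 0, extra_ev <= extra_tot)
    if (extra_tot > 0) {
      cats <- c(cats, NA)
      tot <- c(tot, extra_tot)
      ev <- c(ev, extra_ev)
    }
  }
  out <- tibble::tibble(
    s = rep(cats, times = tot),
    y = unlist(purrr::map2(tot, ev, function(t, e) rep(c(1L, 0L), c(e, t - e))))
  )
  names(out) <- c(stratifier, outcome)
  out
}

#' Published summary counts from the KCMC medical birth registry study
#'
#' Stratified outcome counts (totals and event counts for preterm birth and
#' perinatal death) transcribed from a published analysis of singleton
#' deliveries at the KCMC zonal referral hospital, northern Tanzania,
#' 2000--2017, together with the eligibility-flow totals. These are the
#' arithmetic inputs for the worked descriptive examples; the underlying
#' record-level registry is restricted and is not distributed.
#'
#' @return A tibble with columns `table` (`"background"`, `"conditions"`,
#'   `"overall"` or `"flow"`), `stratifier`, `category`, `outcome`
#'   (`"preterm"` or `"death"`), `total`, `events`.
#' @examples
#' head(kcmc_summary_counts())
#' @export
kcmc_summary_counts <- function() {
  path <- system.file("extdata", "kcmc_summary_counts.csv", package = "perijoint")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    table = readr::col_character(),
                    stratifier = readr::col_character(),
                    category = readr::col_character(),
                    outcome = readr::col_character(),
                    total = readr::col_integer(),
                    events = readr::col_integer()
                  ))
}
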