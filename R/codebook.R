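#' Covariate code book for the delivery-level registry schema
#'
#' Explicit category enumerations for every covariate the joint models and
#' descriptive tables understand. Values outside these sets are validation
#' errors, never silently coerced: registry dialects drift, and a misspelled
#' category should fail loudly at load time.
#'
#' Maternal age supports two partitions of the 25--39 range, because published
#' descriptive tables and model tables in this literature use different bins:
#' the `"descriptive"` scheme uses `25-34` as a single band, while the
#' `"model"` scheme splits it so that `25-29` can act as the reference level.
#'
#' @param age_scheme Which maternal-age partition to declare: `"model"`
#'   (default; bins `15-19, 20-24, 25-29, 30-34, 35-39, 40+`) or
#'   `"descriptive"` (bins `15-19, 20-24, 25-34, 35-39, 40+`).
#'
#' @return A tibble with columns `covariate` (name), `levels` (list column of
#'   allowed category strings, reference level first).
#' @examples
#' covariate_codebook()
#' @export
covariate_codebook <- function(age_scheme = c("model", "descriptive")) {
  age_scheme <- match.arg(age_scheme)
  age_levels <- maternal_age_levels(age_scheme)
  levels <- list(
    maternal_age = age_levels,
    maternal_education = c("higher", "none", "primary", "secondary"),
    maternal_occupation = c("employed", "unemployed", "farmer", "others"),
    marital_status = c("married", "single", "widowed/divorced"),
    residence = c("urban", "rural"),
    bmi_group = c("normal", "underweight", "overweight", "obese"),
    paternal_age = c("25-29", "15-24", "30-34", "35+"),
    paternal_education = c("higher", "none", "primary", "secondary"),
    paternal_occupation = c("employed", "unemployed", "farmer", "others"),
    anc_visits = c("4+", "<4"),
    parity = c("multipara", "primipara"),
    alcohol = c("no", "yes"),
    referral = c("no", "yes"),
    hiv = c("negative", "positive"),
    anemia = c("no", "yes"),
    malaria = c("no", "yes"),
    infection = c("no", "yes"),
    preeclampsia = c("no", "yes"),
    prom = c("no", "yes"),
    pph = c("no", "yes"),
    abruption_placenta = c("no", "yes"),
    placenta_previa = c("no", "yes"),
    child_sex = c("female", "male"),
    birth_weight_group = c("normal", "lbw"),
    presentation = c("cephalic", "breech", "transverse"),
    delivery_mode = c("vaginal", "cs"),
    apgar5_group = c("high", "low"),
    induced_labor = c("no", "yes")
  )
  tibble::tibble(
    covariate = names(levels),
    levels = unname(levels)
  )
}

maternal_age_levels <- function(scheme) {
  switch(scheme,
    model = c("25-29", "15-19", "20-24", "30-34", "35-39", "40+"),
    descriptive = c("25-34", "15-19", "20-24", "35-39", "40+")
  )
}

#' Bin a numeric maternal age into registry age groups
#'
#' @param age Numeric vector of maternal ages in years.
#' @param scheme `"model"` (reference band `25-29`) or `"descriptive"`
#'   (single `25-34` band). See [covariate_codebook()].
#' @return Character vector of age-group labels (`NA` propagates).
#' @examples
#' bin_maternal_age(c(17, 26, 33, 41))
#' bin_maternal_age(c(17, 26, 33, 41), scheme = "descriptive")
#' @export
bin_maternal_age <- function(age, scheme = c("model", "descriptive")) {
  scheme <- match.arg(scheme)
  if (scheme == "model") {
    breaks <- c(-Inf, 19, 24, 29, 34, 39, Inf)
    labels <- c("15-19", "20-24", "25-29", "30-34", "35-39", "40+")
  } else {
    breaks <- c(-Inf, 19, 24, 34, 39, Inf)
    labels <- c("15-19", "20-24", "25-34", "35-39", "40+")
  }
  as.character(cut(age, breaks = breaks, labels = labels))
}

codebook_levels <- function(covariate, age_scheme = "model") {
  cb <- covariate_codebook(age_scheme)
  i <- match(covariate, cb$covariate)
  if (is.na(i)) return(NULL)
  cb$levels[[i]]
}
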