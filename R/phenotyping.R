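vitd_levels <- c("deficient", "insufficient", "sufficient")

#' Classify maternal vitamin D status (IOM cut-offs)
#'
#' Serum 25(OH)D below 12 ng/mL is deficient, 12 to below 20 ng/mL is
#' insufficient, and 20 ng/mL or more is sufficient. The bands are
#' half-open on the real line (12 -> insufficient, 20 -> sufficient), so
#' they partition `[0, Inf)` with no gaps: a value such as 19.99 is
#' insufficient.
#'
#' @param value Serum 25(OH)D in ng/mL (vector; `NA` passes through).
#' @return Factor with levels deficient / insufficient / sufficient.
#' @examples
#' classify_vitd(c(11.9, 12, 19.99, 20))
#' @export
classify_vitd <- function(value) {
  if (any(value < 0, na.rm = TRUE)) {
    stop("25(OH)D values must be non-negative", call. = FALSE)
  }
  out <- ifelse(is.na(value), NA_character_,
                ifelse(value < 12, "deficient",
                       ifelse(value < 20, "insufficient", "sufficient")))
  factor(out, levels = vitd_levels)
}

#' Classify newborn anthropometry (WHO cut-offs)
#'
#' Three independent binary labels: low birth weight below 2500 g, short
#' birth length below 50 cm, small head circumference below 35 cm; at or
#' above each cut-off is normal.
#'
#' @param birth_weight Birth weight in g.
#' @param birth_length Birth length in cm.
#' @param head_circumference Head circumference in cm.
#' @return Tibble with factor columns `birth_weight_cat` (low/normal),
#'   `birth_length_cat` (short/normal), `head_circ_cat` (small/normal).
#' @export
classify_anthro <- function(birth_weight, birth_length, head_circumference) {
  for (v in list(birth_weight, birth_length, head_circumference)) {
    if (any(v <= 0, na.rm = TRUE)) {
      stop("anthropometry measurements must be strictly positive",
           call. = FALSE)
    }
  }
  bin <- function(x, cut, adverse) {
    factor(ifelse(is.na(x), NA_character_,
                  ifelse(x < cut, adverse, "normal")),
           levels = c(adverse, "normal"))
  }
  tibble::tibble(
    birth_weight_cat = bin(birth_weight, 2500, "low"),
    birth_length_cat = bin(birth_length, 50, "short"),
    head_circ_cat = bin(head_circumference, 35, "small"))
}

#' Body mass index with WHO Asian-population category
#'
#' BMI = weight (kg) / height (m)^2, classified with the WHO bands for
#' Asian populations: underweight below 18.5, normal 18.5 to below 23.5,
#' overweight 23.5 to below 25, pre-obese 25 to below 30, obese 30 and
#' above. Printed band upper bounds (23.49, 24.99, 29.99) are read as
#' half-open intervals on the real line.
#'
#' @param weight Weight in kg (> 0).
#' @param height Height in cm (> 0).
#' @return Tibble with `bmi` (kg/m^2) and `bmi_cat` (factor).
#' @export
compute_bmi <- function(weight, height) {
  if (any(weight <= 0, na.rm = TRUE) || any(height <= 0, na.rm = TRUE)) {
    stop("weight and height must be strictly positive", call. = FALSE)
  }
  bmi <- weight / (height / 100)^2
  # band on a 6-dp rounding so values landing on a cut-off through
  # floating-point arithmetic (e.g. 76.8/1.6^2) classify as printed
  cat <- cut(round(bmi, 6), breaks = c(-Inf, 18.5, 23.5, 25, 30, Inf),
             labels = c("underweight", "normal", "overweight",
                        "pre_obese", "obese"),
             right = FALSE)
  tibble::tibble(bmi = bmi, bmi_cat = cat)
}

#' Change in 25(OH)D across pregnancy
#'
#' Signed difference, third minus first trimester; defined only when both
#' visits are present (`NA` otherwise).
#'
#' @param t1,t3 Serum 25(OH)D (ng/mL) at the first and third trimester.
#' @return Numeric vector of T3 - T1 differences.
#' @export
change_25ohd <- function(t1, t3) {
  ifelse(is.na(t1) | is.na(t3), NA_real_, t3 - t1)
}

#' Append derived phenotypes to the participant/neonate tables
#'
#' Adds IOM vitamin D categories at both trimesters, the 25(OH)D change
#' score, the WHO-Asian BMI category, and the WHO newborn anthropometry
#' categories.
#'
#' @param cohort A `cohort_dataset`.
#' @return A tibble: one row per analyzable pair with maternal, neonatal
#'   and derived columns.
#' @export
derive_phenotypes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  p <- cohort$participants
  p$vitd_status_t1 <- classify_vitd(p$vitd_t1)
  p$vitd_status_t3 <- classify_vitd(p$vitd_t3)
  p$delta_25ohd <- change_25ohd(p$vitd_t1, p$vitd_t3)
  if (all(c("prepreg_weight", "height") %in% names(p))) {
    p$prepreg_bmi_cat <- compute_bmi(p$prepreg_weight, p$height)$bmi_cat
  }
  neo <- cohort$neonates
  neo <- dplyr::bind_cols(
    neo, classify_anthro(neo$birth_weight, neo$birth_length,
                         neo$head_circumference))
  dplyr::inner_join(p, neo, by = "sample_id")
}
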