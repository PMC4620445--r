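# Phenotype-side composites: lifetime menstrual-cycle measures and obesity
# variables.

#' Total months of menstrual cycling (TMMC)
#'
#' The months of active menstrual cycling a woman experienced during life (or
#' up to the study interview), computed from reproductive history as
#'
#' \deqn{(age_{menopause} - age_{menarche}) \times 12
#'   - \mathrm{pregnancy\ months}
#'   - \mathrm{live\ births} \times 1.5
#'   - \mathrm{breastfeeding\ months}/2
#'   - \mathrm{OC\ months}}
#'
#' The 1.5-month term reflects the assumed delay to cycle resumption after each
#' parturition, and half the breastfeeding duration extends that delay when
#' breastfeeding occurred; both enter as aggregate totals. For premenopausal
#' subjects (`menopause_type == "pre"`) the attained age (age at diagnosis for
#' cases, at interview for controls) substitutes for age at menopause.
#' Negative values, possible under extreme oral-contraceptive use, are floored
#' at 0 with a warning.
#'
#' @param subjects data frame of subject records; required columns are
#'   `age_menarche`, `age_menopause`, `menopause_type`
#'   (`"pre"`/`"natural"`/`"induced"`), `attained_age`,
#'   `pregnancy_months_total`, `live_births`, `breastfeeding_months_total`,
#'   and `oc_months_total`.
#' @return numeric vector of months, one per row, floored at 0.
#' @seealso [tnmc()] for the cycle-count composite.
#' @export
#' @examples
#' s <- data.frame(age_menarche = 13, age_menopause = 50, menopause_type = "natural",
#'                 attained_age = 62, pregnancy_months_total = 18, live_births = 2,
#'                 breastfeeding_months_total = 12, oc_months_total = 24,
#'                 cycle_length = 28)
#' tmmc(s)  # 393 months
tmmc <- function(subjects) {
  subjects <- as.data.frame(subjects)
  need <- c("age_menarche", "menopause_type", "attained_age",
            "pregnancy_months_total", "live_births",
            "breastfeeding_months_total", "oc_months_total")
  for (f in need) {
    if (is.null(subjects[[f]])) stop_missing_data(f, " (column absent)")
  }
  if (anyNA(subjects$age_menarche)) stop_missing_data("age_menarche")
  pre <- subjects$menopause_type == "pre"
  stop_age <- ifelse(pre, subjects$attained_age, subjects$age_menopause)
  if (anyNA(stop_age)) stop_missing_data("age_menopause")
  months <- (stop_age - subjects$age_menarche) * 12 -
    subjects$pregnancy_months_total -
    subjects$live_births * 1.5 -
    subjects$breastfeeding_months_total / 2 -
    subjects$oc_months_total
  if (any(months < 0)) {
    warning(sum(months < 0), " subject(s) with negative cycling months floored at 0")
    months <- pmax(months, 0)
  }
  months
}

#' Total number of menstrual cycles (TNMC)
#'
#' The lifetime-cycle composite: [tmmc()] months rescaled by the subject's
#' average cycle length, `TMMC * 30 / cycle_length`, so that a 30-day cycle
#' counts one cycle per month of active cycling. See [tmmc()] for the formula,
#' the premenopausal surrogate rule and the floor at 0.
#'
#' @inheritParams tmmc
#' @param impute_cycle_length if `TRUE`, a missing `cycle_length` is replaced
#'   by 28 days; if `FALSE` (default) missing cycle length is an error.
#' @return numeric vector of lifetime cycle counts.
#' @export
#' @examples
#' s <- data.frame(age_menarche = 13, age_menopause = 50, menopause_type = "natural",
#'                 attained_age = 62, pregnancy_months_total = 18, live_births = 2,
#'                 breastfeeding_months_total = 12, oc_months_total = 24,
#'                 cycle_length = 28)
#' tnmc(s)  # 393 * 30/28 = 421.07...
tnmc <- function(subjects, impute_cycle_length = FALSE) {
  subjects <- as.data.frame(subjects)
  if (is.null(subjects$cycle_length)) stop_missing_data("cycle_length", " (column absent)")
  cl <- subjects$cycle_length
  if (anyNA(cl)) {
    if (impute_cycle_length) cl[is.na(cl)] <- 28 else stop_missing_data("cycle_length")
  }
  if (any(cl <= 0)) stop_invalid("cycle_length must be > 0")
  tmmc(subjects) * 30 / cl
}

#' Body mass index and its categories
#'
#' `bmi()` computes weight / height^2 in kg/m^2. `categorize_bmi()` bins BMI
#' into the conventional half-open classes: normal weight `[0, 25)`,
#' overweight `[25, 30)`, obese `[30, Inf)`.
#'
#' @param weight_kg body weight in kilograms (> 0).
#' @param height_m height in metres (> 0).
#' @return `bmi()`: numeric kg/m^2. `categorize_bmi()`: factor with levels
#'   `"<25"`, `"25-<30"`, `">=30"`.
#' @export
bmi <- function(weight_kg, height_m) {
  if (any(weight_kg <= 0) || any(height_m <= 0)) {
    stop_invalid("weight and height must be positive")
  }
  weight_kg / height_m^2
}

#' @rdname bmi
#' @param x numeric BMI values.
#' @export
categorize_bmi <- function(x) {
  cut(x, breaks = c(0, 25, 30, Inf), right = FALSE,
      labels = c("<25", "25-<30", ">=30"))
}

#' Percent BMI change from age 20 and its categories
#'
#' `bmi_change()` is the percent change from BMI at age 20 to BMI 5 years
#' before interview: `(bmi5y - bmi20) / bmi20 * 100`. `categorize_bmi_change()`
#' bins the percentage into upper-closed classes
#' `(-Inf, 5]`, `(5, 20]`, `(20, 35]`, `(35, Inf)`.
#'
#' @param bmi20 BMI at age 20 (kg/m^2, > 0).
#' @param bmi5y BMI 5 years before interview (kg/m^2).
#' @return `bmi_change()`: numeric percent. `categorize_bmi_change()`: factor
#'   with levels `"<=5%"`, `">5%-<=20%"`, `">20%-<=35%"`, `">35%"`.
#' @export
bmi_change <- function(bmi20, bmi5y) {
  if (any(bmi20 <= 0)) stop_invalid("bmi20 must be positive")
  (bmi5y - bmi20) / bmi20 * 100
}

#' @rdname bmi_change
#' @param pct numeric percent changes.
#' @export
categorize_bmi_change <- function(pct) {
  cut(pct, breaks = c(-Inf, 5, 20, 35, Inf), right = TRUE,
      labels = c("<=5%", ">5%-<=20%", ">20%-<=35%", ">35%"))
}

#' Compute the per-subject phenotype score set
#'
#' Convenience wrapper that evaluates every phenotype-side composite on a
#' subject table: TNMC, TMMC, BMI (5 years before interview) category, percent
#' BMI change and its category.
#'
#' @inheritParams tnmc
#' @return data frame keyed by `id` with columns `tnmc`, `tmmc`,
#'   `bmi_category`, `bmi_change_pct`, `bmi_change_category`.
#' @export
compute_scores <- function(subjects, impute_cycle_length = FALSE) {
  subjects <- as.data.frame(subjects)
  ids <- if (!is.null(subjects$id)) subjects$id else seq_len(nrow(subjects))
  out <- data.frame(
    id = ids,
    tnmc = tnmc(subjects, impute_cycle_length = impute_cycle_length),
    tmmc = tmmc(subjects),
    stringsAsFactors = FALSE
  )
  if (!is.null(subjects$bmi5y)) {
    out$bmi_category <- categorize_bmi(subjects$bmi5y)
    if (!is.null(subjects$bmi20)) {
      out$bmi_change_pct <- bmi_change(subjects$bmi20, subjects$bmi5y)
      out$bmi_change_category <- categorize_bmi_change(out$bmi_change_pct)
    }
  }
  out
}

#' Read and write the phenotype CSV dialect
#'
#' Comma-separated, UTF-8, one header row, `NA` for missing. Numeric columns
#' are written with 17 significant digits so that every double round-trips
#' bit-exactly: recomputing [tnmc()] from a re-read record reproduces the
#' original value identically.
#'
#' @param subjects subject data frame.
#' @param path file path.
#' @return `read_phenotypes()`: the subject data frame;
#'   `write_phenotypes()`: the path, invisibly.
#' @export
write_phenotypes <- function(subjects, path) {
  out <- subjects
  for (v in names(out)) {
    if (is.double(out[[v]])) {
      x <- sprintf("%.17g", out[[v]])
      x[is.na(out[[v]])] <- NA_character_
      out[[v]] <- x
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
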