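# Case-control association battery: control-quantile binning, 2x2 and
# logistic odds ratios across the standard adjustment sets, linear
# score-on-age models, the joint cycle/score exposure and its interaction
# test.
#
# Results travel as "assoc_result" data frames: one row per exposure term
# with columns term, measure ("OR" or "beta"), estimate, conf_low, conf_high,
# p_value, n_cases, n_controls, model.

assoc_result <- function(term, measure, estimate, conf_low, conf_high,
                         p_value, n_cases, n_controls, model) {
  structure(
    data.frame(term = term, measure = measure, estimate = estimate,
               conf_low = conf_low, conf_high = conf_high, p_value = p_value,
               n_cases = n_cases, n_controls = n_controls, model = model,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("assoc_result", "data.frame"))
}

#' Covariates of the named adjustment set
#'
#' The analysis uses five nested adjustment sets, keyed `"a"` to `"e"`:
#' `a` none (unadjusted); `b` age, race, education; `c` = b plus family
#' history of cancer, oral-contraceptive ever-use and estrogen use; `d` = c
#' plus BMI (5 years before interview, continuous); `e` = c plus the 4-level
#' BMI-change category. Education enters as an ordinal 4-level code.
#'
#' @param set one of `"a"`, `"b"`, `"c"`, `"d"`, `"e"`, or a character vector
#'   of column names used verbatim.
#' @return character vector of covariate column names.
#' @export
adjustment_set <- function(set = c("a", "b", "c", "d", "e")) {
  if (!all(set %in% c("a", "b", "c", "d", "e"))) return(set)
  set <- match.arg(set)
  b <- c("attained_age", "race", "education")
  cc <- c(b, "family_history", "oc_ever", "estrogen_use")
  switch(set,
         a = character(0),
         b = b,
         c = cc,
         d = c(cc, "bmi5y"),
         e = c(cc, "bmi_change_category"))
}

#' Bin an exposure at control-derived quantiles
#'
#' Cut points are quantiles of the exposure among controls only (median,
#' tertiles or quartiles, linear-interpolation convention, `stats::quantile`
#' type 7); categories are then assigned to all subjects with the boundary
#' convention "low" = at or below the cut, "high" = above it (intervals
#' closed on the right).
#'
#' @param values numeric exposure for every subject (NA allowed; propagates).
#' @param controls logical vector marking the reference controls.
#' @param scheme `"median"`, `"tertiles"` or `"quartiles"`.
#' @return list of class `binning_rule` with `scheme`, `cuts` (the control
#'   quantiles), `reference = "controls"` and `category` (factor over all
#'   subjects; median labels `low`/`high`, otherwise `T1..`/`Q1..`).
#' @export
control_quantile_bins <- function(values, controls,
                                  scheme = c("median", "tertiles", "quartiles")) {
  scheme <- match.arg(scheme)
  controls <- as.logical(controls)
  if (length(controls) != length(values)) {
    stop_invalid("controls mask must align with values")
  }
  probs <- switch(scheme, median = 0.5, tertiles = (1:2) / 3, quartiles = (1:3) / 4)
  ref <- values[controls & !is.na(values)]
  if (length(ref) < length(probs) + 1) {
    stop_invalid("fewer usable controls than requested bins")
  }
  cuts <- unname(stats::quantile(ref, probs, type = 7))
  if (any(diff(c(-Inf, cuts, Inf)) <= 0)) {
    stop_invalid("degenerate control quantiles: cut points not strictly increasing")
  }
  labels <- switch(scheme,
                   median = c("low", "high"),
                   tertiles = paste0("T", 1:3),
                   quartiles = paste0("Q", 1:4))
  category <- cut(values, breaks = c(-Inf, cuts, Inf), right = TRUE,
                  labels = labels)
  if (any(table(category[controls]) == 0)) {
    stop_invalid("degenerate control quantiles: some bins contain no controls")
  }
  structure(list(scheme = scheme, cuts = cuts, reference = "controls",
                 category = category),
            class = "binning_rule")
}

#' Odds ratio from a 2x2 exposure-by-status table
#'
#' Cross-product odds ratio `(a d)/(b c)` with the Woolf (log-OR normal
#' approximation) 95 percent confidence interval
#' `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))` and the corresponding
#' Wald p-value. Zero cells are an error unless `continuity = TRUE`, which
#' adds 0.5 to every cell.
#'
#' @param exposed_cases,exposed_controls,unexposed_cases,unexposed_controls
#'   the four cell counts.
#' @param continuity add the Haldane 0.5 continuity correction to all cells.
#' @return an `assoc_result` row.
#' @export
#' @examples
#' odds_ratio_2x2(286, 269, 173, 269)  # OR 1.65
odds_ratio_2x2 <- function(exposed_cases, exposed_controls,
                           unexposed_cases, unexposed_controls,
                           continuity = FALSE) {
  cells <- c(exposed_cases, exposed_controls, unexposed_cases, unexposed_controls)
  if (any(cells < 0)) stop_invalid("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!continuity) {
      stop(errorCondition(
        "zero cell in 2x2 table; set continuity = TRUE for the 0.5 correction",
        class = c("cyclegrs_zero_cell", "error")))
    }
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- log(or) / se
  assoc_result(term = "exposed", measure = "OR", estimate = or,
               conf_low = exp(log(or) - 1.96 * se),
               conf_high = exp(log(or) + 1.96 * se),
               p_value = 2 * stats::pnorm(-abs(z)),
               n_cases = exposed_cases + unexposed_cases,
               n_controls = exposed_controls + unexposed_controls,
               model = "2x2 cross-product")
}

# ordinal-code an education factor/character as 1..4; other covariates pass
# through (factors/characters become model factors).
prepare_covariates <- function(data, covars) {
  df <- data[, covars, drop = FALSE]
  if ("education" %in% covars && !is.numeric(df$education)) {
    df$education <- as.integer(factor(df$education))
  }
  for (v in names(df)) {
    if (is.character(df[[v]]) || is.logical(df[[v]])) df[[v]] <- factor(df[[v]])
  }
  df
}

check_fit <- function(fit) {
  if (!is.null(fit$converged) && !fit$converged) {
    stop(errorCondition(
      sprintf("model did not converge in %d IRLS iterations", fit$iter),
      class = c("cyclegrs_convergence_error", "error")))
  }
  if (any(is.na(stats::coef(fit)))) {
    stop(errorCondition(
      paste("rank-deficient fit; aliased terms:",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", ")),
      class = c("cyclegrs_rank_deficiency", "error")))
  }
  invisible(fit)
}

#' Unconditional logistic regression for case-control status
#'
#' Maximum-likelihood logistic fit of case status on one exposure plus the
#' covariates of an [adjustment_set()], on the complete cases for the model's
#' variables (so each model's n reflects its own missingness). Reports
#' `exp(coefficient)` odds ratios with Wald 95 percent confidence intervals
#' and p-values for every exposure term (one per non-reference level for
#' factor exposures). Continuous exposures can be rescaled with `per`
#' (e.g. `per = 100` for an odds ratio per 100 menstrual cycles).
#'
#' @param data subject-level data frame with a `status` column
#'   (`"case"`/`"control"`) and the model variables.
#' @param exposure name of the exposure column (numeric or factor).
#' @param adjustment adjustment set key or covariate names ([adjustment_set()]).
#' @param subset `"all"` or `"natural"` (restrict to natural menopause).
#' @param per unit of increment for a continuous exposure (default 1).
#' @return an `assoc_result` data frame, one row per exposure term.
#' @export
fit_logistic <- function(data, exposure, adjustment = "a",
                         subset = c("all", "natural"), per = 1) {
  subset <- match.arg(subset)
  if (subset == "natural") data <- data[data$menopause_type == "natural", , drop = FALSE]
  covars <- adjustment_set(adjustment)
  x <- data[[exposure]]
  if (is.null(x)) stop_invalid("exposure column '", exposure, "' not found")
  if (is.numeric(x)) x <- x / per else x <- factor(x)
  df <- data.frame(.y = as.integer(data$status == "case"), .x = x)
  if (length(covars)) df <- cbind(df, prepare_covariates(data, covars))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  check_fit(fit)
  sm <- stats::summary.glm(fit)$coefficients
  rows <- grep("^\\.x", rownames(sm))
  est <- sm[rows, "Estimate"]
  se <- sm[rows, "Std. Error"]
  z <- stats::qnorm(0.975)
  label <- if (is.factor(df$.x)) {
    paste0(exposure, "=", sub("^\\.x", "", rownames(sm)[rows]))
  } else if (per != 1) paste0(exposure, " per ", per) else exposure
  assoc_result(term = label, measure = "OR", estimate = exp(est),
               conf_low = exp(est - z * se), conf_high = exp(est + z * se),
               p_value = sm[rows, "Pr(>|z|)"],
               n_cases = sum(df$.y == 1), n_controls = sum(df$.y == 0),
               model = paste0("logistic, adjustment ",
                              paste(if (length(covars)) adjustment else "a",
                                    collapse = "+"),
                              if (subset == "natural") ", natural menopause" else ""))
}

#' Linear regression of trait age on a genetic risk score among controls
#'
#' Ordinary least squares of age at menarche (or age at natural menopause) on
#' a genetic risk score among controls, adjusted for attained age and race.
#' The menopause trait is restricted to controls with natural menopause. The
#' score may be continuous or a pre-binned factor (one term per non-reference
#' level).
#'
#' @param data subject-level data frame (needs `status`, `attained_age`,
#'   `race`, `age_menarche` or `age_menopause`, `menopause_type`).
#' @param trait `"menarche"` or `"menopause"`.
#' @param score name of the score column.
#' @param adjust covariate column names (default attained age and race).
#' @return an `assoc_result` data frame with `measure = "beta"`.
#' @export
fit_linear_grs_age <- function(data, trait = c("menarche", "menopause"),
                               score, adjust = c("attained_age", "race")) {
  trait <- match.arg(trait)
  data <- data[data$status == "control", , drop = FALSE]
  if (trait == "menopause") {
    data <- data[data$menopause_type == "natural", , drop = FALSE]
  }
  if (nrow(data) == 0) stop_invalid("empty subset: no eligible controls")
  y <- if (trait == "menarche") data$age_menarche else data$age_menopause
  x <- data[[score]]
  if (!is.numeric(x)) x <- factor(x)
  df <- data.frame(.y = y, .x = x)
  if (length(adjust)) df <- cbind(df, prepare_covariates(data, adjust))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::lm(.y ~ ., data = df)
  check_fit(fit)
  sm <- stats::summary.lm(fit)$coefficients
  rows <- grep("^\\.x", rownames(sm))
  est <- sm[rows, "Estimate"]
  se <- sm[rows, "Std. Error"]
  z <- stats::qnorm(0.975)
  label <- if (is.factor(df$.x)) {
    paste0(score, "=", sub("^\\.x", "", rownames(sm)[rows]))
  } else score
  assoc_result(term = label, measure = "beta", estimate = est,
               conf_low = est - z * se, conf_high = est + z * se,
               p_value = sm[rows, "Pr(>|t|)"],
               n_cases = 0L, n_controls = nrow(df),
               model = paste0("linear, controls, trait ", trait))
}

#' Joint cycle-count / menarche-score exposure with four levels
#'
#' Cross-classifies subjects by whether their lifetime cycle count (TNMC) and
#' menarche genetic risk score (GRS1) lie above or at-or-below the control
#' medians, yielding a 4-level factor (TNMC first):
#' `low/low` (the modelling reference), `low/high`, `high/low`, `high/high`.
#' Values exactly at a median are "low". Subjects missing either exposure get
#' `NA` (excluded from models), with a message giving the count.
#'
#' @param tnmc,grs1 numeric exposures for every subject.
#' @param controls logical vector marking controls (median reference).
#' @return factor with levels `low/low`, `low/high`, `high/low`, `high/high`;
#'   the control median cuts are attached as attribute `cuts`.
#' @export
joint_tnmc_grs1 <- function(tnmc, grs1, controls) {
  t_bin <- control_quantile_bins(tnmc, controls, "median")
  g_bin <- control_quantile_bins(grs1, controls, "median")
  lev <- c("low/low", "low/high", "high/low", "high/high")
  joint <- factor(paste(t_bin$category, g_bin$category, sep = "/"), levels = lev)
  n_na <- sum(is.na(joint))
  if (n_na > 0) {
    message(n_na, " subject(s) missing TNMC or GRS1 excluded from the joint variable")
  }
  attr(joint, "cuts") <- c(tnmc = t_bin$cuts, grs1 = g_bin$cuts)
  joint
}

#' Multiplicative interaction test for two median-split exposures
#'
#' Adds the product of the two high/low indicators (control-median splits) to
#' the main-effects logistic model and reports the Wald test of the product
#' term. A non-significant product term means the joint effect is compatible
#' with multiplicative (odds-scale) combination of the marginals.
#'
#' @inheritParams fit_logistic
#' @param exposure_a,exposure_b names of the two numeric exposure columns.
#' @return list with `p_value`, `coefficient` (log-odds interaction) and
#'   `result` (the full `assoc_result` row for the product term).
#' @export
interaction_test <- function(data, exposure_a, exposure_b, adjustment = "a",
                             subset = c("all", "natural")) {
  subset <- match.arg(subset)
  if (subset == "natural") data <- data[data$menopause_type == "natural", , drop = FALSE]
  controls <- data$status == "control"
  ha <- control_quantile_bins(data[[exposure_a]], controls, "median")$category == "high"
  hb <- control_quantile_bins(data[[exposure_b]], controls, "median")$category == "high"
  covars <- adjustment_set(adjustment)
  df <- data.frame(.y = as.integer(data$status == "case"), .a = ha, .b = hb)
  if (length(covars)) df <- cbind(df, prepare_covariates(data, covars))
  df <- df[stats::complete.cases(df), , drop = FALSE]
  fit <- stats::glm(.y ~ . + .a:.b, data = df, family = stats::binomial())
  check_fit(fit)
  sm <- stats::summary.glm(fit)$coefficients
  row <- grep("^\\.a.*:\\.b", rownames(sm))
  est <- sm[row, "Estimate"]
  se <- sm[row, "Std. Error"]
  z <- stats::qnorm(0.975)
  res <- assoc_result(term = paste0(exposure_a, ":", exposure_b),
                      measure = "OR", estimate = exp(est),
                      conf_low = exp(est - z * se), conf_high = exp(est + z * se),
                      p_value = sm[row, "Pr(>|z|)"],
                      n_cases = sum(df$.y == 1), n_controls = sum(df$.y == 0),
                      model = "logistic interaction (median splits)")
  list(p_value = res$p_value, coefficient = est, result = res)
}
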