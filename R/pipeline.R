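# Pipeline orchestration and summary reporting.

#' Build genetic risk scores for a study dataset
#'
#' Glue for the genotype side of the pipeline: QC filtering
#' ([qc_filter()]), per-trait SNP selection ([select_score_snps()]),
#' risk-allele orientation ([orient_genotypes()]), stratified mean imputation
#' ([impute_missing()]) and the four scores ([unweighted_grs()],
#' [weighted_grs()]).
#'
#' @param subjects phenotype data frame with `status`, ages and covariates,
#'   rows aligned with the genotype matrix.
#' @param genotypes effect-allele-coded genotype matrix (subjects x SNPs).
#' @param annotation SNP annotation (`snp`, `trait`, `beta`, `effect_allele`,
#'   optionally `other_allele`, `locus`).
#' @param thresholds a [qc_thresholds()] object.
#' @param select apply selection criteria (a)-(c); disable to score all
#'   QC-passing annotated SNPs.
#' @return list with `scores` (data frame `id`, `grs1`, `grs2`, `wgrs1`,
#'   `wgrs2`), `qc_report`, `selection` (per-trait exclusion logs),
#'   `annotation` (oriented, selected rows), `genotypes` (oriented, imputed).
#' @export
build_grs <- function(subjects, genotypes, annotation,
                      thresholds = qc_thresholds(), select = TRUE) {
  if (nrow(subjects) != nrow(genotypes)) {
    stop_invalid("subjects and genotype rows must align")
  }
  qc <- qc_filter(genotypes, subjects$status == "control", thresholds)
  annotation <- annotation[annotation$snp %in% colnames(qc$genotypes), ,
                           drop = FALSE]
  selection <- list()
  if (select) {
    kept <- list()
    for (tr in c("menarche", "menopause")) {
      cand <- annotation[annotation$trait == tr, , drop = FALSE]
      if (nrow(cand) == 0) next
      age <- if (tr == "menarche") subjects$age_menarche else
        ifelse(subjects$menopause_type == "natural", subjects$age_menopause, NA)
      sel <- select_score_snps(cand, qc$genotypes, age,
                               adjust = subjects[, intersect(
                                 c("attained_age", "race"), names(subjects)),
                                 drop = FALSE],
                               thresholds = thresholds)
      selection[[tr]] <- sel$exclusions
      kept[[tr]] <- sel$selected
    }
    annotation <- do.call(rbind, kept)
  }
  oriented <- orient_genotypes(
    qc$genotypes[, annotation$snp, drop = FALSE], annotation)
  complete <- impute_missing(oriented$genotypes, subjects$status == "case")
  ann <- oriented$annotation
  scores <- data.frame(id = subjects$id, stringsAsFactors = FALSE)
  if (any(ann$trait == "menarche")) {
    scores$grs1 <- unweighted_grs(complete, ann, "menarche")
    scores$wgrs1 <- weighted_grs(complete, ann, "menarche")
  }
  if (any(ann$trait == "menopause")) {
    scores$grs2 <- unweighted_grs(complete, ann, "menopause")
    scores$wgrs2 <- weighted_grs(complete, ann, "menopause")
  }
  list(scores = scores, qc_report = qc$report, selection = selection,
       annotation = ann, genotypes = complete)
}

#' Run the full association battery on a scored dataset
#'
#' Fits, for each exposure (TNMC per 100 cycles and its control-median split;
#' GRS1 and GRS2 continuous and median-split), the unconditional logistic
#' models across the requested adjustment sets, on all subjects and on the
#' natural-menopause subset; the control-only linear score-on-age models; the
#' 4-level joint TNMC/GRS1 models; and the TNMC-by-GRS1 interaction test.
#'
#' @param data subject-level data frame containing `status`, `tnmc`, `grs1`,
#'   `grs2`, covariate columns, and `menopause_type`.
#' @param adjustments adjustment-set keys to fit (default `"a"` to `"e"`).
#' @return list with `logistic` (tidy `assoc_result` data frame over all
#'   exposures/models/subsets), `linear` (score-on-age results), `joint`
#'   (4-level joint-variable results) and `interaction` (data frame of Wald
#'   p-values per adjustment set).
#' @export
run_associations <- function(data, adjustments = c("a", "b", "c", "d", "e")) {
  controls <- data$status == "control"
  data$tnmc_group <- control_quantile_bins(data$tnmc, controls, "median")$category
  data$grs1_group <- control_quantile_bins(data$grs1, controls, "median")$category
  data$grs2_group <- control_quantile_bins(data$grs2, controls, "median")$category
  exposures <- list(
    list(col = "tnmc", per = 100), list(col = "tnmc_group", per = 1),
    list(col = "grs1", per = 1), list(col = "grs1_group", per = 1),
    list(col = "grs2", per = 1), list(col = "grs2_group", per = 1))
  logistic <- list()
  for (sub in c("all", "natural")) {
    for (ex in exposures) {
      for (adj in adjustments) {
        res <- fit_logistic(data, ex$col, adjustment = adj, subset = sub,
                            per = ex$per)
        res$exposure <- ex$col
        res$adjustment <- adj
        res$subset <- sub
        logistic[[length(logistic) + 1L]] <- res
      }
    }
  }
  logistic <- do.call(rbind, logistic)

  linear <- rbind(
    cbind(fit_linear_grs_age(data, "menarche", "grs1"), score = "grs1"),
    cbind(fit_linear_grs_age(data, "menopause", "grs2"), score = "grs2"))
  if (!is.null(data$wgrs1)) {
    linear <- rbind(
      linear,
      cbind(fit_linear_grs_age(data, "menarche", "wgrs1"), score = "wgrs1"),
      cbind(fit_linear_grs_age(data, "menopause", "wgrs2"), score = "wgrs2"))
  }

  data$joint <- joint_tnmc_grs1(data$tnmc, data$grs1, controls)
  joint <- list()
  inter <- data.frame(adjustment = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  for (adj in adjustments) {
    res <- fit_logistic(data, "joint", adjustment = adj)
    res$adjustment <- adj
    joint[[length(joint) + 1L]] <- res
    it <- interaction_test(data, "tnmc", "grs1", adjustment = adj)
    inter[nrow(inter) + 1L, ] <- list(adj, it$p_value)
  }
  list(logistic = logistic, linear = linear, joint = do.call(rbind, joint),
       interaction = inter)
}

#' Case-control descriptive summary table
#'
#' Renders the standard first table of a case-control report: mean (SD) per
#' stratum with a two-sample Student t-test for numeric variables, count
#' (percent) per level with a chi-square test for categorical variables.
#'
#' @param data subject-level data frame with a `status` column.
#' @param variables columns to summarise (default: all except `id`/`status`).
#' @param log10_p also format p-values in `10^-x` style.
#' @return data frame: `variable`, `level`, `case`, `control`, `p_value`
#'   (and `p_log10` when requested).
#' @export
render_table1 <- function(data, variables = NULL, log10_p = FALSE) {
  if (!all(c("case", "control") %in% data$status) ||
      min(table(data$status)) < 2) {
    stop_invalid("both strata must contain at least two subjects")
  }
  if (is.null(variables)) variables <- setdiff(names(data), c("id", "status"))
  cases <- data$status == "case"
  rows <- list()
  for (v in variables) {
    x <- data[[v]]
    if (is.numeric(x)) {
      p <- tryCatch(
        stats::t.test(x[cases], x[!cases], var.equal = TRUE)$p.value,
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = "",
        case = sprintf("%.2f ± %.2f", mean(x[cases], na.rm = TRUE),
                       stats::sd(x[cases], na.rm = TRUE)),
        control = sprintf("%.2f ± %.2f", mean(x[!cases], na.rm = TRUE),
                          stats::sd(x[!cases], na.rm = TRUE)),
        p_value = p, stringsAsFactors = FALSE)
    } else {
      x <- factor(x)
      tab <- table(x, factor(ifelse(cases, "case", "control"),
                             levels = c("case", "control")))
      p <- tryCatch(suppressWarnings(stats::chisq.test(tab)$p.value),
                    error = function(e) NA_real_)
      pct <- prop.table(tab, 2) * 100
      for (lv in rownames(tab)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variable = v, level = lv,
          case = sprintf("%d (%.1f%%)", tab[lv, "case"], pct[lv, "case"]),
          control = sprintf("%d (%.1f%%)", tab[lv, "control"], pct[lv, "control"]),
          p_value = c(p, NA_real_)[1 + (lv != rownames(tab)[1])],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (log10_p) out$p_log10 <- format_p_log10(out$p_value)
  out
}

#' Two-sample Student t-test from summary statistics
#'
#' Pooled-variance two-sample t-test computed from the group means, standard
#' deviations and sizes alone, for checking published summary tables against
#' their printed p-values without individual-level data.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 per-group summary statistics.
#' @return list with `statistic`, `df` and `p.value`.
#' @export
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  stat <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(statistic = stat, df = df,
       p.value = 2 * stats::pt(-abs(stat), df))
}

#' Format p-values in 10^-x style
#'
#' @param p numeric p-values.
#' @param digits decimals of the exponent.
#' @return character vector like `"10^-4.3"` (`"1"` for p = 1, `NA` preserved).
#' @export
format_p_log10 <- function(p, digits = 1) {
  ifelse(is.na(p), NA_character_,
         ifelse(p >= 1, "1", sprintf("10^%.*f", digits, log10(p))))
}

#' Run the full simulate-score-GRS-associate pipeline
#'
#' Executes every stage in order on either a simulated cohort or real input
#' files, writes each intermediate artifact as CSV into `out_dir`, and emits a
#' JSON manifest recording the seed, per-stage row counts, timings and MD5
#' checksums of every written file.
#'
#' @param config either a [simulation_config()] (simulated run), or a list
#'   with elements `phenotypes`, `genotypes`, `annotation` giving input file
#'   paths (real-data run), or a path to a JSON file encoding either form.
#'   Exactly one input mode must be provided.
#' @param out_dir output directory.
#' @param adjustments adjustment sets passed to [run_associations()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir,
                         adjustments = c("a", "b", "c", "d", "e")) {
  if (is.character(config) && length(config) == 1L) {
    raw <- jsonlite::read_json(config, simplifyVector = TRUE)
    config <- if (!is.null(raw$simulation)) {
      do.call(simulation_config, raw$simulation)
    } else raw
  }
  timings <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(force(expr), error = function(e) {
      manifest <- list(failed_stage = name, error = conditionMessage(e),
                       timings = timings)
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    value
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  is_sim <- inherits(config, "simulation_config")
  if (!is_sim) {
    if (!all(c("phenotypes", "genotypes", "annotation") %in% names(config)) ||
        !is.null(config$simulation)) {
      stop_invalid("config must be either a simulation_config or a list of ",
                   "input paths (phenotypes, genotypes, annotation), not both")
    }
  }
  seed <- if (is_sim) config$seed else config$seed %||% NA

  inputs <- tick("input", {
    if (is_sim) {
      cohort <- simulate_cohort(config)
      write_cohort(cohort, out_dir)
      list(subjects = cohort$subjects, genotypes = cohort$genotypes,
           annotation = cohort$annotation)
    } else {
      raw <- read_genotype_raw(config$genotypes)
      list(subjects = utils::read.csv(config$phenotypes,
                                      stringsAsFactors = FALSE),
           genotypes = raw$genotypes,
           annotation = utils::read.csv(config$annotation,
                                        stringsAsFactors = FALSE))
    }
  })

  scored <- tick("score", {
    s <- compute_scores(inputs$subjects)
    subj <- inputs$subjects
    subj <- subj[, setdiff(names(subj), setdiff(names(s), "id")), drop = FALSE]
    merge(subj, s[, setdiff(names(s), "tmmc")], by = "id", sort = FALSE)
  })

  grs <- tick("grs", {
    g <- inputs$genotypes[match(scored$id, rownames(inputs$genotypes)), ,
                          drop = FALSE]
    build_grs(scored, g, inputs$annotation)
  })
  dataset <- merge(scored, grs$scores, by = "id", sort = FALSE)

  assoc <- tick("associate", run_associations(dataset, adjustments))
  table1 <- tick("report", render_table1(
    dataset, variables = intersect(
      c("attained_age", "age_menarche", "age_menopause", "tnmc", "grs1",
        "grs2", "wgrs1", "wgrs2", "bmi_category", "bmi_change_category",
        "menopause_type", "education", "estrogen_use", "oc_ever",
        "family_history", "race"), names(dataset))))

  files <- c(scores = "scores.csv", qc_report = "qc_report.csv",
             logistic = "results_logistic.csv", linear = "results_linear.csv",
             joint = "results_joint.csv", interaction = "results_interaction.csv",
             table1 = "table1.csv")
  utils::write.csv(dataset, file.path(out_dir, files["scores"]), row.names = FALSE)
  utils::write.csv(grs$qc_report, file.path(out_dir, files["qc_report"]),
                   row.names = FALSE)
  utils::write.csv(assoc$logistic, file.path(out_dir, files["logistic"]),
                   row.names = FALSE)
  utils::write.csv(assoc$linear, file.path(out_dir, files["linear"]),
                   row.names = FALSE)
  utils::write.csv(assoc$joint, file.path(out_dir, files["joint"]),
                   row.names = FALSE)
  utils::write.csv(assoc$interaction, file.path(out_dir, files["interaction"]),
                   row.names = FALSE)
  utils::write.csv(table1, file.path(out_dir, files["table1"]), row.names = FALSE)

  written <- list.files(out_dir, full.names = TRUE)
  written <- written[!grepl("manifest\\.json$", written)]
  manifest <- list(
    seed = seed,
    mode = if (is_sim) "simulated" else "files",
    n_subjects = nrow(dataset),
    n_cases = sum(dataset$status == "case"),
    n_controls = sum(dataset$status == "control"),
    n_snps_input = ncol(inputs$genotypes),
    n_snps_scored = nrow(grs$annotation),
    timings_sec = timings,
    checksums = as.list(stats::setNames(tools::md5sum(written),
                                        basename(written))),
    r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
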