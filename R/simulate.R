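# Synthetic case-control cohort generator.
#
# The generator emulates a population-based case-control study of a
# hormone-related cancer: independent trait-associated SNPs shift age at
# menarche (earlier) and age at natural menopause (later), reproductive
# histories determine the lifetime menstrual-cycle composite, obesity
# trajectories supply BMI at 20 and 5 years before interview, and a logistic
# disease model drives case status, with controls frequency matched to cases
# on age group.

#' Configuration for the synthetic cohort generator
#'
#' Every distributional choice of the generator in one validated object.
#' Defaults emulate a ~482-case / ~571-control study with 26
#' menarche-associated and 22 menopause-associated SNPs; see the package
#' vignette for the rationale behind each default.
#'
#' @param n_cases,n_controls sampled study sizes.
#' @param n_menarche_snps,n_menopause_snps SNP panel sizes.
#' @param allele_freq_range range of the risk-allele frequency, drawn
#'   uniformly per SNP (must lie within (0.01, 0.99)).
#' @param menarche_baseline_mean,menarche_baseline_sd baseline age at
#'   menarche (years) before genetic shifts.
#' @param menopause_baseline_mean,menopause_baseline_sd baseline age at
#'   natural menopause (years).
#' @param per_allele_effect_menarche mean per-risk-allele shift of menarche
#'   age in years (negative = earlier).
#' @param per_allele_effect_menopause mean per-risk-allele shift of natural
#'   menopause age in years (positive = later).
#' @param effect_jitter per-SNP effect magnitudes are scaled by
#'   `U(1 - effect_jitter, 1 + effect_jitter)`; 0 gives identical effects.
#' @param parity_mean Poisson mean number of live births.
#' @param pregnancy_loss_months_mean Poisson mean months of non-live-birth
#'   pregnancy added to `9 x live births`.
#' @param breastfeeding_months_per_birth_mean mean breastfeeding months per
#'   live birth (exponential per birth).
#' @param oc_ever_prob probability of ever using oral contraceptives.
#' @param oc_months_mean mean months of OC use among ever-users.
#' @param cycle_length_mean,cycle_length_sd average menstrual cycle length in
#'   days (normal, clamped to 21-35).
#' @param bmi20_mean,bmi20_sd BMI at age 20, kg/m^2.
#' @param bmi_growth_mean_pct,bmi_growth_sd_pct percent BMI growth from age 20
#'   to 5 years before interview (gamma; positive drift).
#' @param induced_fraction fraction of postmenopausal subjects with induced
#'   menopause.
#' @param disease_intercept log-odds intercept of the disease model.
#' @param beta_tnmc_per100 log-odds per 100 lifetime menstrual cycles.
#' @param beta_bmi log-odds per kg/m^2 of BMI 5 years before interview.
#' @param missing_genotype_rate independent genotype-failure probability.
#' @param age_group_edges age-group boundaries used for frequency matching
#'   (strictly increasing; half-open groups `[e1, e2), ...`).
#' @param n_pool size of the source population the study is sampled from.
#' @param seed master seed; each generation stage draws from its own derived
#'   stream so adding a stage never perturbs earlier draws.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cases = 482, n_controls = 571,
                              n_menarche_snps = 26, n_menopause_snps = 22,
                              allele_freq_range = c(0.25, 0.81),
                              menarche_baseline_mean = 12.6,
                              menarche_baseline_sd = 1.5,
                              menopause_baseline_mean = 50.8,
                              menopause_baseline_sd = 3.9,
                              per_allele_effect_menarche = -0.08,
                              per_allele_effect_menopause = 0.25,
                              effect_jitter = 0.5,
                              parity_mean = 2.5,
                              pregnancy_loss_months_mean = 2,
                              breastfeeding_months_per_birth_mean = 2.5,
                              oc_ever_prob = 0.65,
                              oc_months_mean = 60,
                              cycle_length_mean = 28, cycle_length_sd = 2,
                              bmi20_mean = 21.5, bmi20_sd = 2.5,
                              bmi_growth_mean_pct = 24,
                              bmi_growth_sd_pct = 17,
                              induced_fraction = 0.09,
                              disease_intercept = -7.3,
                              beta_tnmc_per100 = log(1.29),
                              beta_bmi = 0.15,
                              missing_genotype_rate = 0.002,
                              age_group_edges = c(35, 52, 60, 65, 70, 75, 80),
                              n_pool = 8000,
                              seed = 1) {
  cfg <- as.list(environment())
  check_count(n_cases, "n_cases"); check_count(n_controls, "n_controls")
  check_count(n_menarche_snps, "n_menarche_snps")
  check_count(n_menopause_snps, "n_menopause_snps")
  check_count(n_pool, "n_pool")
  if (length(allele_freq_range) != 2 || any(allele_freq_range <= 0.01) ||
      any(allele_freq_range >= 0.99) || diff(allele_freq_range) < 0) {
    stop_invalid("allele_freq_range must be an increasing pair within (0.01, 0.99)")
  }
  check_prob(oc_ever_prob, "oc_ever_prob")
  check_prob(induced_fraction, "induced_fraction")
  check_prob(missing_genotype_rate, "missing_genotype_rate")
  check_prob(effect_jitter, "effect_jitter")
  if (any(diff(age_group_edges) <= 0)) {
    stop_invalid("age_group_edges must be strictly increasing")
  }
  if (any(c(menarche_baseline_sd, menopause_baseline_sd, cycle_length_sd,
            bmi20_sd) < 0)) {
    stop_invalid("standard deviations must be non-negative")
  }
  structure(cfg, class = "simulation_config")
}

#' Generate an independent-SNP genotype panel with its annotation
#'
#' Per SNP, a risk-allele frequency is drawn uniformly from
#' `allele_freq_range` and an effect magnitude from the configured per-allele
#' effect scaled by the jitter factor. The annotated effect allele is the risk
#' allele for a random half of the SNPs and the opposite allele for the rest,
#' so downstream risk-allele orientation is genuinely exercised. Genotypes are
#' drawn binomially (2, effect-allele frequency), independently across SNPs
#' (no linkage disequilibrium). The annotation carries the simulated
#' per-allele effect as the published beta, with its sign as the published
#' direction.
#'
#' @param config a [simulation_config()].
#' @param n_subjects number of subjects (rows).
#' @return list with `genotypes` (n x (n_menarche + n_menopause) integer
#'   matrix in effect-allele coding) and `annotation` (data frame `snp`,
#'   `trait`, `effect_allele`, `other_allele`, `beta`, `direction`, `locus`,
#'   `is_proxy`, `risk_freq`).
#' @export
generate_genotypes <- function(config, n_subjects) {
  check_count(n_subjects, "n_subjects")
  n_snps <- config$n_menarche_snps + config$n_menopause_snps
  trait <- rep(c("menarche", "menopause"),
               c(config$n_menarche_snps, config$n_menopause_snps))
  with_stage_seed(config$seed, "genotypes", {
    risk_freq <- stats::runif(n_snps, config$allele_freq_range[1],
                              config$allele_freq_range[2])
    base_effect <- ifelse(trait == "menarche",
                          config$per_allele_effect_menarche,
                          config$per_allele_effect_menopause)
    magnitude <- abs(base_effect) *
      stats::runif(n_snps, 1 - config$effect_jitter, 1 + config$effect_jitter)
    # risk-allele-coded true effect: negative for menarche, positive for menopause
    risk_effect <- ifelse(trait == "menarche", -magnitude, magnitude)
    effect_is_risk <- stats::runif(n_snps) < 0.5
    eff_freq <- ifelse(effect_is_risk, risk_freq, 1 - risk_freq)
    beta <- ifelse(effect_is_risk, risk_effect, -risk_effect)
    alleles <- t(vapply(seq_len(n_snps),
                        function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    snp <- ifelse(trait == "menarche",
                  sprintf("rs1%05d", seq_len(n_snps)),
                  sprintf("rs2%05d", seq_len(n_snps)))
    g <- vapply(seq_len(n_snps),
                function(j) stats::rbinom(n_subjects, 2, eff_freq[j]),
                integer(n_subjects))
    dim(g) <- c(n_subjects, n_snps)
    dimnames(g) <- list(sprintf("S%05d", seq_len(n_subjects)), snp)
    list(genotypes = g,
         annotation = data.frame(
           snp = snp, trait = trait,
           effect_allele = alleles[, 1], other_allele = alleles[, 2],
           beta = beta, direction = sign(beta), locus = snp,
           is_proxy = FALSE, risk_freq = risk_freq,
           stringsAsFactors = FALSE))
  })
}

#' Generate reproductive phenotypes from genotypes
#'
#' Ages at menarche and natural menopause are linear in the genotype: baseline
#' mean plus the sum over trait SNPs of the annotated beta times the
#' (mean-centred) effect-allele count, plus Gaussian noise; centring keeps the
#' configured baselines as the population means. Parity, pregnancy months
#' (9 per live birth plus losses), breastfeeding, oral-contraceptive use,
#' cycle length, attained age and the BMI trajectory are drawn from the
#' configured distributions; menopause type is `pre` when the attained age is
#' below the generated natural menopause age, otherwise `natural`, with a
#' configured fraction of postmenopausal subjects reassigned to `induced`
#' (their recorded menopause age is drawn 2-15 years before the natural one,
#' which is censored).
#'
#' @param genotypes matrix from [generate_genotypes()].
#' @param annotation its SNP annotation.
#' @param config a [simulation_config()].
#' @return list with `subjects` (phenotype data frame, no `status` yet) and
#'   `truth` (per-subject latent record: genetic liabilities in years,
#'   `natural_menopause_age`; disease probability and TNMC filled in by
#'   [assign_disease_and_sample()]).
#' @export
generate_phenotypes <- function(genotypes, annotation, config) {
  n <- nrow(genotypes)
  if (!all(annotation$snp %in% colnames(genotypes))) {
    stop_invalid("annotation SNPs missing from the genotype matrix")
  }
  liability <- function(trait) {
    ann <- annotation[annotation$trait == trait, , drop = FALSE]
    g <- genotypes[, ann$snp, drop = FALSE]
    centred <- sweep(g, 2, colMeans(g, na.rm = TRUE))
    centred[is.na(centred)] <- 0
    drop(centred %*% ann$beta)
  }
  men_liab <- liability("menarche")
  meno_liab <- liability("menopause")
  with_stage_seed(config$seed, "phenotypes", {
    age_menarche <- config$menarche_baseline_mean + men_liab +
      stats::rnorm(n, 0, config$menarche_baseline_sd)
    age_menarche <- pmax(age_menarche, 8)
    natural_meno <- config$menopause_baseline_mean + meno_liab +
      stats::rnorm(n, 0, config$menopause_baseline_sd)
    natural_meno <- pmax(natural_meno, age_menarche + 10)
    edges <- config$age_group_edges
    attained_age <- stats::runif(n, edges[1], edges[length(edges)])
    live_births <- stats::rpois(n, config$parity_mean)
    pregnancy_months <- 9 * live_births +
      stats::rpois(n, config$pregnancy_loss_months_mean)
    breastfeeding <- ifelse(
      live_births > 0,
      stats::rgamma(n, shape = pmax(live_births, 1e-9),
                    scale = config$breastfeeding_months_per_birth_mean), 0)
    oc_ever <- stats::runif(n) < config$oc_ever_prob
    oc_months <- ifelse(
      oc_ever, stats::rgamma(n, shape = 2, scale = config$oc_months_mean / 2), 0)
    cycle_length <- pmin(pmax(
      stats::rnorm(n, config$cycle_length_mean, config$cycle_length_sd), 21), 35)
    bmi20 <- pmax(stats::rnorm(n, config$bmi20_mean, config$bmi20_sd), 15)
    gm <- config$bmi_growth_mean_pct; gs <- config$bmi_growth_sd_pct
    growth_pct <- stats::rgamma(n, shape = (gm / gs)^2, scale = gs^2 / gm)
    bmi5y <- bmi20 * (1 + growth_pct / 100)

    pre <- attained_age < natural_meno
    induced <- !pre & stats::runif(n) < config$induced_fraction
    menopause_type <- ifelse(pre, "pre", ifelse(induced, "induced", "natural"))
    age_menopause <- ifelse(pre, NA_real_, natural_meno)
    age_menopause[induced] <- pmax(
      natural_meno[induced] - stats::runif(sum(induced), 2, 15),
      age_menarche[induced] + 10)

    race <- ifelse(stats::runif(n) < 0.99, "white", "nonwhite")
    education <- sample(c("<12y", "12y-3y college", "college", "graduate"),
                        n, replace = TRUE, prob = c(0.26, 0.21, 0.25, 0.28))
    estrogen_use <- ifelse(stats::runif(n) < 0.37, "yes", "no")
    family_history <- ifelse(stats::runif(n) < 0.64, "yes", "no")

    subjects <- data.frame(
      id = rownames(genotypes), attained_age = attained_age,
      age_menarche = age_menarche, age_menopause = age_menopause,
      menopause_type = menopause_type,
      pregnancy_months_total = pregnancy_months, live_births = live_births,
      breastfeeding_months_total = breastfeeding,
      oc_months_total = oc_months, oc_ever = ifelse(oc_ever, "ever", "never"),
      cycle_length = cycle_length, bmi20 = bmi20, bmi5y = bmi5y,
      race = race, education = education, estrogen_use = estrogen_use,
      family_history = family_history, stringsAsFactors = FALSE)
    truth <- data.frame(
      id = subjects$id, menarche_liability = men_liab,
      menopause_liability = meno_liab, natural_menopause_age = natural_meno,
      disease_prob = NA_real_, true_tnmc = NA_real_, stringsAsFactors = FALSE)
    list(subjects = subjects, truth = truth)
  })
}

#' Assign disease status and draw a frequency-matched case-control sample
#'
#' Disease indicators are drawn Bernoulli from
#' `logit^-1(intercept + beta_tnmc_per100 * TNMC/100 + beta_bmi * BMI5y)`.
#' Cases are sampled at random from the diseased pool; controls are sampled
#' from the non-diseased pool stratum by stratum so the control age-group
#' distribution matches the sampled cases' (largest-remainder rounding of the
#' case proportions to `n_controls`).
#'
#' @param subjects phenotype table from [generate_phenotypes()].
#' @param truth its latent-truth table.
#' @param config a [simulation_config()].
#' @return list of class `study_dataset`: `subjects` (sampled rows with
#'   `status` and `tnmc` columns), `truth` (matching rows with `disease_prob`
#'   and `true_tnmc` filled), `age_group_counts` (achieved cases/controls per
#'   stratum).
#' @export
assign_disease_and_sample <- function(subjects, truth, config) {
  if (nrow(subjects) != nrow(truth)) stop_invalid("subjects and truth must align")
  tn <- tnmc(subjects)
  p <- stats::plogis(config$disease_intercept +
                     config$beta_tnmc_per100 * tn / 100 +
                     config$beta_bmi * subjects$bmi5y)
  truth$disease_prob <- p
  truth$true_tnmc <- tn
  edges <- config$age_group_edges
  group <- cut(subjects$attained_age, breaks = edges, right = FALSE,
               include.lowest = TRUE)
  with_stage_seed(config$seed, "disease", {
    diseased <- stats::runif(nrow(subjects)) < p
    sampling_exhausted <- function(stratum, need, have) {
      stop(errorCondition(
        sprintf("sampling exhausted in stratum '%s': need %d, have %d",
                stratum, need, have),
        class = c("cyclegrs_sampling_exhausted", "error")))
    }
    case_pool <- which(diseased)
    if (length(case_pool) < config$n_cases) {
      sampling_exhausted("cases (all ages)", config$n_cases, length(case_pool))
    }
    case_idx <- sample(case_pool, config$n_cases)
    case_groups <- table(group[case_idx])
    target <- as.numeric(case_groups) / config$n_cases * config$n_controls
    n_target <- floor(target)
    rem <- config$n_controls - sum(n_target)
    if (rem > 0) {
      order_rem <- order(target - n_target, decreasing = TRUE)
      n_target[order_rem[seq_len(rem)]] <- n_target[order_rem[seq_len(rem)]] + 1L
    }
    control_idx <- integer(0)
    for (k in seq_along(levels(group))) {
      pool <- which(!diseased & group == levels(group)[k])
      if (length(pool) < n_target[k]) {
        sampling_exhausted(levels(group)[k], n_target[k], length(pool))
      }
      control_idx <- c(control_idx, sample(pool, n_target[k]))
    }
    idx <- c(case_idx, control_idx)
    out <- subjects[idx, , drop = FALSE]
    out$status <- rep(c("case", "control"),
                      c(length(case_idx), length(control_idx)))
    out$tnmc <- tn[idx]
    rownames(out) <- NULL
    counts <- data.frame(
      age_group = levels(group),
      n_cases = as.integer(case_groups),
      n_controls = n_target, stringsAsFactors = FALSE)
    structure(list(subjects = out, truth = truth[idx, , drop = FALSE],
                   age_group_counts = counts),
              class = "study_dataset")
  })
}

#' Inject independent genotype missingness
#'
#' Sets each genotype entry to missing independently with the given rate,
#' leaving observed values unchanged. Deterministic for a fixed seed.
#'
#' @param genotypes genotype matrix.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed master seed (the missingness stream is derived from it).
#' @return the matrix with injected `NA`s.
#' @export
inject_missing_genotypes <- function(genotypes, rate, seed) {
  if (!is.numeric(rate) || rate < 0 || rate >= 1) {
    stop_invalid("rate must lie in [0, 1)")
  }
  if (rate == 0) return(genotypes)
  with_stage_seed(seed, "missing", {
    mask <- stats::runif(length(genotypes)) < rate
    genotypes[mask] <- NA
    genotypes
  })
}

#' Simulate a complete case-control study
#'
#' End-to-end generation: genotype panel and annotation for a source
#' population of `n_pool` subjects, phenotypes, disease assignment with
#' age-group frequency-matched sampling, then genotype missingness injection
#' on the sampled study. Fully deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list of class `cyclegrs_cohort` with `subjects`, `genotypes`
#'   (sampled subjects x SNPs, effect-allele coded, with missingness),
#'   `annotation`, `truth`, `age_group_counts`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  gen <- generate_genotypes(config, config$n_pool)
  phen <- generate_phenotypes(gen$genotypes, gen$annotation, config)
  study <- assign_disease_and_sample(phen$subjects, phen$truth, config)
  g <- gen$genotypes[study$subjects$id, , drop = FALSE]
  g <- inject_missing_genotypes(g, config$missing_genotype_rate, config$seed)
  structure(list(subjects = study$subjects, genotypes = g,
                 annotation = gen$annotation, truth = study$truth,
                 age_group_counts = study$age_group_counts, config = config),
            class = "cyclegrs_cohort")
}

#' Write a simulated cohort to plain-text files
#'
#' Emits `phenotypes.csv`, `genotypes.raw.csv` (PLINK .raw-style, see
#' [write_genotype_raw()]), `annotation.csv` and `truth.csv` into a directory.
#'
#' @param cohort a `cyclegrs_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("phenotypes.csv", "genotypes.raw.csv",
                            "annotation.csv", "truth.csv"))
  write_phenotypes(cohort$subjects, paths[1])
  write_genotype_raw(cohort$genotypes, cohort$annotation$effect_allele, paths[2])
  utils::write.csv(cohort$annotation, paths[3], row.names = FALSE)
  utils::write.csv(cohort$truth, paths[4], row.names = FALSE)
  invisible(paths)
}
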