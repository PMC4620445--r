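test_that("simulation_config validates its invariants", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_cases = 0), class = "cyclegrs_invalid_argument")
  expect_error(simulation_config(allele_freq_range = c(0.5, 0.005)),
               class = "cyclegrs_invalid_argument")
  expect_error(simulation_config(allele_freq_range = c(0.8, 0.5)),
               class = "cyclegrs_invalid_argument")
  expect_error(simulation_config(missing_genotype_rate = 1.5),
               class = "cyclegrs_invalid_argument")
  expect_error(simulation_config(age_group_edges = c(35, 52, 52, 60)),
               class = "cyclegrs_invalid_argument")
})

test_that("generated genotypes match their binomial moments", {
  cfg <- simulation_config(n_menarche_snps = 1, n_menopause_snps = 1,
                           allele_freq_range = c(0.5, 0.5), seed = 3)
  g <- generate_genotypes(cfg, 1e4)$genotypes
  # mean 2p = 1.0 within 3 SE, SE = sqrt(2p(1-p)/n)
  se <- sqrt(0.5 / 1e4)
  expect_lt(abs(mean(g[, 1]) - 1), 3 * se)
  expect_true(all(g %in% 0:2))

  cfg3 <- simulation_config(allele_freq_range = c(0.3, 0.3), seed = 4,
                            n_menarche_snps = 1, n_menopause_snps = 1)
  g3 <- generate_genotypes(cfg3, 1e5)$genotypes
  # var(s^2) = (mu4 - sigma^4)/n for binomial(2, .3): mu4 = 0.42, sigma^2 = 0.42
  se_var <- sqrt((0.42 - 0.42^2) / 1e5)
  expect_lt(abs(var(g3[, 1]) - 0.42), 3 * se_var)

  full <- generate_genotypes(simulation_config(seed = 5), 200)
  expect_equal(dim(full$genotypes), c(200, 48))
  expect_equal(table(full$annotation$trait)[["menarche"]], 26)
  expect_equal(table(full$annotation$trait)[["menopause"]], 22)
  expect_error(generate_genotypes(simulation_config(), 0),
               class = "cyclegrs_invalid_argument")
})

test_that("generated allele frequencies track the configured range", {
  cfg <- simulation_config(allele_freq_range = c(0.25, 0.81), seed = 6)
  gen <- generate_genotypes(cfg, 2e4)
  # per-SNP observed effect-allele frequency vs its drawn risk frequency:
  # equal when the effect allele is the risk allele, mirrored otherwise
  obs <- colMeans(gen$genotypes) / 2
  effect_is_risk <- (gen$annotation$trait == "menarche") ==
    (gen$annotation$beta < 0)
  risk_obs <- ifelse(effect_is_risk, obs, 1 - obs)
  se <- sqrt(gen$annotation$risk_freq * (1 - gen$annotation$risk_freq) / (2 * 2e4))
  expect_true(all(abs(risk_obs - gen$annotation$risk_freq) < 4 * se))
})

test_that("per-allele genetic effects propagate linearly into menarche age", {
  cfg <- simulation_config(per_allele_effect_menarche = -0.1,
                           effect_jitter = 0, seed = 8)
  gen <- generate_genotypes(cfg, 1e4)
  ph <- generate_phenotypes(gen$genotypes, gen$annotation, cfg)
  o <- orient_genotypes(gen$genotypes,
                        gen$annotation[gen$annotation$trait == "menarche", ])
  count <- rowSums(o$genotypes[, o$annotation$snp])
  fit <- summary(lm(ph$subjects$age_menarche ~ count))$coefficients
  # slope -0.1/allele, so 0 vs 20 risk alleles differ by 2.0 years
  expect_lt(abs(20 * fit["count", 1] - (-2.0)), 3 * 20 * fit["count", 2])
})

test_that("zero effects and zero noise collapse ages to the baseline", {
  cfg <- simulation_config(per_allele_effect_menarche = 0,
                           per_allele_effect_menopause = 0,
                           menarche_baseline_sd = 0, menopause_baseline_sd = 0,
                           seed = 9)
  gen <- generate_genotypes(cfg, 500)
  ph <- generate_phenotypes(gen$genotypes, gen$annotation, cfg)
  expect_true(all(ph$subjects$age_menarche == cfg$menarche_baseline_mean))
  expect_true(all(ph$truth$natural_menopause_age == cfg$menopause_baseline_mean))
})

test_that("a null disease model equalises case and control TNMC", {
  cfg <- simulation_config(beta_tnmc_per100 = 0, beta_bmi = 0,
                           disease_intercept = -1, n_pool = 4000,
                           n_cases = 400, n_controls = 400, seed = 10)
  co <- suppressWarnings(simulate_cohort(cfg))
  tn <- co$subjects$tnmc
  st <- co$subjects$status
  se <- sqrt(var(tn[st == "case"]) / 400 + var(tn[st == "control"]) / 400)
  expect_lt(abs(mean(tn[st == "case"]) - mean(tn[st == "control"])), 3 * se)
})

test_that("an impossible disease model exhausts case sampling", {
  cfg <- simulation_config(disease_intercept = -20, beta_tnmc_per100 = 0,
                           beta_bmi = 0, n_pool = 2000, seed = 11)
  expect_error(suppressWarnings(simulate_cohort(cfg)),
               class = "cyclegrs_sampling_exhausted")
  err <- tryCatch(suppressWarnings(simulate_cohort(cfg)), error = identity)
  expect_match(conditionMessage(err), "stratum")
})

test_that("controls are frequency matched to cases within one per stratum", {
  cfg <- simulation_config(n_pool = 6000, n_cases = 300, n_controls = 500,
                           seed = 12)
  co <- suppressWarnings(simulate_cohort(cfg))
  ac <- co$age_group_counts
  expect_equal(sum(ac$n_cases), 300)
  expect_equal(sum(ac$n_controls), 500)
  target <- ac$n_cases / 300 * 500
  expect_true(all(abs(ac$n_controls - target) <= 1))
  # achieved counts agree with the sampled subjects
  grp <- cut(co$subjects$attained_age, cfg$age_group_edges, right = FALSE,
             include.lowest = TRUE)
  expect_equal(as.integer(table(grp[co$subjects$status == "control"])),
               ac$n_controls)
})

test_that("genotype missingness injection is calibrated and deterministic", {
  set.seed(13)
  g <- matrix(rbinom(1e4, 2, 0.5), 100, 100,
              dimnames = list(sprintf("S%03d", 1:100), sprintf("rs%03d", 1:100)))
  expect_identical(inject_missing_genotypes(g, 0, seed = 1), g)
  m1 <- inject_missing_genotypes(g, 0.5, seed = 2)
  m2 <- inject_missing_genotypes(g, 0.5, seed = 2)
  expect_identical(m1, m2)
  frac <- mean(is.na(m1))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1e4))
  obs <- !is.na(m1)
  expect_identical(m1[obs], g[obs])
  expect_error(inject_missing_genotypes(g, 1, seed = 1),
               class = "cyclegrs_invalid_argument")
})

test_that("a fixed master seed reproduces the cohort bit-identically", {
  cfg <- simulation_config(n_pool = 2500, n_cases = 150, n_controls = 200,
                           seed = 14)
  a <- suppressWarnings(simulate_cohort(cfg))
  b <- suppressWarnings(simulate_cohort(cfg))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$truth, b$truth)
})

test_that("null genetic effects leave downstream scores uninformative", {
  # with all per-allele effects zero, the GRS carries no age signal
  covered <- logical(20)
  for (r in 1:20) {
    cfg <- simulation_config(per_allele_effect_menarche = 0, effect_jitter = 0,
                             per_allele_effect_menopause = 0.25,
                             n_pool = 1500, seed = 100 + r)
    gen <- generate_genotypes(cfg, 1500)
    ph <- generate_phenotypes(gen$genotypes, gen$annotation, cfg)
    men <- gen$annotation$trait == "menarche"
    grs <- rowSums(gen$genotypes[, gen$annotation$snp[men]])
    fit <- summary(lm(ph$subjects$age_menarche ~ grs))$coefficients
    ci <- fit["grs", 1] + c(-1.96, 1.96) * fit["grs", 2]
    covered[r] <- ci[1] <= 0 && 0 <= ci[2]
  }
  expect_gte(mean(covered), 0.9)
})
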