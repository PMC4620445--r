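test_that("HWE chi-square matches closed-form cases", {
  # exact Hardy-Weinberg proportions: statistic 0, p 1
  perfect <- hwe_test(25, 50, 25)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p.value, 1)
  # complete heterozygote deficit at p = q = 0.5, n = 100: chi-square 100
  deficit <- hwe_test(50, 0, 50)
  expect_equal(deficit$statistic, 100, tolerance = 1e-12)
  expect_lt(deficit$p.value, 1e-20)
  # monomorphic SNP is flagged and trivially in equilibrium
  mono <- hwe_test(80, 0, 0)
  expect_true(mono$monomorphic)
  expect_equal(mono$p.value, 1)
  expect_error(hwe_test(0, 0, 0), class = "cyclegrs_invalid_argument")
})

test_that("qc_filter removes exactly the rule-violating SNPs with reasons", {
  m <- qc_toy_matrix()
  res <- qc_filter(m, qc_toy_controls())
  expect_equal(colnames(res$genotypes), paste0("good", 1:7))
  rep <- res$report
  expect_equal(rep$reasons[rep$snp == "bad_call"], "call_rate")
  expect_equal(rep$reasons[rep$snp == "bad_maf"], "maf")
  expect_equal(rep$reasons[rep$snp == "bad_hwe"], "hwe")
  expect_true(all(rep$pass[grepl("^good", rep$snp)]))
  expect_equal(rep$call_rate[rep$snp == "bad_call"], 0.85)
  expect_equal(rep$maf[rep$snp == "bad_maf"], 1 / 400)
  expect_error(qc_filter(m[0, , drop = FALSE], logical(0)),
               class = "cyclegrs_invalid_argument")
})

test_that("ld_r2 equals squared genotype correlation with its edge cases", {
  set.seed(5)
  g <- rbinom(500, 2, 0.4)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2L - g), 1)  # perfect negative correlation squares to 1
  h <- rbinom(500, 2, 0.4)
  expect_equal(ld_r2(g, h), cor(g, h)^2, tolerance = 1e-12)
  expect_error(ld_r2(g, rep(1L, 500)), class = "cyclegrs_undefined_ld")
  # independent SNPs have near-zero r2 at large n
  set.seed(6)
  r2 <- replicate(50, ld_r2(rbinom(1e4, 2, 0.3), rbinom(1e4, 2, 0.3)))
  expect_gte(mean(r2 < 0.01), 0.99)
})

test_that("score-SNP selection applies the three criteria with a log", {
  set.seed(17)
  n <- 10000
  ga <- rbinom(n, 2, 0.4)
  gb <- ga                                  # fully linked copy, same locus
  gc_ <- rbinom(n, 2, 0.5); gc_[1:5] <- NA  # failed in exactly 5 subjects
  gd <- rbinom(n, 2, 0.5)                   # true effect opposite to annotation
  ge <- rbinom(n, 2, 0.5)                   # clean SNP
  geno <- cbind(snpA = ga, snpB = gb, snpC = gc_, snpD = gd, snpE = ge)
  rownames(geno) <- sprintf("S%05d", 1:n)
  age <- 12.6 - 0.15 * ga + 0.15 * gd - 0.12 * ge + rnorm(n, 0, 1)
  cand <- data.frame(
    snp = c("snpA", "snpB", "snpC", "snpD", "snpE"),
    trait = "menarche",
    beta = c(-0.15, -0.05, -0.1, -0.1, -0.12),
    locus = c("L1", "L1", "L2", "L3", "L4"),
    stringsAsFactors = FALSE)
  sel <- select_score_snps(cand, geno, age)
  expect_setequal(sel$selected$snp, c("snpA", "snpE"))
  ex <- sel$exclusions
  expect_equal(ex$criterion[ex$snp == "snpB"], "ld")         # pruned, smaller |beta|
  expect_equal(ex$criterion[ex$snp == "snpC"], "failed_genotypes")  # 5 is not < 5
  expect_equal(ex$criterion[ex$snp == "snpD"], "direction")
  expect_error(select_score_snps(cand, geno, age[-1]),
               class = "cyclegrs_invalid_argument")
})

test_that("risk-allele orientation follows the trait-specific definition", {
  ann <- data.frame(
    snp = c("m1", "m2", "p1", "p2"),
    trait = c("menarche", "menarche", "menopause", "menopause"),
    effect_allele = c("A", "C", "G", "T"),
    other_allele = c("G", "T", "A", "C"),
    beta = c(-0.1, 0.1, 0.2, -0.2),
    stringsAsFactors = FALSE)
  o <- orient_risk_alleles(ann)
  # menarche: risk allele lowers the age; menopause: raises it
  expect_equal(o$flipped, c(FALSE, TRUE, FALSE, TRUE))
  expect_equal(o$beta, c(-0.1, -0.1, 0.2, 0.2))
  expect_equal(o$risk_beta, abs(ann$beta))
  expect_equal(o$effect_allele, c("A", "T", "G", "C"))
  # idempotence: orienting the oriented annotation flips nothing
  o2 <- orient_risk_alleles(o[names(ann)])
  expect_false(any(o2$flipped))
  expect_equal(o2$beta, o$beta)
  expect_error(orient_risk_alleles(transform(ann, beta = 0)),
               class = "cyclegrs_orientation_undefined")
})

test_that("orienting genotypes mirrors flipped counts and is idempotent", {
  ann <- data.frame(snp = c("m1", "m2"), trait = "menarche",
                    effect_allele = c("A", "C"), other_allele = c("G", "T"),
                    beta = c(-0.1, 0.1), stringsAsFactors = FALSE)
  g <- cbind(m1 = c(0L, 1L, 2L, NA), m2 = c(0L, 1L, 2L, NA))
  rownames(g) <- paste0("S", 1:4)
  o <- orient_genotypes(g, ann)
  expect_equal(o$genotypes[, "m1"], g[, "m1"])         # already risk-coded
  expect_equal(unname(o$genotypes[, "m2"]), c(2L, 1L, 0L, NA))
  o2 <- orient_genotypes(o$genotypes, o$annotation[names(ann)])
  expect_identical(o2$genotypes, o$genotypes)
})

test_that("stratified mean imputation rounds half-up and only fills gaps", {
  g <- cbind(s1 = c(1L, 1L, 1L, 2L, 2L, NA,   1L, 2L, 1L, 2L, NA, 2L))
  rownames(g) <- sprintf("S%02d", 1:12)
  cases <- rep(c(TRUE, FALSE), each = 6)
  # case stratum observed mean 1.4 -> 1; control stratum mean 1.6 -> 2
  filled <- impute_missing(g, cases)
  expect_equal(filled[6, "s1"], 1L)
  expect_equal(filled[11, "s1"], 2L)
  expect_identical(filled[!is.na(g)], g[!is.na(g)])
  # half-up tie: mean exactly 1.5 rounds to 2
  g2 <- cbind(s1 = c(1L, 2L, NA, 0L, 1L, 2L))
  tie <- impute_missing(g2, rep(c(TRUE, FALSE), each = 3))
  expect_equal(unname(tie[3, "s1"]), 2L)
  # no missing entries: identity
  g3 <- cbind(s1 = c(0L, 1L, 2L, 1L))
  expect_identical(impute_missing(g3, c(TRUE, TRUE, FALSE, FALSE)), g3)
  # a stratum with no observed genotypes cannot be imputed
  g4 <- cbind(s1 = c(NA, NA, 1L, 2L))
  expect_error(impute_missing(g4, c(TRUE, TRUE, FALSE, FALSE)),
               class = "cyclegrs_imputation_impossible")
})

test_that("unweighted and weighted scores are sums and weighted sums", {
  ann <- data.frame(snp = paste0("s", 1:4), trait = "menarche",
                    beta = c(-0.1, -0.2, -0.1, -0.2), stringsAsFactors = FALSE)
  g <- matrix(c(0L, 1L, 2L, 2L), nrow = 1,
              dimnames = list("S1", paste0("s", 1:4)))
  expect_equal(unname(unweighted_grs(g, ann, "menarche")), 5)
  expect_equal(unname(weighted_grs(g, ann, "menarche")),
               0 * 0.1 + 1 * 0.2 + 2 * 0.1 + 2 * 0.2)
  # bounds over 26 SNPs
  ann26 <- data.frame(snp = paste0("s", 1:26), trait = "menarche", beta = -0.1)
  expect_equal(unname(unweighted_grs(
    matrix(0L, 1, 26, dimnames = list("S1", paste0("s", 1:26))), ann26,
    "menarche")), 0)
  expect_equal(unname(unweighted_grs(
    matrix(2L, 1, 26, dimnames = list("S1", paste0("s", 1:26))), ann26,
    "menarche")), 52)
  # equal betas make the weighted score proportional to the count
  expect_equal(weighted_grs(g, transform(ann, beta = -0.3), "menarche"),
               0.3 * unweighted_grs(g, ann, "menarche"))
  # doubling betas doubles scores
  expect_equal(weighted_grs(g, transform(ann, beta = 2 * beta), "menarche"),
               2 * weighted_grs(g, ann, "menarche"))
  gna <- g; gna[1, 2] <- NA
  expect_error(unweighted_grs(gna, ann, "menarche"),
               class = "cyclegrs_incomplete_data")
  expect_error(weighted_grs(gna, ann, "menarche"),
               class = "cyclegrs_incomplete_data")
})

test_that("flipping a complete matrix complements the unweighted score", {
  set.seed(31)
  M <- 8
  ann <- data.frame(snp = paste0("s", 1:M), trait = "menopause",
                    beta = runif(M, 0.05, 0.3), stringsAsFactors = FALSE)
  g <- matrix(rbinom(50 * M, 2, 0.5), 50, M,
              dimnames = list(sprintf("S%02d", 1:50), paste0("s", 1:M)))
  expect_equal(unweighted_grs(2L - g, ann, "menopause"),
               2 * M - unweighted_grs(g, ann, "menopause"))
})

test_that("QC then imputation yields a complete matrix, observed untouched", {
  set.seed(41)
  n <- 300
  g <- sapply(1:12, function(j) rbinom(n, 2, runif(1, 0.2, 0.8)))
  colnames(g) <- paste0("s", 1:12)
  rownames(g) <- sprintf("S%03d", 1:n)
  g <- inject_missing_genotypes(g, 0.05, seed = 99)
  cases <- rep(c(TRUE, FALSE), length.out = n)
  qc <- qc_filter(g, !cases, qc_thresholds(min_call_rate = 0.8))
  filled <- impute_missing(qc$genotypes, cases)
  expect_false(anyNA(filled))
  obs <- !is.na(qc$genotypes)
  expect_identical(filled[obs], qc$genotypes[obs])
})

test_that("PLINK raw-style genotype files round-trip", {
  set.seed(51)
  g <- matrix(rbinom(40, 2, 0.5), 10, 4,
              dimnames = list(sprintf("S%02d", 1:10), paste0("rs", 1:4)))
  g[2, 3] <- NA
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_genotype_raw(g, c("A", "C", "G", "T"), path)
  back <- read_genotype_raw(path)
  expect_identical(back$genotypes, g)
  expect_equal(back$alleles$effect_allele, c("A", "C", "G", "T"))
})
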