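# Genotype QC and genetic risk score construction.
#
# Genotypes travel as a plain integer matrix: rows are subjects (rownames =
# subject ids), columns are SNPs (colnames = SNP ids), entries are 0/1/2
# counts of the annotated effect allele, NA for failed genotypes. The SNP
# annotation is a data frame with columns `snp`, `trait` ("menarche" or
# "menopause"), `effect_allele`, `beta` (published per-allele effect on the
# trait age, in years) and optionally `other_allele` and `locus` (gene/locus
# group used for LD pruning).

#' Quality-control thresholds for SNP filtering
#'
#' Bundles the per-SNP inclusion rules applied before score construction:
#' minimum call rate, minimum minor allele frequency, the Hardy-Weinberg
#' equilibrium alpha applied among controls, the maximum number of subjects
#' with a failed genotype tolerated for a score SNP (strict: a SNP failing in
#' `max_failed_subjects` or more subjects is dropped), and the pairwise LD
#' r-squared ceiling for SNPs in the same locus.
#'
#' @param min_call_rate minimum proportion of non-missing genotypes (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @param hwe_alpha Hardy-Weinberg test significance threshold among controls
#'   (default 1e-4).
#' @param max_failed_subjects score SNPs must have fewer failed genotypes than
#'   this (default 5).
#' @param max_pairwise_r2 LD pruning threshold within a locus (default 0.5).
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.01,
                          hwe_alpha = 1e-4, max_failed_subjects = 5,
                          max_pairwise_r2 = 0.5) {
  check_prob(min_call_rate, "min_call_rate")
  check_prob(min_maf, "min_maf")
  check_prob(hwe_alpha, "hwe_alpha")
  check_count(max_failed_subjects, "max_failed_subjects")
  check_prob(max_pairwise_r2, "max_pairwise_r2")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 hwe_alpha = hwe_alpha,
                 max_failed_subjects = as.integer(max_failed_subjects),
                 max_pairwise_r2 = max_pairwise_r2),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of observed genotype counts against
#' the Hardy-Weinberg expectations p^2, 2pq, q^2 computed from the observed
#' allele frequency. A monomorphic SNP (all alleles identical) is in trivial
#' equilibrium and returns p = 1 with `monomorphic = TRUE`.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (homozygous for one
#'   allele, heterozygous, homozygous for the other).
#' @return list with `statistic` (chi-square), `p.value`, `df` (1) and
#'   `monomorphic` flag.
#' @export
#' @examples
#' hwe_test(25, 50, 25)$p.value   # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)$p.value    # complete heterozygote deficit
hwe_test <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || sum(counts) == 0) {
    stop_invalid("genotype counts must be non-negative with positive total")
  }
  n <- sum(counts)
  p <- (2 * n_hom_ref + n_het) / (2 * n)
  if (p == 0 || p == 1) {
    return(list(statistic = 0, p.value = 1, df = 1L, monomorphic = TRUE))
  }
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((counts - expected)^2 / expected)
  list(statistic = stat,
       p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, monomorphic = FALSE)
}

# HWE p-value for a 0/1/2 genotype vector (NA dropped).
hwe_test_geno <- function(g) {
  g <- g[!is.na(g)]
  if (length(g) == 0) return(NA_real_)
  hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p.value
}

#' Filter SNPs on call rate, minor allele frequency and Hardy-Weinberg
#'
#' Removes SNPs with call rate below `min_call_rate` or minor allele frequency
#' below `min_maf` (both computed over all subjects) or a Hardy-Weinberg
#' chi-square p-value below `hwe_alpha` among the controls. Every SNP's
#' metrics and pass/fail reasons are returned in a QC report.
#'
#' @param genotypes integer matrix of 0/1/2 effect-allele counts
#'   (subjects x SNPs, NA = failed genotype).
#' @param controls logical vector (one per subject) marking controls, on whom
#'   the Hardy-Weinberg test is evaluated.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `genotypes` (the filtered matrix) and `report` (data
#'   frame: `snp`, `call_rate`, `maf`, `hwe_p`, `pass`, `reasons`).
#' @export
qc_filter <- function(genotypes, controls, thresholds = qc_thresholds()) {
  if (!is.matrix(genotypes) || nrow(genotypes) == 0 || ncol(genotypes) == 0) {
    stop_invalid("genotypes must be a non-empty subjects x SNPs matrix")
  }
  controls <- as.logical(controls)
  if (length(controls) != nrow(genotypes) || !any(controls)) {
    stop_invalid("controls mask must align with subjects and mark at least one control")
  }
  call_rate <- colMeans(!is.na(genotypes))
  f <- colMeans(genotypes, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  hwe_p <- apply(genotypes[controls, , drop = FALSE], 2, hwe_test_geno)
  reasons <- vapply(seq_len(ncol(genotypes)), function(j) {
    r <- character(0)
    if (call_rate[j] < thresholds$min_call_rate) r <- c(r, "call_rate")
    if (is.na(maf[j]) || maf[j] < thresholds$min_maf) r <- c(r, "maf")
    if (!is.na(hwe_p[j]) && hwe_p[j] < thresholds$hwe_alpha) r <- c(r, "hwe")
    paste(r, collapse = ",")
  }, character(1))
  report <- data.frame(snp = colnames(genotypes), call_rate = call_rate,
                       maf = maf, hwe_p = hwe_p, pass = reasons == "",
                       reasons = reasons, row.names = NULL,
                       stringsAsFactors = FALSE)
  list(genotypes = genotypes[, report$pass, drop = FALSE], report = report)
}

#' Pairwise linkage disequilibrium as squared genotype correlation
#'
#' Composite-LD surrogate for haplotype r-squared: the squared Pearson
#' correlation of the additive genotype counts at two loci, over
#' pairwise-complete subjects. Used for pruning redundant SNPs within a locus.
#'
#' @param snp_a,snp_b aligned 0/1/2 genotype vectors (NA allowed).
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(snp_a, snp_b) {
  if (length(snp_a) != length(snp_b)) stop_invalid("genotype vectors must align")
  ok <- !is.na(snp_a) & !is.na(snp_b)
  a <- snp_a[ok]; b <- snp_b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0) {
    stop(errorCondition(
      "LD undefined: a SNP is monomorphic after pairwise-complete filtering",
      class = c("cyclegrs_undefined_ld", "error")))
  }
  stats::cor(a, b)^2
}

#' Select SNPs for score construction
#'
#' Applies the three score-SNP inclusion criteria to annotated candidates for
#' one trait: (a) LD pruning within each locus group, greedily keeping the SNP
#' with the larger absolute published beta (ties broken by SNP id) and
#' dropping any SNP with pairwise r-squared at or above `max_pairwise_r2`
#' against a kept SNP; (b) fewer failed genotypes than `max_failed_subjects`
#' (strict); (c) the in-study per-allele linear regression of the trait age on
#' the genotype count, adjusted for attained age and race when supplied, must
#' have the same sign as the published beta.
#'
#' @param candidates SNP annotation data frame (single trait) with columns
#'   `snp`, `trait`, `beta`; optional `locus` (defaults to one locus per SNP).
#' @param genotypes genotype matrix containing the candidate SNPs.
#' @param phenotype_age numeric trait-age vector aligned with subjects (age at
#'   menarche for menarche SNPs, age at natural menopause for menopause SNPs;
#'   NA allowed and dropped casewise).
#' @param adjust optional data frame of covariates (e.g. `attained_age`,
#'   `race`) aligned with subjects, entered into the direction regression.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `selected` (annotation rows kept, in input order) and
#'   `exclusions` (data frame `snp`, `criterion`, `detail`).
#' @export
select_score_snps <- function(candidates, genotypes, phenotype_age,
                              adjust = NULL, thresholds = qc_thresholds()) {
  candidates <- as.data.frame(candidates)
  if (length(unique(candidates$trait)) > 1) {
    stop_invalid("candidates must all be annotated with the same trait")
  }
  if (length(phenotype_age) != nrow(genotypes)) {
    stop_invalid("phenotype_age must align with genotype rows")
  }
  if (!all(candidates$snp %in% colnames(genotypes))) {
    stop_invalid("all candidate SNPs must be present in the genotype matrix")
  }
  if (is.null(candidates$locus)) candidates$locus <- candidates$snp
  excl <- data.frame(snp = character(0), criterion = character(0),
                     detail = character(0), stringsAsFactors = FALSE)
  drop_snp <- function(snp, criterion, detail) {
    excl[nrow(excl) + 1L, ] <<- list(snp, criterion, detail)
  }

  # (b) failed-genotype count: strictly fewer than max_failed_subjects
  n_missing <- colSums(is.na(genotypes[, candidates$snp, drop = FALSE]))
  keep_b <- n_missing < thresholds$max_failed_subjects
  for (j in which(!keep_b)) {
    drop_snp(candidates$snp[j], "failed_genotypes",
             sprintf("%d failed genotypes (limit < %d)",
                     n_missing[j], thresholds$max_failed_subjects))
  }
  cand <- candidates[keep_b, , drop = FALSE]

  # (a) greedy LD pruning within locus groups, larger |beta| wins
  kept <- character(0)
  for (loc in unique(cand$locus)) {
    grp <- cand[cand$locus == loc, , drop = FALSE]
    grp <- grp[order(-abs(grp$beta), grp$snp), , drop = FALSE]
    retained <- character(0)
    for (i in seq_len(nrow(grp))) {
      s <- grp$snp[i]
      r2 <- vapply(retained, function(k) {
        tryCatch(ld_r2(genotypes[, s], genotypes[, k]),
                 cyclegrs_undefined_ld = function(e) NA_real_)
      }, numeric(1))
      if (any(!is.na(r2) & r2 >= thresholds$max_pairwise_r2)) {
        hit <- retained[which(!is.na(r2) & r2 >= thresholds$max_pairwise_r2)[1]]
        drop_snp(s, "ld", sprintf("r2 >= %.2f with %s in locus %s",
                                  thresholds$max_pairwise_r2, hit, loc))
      } else {
        retained <- c(retained, s)
      }
    }
    kept <- c(kept, retained)
  }
  cand <- cand[cand$snp %in% kept, , drop = FALSE]

  # (c) in-study direction must match the published direction
  keep_c <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    s <- cand$snp[i]
    df <- data.frame(y = phenotype_age, g = genotypes[, s])
    if (!is.null(adjust)) df <- cbind(df, adjust)
    fit <- stats::lm(y ~ ., data = df)
    slope <- stats::coef(fit)[["g"]]
    keep_c[i] <- !is.na(slope) && sign(slope) == sign(cand$beta[i])
    if (!keep_c[i]) {
      drop_snp(s, "direction",
               sprintf("in-study slope %.4g vs published beta %.4g",
                       slope, cand$beta[i]))
    }
  }
  cand <- cand[keep_c, , drop = FALSE]

  selected <- candidates[candidates$snp %in% cand$snp, , drop = FALSE]
  rownames(selected) <- NULL
  list(selected = selected, exclusions = excl)
}

#' Orient SNP annotations to the risk allele
#'
#' The risk allele is the one associated with younger age at menarche or older
#' age at natural menopause (the direction inferring greater estrogen
#' exposure). For menarche SNPs the risk allele is the allele with a negative
#' age effect; for menopause SNPs, the allele with a positive effect. SNPs
#' whose annotated effect allele is not the risk allele are flagged for count
#' flipping (`x -> 2 - x`), and the stored beta is re-expressed in risk-allele
#' orientation (negative for menarche, positive for menopause), with
#' `risk_beta = |beta|` for use as the weighted-score weight. Orientation is
#' idempotent: orienting an oriented annotation flips nothing further.
#'
#' @param annotation SNP annotation data frame with `snp`, `trait`, `beta`,
#'   `effect_allele` and optionally `other_allele`.
#' @return the annotation with `flipped` (logical), `beta` re-signed,
#'   `risk_beta`, and `effect_allele`/`other_allele` swapped where flipped.
#' @export
orient_risk_alleles <- function(annotation) {
  annotation <- as.data.frame(annotation)
  if (any(annotation$beta == 0)) {
    stop(errorCondition(
      paste("orientation undefined for zero-beta SNP(s):",
            paste(annotation$snp[annotation$beta == 0], collapse = ", ")),
      class = c("cyclegrs_orientation_undefined", "error")))
  }
  flip <- (annotation$trait == "menarche" & annotation$beta > 0) |
          (annotation$trait == "menopause" & annotation$beta < 0)
  out <- annotation
  out$flipped <- flip
  out$risk_beta <- abs(annotation$beta)
  out$beta <- ifelse(annotation$trait == "menarche", -1, 1) * out$risk_beta
  if (!is.null(out$other_allele)) {
    ea <- out$effect_allele
    out$effect_allele[flip] <- out$other_allele[flip]
    out$other_allele[flip] <- ea[flip]
  } else {
    out$effect_allele[flip] <- NA_character_
  }
  out
}

#' Flip genotype counts into risk-allele orientation
#'
#' Applies an [orient_risk_alleles()] map to a genotype matrix: for flipped
#' SNPs each count x becomes 2 - x (NA preserved), so every column counts risk
#' alleles.
#'
#' @param genotypes genotype matrix in effect-allele coding.
#' @param annotation un-oriented SNP annotation covering the matrix columns.
#' @return list with `genotypes` (risk-oriented matrix) and `annotation`
#'   (the oriented annotation).
#' @export
orient_genotypes <- function(genotypes, annotation) {
  oriented <- orient_risk_alleles(annotation)
  idx <- match(oriented$snp, colnames(genotypes))
  if (anyNA(idx)) stop_invalid("annotation SNPs missing from genotype matrix")
  g <- genotypes
  flip_cols <- idx[oriented$flipped]
  g[, flip_cols] <- 2L - g[, flip_cols, drop = FALSE]
  list(genotypes = g, annotation = oriented)
}

#' Impute missing genotypes by stratified rounded means
#'
#' Each missing count is replaced by the mean risk-allele count for that SNP
#' computed separately among cases and among controls, rounded half-up to the
#' nearest whole unit. Observed entries are never altered. With
#' `pooled = TRUE` (for unlabeled data) a single pooled mean is used instead.
#'
#' @param genotypes genotype matrix (risk-oriented; NA = missing).
#' @param cases logical vector marking cases; required unless `pooled = TRUE`.
#' @param pooled use the pooled mean instead of case/control strata.
#' @return the completed integer matrix.
#' @export
impute_missing <- function(genotypes, cases = NULL, pooled = FALSE) {
  if (!anyNA(genotypes)) return(genotypes)
  strata <- if (pooled) list(all = rep(TRUE, nrow(genotypes)))
            else {
              if (is.null(cases)) stop_invalid("cases mask required unless pooled = TRUE")
              cases <- as.logical(cases)
              list(case = cases, control = !cases)
            }
  g <- genotypes
  for (nm in names(strata)) {
    rows <- strata[[nm]]
    sub <- g[rows, , drop = FALSE]
    miss_cols <- which(colSums(is.na(sub)) > 0)
    for (j in miss_cols) {
      obs <- sub[, j]
      if (all(is.na(obs))) {
        stop(errorCondition(
          sprintf("cannot impute SNP '%s': all genotypes missing in stratum '%s'",
                  colnames(g)[j], nm),
          class = c("cyclegrs_imputation_impossible", "error")))
      }
      fill <- round_half_up(mean(obs, na.rm = TRUE))
      sub[is.na(obs), j] <- fill
    }
    g[rows, ] <- sub
  }
  storage.mode(g) <- "integer"
  g
}

#' Unweighted genetic risk score
#'
#' The total number of risk alleles over a trait's selected SNPs, assuming an
#' equal and additive effect of each risk allele: the row sum of the
#' risk-oriented, imputation-completed genotype matrix over that trait's
#' columns. For M SNPs the score lies in `[0, 2M]`.
#'
#' @param genotypes complete, risk-oriented genotype matrix.
#' @param annotation oriented SNP annotation with `trait`.
#' @param trait `"menarche"` or `"menopause"`.
#' @return named numeric vector of per-subject risk-allele counts.
#' @export
unweighted_grs <- function(genotypes, annotation, trait) {
  snps <- annotation$snp[annotation$trait == trait]
  if (length(snps) == 0) stop_invalid("no SNPs annotated for trait '", trait, "'")
  g <- genotypes[, snps, drop = FALSE]
  if (anyNA(g)) {
    stop(errorCondition("genotype matrix contains missing values; impute first",
                        class = c("cyclegrs_incomplete_data", "error")))
  }
  rowSums(g)
}

#' Weighted genetic risk score
#'
#' The sum over a trait's SNPs of risk-allele count times the absolute
#' published per-allele beta, so each allele contributes in proportion to its
#' reported effect on the trait age.
#'
#' @inheritParams unweighted_grs
#' @return named numeric vector of per-subject weighted scores.
#' @export
weighted_grs <- function(genotypes, annotation, trait) {
  ann <- annotation[annotation$trait == trait, , drop = FALSE]
  if (nrow(ann) == 0) stop_invalid("no SNPs annotated for trait '", trait, "'")
  if (is.null(ann$beta) || anyNA(ann$beta)) {
    stop(errorCondition("annotation beta missing for weighted score",
                        class = c("cyclegrs_annotation_error", "error")))
  }
  g <- genotypes[, ann$snp, drop = FALSE]
  if (anyNA(g)) {
    stop(errorCondition("genotype matrix contains missing values; impute first",
                        class = c("cyclegrs_incomplete_data", "error")))
  }
  drop(g %*% abs(ann$beta))
}

#' Read and write additive genotype matrices in PLINK .raw-style text
#'
#' The dialect is one header row, a subject id column `IID`, then one column
#' per SNP named `SNPID_EFFECTALLELE` holding 0/1/2 effect-allele counts with
#' `NA` for failed genotypes. Comma- and whitespace-delimited files are both
#' accepted on read; files are written comma-separated. Standard PLINK
#' `--recode A` output (with FID/PAT/MAT/SEX/PHENOTYPE columns) is also
#' accepted: non-SNP leading columns are recognised by name and dropped.
#'
#' @param path file path.
#' @return `read_genotype_raw()`: list with `genotypes` (integer matrix,
#'   rownames = subject ids) and `alleles` (data frame `snp`,
#'   `effect_allele` parsed from the header).
#' @export
read_genotype_raw <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                         colnames(df))
  if (!"IID" %in% meta_cols) stop_invalid("raw genotype file must have an IID column")
  snp_cols <- setdiff(colnames(df), meta_cols)
  m <- as.matrix(df[, snp_cols, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(!is.na(m) & !(m %in% 0:2))) stop_invalid("genotype counts must be 0, 1 or 2")
  split_at <- regexpr("_[^_]+$", snp_cols)
  rownames(m) <- as.character(df$IID)
  snp <- substr(snp_cols, 1L, split_at - 1L)
  allele <- substr(snp_cols, split_at + 1L, nchar(snp_cols))
  colnames(m) <- snp
  list(genotypes = m,
       alleles = data.frame(snp = snp, effect_allele = allele,
                            stringsAsFactors = FALSE))
}

#' @rdname read_genotype_raw
#' @param genotypes integer genotype matrix (rownames = subject ids).
#' @param effect_alleles character vector of effect alleles, one per column.
#' @export
write_genotype_raw <- function(genotypes, effect_alleles, path) {
  if (length(effect_alleles) != ncol(genotypes)) {
    stop_invalid("one effect allele required per SNP column")
  }
  df <- data.frame(IID = rownames(genotypes), genotypes,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("IID", paste0(colnames(genotypes), "_", effect_alleles))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
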