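# Shared fixtures, all built in code.

# one-row subject record with overridable fields; defaults are the worked
# example: menarche 13, menopause 50, 18 pregnancy months, 2 live births,
# 12 months breastfeeding, 24 OC months, 28-day cycles.
make_subject <- function(...) {
  s <- list(id = "S1", status = "control", attained_age = 62,
            age_menarche = 13, age_menopause = 50, menopause_type = "natural",
            pregnancy_months_total = 18, live_births = 2,
            breastfeeding_months_total = 12, oc_months_total = 24,
            cycle_length = 28, bmi20 = 22, bmi5y = 26, race = "white",
            education = "college", estrogen_use = "no", oc_ever = "ever",
            family_history = "no")
  over <- list(...)
  s[names(over)] <- over
  as.data.frame(s, stringsAsFactors = FALSE)
}

# subject-level expansion of a 2x2 exposure-by-status table
expand_2x2 <- function(exposed_cases, exposed_controls,
                       unexposed_cases, unexposed_controls) {
  data.frame(
    status = rep(c("case", "control", "case", "control"),
                 c(exposed_cases, exposed_controls,
                   unexposed_cases, unexposed_controls)),
    exposed = rep(c(1L, 1L, 0L, 0L),
                  c(exposed_cases, exposed_controls,
                    unexposed_cases, unexposed_controls)),
    stringsAsFactors = FALSE)
}

# deterministic genotype matrix whose SNPs each violate exactly one QC rule
# (or none): 200 subjects, first 100 are controls.
#   bad_call: 30/200 genotypes missing (call rate 0.85)
#   bad_maf:  a single heterozygote (MAF 1/400 = 0.0025)
#   bad_hwe:  controls split 50/0/50 (complete heterozygote deficit)
#   good1..good7: exact Hardy-Weinberg proportions 50/100/50
qc_toy_matrix <- function() {
  n <- 200
  hwe_ok <- rep(c(0L, 1L, 1L, 2L), n / 4)
  m <- sapply(1:7, function(i) hwe_ok)
  colnames(m) <- paste0("good", 1:7)
  bad_call <- hwe_ok
  bad_call[1:30] <- NA
  bad_maf <- c(1L, rep(0L, n - 1))
  bad_hwe <- rep(c(0L, 2L), n / 2)
  out <- cbind(bad_call = bad_call, bad_maf = bad_maf, bad_hwe = bad_hwe, m)
  rownames(out) <- sprintf("S%03d", seq_len(n))
  out
}

# controls mask for qc_toy_matrix()
qc_toy_controls <- function() rep(c(TRUE, FALSE), each = 100)
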