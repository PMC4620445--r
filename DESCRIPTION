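Package: cyclegrs
Title: Lifetime Menstrual-Cycle Composites and Reproductive Genetic Risk
    Scores for Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for joint genotype-phenotype analysis of hormone-related
    cancer risk in case-control studies. Computes the total number of
    menstrual cycles (TNMC) and total months of menstrual cycling (TMMC)
    composites from reproductive history, builds unweighted and weighted
    genetic risk scores for age at menarche and age at natural menopause
    from additively coded SNP genotypes (with call-rate, minor-allele
    frequency and Hardy-Weinberg quality control, linkage-disequilibrium
    pruning, risk-allele orientation and stratified mean imputation), and
    fits the full battery of unconditional logistic and linear association
    models, including control-quantile binning, joint-exposure variables
    and interaction tests. A synthetic cohort generator with a configurable
    disease model and age-group frequency matching makes every stage of the
    pipeline exercisable and testable without access to individual-level
    study data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
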