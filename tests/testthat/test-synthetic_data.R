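test_that("default design matches the published study counts and panel", {
  d <- default_study_design()
  expect_length(d$studies, 8)
  expect_length(d$panel, 9)
  tot <- summarize_cohorts(d$studies)
  expect_identical(unname(tot["total_cases"]), 16399L)
  expect_identical(unname(tot["total_controls"]), 21779L)
  alleles <- vapply(d$panel, `[[`, character(1), "effect_allele")
  names(alleles) <- vapply(d$panel, `[[`, character(1), "rsid")
  expect_identical(alleles[c("rs2910164", "rs2043556", "rs895819", "rs4919510")],
                   c(rs2910164 = "C", rs2043556 = "C", rs895819 = "C",
                     rs4919510 = "G"))
  expect_error(summarize_cohorts(list()), "at least one")
})

test_that("simulation is deterministic in the seed", {
  d <- default_study_design()
  spec <- study_spec("toy", "Toy", 120, 150)
  a <- simulate_cohort(spec, d$panel, seed = 7)
  b <- simulate_cohort(spec, d$panel, seed = 7)
  c2 <- simulate_cohort(spec, d$panel, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$genotypes, c2$genotypes))
  expect_identical(sum(a$phenotype), 120L)
  expect_identical(length(a$phenotype), 270L)
})

test_that("null cohorts at fst = 0 sit in Hardy-Weinberg equilibrium", {
  d <- default_study_design()   # all log_or = 0
  co <- simulate_cohort(study_spec("hwe", "HWE", 1000, 1000), d$panel, seed = 3)
  n <- length(co$phenotype)
  for (k in seq_len(ncol(co$genotypes))) {
    g <- co$genotypes[, k]
    p <- d$panel[[k]]$allele_freq
    exp_counts <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    sds <- sqrt(n * c((1 - p)^2, 2 * p * (1 - p), p^2) *
                  (1 - c((1 - p)^2, 2 * p * (1 - p), p^2)))
    obs <- tabulate(g + 1L, nbins = 3L)
    expect_true(all(abs(obs - exp_counts) < 3.5 * sds),
                label = sprintf("HWE counts for %s", colnames(co$genotypes)[k]))
  }
})

test_that("HWE chi-square is non-significant in >= 94% of null simulations", {
  panel <- one_snp_panel()
  spec <- study_spec("hwe", "HWE", 150, 150)
  ps <- vapply(1:500, function(s) {
    co <- simulate_cohort(spec, panel, seed = 10000 + s)
    oracle_hwe_p(co$genotypes[, 1])
  }, numeric(1))
  expect_gte(mean(ps >= 0.05), 0.94)
})

test_that("case-control allele-frequency gap grows with the effect size", {
  gaps <- vapply(c(0, log(1.3), log(1.8)), function(lo) {
    co <- simulate_cohort(study_spec("eff", "Eff", 2000, 2000),
                          one_snp_panel(log_or = lo), seed = 11)
    mean(co$genotypes[co$phenotype == 1, 1]) / 2 -
      mean(co$genotypes[co$phenotype == 0, 1]) / 2
  }, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("simulated effects are recovered by the downstream fit", {
  panel <- one_snp_panel(log_or = log(1.5))
  ors <- vapply(1:10, function(s) {
    co <- simulate_cohort(study_spec("rec", "Rec", 5000, 5000), panel,
                          seed = 500 + s)
    suppressMessages(fit_additive_logistic(co$genotypes[, 1], co$phenotype))$or_
  }, numeric(1))
  expect_true(all(ors > 1.35 & ors < 1.65))
  expect_lt(abs(mean(log(ors)) - log(1.5)), 0.03)
})

test_that("missingness and the size cap behave as documented", {
  panel <- one_snp_panel()
  co <- simulate_cohort(study_spec("mis", "Mis", 400, 400), panel, seed = 5,
                        missing_rate = 0.1)
  expect_gt(mean(is.na(co$genotypes)), 0.05)
  expect_lt(mean(is.na(co$genotypes)), 0.15)
  expect_error(simulate_cohort(study_spec("big", "Big", 1e6, 1e6), panel,
                               seed = 1, max_n = 1e5),
               "exceeds max_n")
})

test_that("cohort TSV round-trips through write/read", {
  d <- default_study_design()
  co <- simulate_cohort(study_spec("io", "IO", 80, 90), d$panel, seed = 2,
                        missing_rate = 0.05)
  path <- file.path(withr::local_tempdir(), "io.tsv")
  write_cohort_tsv(co, path)
  back <- read_cohort_tsv(path)
  expect_identical(back$genotypes, co$genotypes)
  expect_identical(back$phenotype, co$phenotype)
  expect_identical(back$spec$n_cases, co$spec$n_cases)
})
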