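test_that("ancestry PCs recover hidden population structure", {
  panel <- random_panel(100)
  co <- simulate_cohort(study_spec("str", "Str", 1000, 1000,
                                   substructure_fraction = 0.5, fst = 0.1),
                        panel, seed = 21)
  pcs <- eigenstrat_pcs(co$genotypes, k = 5)
  expect_gt(abs(cor(pcs[, 1], co$subpop)), 0.8)
  # orthonormality of the score columns
  expect_lt(max(abs(crossprod(pcs) - diag(5))), 1e-8)
  # oracle: eigendecomposition of the standardized covariance on the same data
  G <- co$genotypes
  p_hat <- (1 + colSums(G)) / (2 + 2 * nrow(G))
  X <- sweep(sweep(G, 2, colMeans(G), "-"), 2, sqrt(p_hat * (1 - p_hat)), "/")
  ev <- eigen(tcrossprod(X), symmetric = TRUE)$vectors[, 1]
  expect_gt(abs(cor(pcs[, 1], ev)), 1 - 1e-8)
})

test_that("PCA edge cases: k = 0, k > rank, monomorphic columns", {
  G <- matrix(rbinom(300, 2, 0.4), 100, 3)
  expect_identical(ncol(eigenstrat_pcs(G, 0)), 0L)
  expect_error(eigenstrat_pcs(G, 10), "exceeds the rank")
  G2 <- cbind(G, mono = rep(1L, 100))
  expect_warning(p2 <- eigenstrat_pcs(G2, 2), "monomorphic")
  expect_identical(dim(p2), c(100L, 2L))
})

test_that("trend fit matches an independent Newton oracle on the 2x3 table", {
  controls <- c(200, 500, 300)
  cases <- c(300, 500, 200)
  g <- rep(rep(0:2, 2), c(controls, cases))
  y <- rep(c(0, 1), c(sum(controls), sum(cases)))
  fit <- fit_additive_logistic(g, y)
  orc <- oracle_logistic_2x3(controls, cases)
  expect_lt(abs(fit$beta - orc$beta), 1e-6)
  expect_lt(abs(fit$se - orc$se), 1e-6)
  # Wald identities hold bit-for-bit from the stored beta/se
  expect_identical(fit$or_, exp(fit$beta))
  expect_identical(fit$ci_low, exp(fit$beta - qnorm(0.975) * fit$se))
  expect_identical(fit$ci_high, exp(fit$beta + qnorm(0.975) * fit$se))
  expect_identical(fit$p, 2 * pnorm(-abs(fit$beta / fit$se)))
})

test_that("null calibration: |beta| < 3 se almost always", {
  set.seed(31)
  hits <- vapply(1:500, function(i) {
    g <- rbinom(4000, 2, 0.3)
    y <- rbinom(4000, 1, 0.5)
    f <- fit_additive_logistic(g, y)
    abs(f$beta) < 3 * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("95% CI covers the simulated log-OR at nominal rate", {
  set.seed(41)
  b0 <- log(1.3)
  cover <- vapply(1:1000, function(i) {
    g <- rbinom(600, 2, 0.3)
    y <- rbinom(600, 1, plogis(-0.5 + b0 * g))
    f <- fit_additive_logistic(g, y)
    f$ci_low <= exp(b0) && exp(b0) <= f$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)
})

test_that("degenerate covariates are dropped without changing the estimate", {
  set.seed(51)
  g <- rbinom(800, 2, 0.4)
  y <- rbinom(800, 1, plogis(0.2 * g - 0.3))
  base <- fit_additive_logistic(g, y)
  msgs <- capture_messages(
    with_const <- fit_additive_logistic(g, y,
      covariates = list(pcs = matrix(1, 800, 1,
                                     dimnames = list(NULL, "const")))))
  expect_match(paste(msgs, collapse = " "), "constant covariate")
  expect_equal(with_const$beta, base$beta, tolerance = 1e-12)
  # collinear duplicate of an informative covariate is dropped, fit proceeds
  gender <- rbinom(800, 1, 0.5)
  msgs2 <- capture_messages(
    dup <- fit_additive_logistic(g, y,
      covariates = list(pcs = cbind(dup = gender), gender = gender)))
  expect_match(paste(msgs2, collapse = " "), "collinear")
  expect_equal(dup$status, "ok")
})

test_that("fit errors and flags: monomorphic, one class, separation", {
  y <- rbinom(300, 1, 0.5)
  expect_error(fit_additive_logistic(rep(1L, 300), y), "monomorphic")
  expect_error(fit_additive_logistic(rbinom(300, 2, 0.3), rep(1L, 300)),
               "both phenotype classes")
  # complete separation: genotype > 0 iff case
  g <- c(rep(0L, 150), rep(2L, 150))
  ysep <- c(rep(0L, 150), rep(1L, 150))
  f <- fit_additive_logistic(g, ysep)
  expect_identical(f$status, "separation")
})

test_that("missing genotypes are dropped listwise with n_used reported", {
  set.seed(61)
  g <- rbinom(500, 2, 0.3)
  g[1:50] <- NA
  y <- rbinom(500, 1, 0.5)
  f <- fit_additive_logistic(g, y)
  expect_identical(f$n_used, 450L)
  f2 <- fit_additive_logistic(g[51:500], y[51:500])
  expect_equal(f$beta, f2$beta, tolerance = 1e-12)
})

test_that("assoc_grid composes per-study fits into the SNP x study grid", {
  d <- scaled_design(120)
  cohorts <- lapply(seq_along(d$studies), function(i)
    simulate_cohort(d$studies[[i]], d$panel, seed = 700 + i))
  g <- suppressMessages(assoc_grid(cohorts, k_pcs = 2))
  expect_s3_class(g, "result_grid")
  expect_identical(nrow(g$assoc), 72L)
  expect_identical(nrow(g$snps), 9L)
  expect_identical(nrow(g$studies), 8L)
  expect_error(assoc_grid(list()), "non-empty")
  # composition identity on a single study / single SNP
  co <- cohorts[[1]]
  one <- suppressMessages(assoc_grid(list(co), k_pcs = 0, panel = "rs2910164"))
  direct <- suppressMessages(fit_additive_logistic(
    co$genotypes[, "rs2910164"], co$phenotype,
    covariates = list(gender = co$gender, cohort = co$cohort),
    rsid = "rs2910164", study = co$spec$name))
  expect_identical(nrow(one$assoc), 1L)
  expect_equal(one$assoc$beta, direct$beta, tolerance = 1e-12)
})
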