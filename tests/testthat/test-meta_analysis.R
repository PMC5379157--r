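test_that("se_from_ci inverts the Wald CI construction", {
  expect_lt(abs(se_from_ci(1.12, 1.04, 1.21) - 0.03862), 1e-4)
  # exact round-trip identity on (beta, se)
  set.seed(71)
  b <- rnorm(20); s <- runif(20, 0.01, 0.3)
  z <- qnorm(0.975)
  expect_lt(max(abs(se_from_ci(exp(b), exp(b - z * s), exp(b + z * s)) - s)),
            1e-12)
  expect_warning(w <- se_from_ci(1.1, 1.1, 1.1), "zero-width")
  expect_identical(w, 0)
  expect_error(se_from_ci(1.0, 1.1, 1.2), "ci_low <= or_")
})

test_that("Cochran's Q: closed forms and chi-square calibration", {
  no_het <- cochran_q(rep(0.3, 5), rep(0.1, 5))
  expect_equal(no_het$q, 0)
  expect_equal(no_het$p_het, 1)
  # two studies, betas 0 and b, equal variance v: Q = b^2 / (2v)
  b <- 0.7; v <- 0.04
  expect_equal(cochran_q(c(0, b), rep(sqrt(v), 2))$q, b^2 / (2 * v),
               tolerance = 1e-12)
  # under homogeneity Q ~ chi-square(k-1): mean 7 at k = 8
  set.seed(81)
  ses <- runif(8, 0.05, 0.2)
  qs <- vapply(1:5000, function(i)
    cochran_q(rnorm(8, 0.1, ses), ses)$q, numeric(1))
  expect_lt(abs(mean(qs) - 7), 0.15)
})

test_that("fixed-effect pooling equals the brute-force weighted mean", {
  # two identical studies: pooled (b, s / sqrt(2))
  px <- pool_fixed(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(px$pooled_beta, 0.2, tolerance = 1e-15)
  expect_equal(px$pooled_se, 0.1 / sqrt(2), tolerance = 1e-15)
  # arbitrary 4-study fixture vs direct summation
  b <- c(0.11, -0.25, 0.4, 0.02); s <- c(0.05, 0.12, 0.2, 0.08)
  p4 <- pool_fixed(b, s)
  num <- 0; den <- 0
  for (i in 1:4) { num <- num + b[i] / s[i]^2; den <- den + 1 / s[i]^2 }
  expect_lt(abs(p4$pooled_beta - num / den), 1e-12)
  expect_lt(abs(p4$pooled_se - 1 / sqrt(den)), 1e-12)
  expect_lte(p4$pooled_se, min(s))
})

test_that("DerSimonian-Laird pooling matches the hand-computed fixture", {
  # betas 0, 0.5, 1 with se 0.1: w = 100 each, b_F = 0.5, Q = 50, df = 2,
  # C = 300 - 30000/300 = 200, tau2 = 48/200 = 0.24,
  # w* = 1/0.25 = 4 each -> pooled 0.5, se = 1/sqrt(12)
  dl <- pool_random(c(0, 0.5, 1), rep(0.1, 3))
  expect_lt(abs(dl$tau2 - 0.24), 1e-10)
  expect_lt(abs(dl$pooled_beta - 0.5), 1e-10)
  expect_lt(abs(dl$pooled_se - 1 / sqrt(12)), 1e-10)
  # truncation boundary: Q <= df collapses to the fixed-effect result exactly
  b <- c(0.30, 0.31, 0.29); s <- c(0.1, 0.12, 0.11)
  expect_lte(cochran_q(b, s)$q, 2)
  expect_identical(pool_random(b, s)[names(pool_fixed(b, s))], pool_fixed(b, s))
})

test_that("pooled estimates respect convexity and variance ordering", {
  set.seed(91)
  for (i in 1:50) {
    k <- sample(3:10, 1)
    b <- rnorm(k, 0, 0.5); s <- runif(k, 0.02, 0.4)
    fx <- pool_fixed(b, s); rd <- pool_random(b, s)
    expect_gte(fx$pooled_beta, min(b)); expect_lte(fx$pooled_beta, max(b))
    expect_gte(rd$pooled_beta, min(b)); expect_lte(rd$pooled_beta, max(b))
    expect_gte(rd$pooled_se, fx$pooled_se)
    expect_gte(rd$tau2, 0)
  }
})

test_that("meta_per_snp selects the model from the heterogeneity p-value", {
  g <- ref_grid()
  m <- meta_per_snp(g)
  expect_identical(nrow(m), 9L)
  expect_identical(m$model, ifelse(m$p_het < 0.05, "random", "fixed"))
  # published rs2910164 row: pooled OR inside the study range
  r <- m[m$rsid == "rs2910164", ]
  expect_gte(r$pooled_or, 0.85)
  expect_lte(r$pooled_or, 1.12)
  # homogeneous synthetic row selects fixed
  hom <- result_grid(data.frame(
    rsid = "rsH", study = paste0("s", 1:4), beta = rep(0.1, 4),
    se = rep(0.05, 4), or_ = exp(0.1), ci_low = 1, ci_high = 1.3,
    p = 0.05, stringsAsFactors = FALSE))
  expect_identical(meta_per_snp(hom)$model, "fixed")
})

test_that("meta_per_snp skips unusable cells and decrements k_studies", {
  g <- ref_grid()
  g$assoc$status[g$assoc$rsid == "rs2910164" & g$assoc$study == "bladder"] <- "error"
  m <- meta_per_snp(g)
  expect_identical(m$k_studies[m$rsid == "rs2910164"], 7L)
  expect_identical(m$k_studies[m$rsid == "rs895819"], 8L)
  # a SNP with < 2 usable cells is skipped with a warning
  g$assoc$status[g$assoc$rsid == "rs3746444"][1:7] <- "error"
  expect_warning(m2 <- meta_per_snp(g), "rs3746444")
  expect_false("rs3746444" %in% m2$rsid)
})
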