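#' Standard error of a log odds ratio from a 95% confidence interval
#'
#' Inverts the Wald construction `CI = exp(beta +/- 1.959964 se)`:
#' `se = (ln ci_high - ln ci_low) / (2 * 1.959964)`. This is how published
#' OR (95% CI) summaries are converted back to an (estimate, se) pair for
#' pooling.
#'
#' @param or_ odds ratio point estimate.
#' @param ci_low,ci_high 95% CI bounds, `0 < ci_low <= or_ <= ci_high`.
#' @return standard error on the log-OR scale (vectorized).
#' @examples
#' se_from_ci(1.12, 1.04, 1.21)   # ~0.0386
#' @export
se_from_ci <- function(or_, ci_low, ci_high) {
  assert_that(all(ci_low > 0), "ci_low must be positive")
  assert_that(all(ci_low <= or_ & or_ <= ci_high),
              "need ci_low <= or_ <= ci_high")
  if (any(ci_low == ci_high))
    warning("zero-width confidence interval: returning se = 0")
  (log(ci_high) - log(ci_low)) / (2 * z975)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (b_i - b_fixed)^2` with inverse-variance weights
#' `w_i = 1/se_i^2`, referenced to a chi-square with `k - 1` degrees of
#' freedom.
#'
#' @param betas,ses study log-OR estimates and their standard errors
#'   (`length >= 2`, `ses > 0`).
#' @return list `(q, df, p_het)`.
#' @export
cochran_q <- function(betas, ses) {
  check_meta_input(betas, ses)
  w <- 1 / ses^2
  b_fixed <- sum(w * betas) / sum(w)
  q <- sum(w * (betas - b_fixed)^2)
  df <- length(betas) - 1L
  list(q = q, df = df, p_het = stats::pchisq(q, df, lower.tail = FALSE))
}

check_meta_input <- function(betas, ses) {
  assert_that(length(betas) >= 2 && length(betas) == length(ses),
              "need >= 2 studies with matching betas/ses")
  assert_that(all(is.finite(betas)) && all(is.finite(ses)) && all(ses > 0),
              "betas must be finite and ses finite and > 0")
  invisible(TRUE)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' `pooled = sum(w_i b_i) / sum(w_i)`, `se = sum(w_i)^(-1/2)`,
#' `w_i = 1/se_i^2`.
#'
#' @inheritParams cochran_q
#' @return list `(pooled_beta, pooled_se, pooled_or, ci_low, ci_high, p)`.
#' @export
pool_fixed <- function(betas, ses) {
  check_meta_input(betas, ses)
  w <- 1 / ses^2
  b <- sum(w * betas) / sum(w)
  s <- 1 / sqrt(sum(w))
  pooled_result(b, s)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimator of the between-study variance
#' `tau2 = max(0, (Q - df) / C)` with `C = sum(w_i) - sum(w_i^2)/sum(w_i)`,
#' then inverse-variance pooling with weights `1/(se_i^2 + tau2)`. When
#' `Q <= df` the estimate truncates to `tau2 = 0` and the result equals
#' [pool_fixed()] exactly.
#'
#' @inheritParams cochran_q
#' @return list as [pool_fixed()] plus `tau2`.
#' @export
pool_random <- function(betas, ses) {
  check_meta_input(betas, ses)
  w <- 1 / ses^2
  cq <- cochran_q(betas, ses)
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (cq$q - cq$df) / C)
  ws <- 1 / (ses^2 + tau2)
  b <- sum(ws * betas) / sum(ws)
  s <- 1 / sqrt(sum(ws))
  c(pooled_result(b, s), list(tau2 = tau2))
}

pooled_result <- function(b, s) {
  list(pooled_beta = b, pooled_se = s, pooled_or = exp(b),
       ci_low = exp(b - z975 * s), ci_high = exp(b + z975 * s),
       p = 2 * stats::pnorm(-abs(b / s)))
}

#' Per-SNP meta-analysis across studies with heterogeneity-driven model choice
#'
#' For each SNP of a [result_grid]: computes Cochran's Q over the usable
#' study estimates, selects the DerSimonian-Laird random-effects model when
#' the heterogeneity p-value `Ph < het_threshold` and the fixed-effect
#' inverse-variance model otherwise, and reports both alongside the selection.
#'
#' @param grid a [result_grid] with an `assoc` table.
#' @param het_threshold heterogeneity significance cutoff (default 0.05).
#' @return data.frame with one row per SNP: `rsid, k_studies, q, df, p_het,
#'   tau2, model` plus `pooled_*` columns for the selected model and
#'   `fixed_*` / `random_*` columns for both candidates. SNPs with fewer than
#'   two usable cells are skipped with a warning.
#' @export
meta_per_snp <- function(grid, het_threshold = 0.05) {
  a <- usable_assoc(grid)
  out <- list()
  for (rs in unique(grid$snps$rsid)) {
    rows <- a[a$rsid == rs, ]
    if (nrow(rows) < 2) {
      warning(sprintf("SNP %s has < 2 usable study estimates; skipped", rs))
      next
    }
    cq <- cochran_q(rows$beta, rows$se)
    fx <- pool_fixed(rows$beta, rows$se)
    rd <- pool_random(rows$beta, rows$se)
    model <- if (cq$p_het < het_threshold) "random" else "fixed"
    sel <- if (model == "random") rd else fx
    out[[rs]] <- data.frame(
      rsid = rs, k_studies = nrow(rows), q = cq$q, df = cq$df,
      p_het = cq$p_het, tau2 = rd$tau2, model = model,
      pooled_beta = sel$pooled_beta, pooled_se = sel$pooled_se,
      pooled_or = sel$pooled_or, ci_low = sel$ci_low, ci_high = sel$ci_high,
      p = sel$p,
      fixed_or = fx$pooled_or, fixed_ci_low = fx$ci_low,
      fixed_ci_high = fx$ci_high,
      random_or = rd$pooled_or, random_ci_low = rd$ci_low,
      random_ci_high = rd$ci_high,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
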