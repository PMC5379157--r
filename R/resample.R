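#' Subsample robustness of a single-study association
#'
#' Repeats the additive logistic association `b` times on random subsamples
#' containing `fraction` of the study (by default 70% of cases and 70% of
#' controls, drawn without replacement and stratified by case status),
#' recomputing ancestry PCs on each subsample, and summarizes how often the
#' association stays significant at `alpha`. Persistence is assessed by a
#' one-sided exact binomial test of the per-replicate significance
#' probability against 0.5; the full replicate p-value distribution is kept
#' so any other summary can be recomputed.
#'
#' @param cohort a `cohort_data`.
#' @param rsid SNP to test (must be a genotype column of the cohort).
#' @param k_pcs ancestry PCs per replicate (capped as in [assoc_grid()]).
#' @param fraction subsample fraction in (0, 1]; `1` reuses the full sample.
#' @param b number of replicates (default 1000).
#' @param alpha per-replicate significance level (default 0.05).
#' @param seed integer seed; the report is reproducible given the seed.
#' @param stratified draw `fraction` of cases and of controls separately
#'   (default) instead of `fraction` of all individuals.
#' @return object of class `resample_report`: list with `rsid`, `study`,
#'   `b_replicates`, `fraction`, `prop_significant`, `binom_p`, quantiles
#'   `q05_p`/`median_p`/`q95_p`, `n_failed`, `flagged` (TRUE when > 5% of
#'   replicate fits failed), `seed`, and the vector `replicate_p`.
#' @export
resample_robustness <- function(cohort, rsid, k_pcs = 2L, fraction = 0.7,
                                b = 1000L, alpha = 0.05, seed = 1L,
                                stratified = TRUE) {
  assert_that(inherits(cohort, "cohort_data"), "'cohort' must be a cohort_data")
  assert_that(rsid %in% colnames(cohort$genotypes),
              sprintf("SNP %s is not in the cohort", rsid))
  assert_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  G <- cohort$genotypes
  y <- cohort$phenotype
  ics <- which(y == 1L); ict <- which(y == 0L)
  assert_that(floor(fraction * length(ics)) >= 1 &&
              floor(fraction * length(ict)) >= 1,
              "subsample would lose one of the phenotype classes")
  nm <- sum(apply(G, 2, function(g) stats::var(g, na.rm = TRUE) > 0), na.rm = TRUE)
  k_eff <- min(k_pcs, max(nm - 1L, 0L))

  ps <- rep(NA_real_, b)
  with_seed(seed, {
    for (r in seq_len(b)) {
      idx <- if (fraction == 1) {
        seq_along(y)   # degenerate: every replicate IS the full sample
      } else if (stratified) {
        c(sample(ics, floor(fraction * length(ics))),
          sample(ict, floor(fraction * length(ict))))
      } else {
        sample(seq_along(y), floor(fraction * length(y)))
      }
      ps[r] <- tryCatch({
        Gs <- G[idx, , drop = FALSE]
        pcs <- if (k_eff > 0) suppressWarnings(eigenstrat_pcs(Gs, k_eff)) else NULL
        fit <- suppressMessages(fit_additive_logistic(
          Gs[, rsid], y[idx],
          covariates = list(pcs = pcs, gender = cohort$gender[idx]),
          rsid = rsid, study = cohort$spec$name))
        if (fit$status == "ok") fit$p else NA_real_
      }, error = function(e) NA_real_)
    }
  })
  n_failed <- sum(is.na(ps))
  ok <- ps[!is.na(ps)]
  if (length(ok) == 0)
    stop("every replicate fit failed; the cohort/SNP is not analysable",
         call. = FALSE)
  n_sig <- sum(ok < alpha)
  prop <- n_sig / length(ok)
  binom_p <- stats::binom.test(n_sig, length(ok), p = 0.5,
                               alternative = "greater")$p.value
  qs <- stats::quantile(ok, c(0.05, 0.5, 0.95), names = FALSE)
  structure(list(rsid = rsid, study = cohort$spec$name,
                 b_replicates = as.integer(b), fraction = fraction,
                 prop_significant = prop, binom_p = binom_p,
                 q05_p = qs[1], median_p = qs[2], q95_p = qs[3],
                 alpha = alpha, n_failed = n_failed,
                 flagged = n_failed > 0.05 * b, seed = as.integer(seed),
                 replicate_p = ps),
            class = "resample_report")
}

#' @export
print.resample_report <- function(x, ...) {
  cat(sprintf(
    "<resample_report> %s in %s: %d x %.0f%% subsamples, %.1f%% significant at %.2f (persistence p = %.3g)%s\n",
    x$rsid, x$study, x$b_replicates, 100 * x$fraction,
    100 * x$prop_significant, x$alpha, x$binom_p,
    if (x$flagged) sprintf(" [FLAGGED: %d failed fits]", x$n_failed) else ""))
  invisible(x)
}

#' @export
as.data.frame.resample_report <- function(x, ...) {
  data.frame(rsid = x$rsid, study = x$study, B = x$b_replicates,
             fraction = x$fraction, prop_significant = x$prop_significant,
             q05_p = x$q05_p, median_p = x$median_p, q95_p = x$q95_p,
             binom_p = x$binom_p, seed = x$seed,
             stringsAsFactors = FALSE)
}
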