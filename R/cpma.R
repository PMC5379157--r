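#' Cross-phenotype meta-analysis (CPMA) statistic
#'
#' Tests whether a SNP's association p-values across several phenotypes
#' deviate from the uniform null in aggregate, agnostic to effect direction.
#' Under the null each `-ln p_i` is Exponential(1); the alternative fits a
#' common rate by maximum likelihood, `lambda_hat = n / sum(-ln p_i)`, and
#' the likelihood-ratio statistic
#' `2 * (n * ln(lambda_hat) + (1 - lambda_hat) * sum(-ln p_i))`
#' is referenced to a chi-square with one degree of freedom (full two-sided
#' tail by default).
#'
#' @param pvals vector of `n >= 2` p-values in `(0, 1]`. Values are clipped
#'   into `[1e-300, 1 - 1e-16]` before taking logs; clipping is reported via
#'   the `clipped` field.
#' @param rsid optional label.
#' @param reference `"chisq1"` (default; full chi-square(1) upper tail) or
#'   `"mixture"` (half-chi-square boundary mixture for the one-sided
#'   `lambda < 1` alternative; returns 1 when the deviation is toward
#'   `lambda > 1`).
#' @return object of class `cpma_result`: list with `rsid`, `n_phenotypes`,
#'   `neglog_sum`, `rate_mle`, `statistic`, `p`, `status` (`"ok"` or
#'   `"invalid"` when all inputs are 1 and the statistic diverges) and
#'   `clipped`.
#' @examples
#' # identical p-values at exp(-1) sit exactly on the null: statistic 0, p 1
#' cpma_statistic(rep(exp(-1), 8))
#' @export
cpma_statistic <- function(pvals, rsid = NA_character_,
                           reference = c("chisq1", "mixture")) {
  reference <- match.arg(reference)
  assert_that(length(pvals) >= 2, "need >= 2 p-values")
  assert_that(all(pvals > 0 & pvals <= 1), "all p-values must be in (0, 1]")
  n <- length(pvals)
  if (all(pvals == 1)) {
    # the rate MLE diverges and so does the statistic; flag, don't guess
    return(structure(list(rsid = rsid, n_phenotypes = n, neglog_sum = 0,
                          rate_mle = Inf, statistic = Inf, p = 0,
                          status = "invalid", clipped = FALSE),
                     class = "cpma_result"))
  }
  pc <- pmin(pmax(pvals, 1e-300), 1 - 1e-16)
  clipped <- any(pc != pvals)
  if (clipped) warning("p-values clipped to [1e-300, 1 - 1e-16]")
  x <- -log(pc)
  T <- sum(x)
  status <- "ok"
  lambda <- n / T
  stat <- 2 * (n * log(lambda) + (1 - lambda) * T)
  stat <- max(stat, 0)   # guard tiny negative round-off at lambda == 1
  p <- if (reference == "chisq1") {
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    if (lambda <= 1) 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) else 1
  }
  structure(list(rsid = rsid, n_phenotypes = n, neglog_sum = T,
                 rate_mle = lambda, statistic = stat, p = p,
                 status = status, clipped = clipped),
            class = "cpma_result")
}

#' @export
print.cpma_result <- function(x, ...) {
  cat(sprintf("<cpma_result> %s: n = %d, lambda_hat = %.4f, stat = %.3f, p = %.3g [%s]\n",
              x$rsid, x$n_phenotypes, x$rate_mle, x$statistic, x$p, x$status))
  invisible(x)
}

#' CPMA over every SNP of a result grid
#'
#' Applies [cpma_statistic()] to each SNP's vector of raw (unadjusted)
#' per-phenotype association p-values. The result is invariant to the order
#' of phenotypes and to the direction of the underlying effects.
#'
#' @param grid a [result_grid].
#' @param reference passed to [cpma_statistic()].
#' @return data.frame `rsid, n_phenotypes, neglog_sum, rate_mle, statistic,
#'   p, status`; SNPs with fewer than two usable p-values are skipped with a
#'   warning.
#' @export
cpma_grid <- function(grid, reference = "chisq1") {
  a <- usable_assoc(grid)
  out <- list()
  for (rs in unique(grid$snps$rsid)) {
    p <- a$p[a$rsid == rs]
    if (length(p) < 2) {
      warning(sprintf("SNP %s has < 2 usable p-values; skipped", rs))
      next
    }
    r <- cpma_statistic(p, rsid = rs, reference = reference)
    out[[rs]] <- data.frame(rsid = rs, n_phenotypes = r$n_phenotypes,
                            neglog_sum = r$neglog_sum, rate_mle = r$rate_mle,
                            statistic = r$statistic, p = r$p,
                            status = r$status, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
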