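#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Sorts the p-values ascending, forms candidates `p_(j) * m / j`, and sets
#' the adjusted value at rank `k` to `min(1, min_{j >= k} candidate_j)`
#' (the step-up minimum enforces monotonicity), returning the adjusted
#' values in the original order. `m` may exceed the number of supplied
#' p-values when the family is larger than the vector at hand.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param m family size, `m >= length(pvals)`.
#' @return adjusted p-values, same order as the input.
#' @examples
#' bh_adjust(c(0.001, 0.01, 0.04, 0.5))
#' @export
bh_adjust <- function(pvals, m = length(pvals)) {
  assert_that(all(pvals >= 0 & pvals <= 1), "p-values must lie in [0, 1]")
  n <- length(pvals)
  assert_that(m >= n, "family size m must be >= length(pvals)")
  if (n == 0) return(numeric(0))
  o <- order(pvals, decreasing = TRUE)          # largest first
  ro <- order(o)
  cand <- pvals[o] * m / seq(n, 1)              # p_(j) * m / j, ranks n..1
  pmin(1, cummin(cand))[ro]
}

#' FDR-adjust an analysed result grid
#'
#' Applies [bh_adjust()] over two separate families: all usable association
#' p-values of the SNP x phenotype grid jointly (one family, `m` = number of
#' usable cells), and the per-SNP CPMA p-values (a second family). Adjusted
#' values are attached to the grid's `assoc` and `cpma` tables as `p_fdr`
#' columns, and an `adjusted` element records each family's size, threshold
#' and significance calls.
#'
#' @param grid a [result_grid]; run [cpma_grid()] first (or [run_all()]) if
#'   CPMA adjustment is wanted.
#' @param q_threshold significance threshold on the adjusted scale
#'   (default 0.05).
#' @return the grid, with `p_fdr` columns and an `adjusted` list of
#'   per-family summaries `(family, m, q_threshold, n_significant)`.
#' @export
adjust_grid <- function(grid, q_threshold = 0.05) {
  ok <- !is.na(grid$assoc$p) & grid$assoc$status == "ok"
  if (any(!ok))
    message(sprintf("excluding %d unusable cell(s) from the grid family", sum(!ok)))
  grid$assoc$p_fdr <- NA_real_
  grid$assoc$p_fdr[ok] <- bh_adjust(grid$assoc$p[ok])
  adjusted <- list(list(family = sprintf("grid-%d", sum(ok)), m = sum(ok),
                        q_threshold = q_threshold,
                        n_significant = sum(grid$assoc$p_fdr[ok] <= q_threshold)))
  if (!is.null(grid$cpma)) {
    okc <- !is.na(grid$cpma$p) & grid$cpma$status == "ok"
    grid$cpma$p_fdr <- NA_real_
    grid$cpma$p_fdr[okc] <- bh_adjust(grid$cpma$p[okc])
    adjusted[[2]] <- list(family = sprintf("cpma-%d", sum(okc)), m = sum(okc),
                          q_threshold = q_threshold,
                          n_significant = sum(grid$cpma$p_fdr[okc] <= q_threshold))
  }
  grid$adjusted <- adjusted
  grid
}
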