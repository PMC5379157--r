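#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Correlates standardized effect deviates with their sampling variances
#' across studies. With fixed-effect pooled mean `b_hat` (weights `1/v_i`),
#' the deviates are `t_i = (b_i - b_hat) / sqrt(v_i - 1/sum(1/v_j))`;
#' `s` is the Kendall score between `(t_i)` and `(v_i)`;
#' `z = max(0, |s| - 1) / sqrt(var_s)` applies a continuity correction with
#' `var_s = n(n-1)(2n+5)/18` (tie-corrected when ties occur in either
#' ranking); the p-value is the two-sided normal tail `2 * (1 - Phi(z))`.
#' Scores with `|s| <= 1` therefore give p = 1 exactly.
#'
#' @param betas study effects on an additive (log-OR) scale, `n >= 3`.
#' @param variances their sampling variances (`se^2`), all positive.
#' @param rsid optional label.
#' @param labels optional study labels used in error messages.
#' @return object of class `begg_result`: list `(rsid, n, s, z, p)`.
#' @examples
#' begg_test(c(0.1, 0.02, -0.05, 0.2), c(0.01, 0.02, 0.015, 0.05))
#' @export
begg_test <- function(betas, variances, rsid = NA_character_, labels = NULL) {
  n <- length(betas)
  assert_that(n >= 3 && length(variances) == n,
              "need >= 3 studies with matching betas/variances")
  assert_that(all(variances > 0), "variances must be positive")
  if (is.null(labels)) labels <- paste0("study", seq_len(n))
  w <- 1 / variances
  b_hat <- sum(w * betas) / sum(w)
  vstar <- variances - 1 / sum(w)
  if (any(vstar <= 0))
    stop(sprintf("non-positive deviate variance for %s (study variance <= pooled variance)",
                 paste(labels[vstar <= 0], collapse = ", ")), call. = FALSE)
  t <- (betas - b_hat) / sqrt(vstar)

  ij <- utils::combn(n, 2)
  s <- sum(sign((t[ij[1, ]] - t[ij[2, ]]) * (variances[ij[1, ]] - variances[ij[2, ]])))
  tie_term <- function(x) {
    tt <- table(x); tt <- tt[tt > 1]
    sum(tt * (tt - 1) * (2 * tt + 5))
  }
  ties <- tie_term(t) + tie_term(variances)
  if (ties > 0) message("ties present; applying tie correction to var(s)")
  var_s <- (n * (n - 1) * (2 * n + 5) - tie_term(t) - tie_term(variances)) / 18
  z <- max(0, abs(s) - 1) / sqrt(var_s)
  structure(list(rsid = rsid, n = n, s = as.integer(s), z = z,
                 p = min(1, 2 * stats::pnorm(-z))),
            class = "begg_result")
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("<begg_result> %s: n = %d, s = %d, z = %.3f, p = %.3f\n",
              x$rsid, x$n, x$s, x$z, x$p))
  invisible(x)
}

#' Begg's test for every SNP of a result grid
#'
#' Runs [begg_test()] per SNP over its usable study estimates (log-OR scale,
#' variances `se^2`). SNPs with fewer than three usable cells, or whose test
#' errors, are reported with `NA` and the failure message; the run continues.
#'
#' @param grid a [result_grid].
#' @return data.frame `rsid, n, s, z, p, status`.
#' @export
begg_grid <- function(grid) {
  a <- usable_assoc(grid)
  out <- list()
  for (rs in unique(grid$snps$rsid)) {
    rows <- a[a$rsid == rs, ]
    r <- tryCatch({
      assert_that(nrow(rows) >= 3, "fewer than 3 usable study estimates")
      b <- begg_test(rows$beta, rows$se^2, rsid = rs, labels = rows$study)
      data.frame(rsid = rs, n = b$n, s = b$s, z = b$z, p = b$p,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("Begg's test failed for %s: %s", rs, conditionMessage(e)))
      data.frame(rsid = rs, n = nrow(rows), s = NA_integer_, z = NA_real_,
                 p = NA_real_, status = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    out[[rs]] <- r
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
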