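#' Additive (trend) logistic association of disease on genotype
#'
#' Fits `logit P(case) = alpha + beta * g + covariates` by iteratively
#' reweighted least squares, where `g` counts copies of the effect allele
#' (0/1/2), and reports the one-degree-of-freedom per-allele trend effect:
#' log odds ratio `beta`, its standard error from the inverse observed
#' information, the odds ratio with Wald 95% CI `exp(beta +/- 1.959964 se)`,
#' and the two-sided normal-tail p-value.
#'
#' @param genotype integer vector of 0/1/2 (NA allowed; such rows are dropped
#'   listwise and `n_used` reports the remainder).
#' @param phenotype 0/1 vector, 1 = case; both classes must be present.
#' @param covariates optional list with any of `pcs` (matrix), `gender`
#'   (vector), `cohort` (factor/character; one-hot encoded with the first
#'   level absorbed into the intercept). Constant columns (e.g. the cohort
#'   label inside a single study) are dropped with a message, as are
#'   collinear columns; the genotype column itself is never dropped.
#' @param rsid,study optional labels carried into the result.
#' @param max_iter,tol IRLS iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @return object of class `assoc_result`: list with `rsid`, `study`, `beta`,
#'   `se`, `or_`, `ci_low`, `ci_high`, `p`, `n_used`, `status` (`"ok"`,
#'   `"no_convergence"` or `"separation"`) and `message`.
#' @examples
#' g <- rep(0:2, c(500, 400, 100)); y <- rbinom(1000, 1, 0.4)
#' fit_additive_logistic(g, y)
#' @export
fit_additive_logistic <- function(genotype, phenotype, covariates = NULL,
                                  rsid = NA_character_, study = NA_character_,
                                  max_iter = 50L, tol = 1e-10) {
  keep <- !is.na(genotype)
  X <- cbind(`(Intercept)` = 1, genotype = as.numeric(genotype))
  if (!is.null(covariates)) {
    if (!is.null(covariates$pcs) && ncol(covariates$pcs) > 0)
      X <- cbind(X, covariates$pcs)
    if (!is.null(covariates$gender))
      X <- cbind(X, gender = as.numeric(covariates$gender))
    if (!is.null(covariates$cohort)) {
      f <- factor(covariates$cohort)
      if (nlevels(f) > 1) {
        mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
        colnames(mm) <- paste0("cohort", levels(f)[-1])
        X <- cbind(X, mm)
      }
    }
  }
  keep <- keep & stats::complete.cases(X) & !is.na(phenotype)
  X <- X[keep, , drop = FALSE]
  y <- as.numeric(phenotype[keep])
  n_used <- length(y)
  assert_that(n_used > 0, "no usable rows after removing missing data")
  assert_that(length(unique(y)) == 2, "both phenotype classes must be present")
  assert_that(stats::var(X[, "genotype"]) > 0,
              "genotype is monomorphic among the used individuals")

  # drop constant (non-intercept) and collinear columns, keeping genotype
  const <- apply(X[, -1, drop = FALSE], 2, function(z) stats::var(z) == 0)
  if (any(const)) {
    dropped <- colnames(X)[-1][const]
    message("dropping constant covariate column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, !c(FALSE, const), drop = FALSE]
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    gi <- which(colnames(X) == "genotype")
    if (!(gi %in% keep_cols))
      stop("genotype column is collinear with the covariates", call. = FALSE)
    message("dropping collinear covariate column(s): ",
            paste(colnames(X)[-keep_cols], collapse = ", "))
    X <- X[, keep_cols, drop = FALSE]
  }

  fit <- irls_logistic(X, y, max_iter = max_iter, tol = tol)
  j <- which(colnames(X) == "genotype")
  beta <- unname(fit$beta[j])
  se <- unname(sqrt(fit$vcov[j, j]))
  status <- "ok"; msg <- ""
  if (abs(beta) > 15) { status <- "separation"; msg <- "effect diverging; probable complete separation" }
  else if (!fit$converged) { status <- "no_convergence"; msg <- sprintf("IRLS did not converge in %d iterations", max_iter) }
  z <- beta / se
  structure(list(rsid = rsid, study = study,
                 beta = beta, se = se, or_ = exp(beta),
                 ci_low = exp(beta - z975 * se),
                 ci_high = exp(beta + z975 * se),
                 p = 2 * stats::pnorm(-abs(z)),
                 n_used = n_used, status = status, message = msg),
            class = "assoc_result")
}

# Plain IRLS for a Bernoulli GLM with logit link; returns coefficients,
# observed-information covariance and a convergence flag.
irls_logistic <- function(X, y, max_iter = 50L, tol = 1e-10) {
  beta <- numeric(ncol(X))
  ll_old <- -Inf; converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    XtWX <- crossprod(X, X * w)
    beta_new <- tryCatch(drop(solve(XtWX, crossprod(X, w * z))),
                         error = function(e)
                           stop("IRLS normal equations are singular", call. = FALSE))
    beta <- beta_new
    eta <- drop(X %*% beta)
    # numerically stable Bernoulli log-likelihood
    ll <- sum(y * eta - ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))))
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 0.1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    if (any(abs(beta) > 30)) break  # runaway: separation, stop early
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  XtWX <- crossprod(X, X * w)
  list(beta = stats::setNames(beta, colnames(X)),
       vcov = solve(XtWX), converged = converged)
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s in %s: OR %.3f (%.3f-%.3f), p = %.3g, n = %d [%s]\n",
              x$rsid, x$study, x$or_, x$ci_low, x$ci_high, x$p, x$n_used, x$status))
  invisible(x)
}

#' @export
as.data.frame.assoc_result <- function(x, ...) {
  data.frame(rsid = x$rsid, study = x$study, n_used = x$n_used,
             beta = x$beta, se = x$se, or_ = x$or_,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             status = x$status, stringsAsFactors = FALSE)
}

#' Per-study association grid over a SNP panel
#'
#' Runs [fit_additive_logistic()] for every SNP of the panel in every cohort,
#' with ancestry PCs recomputed per cohort via [eigenstrat_pcs()] and gender
#' (plus cohort, when a cohort carries several labels) as covariates, and
#' assembles the SNP x study grid of association results.
#'
#' @param cohorts non-empty list of `cohort_data`.
#' @param k_pcs requested number of ancestry PCs per cohort; automatically
#'   capped at (number of non-monomorphic panel SNPs - 1) with a message,
#'   since PCs are computed from the panel itself.
#' @param panel optional character vector of rsids restricting the grid.
#' @return a [result_grid] whose `assoc` table has one row per (SNP, study);
#'   failed fits appear with `NA` estimates and an explanatory `status`.
#' @export
assoc_grid <- function(cohorts, k_pcs = 10L, panel = NULL) {
  assert_that(length(cohorts) >= 1, "'cohorts' must be a non-empty list")
  rows <- list()
  for (co in cohorts) {
    rsids <- colnames(co$genotypes)
    if (!is.null(panel)) rsids <- intersect(rsids, panel)
    assert_that(length(rsids) >= 1, "cohort shares no SNPs with the panel")
    G <- co$genotypes[, rsids, drop = FALSE]
    nm <- sum(apply(G, 2, function(g) stats::var(g, na.rm = TRUE) > 0), na.rm = TRUE)
    k_eff <- min(k_pcs, max(nm - 1L, 0L))
    if (k_eff < k_pcs)
      message(sprintf("study %s: reducing k_pcs from %d to %d (panel has %d informative SNPs)",
                      co$spec$name, k_pcs, k_eff, nm))
    pcs <- if (k_eff > 0) suppressWarnings(eigenstrat_pcs(G, k_eff)) else NULL
    for (rs in rsids) {
      res <- tryCatch(
        fit_additive_logistic(G[, rs], co$phenotype,
                              covariates = list(pcs = pcs, gender = co$gender,
                                                cohort = co$cohort),
                              rsid = rs, study = co$spec$name),
        error = function(e)
          structure(list(rsid = rs, study = co$spec$name, beta = NA_real_,
                         se = NA_real_, or_ = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, p = NA_real_, n_used = 0L,
                         status = "error", message = conditionMessage(e)),
                    class = "assoc_result"))
      if (res$status == "error")
        warning(sprintf("fit failed for %s in %s: %s", rs, co$spec$name, res$message))
      df <- as.data.frame(res)
      df$cancer_type <- co$spec$cancer_type
      rows[[length(rows) + 1L]] <- df
    }
  }
  assoc <- do.call(rbind, rows)
  snps <- unique(do.call(rbind, lapply(cohorts, function(co)
    co$panel[, c("rsid", "effect_allele")])))
  studies <- do.call(rbind, lapply(cohorts, function(co)
    data.frame(study = co$spec$name, cancer_type = co$spec$cancer_type,
               n_cases = co$spec$n_cases, n_controls = co$spec$n_controls,
               stringsAsFactors = FALSE)))
  result_grid(assoc = assoc, snps = snps, studies = studies)
}
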