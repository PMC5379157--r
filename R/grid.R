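#' SNP x study result grid
#'
#' The central container of the pipeline: a long-format table of per-SNP,
#' per-study association results plus SNP and study metadata, to which the
#' meta-analysis ([meta_per_snp()]), CPMA ([cpma_grid()]), FDR
#' ([adjust_grid()]) and publication-bias ([begg_grid()]) stages attach their
#' outputs.
#'
#' @param assoc data.frame with at least `rsid, study, beta, se, or_, ci_low,
#'   ci_high, p`; a `status` column defaults to `"ok"`.
#' @param snps data.frame of SNP metadata (`rsid`, optionally `chr`, `mirna`,
#'   `effect_allele`, `genotyped`); derived from `assoc` when omitted.
#' @param studies data.frame of study metadata (`study`, optionally
#'   `cancer_type`, `n_cases`, `n_controls`); derived when omitted.
#' @return object of class `result_grid`: list with `assoc`, `snps`,
#'   `studies` and (after the respective stages) `meta`, `cpma`, `begg`,
#'   `adjusted`, `reference`.
#' @export
result_grid <- function(assoc, snps = NULL, studies = NULL) {
  need <- c("rsid", "study", "beta", "se", "or_", "ci_low", "ci_high", "p")
  assert_that(all(need %in% names(assoc)),
              paste("assoc is missing columns:",
                    paste(setdiff(need, names(assoc)), collapse = ", ")))
  if (is.null(assoc$status)) assoc$status <- "ok"
  if (is.null(snps))
    snps <- data.frame(rsid = unique(assoc$rsid), stringsAsFactors = FALSE)
  if (is.null(studies))
    studies <- data.frame(study = unique(assoc$study), stringsAsFactors = FALSE)
  structure(list(assoc = assoc, snps = snps, studies = studies,
                 meta = NULL, cpma = NULL, begg = NULL, adjusted = NULL,
                 reference = NULL),
            class = "result_grid")
}

usable_assoc <- function(grid) {
  assert_that(inherits(grid, "result_grid"), "expected a result_grid")
  a <- grid$assoc
  a[a$status == "ok" & !is.na(a$p) & !is.na(a$beta) & !is.na(a$se), , drop = FALSE]
}

#' @export
print.result_grid <- function(x, ...) {
  cat(sprintf("<result_grid> %d SNPs x %d studies (%d cells",
              nrow(x$snps), nrow(x$studies), nrow(x$assoc)))
  extras <- c("meta", "cpma", "begg", "adjusted")[!vapply(
    x[c("meta", "cpma", "begg", "adjusted")], is.null, logical(1))]
  if (length(extras)) cat("; stages: ", paste(extras, collapse = ", "), sep = "")
  cat(")\n")
  invisible(x)
}

#' Build a result grid from published summary rows
#'
#' Converts a long summary table of odds ratios with 95% CIs and p-values
#' (one row per SNP per study) into a [result_grid], reconstructing the
#' log-OR and its standard error via [se_from_ci()]. This is the "summary
#' mode" entry point used when individual-level genotypes are unavailable.
#'
#' @param df data.frame with columns `rsid, study, or_, ci_low, ci_high, p`
#'   (extra columns are kept as metadata where recognised:
#'   `chr, mirna, effect_allele, genotyped, cancer_type, n_cases,
#'   n_controls`).
#' @return a [result_grid].
#' @export
summary_grid <- function(df) {
  need <- c("rsid", "study", "or_", "ci_low", "ci_high", "p")
  assert_that(all(need %in% names(df)),
              paste("summary table is missing columns:",
                    paste(setdiff(need, names(df)), collapse = ", ")))
  assoc <- df
  assoc$beta <- log(df$or_)
  assoc$se <- se_from_ci(df$or_, df$ci_low, df$ci_high)
  assoc$status <- "ok"
  snp_cols <- intersect(c("rsid", "chr", "mirna", "effect_allele", "genotyped"),
                        names(df))
  study_cols <- intersect(c("study", "cancer_type", "n_cases", "n_controls"),
                          names(df))
  result_grid(assoc,
              snps = unique(df[snp_cols]),
              studies = unique(df[study_cols]))
}

#' Read a summary TSV into a result grid
#'
#' @param path TSV with the [summary_grid()] columns; `#` lines are comments.
#' @return a [result_grid].
#' @export
read_summary_tsv <- function(path) summary_grid(read_tsv_meta(path))

# md5 of the packaged fixture files, pinned at build time
.fixture_md5 <- c(
  mirsnp_summary = "d5fe2b389e39669a2e020e197ed136dc",
  mirsnp_cpma = "7ac21cf6ecfeb0b76ee767d99136c1eb")

#' Load the packaged nine-SNP, eight-cancer published summary grid
#'
#' Returns the grid of published per-cancer association summaries for nine
#' microRNA-gene SNPs across eight cancer case-control studies (72 cells:
#' OR, 95% CI, p-value each), together with the published FDR-adjusted and
#' CPMA p-values attached under `$reference` for regression testing. The
#' packaged files are checksummed; a mismatch is an error.
#'
#' @return a [result_grid] with `reference = list(assoc, cpma)` holding the
#'   published `p_fdr` / CPMA columns (NA where the source prints none).
#' @examples
#' g <- load_reference_grid()
#' nrow(g$assoc)   # 72
#' @export
load_reference_grid <- function() {
  f1 <- system.file("extdata", "mirsnp_summary.tsv", package = "mirsnpmeta",
                    mustWork = TRUE)
  f2 <- system.file("extdata", "mirsnp_cpma.tsv", package = "mirsnpmeta",
                    mustWork = TRUE)
  sums <- unname(tools::md5sum(c(f1, f2)))
  if (!identical(sums, unname(.fixture_md5)))
    stop("packaged summary fixture failed its checksum", call. = FALSE)
  df <- read_tsv_meta(f1)
  cp <- read_tsv_meta(f2)
  grid <- summary_grid(df)
  grid$reference <- list(
    assoc = df[, c("rsid", "study", "p", "p_fdr_printed")],
    cpma = cp)
  grid
}
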