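#' Pipeline configuration
#'
#' Collects and validates the tunable parameters of [run_all()]. Defaults
#' mirror the analysis this package reproduces: heterogeneity threshold 0.05,
#' FDR q 0.05, 70% subsamples, 1000 replicates.
#'
#' @param mode `"summary"` (consume a published OR/CI/p table; runs meta,
#'   CPMA, FDR and Begg stages) or `"cohort"` (simulate or load
#'   individual-level cohorts; additionally runs the association stage and,
#'   optionally, resampling).
#' @param summary for summary mode: a [result_grid], a summary data.frame /
#'   TSV path, or `NULL` for the packaged reference grid.
#' @param design for cohort mode: a list `(studies, panel)` as from
#'   [default_study_design()], or `NULL` for that default.
#' @param k_pcs ancestry PCs per study (cohort mode).
#' @param het_threshold Cochran's Q p-value below which the random-effects
#'   model is selected.
#' @param fdr_q FDR significance threshold.
#' @param resample_rsids optional character vector of SNPs to run the
#'   robustness procedure on (cohort mode).
#' @param resample_fraction,resample_b,alpha resampling parameters.
#' @param seed master seed for all randomness.
#' @param out optional output directory; when set, every stage writes a TSV.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("summary", "cohort"), summary = NULL,
                            design = NULL, k_pcs = 10L, het_threshold = 0.05,
                            fdr_q = 0.05, resample_rsids = NULL,
                            resample_fraction = 0.7, resample_b = 1000L,
                            alpha = 0.05, seed = 1L, out = NULL) {
  mode <- match.arg(mode)
  assert_that(het_threshold > 0 && het_threshold < 1, "het_threshold in (0,1)")
  assert_that(fdr_q > 0 && fdr_q < 1, "fdr_q in (0,1)")
  assert_that(resample_fraction > 0 && resample_fraction <= 1,
              "resample_fraction in (0,1]")
  assert_that(k_pcs >= 0, "k_pcs >= 0")
  structure(list(mode = mode, summary = summary, design = design,
                 k_pcs = as.integer(k_pcs), het_threshold = het_threshold,
                 fdr_q = fdr_q, resample_rsids = resample_rsids,
                 resample_fraction = resample_fraction,
                 resample_b = as.integer(resample_b), alpha = alpha,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Composes the stages in analysis order. Summary mode: ingest a published
#' OR/CI/p grid, then per-SNP meta-analysis with heterogeneity-driven model
#' choice, CPMA, BH-FDR over the grid and CPMA families, and Begg's test.
#' Cohort mode: simulate the configured multi-study design (seeded per
#' study from the master seed), fit the per-study association grid with PC,
#' gender and cohort adjustment, then the same downstream stages, plus the
#' 70% resampling procedure for any requested SNPs. With `config$out` set,
#' each stage's table is written as a TSV with `#` provenance headers.
#'
#' @param config a [pipeline_config()].
#' @return the analysed [result_grid]; cohort mode attaches `cohorts` and
#'   any `resample` reports as attributes-free list elements.
#' @examples
#' g <- run_all(pipeline_config(mode = "summary"))
#' subset(g$cpma, p_fdr <= 0.05)
#' @export
run_all <- function(config = pipeline_config()) {
  assert_that(inherits(config, "pipeline_config"), "need a pipeline_config")
  grid <- switch(config$mode,
    summary = {
      s <- config$summary
      if (is.null(s)) load_reference_grid()
      else if (inherits(s, "result_grid")) s
      else if (is.character(s)) read_summary_tsv(s)
      else summary_grid(s)
    },
    cohort = {
      design <- if (is.null(config$design)) default_study_design() else config$design
      cohorts <- lapply(seq_along(design$studies), function(i)
        simulate_cohort(design$studies[[i]], design$panel,
                        seed = config$seed * 1000L + i))
      grid <- suppressMessages(assoc_grid(cohorts, k_pcs = config$k_pcs))
      grid$cohorts <- cohorts
      grid
    })

  grid$meta <- meta_per_snp(grid, het_threshold = config$het_threshold)
  grid$cpma <- cpma_grid(grid)
  grid <- suppressMessages(adjust_grid(grid, q_threshold = config$fdr_q))
  grid$begg <- begg_grid(grid)

  if (config$mode == "cohort" && length(config$resample_rsids)) {
    grid$resample <- list()
    for (co in grid$cohorts) {
      for (rs in intersect(config$resample_rsids, colnames(co$genotypes))) {
        rep <- resample_robustness(co, rs, k_pcs = config$k_pcs,
                                   fraction = config$resample_fraction,
                                   b = config$resample_b, alpha = config$alpha,
                                   seed = config$seed)
        grid$resample[[paste(rs, co$spec$name, sep = ":")]] <- rep
      }
    }
  }

  if (!is.null(config$out)) write_pipeline_outputs(grid, config)
  grid
}

write_pipeline_outputs <- function(grid, config) {
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  meta <- list(seed = config$seed, mode = config$mode,
               het_threshold = config$het_threshold, fdr_q = config$fdr_q)
  fam <- if (!is.null(grid$adjusted))
    paste(vapply(grid$adjusted, function(a) a$family, character(1)),
          collapse = ", ") else ""
  p <- function(f) file.path(config$out, f)
  write_tsv_meta(grid$assoc, p("assoc.tsv"), c(meta, families = fam))
  write_tsv_meta(grid$meta, p("meta.tsv"), meta)
  write_tsv_meta(grid$cpma, p("cpma.tsv"), c(meta, families = fam))
  write_tsv_meta(grid$begg, p("begg.tsv"), meta)
  if (!is.null(grid$resample))
    write_tsv_meta(do.call(rbind, lapply(grid$resample, as.data.frame)),
                   p("resample.tsv"), meta)
  invisible(config$out)
}

#' Pretty, publication-style rendering of the analysed grid
#'
#' Wide table with one row per SNP and, per study, the p-value (with the
#' FDR-adjusted value in parentheses when it clears the threshold) and
#' `OR(L95-U95)`, followed by the CPMA column. P-values below 0.01 are shown
#' in scientific notation, otherwise with four decimals, mimicking how such
#' grids are conventionally printed.
#'
#' @param grid an analysed [result_grid] (after [adjust_grid()]).
#' @param q_threshold show the adjusted value when `p_fdr <=` this.
#' @return data.frame of formatted strings.
#' @export
render_wide_grid <- function(grid, q_threshold = 0.25) {
  fmtp <- function(p) ifelse(p < 0.01, sprintf("%.2E", p), sprintf("%.4f", p))
  rows <- list()
  for (rs in grid$snps$rsid) {
    row <- list(rsid = rs)
    for (st in grid$studies$study) {
      cell <- grid$assoc[grid$assoc$rsid == rs & grid$assoc$study == st, ]
      if (nrow(cell) != 1 || is.na(cell$p)) { row[[st]] <- NA; next }
      ptxt <- fmtp(cell$p)
      if (!is.null(cell$p_fdr) && !is.na(cell$p_fdr) && cell$p_fdr <= q_threshold)
        ptxt <- sprintf("%s(%s)", ptxt, fmtp(cell$p_fdr))
      row[[st]] <- sprintf("%s; %.2f(%.2f-%.2f)", ptxt, cell$or_,
                           cell$ci_low, cell$ci_high)
    }
    if (!is.null(grid$cpma)) {
      cc <- grid$cpma[grid$cpma$rsid == rs, ]
      if (nrow(cc) == 1)
        row$CPMA <- if (!is.null(cc$p_fdr) && !is.na(cc$p_fdr) && cc$p_fdr <= q_threshold)
          sprintf("%s(%s)", fmtp(cc$p), fmtp(cc$p_fdr)) else fmtp(cc$p)
    }
    rows[[rs]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
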