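#' Specify one case-control study
#'
#' A `study_spec` describes a single case-control stratum of a multi-study
#' design: its label, phenotype, sample sizes, and (for simulation) the amount
#' of hidden two-subpopulation ancestry structure.
#'
#' @param name short unique study label, e.g. `"bladder"`.
#' @param cancer_type phenotype label for reporting.
#' @param n_cases,n_controls positive integer sample sizes.
#' @param substructure_fraction proportion of individuals drawn from the second
#'   ancestral subpopulation, in `[0, 1]`. `0` (default) means a homogeneous
#'   population.
#' @param fst Wright's fixation index governing how far the two subpopulation
#'   allele frequencies drift from the ancestral frequency (Balding-Nichols
#'   model); `0` disables structure.
#' @return an object of class `study_spec`.
#' @seealso [snp_spec()], [default_study_design()], [simulate_cohort()]
#' @export
study_spec <- function(name, cancer_type, n_cases, n_controls,
                       substructure_fraction = 0, fst = 0) {
  assert_that(is.character(name) && nzchar(name), "'name' must be a non-empty string")
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  assert_that(n_cases >= 1L && n_controls >= 1L,
              "n_cases and n_controls must both be >= 1")
  assert_that(substructure_fraction >= 0 && substructure_fraction <= 1,
              "substructure_fraction must be in [0, 1]")
  assert_that(fst >= 0, "fst must be >= 0")
  structure(list(name = name, cancer_type = cancer_type,
                 n_cases = n_cases, n_controls = n_controls,
                 substructure_fraction = substructure_fraction, fst = fst),
            class = "study_spec")
}

#' Specify one SNP for simulation
#'
#' @param rsid SNP identifier.
#' @param effect_allele the counted allele, one of `"A"`, `"C"`, `"G"`, `"T"`.
#' @param allele_freq ancestral effect-allele frequency, strictly in `(0, 1)`.
#' @param log_or per-allele additive log odds ratio on disease. Either a single
#'   number applied to every study or a named vector keyed by study name
#'   (unnamed studies get 0).
#' @return an object of class `snp_spec`.
#' @export
snp_spec <- function(rsid, effect_allele, allele_freq, log_or = 0) {
  assert_that(effect_allele %in% c("A", "C", "G", "T"),
              "effect_allele must be one of A, C, G, T")
  assert_that(allele_freq > 0 && allele_freq < 1,
              "allele_freq must be strictly inside (0, 1)")
  structure(list(rsid = rsid, effect_allele = effect_allele,
                 allele_freq = allele_freq, log_or = log_or),
            class = "snp_spec")
}

# Per-study effect lookup for one SNP.
snp_log_or <- function(snp, study_name) {
  lo <- snp$log_or
  if (is.null(names(lo))) return(unname(lo[1]))
  if (study_name %in% names(lo)) unname(lo[[study_name]]) else 0
}

#' The default eight-study, nine-SNP design
#'
#' Returns the design used throughout the package documentation and tests:
#' eight case-control cancer studies (16399 cases, 21779 controls in total)
#' and a panel of nine microRNA-gene SNPs with their effect (counted) alleles.
#' Sample sizes match the published studies this pipeline re-analyses;
#' per-SNP allele frequencies are plausible simulation defaults (the source
#' studies do not publish them), and all per-study effects default to zero
#' (a global null) unless overridden via `effects`.
#'
#' @param effects optional named list `rsid -> (named) log-OR vector` merged
#'   into the panel, see [snp_spec()].
#' @param substructure_fraction,fst passed to every [study_spec()]; defaults
#'   give homogeneous populations.
#' @return list with elements `studies` (list of `study_spec`) and
#'   `panel` (list of `snp_spec`).
#' @examples
#' d <- default_study_design()
#' summarize_cohorts(d$studies)   # 16399 cases, 21779 controls
#' @export
default_study_design <- function(effects = NULL,
                                 substructure_fraction = 0, fst = 0) {
  counts <- list(
    bladder    = c(3527L, 5119L),
    breast     = c(1145L, 1142L),
    escc       = c(1898L, 2100L),
    gastric    = c(1625L, 2100L),
    lung       = c(3782L, 3840L),
    pancreatic = c(2452L, 2461L),
    prostate   = c( 659L, 1593L),
    rcc        = c(1311L, 3424L))
  labels <- c(bladder = "Bladder cancer", breast = "Breast cancer",
              escc = "ESCC", gastric = "Gastric cancer",
              lung = "Lung cancer", pancreatic = "Pancreatic cancer",
              prostate = "Prostate cancer", rcc = "RCC")
  studies <- lapply(names(counts), function(nm)
    study_spec(nm, labels[[nm]], counts[[nm]][1], counts[[nm]][2],
               substructure_fraction = substructure_fraction, fst = fst))
  # effect alleles from the published per-allele ORs; frequencies are
  # simulation defaults in the common range 0.15-0.45
  panel_def <- list(
    c("rs2292832",  "T", 0.35),
    c("rs2910164",  "C", 0.30),
    c("rs2043556",  "C", 0.35),
    c("rs4919510",  "G", 0.20),
    c("rs1834306",  "A", 0.25),
    c("rs11614913", "T", 0.40),
    c("rs6505162",  "C", 0.45),
    c("rs895819",   "C", 0.30),
    c("rs3746444",  "G", 0.15))
  panel <- lapply(panel_def, function(x) {
    lo <- if (!is.null(effects) && x[1] %in% names(effects)) effects[[x[1]]] else 0
    snp_spec(x[1], x[2], as.numeric(x[3]), log_or = lo)
  })
  list(studies = studies, panel = panel)
}

#' Total cases and controls across studies
#'
#' @param specs non-empty list of [study_spec()] objects.
#' @return named integer vector `c(total_cases, total_controls)`.
#' @export
summarize_cohorts <- function(specs) {
  assert_that(length(specs) >= 1, "need at least one study spec")
  c(total_cases = sum(vapply(specs, function(s) s$n_cases, integer(1))),
    total_controls = sum(vapply(specs, function(s) s$n_controls, integer(1))))
}

#' @export
print.study_spec <- function(x, ...) {
  cat(sprintf("<study_spec> %s (%s): %d cases / %d controls, substructure %.2f, Fst %.3f\n",
              x$name, x$cancer_type, x$n_cases, x$n_controls,
              x$substructure_fraction, x$fst))
  invisible(x)
}

#' @export
print.snp_spec <- function(x, ...) {
  cat(sprintf("<snp_spec> %s allele %s freq %.3f\n",
              x$rsid, x$effect_allele, x$allele_freq))
  invisible(x)
}
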