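#' Simulate one case-control cohort with known SNP effects
#'
#' Draws genotypes under Hardy-Weinberg equilibrium within each of (up to) two
#' ancestral subpopulations whose allele frequencies follow the
#' Balding-Nichols model around each SNP's ancestral frequency
#' (`Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst`; `fst = 0` means no
#' structure). Disease status follows an additive logistic model
#' `logit P(case) = alpha + sum_k beta_k g_k + gamma * gender`, with `alpha`
#' calibrated so the population prevalence is `prevalence` at the covariate
#' means. A large source population is simulated and cases/controls are then
#' sampled without replacement to the exact counts in `spec` (case-control
#' sampling), so the intercept of a downstream logistic fit is shifted but
#' the per-allele log odds ratios remain the simulated `beta_k`.
#'
#' @param spec a [study_spec()].
#' @param panel non-empty list of [snp_spec()].
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @param prevalence source-population disease prevalence (default 0.10).
#' @param gender_log_or log odds ratio of gender on disease (default 0).
#' @param missing_rate per-genotype missingness probability (default 0;
#'   missing genotypes are `NA` and are dropped listwise by the association
#'   fit).
#' @param max_n refuse designs with `n_cases + n_controls > max_n`.
#' @return an object of class `cohort_data`: list with `genotypes`
#'   (individuals x SNPs integer matrix, values 0/1/2/NA, columns named by
#'   rsid), `phenotype` (1 = case), `gender` (0/1), `cohort` (study label),
#'   `subpop` (hidden truth label, for tests only), `panel` (data.frame),
#'   and `spec`.
#' @examples
#' d <- default_study_design()
#' co <- simulate_cohort(study_spec("toy", "Toy", 100, 100), d$panel, seed = 1)
#' table(co$phenotype)
#' @export
simulate_cohort <- function(spec, panel, seed, prevalence = 0.10,
                            gender_log_or = 0, missing_rate = 0,
                            max_n = 1e6) {
  assert_that(inherits(spec, "study_spec"), "'spec' must be a study_spec")
  assert_that(length(panel) >= 1, "'panel' must be non-empty")
  rsids <- vapply(panel, function(s) s$rsid, character(1))
  assert_that(!anyDuplicated(rsids), "panel rsids must be unique")
  n_need <- spec$n_cases + spec$n_controls
  assert_that(n_need <= max_n,
              sprintf("requested %d individuals exceeds max_n = %g", n_need, max_n))
  K <- length(panel)
  freq <- vapply(panel, function(s) s$allele_freq, numeric(1))
  beta <- vapply(panel, function(s) snp_log_or(s, spec$name), numeric(1))

  with_seed(seed, {
    # subpopulation allele frequencies (Balding-Nichols), clipped off {0,1}
    pf <- matrix(freq, nrow = 2, ncol = K, byrow = TRUE)
    if (spec$fst > 0) {
      a <- freq * (1 - spec$fst) / spec$fst
      b <- (1 - freq) * (1 - spec$fst) / spec$fst
      pf[1, ] <- rbeta(K, a, b)
      pf[2, ] <- rbeta(K, a, b)
      pf <- pmin(pmax(pf, 1e-4), 1 - 1e-4)
    }
    alpha <- qlogis(prevalence) - sum(2 * freq * beta) - 0.5 * gender_log_or

    cases <- list(); controls <- list()
    n_cs <- 0L; n_ct <- 0L
    batch <- ceiling(1.3 * max(spec$n_cases / prevalence,
                               spec$n_controls / (1 - prevalence)))
    batch <- min(batch, 5e5)
    for (round in 1:50) {
      if (n_cs >= spec$n_cases && n_ct >= spec$n_controls) break
      sub <- 1L + (runif(batch) < spec$substructure_fraction)
      G <- matrix(0L, batch, K)
      for (k in seq_len(K)) G[, k] <- rbinom(batch, 2L, pf[cbind(sub, k)])
      gender <- rbinom(batch, 1L, 0.5)
      eta <- alpha + drop(G %*% beta) + gender_log_or * gender
      y <- rbinom(batch, 1L, plogis(eta))
      take <- function(idx) list(G = G[idx, , drop = FALSE],
                                 gender = gender[idx], sub = sub[idx])
      cases[[round]] <- take(which(y == 1L))
      controls[[round]] <- take(which(y == 0L))
      n_cs <- n_cs + sum(y == 1L); n_ct <- n_ct + sum(y == 0L)
    }
    assert_that(n_cs >= spec$n_cases && n_ct >= spec$n_controls,
                "could not accumulate enough cases/controls; raise max_n or prevalence")
    bindpool <- function(lst) list(
      G = do.call(rbind, lapply(lst, `[[`, "G")),
      gender = unlist(lapply(lst, `[[`, "gender")),
      sub = unlist(lapply(lst, `[[`, "sub")))
    cs <- bindpool(cases); ct <- bindpool(controls)
    # pools are already in random order; take the first n of a random permutation
    ics <- sample.int(length(cs$gender))[seq_len(spec$n_cases)]
    ict <- sample.int(length(ct$gender))[seq_len(spec$n_controls)]
    G <- rbind(cs$G[ics, , drop = FALSE], ct$G[ict, , drop = FALSE])
    colnames(G) <- rsids
    gender <- c(cs$gender[ics], ct$gender[ict])
    sub <- c(cs$sub[ics], ct$sub[ict])
    phen <- rep(c(1L, 0L), c(spec$n_cases, spec$n_controls))
    if (missing_rate > 0)
      G[runif(length(G)) < missing_rate] <- NA_integer_

    structure(list(
      genotypes = G,
      phenotype = phen,
      gender = gender,
      cohort = rep(spec$name, n_need),
      subpop = sub,
      panel = data.frame(rsid = rsids,
                         effect_allele = vapply(panel, `[[`, character(1), "effect_allele"),
                         allele_freq = freq,
                         sim_log_or = beta,
                         stringsAsFactors = FALSE),
      spec = spec), class = "cohort_data")
  })
}

#' @export
print.cohort_data <- function(x, ...) {
  cat(sprintf("<cohort_data> %s: %d cases / %d controls, %d SNPs\n",
              x$spec$name, sum(x$phenotype == 1), sum(x$phenotype == 0),
              ncol(x$genotypes)))
  invisible(x)
}

#' Write / read a cohort as TSV plus a JSON panel sidecar
#'
#' The TSV has one row per individual with columns
#' `iid, phenotype, gender, cohort, <rsid1>, ..., <rsidK>`; genotypes are
#' counts of the effect allele (0/1/2) or `NA`. A `<path>.panel.json` sidecar
#' records the panel (rsid, effect allele, ancestral frequency). The hidden
#' `subpop` truth label is intentionally not serialized.
#'
#' @param cohort a `cohort_data` object.
#' @param path TSV output path.
#' @return `path` invisibly (writer); a `cohort_data` (reader, with
#'   `subpop = NA`).
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- data.frame(iid = sprintf("%s_%05d", cohort$spec$name,
                                 seq_along(cohort$phenotype)),
                   phenotype = cohort$phenotype,
                   gender = cohort$gender,
                   cohort = cohort$cohort,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(cohort$genotypes))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(panel = cohort$panel,
         spec = unclass(cohort$spec)),
    paste0(path, ".panel.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".panel.json"), simplifyVector = TRUE)
  panel <- side$panel
  G <- as.matrix(df[, panel$rsid, drop = FALSE])
  storage.mode(G) <- "integer"
  spec <- do.call(study_spec, side$spec[c("name", "cancer_type", "n_cases",
                                          "n_controls", "substructure_fraction",
                                          "fst")])
  structure(list(genotypes = G, phenotype = df$phenotype, gender = df$gender,
                 cohort = df$cohort, subpop = rep(NA_integer_, nrow(df)),
                 panel = panel, spec = spec),
            class = "cohort_data")
}
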