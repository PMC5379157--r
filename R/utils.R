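#' @keywords internal
"_PACKAGE"

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

z975 <- qnorm(0.975)  # 1.959964...

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Write a TSV with '#'-prefixed provenance header lines
#'
#' All pipeline outputs use this format: any number of `# key: value` comment
#' lines followed by a regular tab-separated table with a header row.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param meta named character vector or list written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    for (nm in names(meta))
      writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path file path.
#' @return data.frame; comment lines are skipped.
#' @export
read_tsv_meta <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
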