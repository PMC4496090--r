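#' Write a data frame as TSV with stable formatting
#'
#' Numeric columns are formatted with `sprintf("%.15g")` so repeated runs
#' produce byte-identical files regardless of print options.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @keywords internal
write_tsv_stable <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.15g", out[[j]])
    if (is.logical(out[[j]])) out[[j]] <- ifelse(out[[j]], "TRUE", "FALSE")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# format a number for graph labels / logs: compact, deterministic
fmt_num <- function(x, digits = 3) {
  formatC(signif(x, digits), format = "fg", flag = "#", digits = digits)
}

# run an expression with a locally-seeded RNG, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
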