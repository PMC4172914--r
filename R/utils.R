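# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
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

# Deterministic TSV writer: fixed decimal notation, no quoting, "NA" for
# missing, so identical inputs yield byte-identical files.
writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, format(x, digits = 15, scientific = FALSE,
                                           trim = TRUE))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

assertCount <- function(x, name) {
  if (length(x) == 0L || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop(name, " must be a nonnegative integer count")
  as.integer(x)
}
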