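# Internal utilities: seeded evaluation, tiny config hash, atomic TSV output.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded package functions never disturb the
#' caller's random stream. With `seed = NULL` the expression runs on the
#' current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Polynomial rolling hash of a deparsed R object, as 8 hex digits; used to
# stamp output headers with a config fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Write lines to `path` atomically (tempfile in the same directory + rename).
atomic_writelines <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

# Serialise a data.frame as TSV preceded by '#' comment header lines
# (tool version, stage, seed, config hash).
write_tsv_with_header <- function(df, path, stage, seed = NULL, config = list()) {
  version <- as.character(utils::packageVersion("trnaswitch"))
  hdr <- sprintf("# trnaswitch %s; stage=%s; seed=%s; config=%s",
                 version, stage, if (is.null(seed)) "NA" else seed,
                 config_hash(config))
  body <- c(paste(names(df), collapse = "\t"),
            if (nrow(df) > 0) apply(df, 1, function(r) paste(trimws(r), collapse = "\t")))
  atomic_writelines(c(hdr, body), path)
}

# Read back a TSV written by write_tsv_with_header.
read_tsv_with_header <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
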