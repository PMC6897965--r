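# internal helpers shared across modules

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# derive a child seed from a base seed and an index; kept < 2^31
#' @noRd
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(i)) %% 2147483647L)
}

# evaluate expr with a local RNG seed, restoring global state afterwards
#' @noRd
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647L), expr)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# comment header stamped into every output file: version + effective seed
#' @noRd
output_header <- function(seed = NULL) {
  ver <- as.character(utils::packageVersion("stemnet"))
  h <- sprintf("# stemnet %s", ver)
  if (!is.null(seed)) h <- sprintf("%s seed=%s", h, format(seed))
  h
}

# write a data.frame as TSV with an optional comment header, atomically
#' @noRd
write_tsv_atomic <- function(df, path, header = NULL) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, open = "wt")
  closed <- FALSE
  on.exit(if (!closed) try(close(con), silent = TRUE), add = TRUE)
  if (!is.null(header)) writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con); closed <- TRUE
  file.rename(tmp, path)
  invisible(path)
}

#' @noRd
read_tsv_comments <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
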