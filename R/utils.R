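# internal helpers shared across modules

# scalar integer-ish check
is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

assert_seed <- function(seed) {
  if (!is_count(seed)) {
    stop("`seed` is required and must be a single non-negative integer; ",
         "generators never default it from the clock.", call. = FALSE)
  }
  as.integer(seed %% .Machine$integer.max)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset) %% 2147483629
}

#' Write a tibble as TSV with a commented metadata header
#'
#' All tabular outputs of the package carry their provenance (parameters,
#' seed) as `#`-prefixed header lines so a run can be reconstructed from
#' its files.
#'
#' @param x data frame to write.
#' @param path output file path.
#' @param meta named list of scalar metadata written as `# key: value`.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(x, path, meta = list()) {
  lines <- character(0)
  if (length(meta)) {
    lines <- sprintf("# %s: %s", names(meta),
                     vapply(meta, function(v) paste(format(v), collapse = ","),
                            character(1)))
  }
  writeLines(lines, path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path file path.
#' @return a tibble; the parsed `# key: value` header is attached as the
#'   `"meta"` attribute.
#' @export
read_tsv_meta <- function(path) {
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    hdr <- c(hdr, ln)
  }
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  meta <- list()
  if (length(hdr)) {
    kv <- stringr::str_match(hdr, "^#\\s*([^:]+):\\s*(.*)$")
    meta <- as.list(setNames(kv[, 3], trimws(kv[, 2])))
  }
  attr(x, "meta") <- meta
  x
}
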