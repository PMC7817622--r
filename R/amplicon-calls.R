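# Per-read CpG calling, QC filtering, methylation summaries, pattern
# maps and read classification.

#' Call per-read CpG methylation states
#'
#' Aligns reads (see [align_reads()]) and reads back the original
#' (unconverted) base at every reference CpG column: C is a methylated
#' call (`M`), T an unmethylated call (`U`), any other base or a gap is
#' missing (`.`). Per read, the bisulfite conversion rate is the
#' fraction of non-CpG reference-C columns observed as T (C counts as
#' unconverted, other bases are ignored), identity is the fraction of
#' matching aligned non-C reference columns, and CpG coverage is the
#' fraction of design CpGs with a non-missing call.
#'
#' @inheritParams align_reads
#' @return a `read_calls` tibble: `read_id`, `pattern` (M/U/. string,
#'   one character per design CpG), `conversion_rate`, `identity`,
#'   `cpg_coverage`, `orientation`, `score`. Dropped reads are recorded
#'   in the `"dropped"` attribute, CpG positions in `"cpg_positions"`.
#' @export
call_reads <- function(reads, design, min_length = 30,
                       min_score_per_base = 0.5) {
  conv <- convert_reference(design)
  aln <- align_reads(reads, design, min_length = min_length,
                     min_score_per_base = min_score_per_base)
  rb <- aln$ref_bases
  n <- nrow(rb)
  ref_chars <- strsplit(design$reference, "")[[1]]

  cpg <- rb[, conv$cpg_columns, drop = FALSE]
  calls <- matrix(".", nrow(cpg), ncol(cpg))
  calls[cpg == "C"] <- "M"
  calls[cpg == "T"] <- "U"

  ncc <- rb[, conv$non_cpg_c_columns, drop = FALSE]
  n_conv <- rowSums(ncc == "T", na.rm = TRUE)
  n_unconv <- rowSums(ncc == "C", na.rm = TRUE)
  conv_rate <- ifelse(n_conv + n_unconv > 0, n_conv / (n_conv + n_unconv),
                      NA_real_)

  non_c <- which(ref_chars != "C")
  nb <- rb[, non_c, drop = FALSE]
  ref_row <- matrix(rep(ref_chars[non_c], each = n), n, length(non_c))
  covered <- !is.na(nb)
  n_match <- rowSums(covered & nb == ref_row, na.rm = TRUE)
  n_cov <- rowSums(covered)
  identity <- ifelse(n_cov > 0, n_match / n_cov, NA_real_)

  out <- tibble(
    read_id = aln$alignments$read_id,
    pattern = apply(calls, 1L, paste0, collapse = ""),
    conversion_rate = conv_rate,
    identity = identity,
    cpg_coverage = rowMeans(calls != "."),
    orientation = aln$alignments$orientation,
    score = aln$alignments$score
  )
  new_read_calls(out, design, dropped = aln$dropped)
}

new_read_calls <- function(x, design, dropped) {
  structure(x, class = c("read_calls", class(tibble())),
            cpg_positions = design$cpg_positions,
            amplicon = design$name, dropped = dropped)
}

calls_matrix <- function(calls) {
  m <- do.call(rbind, strsplit(calls$pattern, ""))
  if (is.null(m)) m <- matrix(character(0), 0,
                              length(attr(calls, "cpg_positions")))
  rownames(m) <- calls$read_id
  m
}

#' QC-filter a read call table
#'
#' Retains reads passing all three thresholds; counts per rejection
#' reason are attached as the `"filter_log"` attribute (a read failing
#' several thresholds is counted under each). Filtering is idempotent.
#'
#' @param calls a `read_calls` tibble from [call_reads()].
#' @param min_conversion minimum bisulfite conversion rate.
#' @param min_identity minimum alignment identity over non-C columns.
#' @param min_cpg_coverage minimum fraction of CpGs with a call.
#' @return the retained `read_calls` rows; warns if nothing survives.
#' @export
filter_reads <- function(calls, min_conversion = 0.95, min_identity = 0.9,
                         min_cpg_coverage = 0.8) {
  stopifnot(inherits(calls, "read_calls"))
  fail_conv <- !is.na(calls$conversion_rate) &
    calls$conversion_rate < min_conversion
  fail_id <- !is.na(calls$identity) & calls$identity < min_identity
  fail_cov <- calls$cpg_coverage < min_cpg_coverage
  keep <- !(fail_conv | fail_id | fail_cov)
  out <- calls[keep, , drop = FALSE]
  attr(out, "cpg_positions") <- attr(calls, "cpg_positions")
  attr(out, "amplicon") <- attr(calls, "amplicon")
  attr(out, "dropped") <- attr(calls, "dropped")
  attr(out, "filter_log") <- tibble(
    reason = c("incomplete_conversion", "low_identity", "low_cpg_coverage"),
    n = c(sum(fail_conv), sum(fail_id), sum(fail_cov))
  )
  if (!nrow(out)) {
    warning("all reads rejected by QC filtering; downstream summaries ",
            "will be empty", call. = FALSE)
  }
  out
}

#' Summarise methylation over a read call table
#'
#' Per CpG, mean methylation is `M / (M + U)` in percent (missing calls
#' excluded); the overall mean pools all non-missing calls. A CpG with
#' no non-missing call is reported as `NA`.
#'
#' @param calls a `read_calls` tibble.
#' @return a `meth_summary` tibble (`cpg_index`, `position`, `n_meth`,
#'   `n_unmeth`, `mean_meth_pct`) with attributes `overall_meth_pct` and
#'   `n_reads`; see [glance.meth_summary()].
#' @export
summarize_methylation <- function(calls) {
  stopifnot(inherits(calls, "read_calls"))
  if (!nrow(calls)) stop("no reads to summarise", call. = FALSE)
  m <- calls_matrix(calls)
  n_meth <- colSums(m == "M")
  n_unmeth <- colSums(m == "U")
  per <- tibble(
    cpg_index = seq_along(n_meth),
    position = attr(calls, "cpg_positions"),
    n_meth = n_meth, n_unmeth = n_unmeth,
    mean_meth_pct = ifelse(n_meth + n_unmeth > 0,
                           100 * n_meth / (n_meth + n_unmeth), NA_real_)
  )
  structure(per, class = c("meth_summary", class(tibble())),
            overall_meth_pct = 100 * sum(n_meth) / sum(n_meth + n_unmeth),
            n_reads = nrow(calls))
}

#' One-row overview of a methylation summary
#'
#' @param x a `meth_summary` from [summarize_methylation()].
#' @param ... unused.
#' @return tibble with `overall_meth_pct`, `n_reads`, `n_cpgs`.
#' @method glance meth_summary
#' @export
glance.meth_summary <- function(x, ...) {
  tibble(overall_meth_pct = attr(x, "overall_meth_pct"),
         n_reads = attr(x, "n_reads"),
         n_cpgs = nrow(x))
}

#' Order reads into a pattern map
#'
#' Reorders the call table for display as a read x CpG pattern map
#' (the per-molecule methylation "lollipop" view). The default key
#' sorts by per-read mean methylation, descending, with ties broken by
#' the pattern string; content is the input rows, reordered only.
#'
#' @param calls a `read_calls` tibble.
#' @param order `"mean_desc"` (default) or `"input"`.
#' @return a `pattern_map` tibble (the reordered calls); plot with
#'   [autoplot.pattern_map()].
#' @export
pattern_map <- function(calls, order = c("mean_desc", "input")) {
  stopifnot(inherits(calls, "read_calls"))
  order <- match.arg(order)
  if (!nrow(calls)) stop("no reads to map", call. = FALSE)
  out <- calls
  if (order == "mean_desc") {
    m <- calls_matrix(calls)
    frac <- rowSums(m == "M") / pmax(1, rowSums(m != "."))
    out <- calls[order(-frac, calls$pattern, method = "radix"), ,
                 drop = FALSE]
  }
  structure(out, class = unique(c("pattern_map", class(calls))),
            cpg_positions = attr(calls, "cpg_positions"),
            amplicon = attr(calls, "amplicon"),
            order = order)
}

#' Classify reads by their methylated fraction
#'
#' Per read, the methylated fraction over non-missing calls classifies
#' the molecule: `<= lo` fully demethylated, `>= hi` fully methylated,
#' otherwise heterogeneous — the read-level distinction between
#' complete demethylation and the heterogeneous patterns produced by
#' partial editing.
#'
#' @param calls a `read_calls` tibble.
#' @param lo,hi classification thresholds on the methylated fraction.
#' @return tibble (`class`, `n`, `fraction`) with the per-read
#'   assignment in attribute `"per_read"` and thresholds in
#'   `"thresholds"`.
#' @export
classify_reads <- function(calls, lo = 0.1, hi = 0.9) {
  stopifnot(inherits(calls, "read_calls"), lo < hi)
  if (!nrow(calls)) stop("no reads to classify", call. = FALSE)
  m <- calls_matrix(calls)
  frac <- rowSums(m == "M") / pmax(1, rowSums(m != "."))
  cls <- dplyr::case_when(
    frac <= lo ~ "fully_demethylated",
    frac >= hi ~ "fully_methylated",
    TRUE ~ "heterogeneous"
  )
  lv <- c("fully_demethylated", "heterogeneous", "fully_methylated")
  profile <- tibble(class = lv,
                    n = as.integer(table(factor(cls, levels = lv)))) |>
    mutate(fraction = .data$n / sum(.data$n))
  structure(profile,
            per_read = tibble(read_id = calls$read_id,
                              meth_fraction = frac, class = cls),
            thresholds = c(lo = lo, hi = hi))
}
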