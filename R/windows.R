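# Genomic window sets: BED I/O, flank extension, top-N off-target
# selection and probe membership. All coordinates are 0-based half-open.

validate_windows <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end") %in% names(windows)))
  if (nrow(windows) && any(windows$start < 0 | windows$start >= windows$end)) {
    stop("windows must satisfy 0 <= start < end", call. = FALSE)
  }
  invisible(windows)
}

#' Read a BED file as a window tibble
#'
#' @param path BED path (0-based half-open, as the format defines).
#' @return tibble `chrom`, `start`, `end` and, when present, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr))
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write a window tibble as BED
#'
#' @param windows tibble with `chrom`, `start`, `end` and optional
#'   `name`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(windows, path) {
  validate_windows(windows)
  gr <- windows_to_granges(windows)
  if (!is.null(windows$name)) gr$name <- windows$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

# 0-based half-open tibble -> 1-based closed GRanges
windows_to_granges <- function(windows) {
  GenomicRanges::GRanges(
    seqnames = windows$chrom,
    ranges = IRanges::IRanges(start = windows$start + 1L, end = windows$end))
}

#' Extend windows by a symmetric flank
#'
#' Each window `(start, end)` becomes `(max(0, start - flank),
#' end + flank)`; the window count and per-chromosome order are
#' preserved and overlapping results are not merged.
#'
#' @param windows window tibble (`chrom`, `start`, `end`, ...).
#' @param flank non-negative flank in bp (default 1000, i.e. 1 kb up-
#'   and downstream).
#' @return the extended window tibble.
#' @export
extend_windows <- function(windows, flank = 1000) {
  validate_windows(windows)
  stopifnot(flank >= 0)
  mutate(windows,
         start = pmax(0L, as.integer(.data$start - flank)),
         end = as.integer(.data$end + flank))
}

#' Keep the top-scoring predicted off-target regions per sgRNA
#'
#' Retains, for every sgRNA, the `top_n` highest-scoring predicted
#' regions. Score ties at the cutoff are all kept (deterministic, no
#' arbitrary drops; logged via message). sgRNAs with fewer than `top_n`
#' predictions contribute everything they have, with a warning.
#'
#' @param predictions tibble with `sgrna`, `chrom`, `start`, `end`,
#'   `score`.
#' @param top_n predictions retained per sgRNA (default 50).
#' @return window tibble (`chrom`, `start`, `end`, `name` =
#'   `sgrna:rank`), sorted per chromosome.
#' @export
select_top_offtargets <- function(predictions, top_n = 50) {
  stopifnot(is.data.frame(predictions),
            all(c("sgrna", "chrom", "start", "end", "score") %in%
                  names(predictions)),
            is_count(top_n, 1))
  short <- predictions |>
    count(.data$sgrna) |>
    filter(.data$n < top_n)
  if (nrow(short)) {
    warning("sgRNA(s) with fewer than ", top_n, " predictions: ",
            paste(short$sgrna, collapse = ", "),
            "; all their predictions retained", call. = FALSE)
  }
  kept <- predictions |>
    group_by(.data$sgrna) |>
    mutate(.rank = dplyr::min_rank(dplyr::desc(.data$score))) |>
    filter(.data$.rank <= top_n) |>
    ungroup()
  n_ties <- nrow(kept) - sum(pmin(top_n, dplyr::count(predictions,
                                                      .data$sgrna)$n))
  if (n_ties > 0) {
    message(n_ties, " tied region(s) at the top-", top_n,
            " boundary retained")
  }
  kept |>
    mutate(name = paste0(.data$sgrna, ":", .data$.rank)) |>
    select("chrom", "start", "end", "name") |>
    arrange(.data$chrom, .data$start)
}

#' Probes covered by a window set
#'
#' A probe belongs to the set iff its position falls in any window
#' (half-open test, `pos` in `[start, end)`); overlapping windows count
#' a probe once. Implemented over GenomicRanges interval overlap.
#'
#' @param manifest probe manifest tibble (`probe_id`, `chrom`, `pos`).
#' @param windows window tibble (`chrom`, `start`, `end`).
#' @return character vector of covered probe ids (manifest order).
#' @export
probes_in_windows <- function(manifest, windows) {
  validate_windows(windows)
  if (!nrow(windows)) return(character(0))
  unseen <- setdiff(unique(windows$chrom), unique(manifest$chrom))
  if (length(unseen)) {
    warning("window chromosome(s) absent from the manifest: ",
            paste(unseen, collapse = ", "), call. = FALSE)
    windows <- windows[!windows$chrom %in% unseen, , drop = FALSE]
    if (!nrow(windows)) return(character(0))
  }
  probes <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(probes, windows_to_granges(windows))
  manifest$probe_id[sort(unique(S4Vectors::queryHits(hits)))]
}
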