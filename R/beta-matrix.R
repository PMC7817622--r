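# Beta-value matrix container: probes x samples methylation fractions
# with a sample -> group mapping.

#' Construct a beta-value matrix
#'
#' @param beta numeric matrix, probes as rows (rownames = probe ids),
#'   samples as columns (colnames = sample ids); values in \[0,1\] or
#'   `NA`.
#' @param groups tibble with `sample` and `group`; every column of
#'   `beta` must appear exactly once.
#' @return a `beta_matrix` object.
#' @export
beta_matrix <- function(beta, groups) {
  stopifnot(is.matrix(beta), is.numeric(beta),
            !is.null(rownames(beta)), !is.null(colnames(beta)),
            is.data.frame(groups), all(c("sample", "group") %in% names(groups)))
  if (anyDuplicated(rownames(beta))) {
    stop("duplicate probe id in beta matrix", call. = FALSE)
  }
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value outside [0,1] at probe ", rownames(beta)[bad[1, 1]],
         ", sample ", colnames(beta)[bad[1, 2]], call. = FALSE)
  }
  if (anyDuplicated(groups$sample)) {
    stop("a sample is assigned to more than one group", call. = FALSE)
  }
  missing_s <- setdiff(colnames(beta), groups$sample)
  if (length(missing_s)) {
    stop("sample(s) missing from the group mapping: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  groups <- groups[match(colnames(beta), groups$sample), c("sample", "group")]
  structure(list(beta = beta, groups = as_tibble(groups)),
            class = "beta_matrix")
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("<beta_matrix> ", nrow(x$beta), " probes x ", ncol(x$beta),
      " samples\n", sep = "")
  print(dplyr::count(x$groups, .data$group))
  invisible(x)
}

#' @export
dim.beta_matrix <- function(x) dim(x$beta)

#' Long-format view of a beta matrix
#'
#' @param x a [beta_matrix()].
#' @param ... unused.
#' @return tibble with `probe_id`, `sample`, `group`, `beta`.
#' @method as_tibble beta_matrix
#' @export
as_tibble.beta_matrix <- function(x, ...) {
  as_tibble(x$beta, rownames = "probe_id") |>
    tidyr::pivot_longer(-"probe_id", names_to = "sample",
                        values_to = "beta") |>
    left_join(x$groups, by = "sample") |>
    select("probe_id", "sample", "group", "beta")
}

#' Write a beta matrix and its group mapping to TSV
#'
#' @param bm a [beta_matrix()].
#' @param beta_path,groups_path output paths.
#' @param meta optional named metadata list for the header.
#' @return invisibly, the two paths.
#' @export
write_beta <- function(bm, beta_path, groups_path, meta = list()) {
  wide <- as_tibble(bm$beta, rownames = "probe_id")
  write_tsv_meta(wide, beta_path, meta = meta)
  write_tsv_meta(bm$groups, groups_path, meta = meta)
  invisible(c(beta_path, groups_path))
}

#' Load and validate a beta matrix, manifest and group mapping
#'
#' Reads the three tab-separated inputs, validates beta values (any
#' value outside \[0,1\] is an error naming probe and sample; duplicate
#' probe ids are an error; samples absent from the group mapping are an
#' error) and drops probes absent from the manifest with a report.
#'
#' @param beta_path wide TSV, `probe_id` column plus one column per
#'   sample.
#' @param manifest_path TSV with `probe_id`, `chrom`, `pos`, `genes`.
#' @param groups_path TSV with `sample`, `group`.
#' @return list with `bm` (a [beta_matrix()]) and `manifest` (tibble);
#'   the number of probes rejected for missing annotation is attached as
#'   attribute `"n_unannotated"` on the result.
#' @export
load_beta <- function(beta_path, manifest_path, groups_path) {
  wide <- read_tsv_meta(beta_path)
  manifest <- read_tsv_meta(manifest_path)
  groups <- read_tsv_meta(groups_path)
  if (anyDuplicated(wide$probe_id)) {
    stop("duplicate probe id in beta file: ",
         wide$probe_id[duplicated(wide$probe_id)][1], call. = FALSE)
  }
  beta <- as.matrix(wide[setdiff(names(wide), "probe_id")])
  rownames(beta) <- wide$probe_id
  known <- rownames(beta) %in% manifest$probe_id
  if (any(!known)) {
    message(sum(!known), " probe(s) absent from the manifest were dropped")
    beta <- beta[known, , drop = FALSE]
  }
  out <- list(bm = beta_matrix(beta, groups), manifest = manifest)
  attr(out, "n_unannotated") <- sum(!known)
  out
}
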