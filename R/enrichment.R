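# Fisher-based enrichment procedures: CpG-subset enrichment within
# window-derived probe sets, and per-gene enrichment of top
# principal-component loadings with probe-count correction and FDR.

#' Fisher enrichment of a probe subset within a focal set
#'
#' Builds the 2x2 table `a = |subset & focal|`, `b = |subset \ focal|`,
#' `c = |focal \ subset|`, `d` = the remaining background, and applies
#' the two-sided Fisher exact test; direction follows the odds ratio.
#' Typical use: `subset` = probes covered by binding-site or off-target
#' windows, `focal` = the hypo-methylated probe set, `background` = all
#' probes analysed in the comparison.
#'
#' @param subset,focal character vectors of probe ids; both must be
#'   contained in `background`.
#' @param background character vector of all probe ids under
#'   consideration.
#' @return one-row tibble: the four cells, `odds_ratio`, `p_two_sided`,
#'   `direction`, plus `n_background`.
#' @export
subset_enrichment <- function(subset, focal, background) {
  if (!length(background)) stop("empty background", call. = FALSE)
  background <- unique(background)
  subset <- unique(subset)
  focal <- unique(focal)
  if (!all(subset %in% background) || !all(focal %in% background)) {
    stop("subset and focal must be contained in background", call. = FALSE)
  }
  a <- length(intersect(subset, focal))
  b <- length(subset) - a
  c <- length(focal) - a
  d <- length(background) - a - b - c
  fisher_exact(a, b, c, d) |>
    mutate(n_background = length(background))
}

#' Top-k probes by absolute component loading
#'
#' Probes "associated with" a principal component are ranked by the
#' magnitude of their loading on that component (signed alternatives via
#' `direction`); the top `k` are returned, ties broken by probe id for
#' determinism.
#'
#' @param pca a `meth_pca` from [pca_beta()].
#' @param component component name (e.g. `"PC1"`).
#' @param k number of probes (default 5000, the conventional top-CpG
#'   cut).
#' @param direction `"abs"` (default), `"positive"` or `"negative"`
#'   loadings.
#' @return character vector of probe ids, ranked.
#' @export
topk_loadings <- function(pca, component = "PC1", k = 5000,
                          direction = c("abs", "positive", "negative")) {
  stopifnot(inherits(pca, "meth_pca"), is_count(k, 1))
  direction <- match.arg(direction)
  if (!component %in% names(pca$loadings)) {
    stop("component not present: ", component, call. = FALSE)
  }
  l <- pca$loadings[[component]]
  key <- switch(direction, abs = abs(l), positive = l, negative = -l)
  if (k > length(l)) {
    warning("k exceeds the probe count; returning all probes",
            call. = FALSE)
    k <- length(l)
  }
  ord <- order(-key, pca$loadings$probe_id, method = "radix")
  pca$loadings$probe_id[ord[seq_len(k)]]
}

#' Per-gene enrichment of a CpG set, corrected for gene probe totals
#'
#' For every gene with at least one hit among `cpgs`, counts hits and
#' corrects for the total number of array probes annotated to the gene
#' via a two-sided Fisher test on `a` = hits, `b` = remaining focal
#' CpGs, `c` = remaining probes of the gene, `d` = remaining manifest,
#' followed by Benjamini-Hochberg FDR across the tested genes. Probes
#' annotated to several genes contribute one hit to each; unannotated
#' probes participate in the background only.
#'
#' @param cpgs character vector of focal probe ids (subset of the
#'   manifest).
#' @param manifest probe manifest tibble (`probe_id`, `genes`
#'   semicolon-joined).
#' @return tibble (`gene`, `hits`, `gene_total`, `odds_ratio`,
#'   `p_two_sided`, `q_fdr`, `direction`) ranked by `q_fdr`, then
#'   `p_two_sided`, then gene label.
#' @export
gene_enrichment <- function(cpgs, manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("probe_id", "genes") %in% names(manifest)))
  cpgs <- unique(cpgs)
  if (!all(cpgs %in% manifest$probe_id)) {
    stop("cpgs must be a subset of the manifest probes", call. = FALSE)
  }
  empty <- tibble(gene = character(0), hits = integer(0),
                  gene_total = integer(0), odds_ratio = numeric(0),
                  p_two_sided = numeric(0), q_fdr = numeric(0),
                  direction = character(0))
  if (!length(cpgs)) return(empty)

  ann <- manifest |>
    select("probe_id", "genes") |>
    filter(!is.na(.data$genes), .data$genes != "") |>
    tidyr::separate_rows("genes", sep = ";") |>
    rename(gene = "genes")
  totals <- count(ann, .data$gene, name = "gene_total")
  hits <- ann |>
    filter(.data$probe_id %in% cpgs) |>
    count(.data$gene, name = "hits")
  if (!nrow(hits)) return(empty)
  tab <- inner_join(hits, totals, by = "gene")
  if (any(tab$hits > tab$gene_total)) {
    stop("annotation inconsistency: more hits than gene probes",
         call. = FALSE)
  }
  N <- nrow(manifest)
  n_focal <- length(cpgs)
  res <- fisher_exact(tab$hits, n_focal - tab$hits,
                      tab$gene_total - tab$hits,
                      N - n_focal - tab$gene_total + tab$hits)
  out <- tibble(gene = tab$gene, hits = tab$hits,
                gene_total = tab$gene_total,
                odds_ratio = res$odds_ratio,
                p_two_sided = res$p_two_sided,
                q_fdr = bh_fdr(res$p_two_sided),
                direction = res$direction)
  arrange(out, .data$q_fdr, .data$p_two_sided, .data$gene)
}
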