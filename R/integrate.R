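# Integration of hypo-CpG-associated genes with differential-expression
# gene sets.

#' Simple two-group differential expression on log-scale values
#'
#' A lightweight differential-expression call for integration purposes:
#' per gene, a Welch two-sample t-test on log2-scale values with
#' Benjamini-Hochberg FDR; a gene enters the set iff `q <= q_max` and
#' the absolute mean log2 difference is at least `lfc_min`. Externally
#' computed gene lists (e.g. from a dedicated count-model package) can
#' be supplied to [annotate_and_intersect()] instead.
#'
#' @param expr tibble, `gene` column plus one numeric column per sample
#'   (log2 scale).
#' @param groups tibble with `sample` and `group`.
#' @param g1,g2 group labels; the reported `log2fc` is `g2 - g1`.
#' @param lfc_min minimum absolute mean log2 difference.
#' @param q_max maximum BH-FDR q-value.
#' @return a `de_result` object; `tidy()` gives the per-gene table,
#'   `glance()` the counts, [de_genes()] the selected gene set. Genes
#'   constant across all samples are excluded and counted.
#' @export
simple_de <- function(expr, groups, g1, g2, lfc_min = 1.0, q_max = 0.05) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr),
            all(c("sample", "group") %in% names(groups)))
  s1 <- groups$sample[groups$group == g1]
  s2 <- groups$sample[groups$group == g2]
  if (length(s1) < 2 || length(s2) < 2) {
    stop("each group needs at least 2 replicates", call. = FALSE)
  }
  m1 <- as.matrix(expr[s1])
  m2 <- as.matrix(expr[s2])
  constant <- apply(cbind(m1, m2), 1L, function(v) sd(v) == 0)
  p <- rep(NA_real_, nrow(expr))
  for (i in which(!constant)) {
    p[i] <- tryCatch(t.test(m1[i, ], m2[i, ])$p.value,
                     error = function(e) NA_real_)
  }
  usable <- !is.na(p)
  q <- rep(NA_real_, length(p))
  q[usable] <- bh_fdr(pmax(p[usable], .Machine$double.xmin))
  lfc <- rowMeans(m2) - rowMeans(m1)
  table <- tibble(gene = expr$gene,
                  mean_g1 = rowMeans(m1), mean_g2 = rowMeans(m2),
                  log2fc = lfc, p_value = p, q_fdr = q,
                  significant = usable & q <= q_max & abs(lfc) >= lfc_min)
  structure(list(table = table, g1 = g1, g2 = g2,
                 lfc_min = lfc_min, q_max = q_max,
                 n_excluded = sum(!usable)),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> ", x$g2, " vs ", x$g1, ": ",
      sum(x$table$significant), " / ", nrow(x$table),
      " genes at |log2fc| >= ", x$lfc_min, ", q <= ", x$q_max,
      " (", x$n_excluded, " constant/untestable excluded)\n", sep = "")
  invisible(x)
}

#' @rdname simple_de
#' @param x a `de_result` object.
#' @param ... unused.
#' @method tidy de_result
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname simple_de
#' @method glance de_result
#' @export
glance.de_result <- function(x, ...) {
  tibble(n_genes = nrow(x$table), n_de = sum(x$table$significant),
         n_excluded = x$n_excluded, lfc_min = x$lfc_min, q_max = x$q_max)
}

#' @rdname simple_de
#' @param de a `de_result` object.
#' @export
de_genes <- function(de) {
  stopifnot(inherits(de, "de_result"))
  de$table$gene[de$table$significant]
}

#' Annotate hypo-CpGs to genes and intersect with gene sets
#'
#' Maps a hypo-methylated probe set to gene labels via the manifest
#' annotation, then intersects the resulting gene set sequentially with
#' each supplied differential-expression gene set, reporting size and
#' membership at every step (the "Treg genes" logic: genes both
#' enriched with hypo-CpGs and differentially expressed).
#'
#' @param hypo_cpgs character vector of probe ids.
#' @param manifest probe manifest tibble (`probe_id`, `genes`).
#' @param de_sets named list of character vectors (gene sets).
#' @param normalize_case if `TRUE`, gene labels are upper-cased before
#'   matching; default is case-sensitive exact matching.
#' @return tibble (`step`, `name`, `n`, `genes` list-column): step 0 is
#'   the annotated hypo gene set, each following row one intersection.
#' @export
annotate_and_intersect <- function(hypo_cpgs, manifest, de_sets = list(),
                                   normalize_case = FALSE) {
  stopifnot(is.data.frame(manifest),
            all(c("probe_id", "genes") %in% names(manifest)))
  norm <- if (normalize_case) toupper else identity
  hypo_genes <- manifest |>
    filter(.data$probe_id %in% hypo_cpgs,
           !is.na(.data$genes), .data$genes != "") |>
    pull("genes") |>
    strsplit(";") |>
    unlist() |>
    norm() |>
    unique()
  steps <- tibble(step = 0L, name = "hypo_genes",
                  n = length(hypo_genes), genes = list(hypo_genes))
  current <- hypo_genes
  for (i in seq_along(de_sets)) {
    current <- intersect(current, norm(de_sets[[i]]))
    steps <- bind_rows(steps, tibble(
      step = i, name = names(de_sets)[i] %||% paste0("set", i),
      n = length(current), genes = list(current)))
  }
  steps
}
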