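# Beta-matrix analytics: delta-threshold differential methylation,
# locus clustering and principal component analysis.

group_columns <- function(bm, group) {
  s <- bm$groups$sample[bm$groups$group == group]
  if (!length(s)) stop("unknown or empty group: ", group, call. = FALSE)
  s
}

#' Delta-threshold differential methylation between two groups
#'
#' Computes per-probe group-mean beta values and the signed difference
#' `delta = mean(reference) - mean(treatment)`, so that probes
#' de-methylated in the treatment group ("hypo" probes) have
#' `delta >= threshold` and hyper-methylated probes `delta <=
#' -threshold`. Probes with any missing value in either group are
#' excluded (complete-case) and counted. The Pearson correlation of the
#' two mean vectors summarises global concordance.
#'
#' @param bm a [beta_matrix()].
#' @param reference,treatment group labels; delta is reference minus
#'   treatment.
#' @param threshold absolute delta threshold for set membership
#'   (default 0.2).
#' @return a `meth_diff` object; `tidy()` gives the per-probe table
#'   (`probe_id`, `mean_reference`, `mean_treatment`, `delta`,
#'   `status` in hypo/hyper/none), `glance()` the set sizes, Pearson r
#'   and threshold.
#' @export
compare_groups <- function(bm, reference, treatment, threshold = 0.2) {
  stopifnot(inherits(bm, "beta_matrix"), threshold >= 0)
  s1 <- group_columns(bm, reference)
  s2 <- group_columns(bm, treatment)
  sub <- bm$beta[, c(s1, s2), drop = FALSE]
  complete <- stats::complete.cases(sub)
  n_dropped <- sum(!complete)
  sub <- sub[complete, , drop = FALSE]
  if (!nrow(sub)) stop("no complete-case probes in the two groups",
                       call. = FALSE)
  m1 <- rowMeans(sub[, s1, drop = FALSE])
  m2 <- rowMeans(sub[, s2, drop = FALSE])
  delta <- m1 - m2
  table <- tibble(
    probe_id = rownames(sub),
    mean_reference = m1, mean_treatment = m2, delta = delta,
    status = dplyr::case_when(delta >= threshold ~ "hypo",
                              delta <= -threshold ~ "hyper",
                              TRUE ~ "none")
  )
  structure(
    list(table = table,
         pearson_r = if (sd(m1) > 0 && sd(m2) > 0) cor(m1, m2) else NA_real_,
         threshold = threshold, reference = reference,
         treatment = treatment, n_dropped = n_dropped),
    class = "meth_diff"
  )
}

#' @export
print.meth_diff <- function(x, ...) {
  g <- glance(x)
  cat("<meth_diff> ", x$reference, " vs ", x$treatment,
      " (delta threshold ", x$threshold, ")\n",
      "  probes: ", g$n_probes, " (", x$n_dropped, " dropped incomplete)\n",
      "  hypo: ", g$n_hypo, "   hyper: ", g$n_hyper,
      "   Pearson r: ", round(g$pearson_r, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname compare_groups
#' @param x a `meth_diff` object.
#' @param ... unused.
#' @method tidy meth_diff
#' @export
tidy.meth_diff <- function(x, ...) x$table

#' @rdname compare_groups
#' @method glance meth_diff
#' @export
glance.meth_diff <- function(x, ...) {
  tibble(n_probes = nrow(x$table),
         n_hypo = sum(x$table$status == "hypo"),
         n_hyper = sum(x$table$status == "hyper"),
         pearson_r = x$pearson_r,
         threshold = x$threshold,
         n_dropped = x$n_dropped)
}

#' Probe ids of the hypo- or hyper-methylated set
#'
#' @param diff a `meth_diff` object.
#' @param which `"hypo"` or `"hyper"`.
#' @return character vector of probe ids.
#' @export
diff_set <- function(diff, which = c("hypo", "hyper")) {
  which <- match.arg(which)
  diff$table$probe_id[diff$table$status == which]
}

#' Hierarchical clustering of samples over one locus
#'
#' Euclidean distances between the samples' beta vectors over the
#' complete-case probes of a genomic region, agglomerated with the
#' chosen linkage.
#'
#' @param bm a [beta_matrix()].
#' @param manifest probe manifest tibble (`probe_id`, `chrom`, `pos`).
#' @param chrom chromosome label.
#' @param start,end 0-based half-open interval.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list (class `locus_clust`) with the `hclust` object,
#'   `ordered_samples` and the region probe count.
#' @export
locus_cluster <- function(bm, manifest, chrom, start, end,
                          linkage = "average") {
  stopifnot(inherits(bm, "beta_matrix"), ncol(bm$beta) >= 2)
  probes <- manifest$probe_id[manifest$chrom == chrom &
                                manifest$pos >= start & manifest$pos < end]
  probes <- intersect(probes, rownames(bm$beta))
  if (!length(probes)) stop("no probes in the requested region",
                            call. = FALSE)
  sub <- bm$beta[probes, , drop = FALSE]
  sub <- sub[stats::complete.cases(sub), , drop = FALSE]
  if (!nrow(sub)) stop("no complete-case probes in the requested region",
                       call. = FALSE)
  hc <- hclust(dist(t(sub)), method = linkage)
  structure(list(hclust = hc,
                 ordered_samples = hc$labels[hc$order],
                 n_probes = nrow(sub), region = c(chrom, start, end),
                 linkage = linkage),
            class = "locus_clust")
}

#' Principal component analysis of a beta matrix
#'
#' Samples are observations and probes features; features are centred
#' but not scaled and the decomposition is computed by singular value
#' decomposition, with a deterministic sign convention (the
#' largest-magnitude loading of each component is made positive).
#' Probes with any missing value are dropped (complete-case) and
#' counted; numerically null components (singular value below 1e-8 of
#' the largest, e.g. the direction consumed by centring) are not
#' returned, while variance fractions are computed over the full
#' spectrum.
#'
#' @param bm a [beta_matrix()].
#' @return a `meth_pca` object; `tidy()` returns per-sample scores
#'   (default) or per-probe `loadings` / `variance` fractions via the
#'   `matrix` argument, `glance()` the dimensions and variance of the
#'   leading components.
#' @export
pca_beta <- function(bm) {
  stopifnot(inherits(bm, "beta_matrix"), ncol(bm$beta) >= 2)
  complete <- stats::complete.cases(bm$beta)
  n_dropped <- sum(!complete)
  B <- bm$beta[complete, , drop = FALSE]
  if (nrow(B) < 2) stop("fewer than 2 complete-case probes", call. = FALSE)
  X <- t(B)                                  # samples x probes
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc)
  keep <- sv$d > sv$d[1] * 1e-8
  prop <- sv$d^2 / sum(sv$d^2)
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  d <- sv$d[keep]
  for (j in seq_along(d)) {                  # sign convention
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  pcs <- paste0("PC", seq_along(d))
  scores <- U %*% diag(d, length(d))
  dimnames(scores) <- list(rownames(X), pcs)
  dimnames(V) <- list(rownames(B), pcs)
  structure(
    list(scores = bind_cols(bm$groups,
                            as_tibble(scores)),
         loadings = as_tibble(V, rownames = "probe_id"),
         variance = tibble(component = pcs, sdev = d / sqrt(max(1, nrow(X) - 1)),
                           prop_variance = prop[keep]),
         n_probes = nrow(B), n_dropped = n_dropped),
    class = "meth_pca"
  )
}

#' @export
print.meth_pca <- function(x, ...) {
  cat("<meth_pca> ", nrow(x$scores), " samples x ", x$n_probes,
      " probes (", x$n_dropped, " dropped incomplete)\n", sep = "")
  print(x$variance)
  invisible(x)
}

#' @rdname pca_beta
#' @param x a `meth_pca` object.
#' @param matrix which table to return: `"scores"`, `"loadings"` or
#'   `"variance"`.
#' @param ... unused.
#' @method tidy meth_pca
#' @export
tidy.meth_pca <- function(x, matrix = c("scores", "loadings", "variance"),
                          ...) {
  switch(match.arg(matrix),
         scores = x$scores, loadings = x$loadings, variance = x$variance)
}

#' @rdname pca_beta
#' @method glance meth_pca
#' @export
glance.meth_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores), n_probes = x$n_probes,
         n_components = nrow(x$variance),
         prop_variance_pc1 = x$variance$prop_variance[1],
         prop_variance_pc2 = if (nrow(x$variance) > 1)
           x$variance$prop_variance[2] else NA_real_)
}
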