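# EPIC-like array simulators: probe manifest, replicate beta matrices
# with planted hypo/hyper sets, region sets with planted overlap odds,
# and expression tables with planted differential genes. Every generator
# takes a mandatory seed and returns its ground truth.

#' Simulate an EPIC-like probe manifest
#'
#' Probes are laid out on synthetic chromosomes with sorted, unique
#' positions. Gene annotation mimics an array manifest: genes occupy
#' contiguous probe runs whose sizes follow a shifted negative-binomial
#' distribution, a fraction of probes is intergenic (no gene label) and a
#' small fraction carries a second, overlapping gene label
#' (semicolon-joined). The default scale matches the number of
#' methylation sites interrogated by the EPIC array (865,859).
#'
#' @param n_probes number of probes (default the full EPIC scale).
#' @param n_chrom number of synthetic chromosomes.
#' @param mean_probes_per_gene mean probes per annotated gene.
#' @param p_intergenic fraction of probes with no gene label.
#' @param p_multi fraction of annotated probes with a second gene label.
#' @param mean_gap mean genomic spacing between adjacent probes (bp).
#' @param seed required integer seed.
#' @return tibble (`probe_id`, `chrom`, `pos`, `genes`); `genes` is a
#'   semicolon-joined label string, `NA` for intergenic probes.
#' @export
simulate_probe_manifest <- function(n_probes = 865859, n_chrom = 22,
                                    mean_probes_per_gene = 8,
                                    p_intergenic = 0.15, p_multi = 0.02,
                                    mean_gap = 5000, seed) {
  stopifnot(is_count(n_probes, 1), is_count(n_chrom, 1))
  seed <- assert_seed(seed)
  withr::local_seed(seed)

  per_chrom <- diff(round(seq(0, n_probes, length.out = n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(nc) {
    if (nc == 0) return(integer(0))
    sort(sample.int(max(nc * mean_gap, nc), nc)) - 1L
  }), use.names = FALSE)

  # contiguous gene runs along the manifest
  sizes <- rnbinom(n_probes, mu = mean_probes_per_gene - 1, size = 2) + 1L
  sizes <- sizes[cumsum(sizes) <= n_probes]
  if (sum(sizes) < n_probes) sizes <- c(sizes, n_probes - sum(sizes))
  gene_id <- rep(sprintf("G%06d", seq_along(sizes)), sizes)
  genes <- gene_id
  genes[runif(n_probes) < p_intergenic] <- NA_character_
  second <- !is.na(genes) & runif(n_probes) < p_multi
  if (any(second)) {
    partner <- sprintf("G%06d",
                       pmin(length(sizes),
                            match(genes[second], unique(gene_id)) + 1L))
    genes[second] <- paste(genes[second], partner, sep = ";")
  }

  tibble(
    probe_id = sprintf("cg%08d", seq_len(n_probes)),
    chrom = chrom, pos = pos, genes = genes
  )
}

#' Simulate replicate beta matrices with planted differential sets
#'
#' Per-probe baseline methylation is drawn from a bimodal mixture of two
#' beta distributions (the classical two-peak array profile). For each
#' planted probe/group the signed `delta` effect is added to the group
#' mean; planted baselines are drawn from the sub-interval of \[0,1\]
#' that can absorb the full effect, so planted differences are realised
#' undistorted by clamping. Replicates are the group mean plus additive
#' Gaussian noise, clamped to \[0,1\]; missing entries are injected at
#' `missing_rate`.
#'
#' @param manifest probe manifest tibble (see
#'   [simulate_probe_manifest()]).
#' @param groups named integer vector: replicate count per group.
#' @param planted tibble with `probe_id`, `group`, `delta` (signed effect
#'   added to that group's mean), or `NULL` for a pure null matrix.
#' @param baseline_weight_high weight of the high-methylation mixture
#'   peak.
#' @param baseline_shape shape parameter of the two beta peaks
#'   (`Beta(shape, 8)` low, `Beta(8, shape)` high with `shape = 2`).
#' @param noise_sd replicate noise standard deviation.
#' @param missing_rate probability any single entry is missing.
#' @param seed required integer seed.
#' @return list with `bm` (a [beta_matrix()]) and `truth` (tibble
#'   `probe_id`, `group`, `delta`, `baseline`).
#' @export
simulate_beta_matrix <- function(manifest, groups = c(ctrl = 3, treat = 3),
                                 planted = NULL,
                                 baseline_weight_high = 0.5,
                                 baseline_shape = 2,
                                 noise_sd = 0.03, missing_rate = 0, seed) {
  stopifnot(is.data.frame(manifest), !is.null(names(groups)),
            all(groups >= 1))
  seed <- assert_seed(seed)
  withr::local_seed(seed)
  n <- nrow(manifest)

  hi <- runif(n) < baseline_weight_high
  baseline <- ifelse(hi, rbeta(n, 8, baseline_shape),
                     rbeta(n, baseline_shape, 8))

  if (!is.null(planted)) {
    stopifnot(all(c("probe_id", "group", "delta") %in% names(planted)))
    idx <- match(planted$probe_id, manifest$probe_id)
    if (anyNA(idx)) stop("planted probe_id not present in manifest",
                         call. = FALSE)
    if (!all(planted$group %in% names(groups))) {
      stop("planted group not present in the group design", call. = FALSE)
    }
    lo <- pmax(0.02, 0.02 - planted$delta)
    hi_b <- pmin(0.98, 0.98 - planted$delta)
    if (any(lo >= hi_b)) {
      stop("planted delta leaves no feasible baseline in [0,1]",
           call. = FALSE)
    }
    baseline[idx] <- lo + runif(nrow(planted)) * (hi_b - lo)
  }

  samples <- unlist(lapply(names(groups), function(g) {
    paste(g, seq_len(groups[[g]]), sep = "_")
  }))
  grp_of <- rep(names(groups), groups)

  means <- matrix(baseline, n, length(groups),
                  dimnames = list(manifest$probe_id, names(groups)))
  if (!is.null(planted)) {
    idx <- match(planted$probe_id, manifest$probe_id)
    means[cbind(idx, match(planted$group, names(groups)))] <-
      baseline[idx] + planted$delta
  }

  beta <- means[, match(grp_of, names(groups)), drop = FALSE]
  if (noise_sd > 0) beta <- beta + rnorm(length(beta), sd = noise_sd)
  beta <- pmin(pmax(beta, 0), 1)   # args ordered to preserve dim
  if (missing_rate > 0) beta[runif(length(beta)) < missing_rate] <- NA_real_
  dimnames(beta) <- list(manifest$probe_id, samples)

  truth <- if (is.null(planted)) {
    tibble(probe_id = character(0), group = character(0),
           delta = numeric(0), baseline = numeric(0))
  } else {
    tibble(probe_id = planted$probe_id, group = planted$group,
           delta = planted$delta,
           baseline = baseline[match(planted$probe_id, manifest$probe_id)])
  }

  list(bm = beta_matrix(beta, tibble(sample = samples, group = grp_of)),
       truth = truth)
}

#' Simulate genomic window sets with a planted coverage odds
#'
#' Places `n_regions` small windows, each centred on a manifest probe;
#' centre probes are drawn with sampling weight `odds` for probes in
#' `enriched_in` and 1 otherwise, so the odds of a window covering an
#' `enriched_in` probe equals the configured odds in expectation
#' (`odds = 1` gives a null set). A scored off-target-style prediction
#' list over the same windows is emitted for top-N selection.
#'
#' @param manifest probe manifest tibble.
#' @param enriched_in character vector of probe ids the windows should
#'   favour.
#' @param odds sampling odds (> 0) for `enriched_in` probes.
#' @param n_regions number of windows.
#' @param halfwidth half-width of each window around the probe (bp).
#' @param n_sgrna number of sgRNA labels cycled over the scored list.
#' @param seed required integer seed.
#' @return list with `windows` (tibble `chrom`, `start`, `end`, `name`,
#'   sorted per chromosome), `scored` (tibble `sgrna`, `chrom`, `start`,
#'   `end`, `score`) and `truth` (tibble `name`, `probe_id`,
#'   `enriched`).
#' @export
simulate_region_sets <- function(manifest, enriched_in = character(0),
                                 odds = 1, n_regions, halfwidth = 50,
                                 n_sgrna = 12, seed) {
  stopifnot(odds > 0, is_count(n_regions))
  seed <- assert_seed(seed)
  withr::local_seed(seed)
  if (n_regions == 0) {
    empty <- tibble(chrom = character(0), start = integer(0),
                    end = integer(0), name = character(0))
    return(list(windows = empty,
                scored = tibble(sgrna = character(0), chrom = character(0),
                                start = integer(0), end = integer(0),
                                score = numeric(0)),
                truth = tibble(name = character(0), probe_id = character(0),
                               enriched = logical(0))))
  }
  w <- ifelse(manifest$probe_id %in% enriched_in, odds, 1)
  pick <- sample.int(nrow(manifest), n_regions, prob = w)
  windows <- tibble(
    chrom = manifest$chrom[pick],
    start = pmax(0L, manifest$pos[pick] - as.integer(halfwidth)),
    end = manifest$pos[pick] + as.integer(halfwidth) + 1L,
    name = sprintf("region_%05d", seq_len(n_regions))
  )
  truth <- tibble(name = windows$name,
                  probe_id = manifest$probe_id[pick],
                  enriched = manifest$probe_id[pick] %in% enriched_in)
  scored <- dplyr::mutate(windows,
                          sgrna = paste0("sgRNA", ((seq_len(n_regions) - 1L) %%
                                                     n_sgrna) + 1L),
                          score = runif(n_regions, 50, 100)) |>
    select("sgrna", "chrom", "start", "end", "score")
  windows <- arrange(windows, .data$chrom, .data$start)
  list(windows = windows, scored = scored, truth = truth)
}

#' Simulate a log-scale expression table with planted differential genes
#'
#' Per-gene baseline log2 expression is Gaussian; genes in `de_genes`
#' receive an additive `effect_log2fc` in the second group. Replicates
#' add Gaussian noise.
#'
#' @param genes character vector of gene labels.
#' @param de_genes subset of `genes` carrying the effect.
#' @param effect_log2fc additive log2 effect in the second group.
#' @param n_per_group replicates per group.
#' @param group_names length-2 character vector of group labels.
#' @param noise_sd replicate noise sd (log2 scale).
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param seed required integer seed.
#' @return list with `expr` (tibble, `gene` + one column per sample),
#'   `groups` (tibble `sample`, `group`) and `truth` (tibble `gene`,
#'   `log2fc`).
#' @export
simulate_expression <- function(genes, de_genes = character(0),
                                effect_log2fc = 2, n_per_group = 3,
                                group_names = c("ctrl", "treat"),
                                noise_sd = 0.5, baseline_mean = 6,
                                baseline_sd = 2, seed) {
  if (!all(de_genes %in% genes)) {
    stop("de_genes must be a subset of genes", call. = FALSE)
  }
  stopifnot(length(group_names) == 2L, is_count(n_per_group, 1))
  seed <- assert_seed(seed)
  withr::local_seed(seed)
  n <- length(genes)
  base <- rnorm(n, baseline_mean, baseline_sd)
  eff <- ifelse(genes %in% de_genes, effect_log2fc, 0)
  samples <- c(paste(group_names[1], seq_len(n_per_group), sep = "_"),
               paste(group_names[2], seq_len(n_per_group), sep = "_"))
  grp <- rep(group_names, each = n_per_group)
  mat <- sapply(seq_along(samples), function(j) {
    mu <- base + if (grp[j] == group_names[2]) eff else 0
    mu + rnorm(n, sd = noise_sd)
  })
  colnames(mat) <- samples
  list(
    expr = bind_cols(tibble(gene = genes), as_tibble(mat)),
    groups = tibble(sample = samples, group = grp),
    truth = tibble(gene = de_genes,
                   log2fc = rep(effect_log2fc, length(de_genes)))
  )
}
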