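# One-shot deterministic end-to-end run on synthetic data: generates
# every input, runs every analysis stage, and (optionally) writes the
# full output tree with metadata headers.

#' Run the full pipeline end-to-end on synthetic data
#'
#' Generates a synthetic study with known planted truth — a TSDR-like
#' bisulfite amplicon read set, an EPIC-like manifest and replicate beta
#' matrix with hypo-methylated probe sets planted in an edited ("TET1")
#' and a regulatory ("Treg") group, binding-site-like windows enriched
#' around the edited probes, a null predicted-off-target list, and an
#' expression table with planted differential genes — then runs every
#' stage: per-read calling, QC, summaries, pattern map and read
#' classes; delta-threshold differential methylation for both
#' comparisons; window extension, probe membership and Fisher subset
#' enrichment; PCA, top-loading extraction and per-gene enrichment;
#' simple differential expression and gene-set intersection. All
#' randomness derives from `seed`; identical seeds give identical
#' outputs.
#'
#' @param seed required integer seed.
#' @param dir optional output directory; when given, every table is
#'   written as TSV with a `#` metadata header (plus FASTQ/FASTA/BED for
#'   the sequence and region inputs).
#' @param n_probes manifest size of the scaled-down array.
#' @param n_reads amplicon reads simulated.
#' @param delta_threshold differential methylation threshold.
#' @param flank window flank in bp.
#' @param top_k loadings taken per component.
#' @param top_n_offtargets predictions retained per sgRNA.
#' @return invisibly, a list with every intermediate result and a
#'   `summary` tibble of headline numbers (including recovery of the
#'   planted hypo set).
#' @export
run_demo <- function(seed, dir = NULL, n_probes = 20000, n_reads = 2000,
                     delta_threshold = 0.2, flank = 1000, top_k = 500,
                     top_n_offtargets = 50) {
  seed <- assert_seed(seed)

  ## --- amplicon arm -------------------------------------------------
  design <- make_tsdr_fixture()
  sim_reads <- simulate_bisulfite_reads(
    design, n_reads = n_reads,
    components = list(list(weight = 0.45, p = 0),
                      list(weight = 0.25, p = 1),
                      list(weight = 0.30, p = 0.5)),
    conversion_failure = 0.005, sequencing_error = 0.001,
    seed = child_seed(seed, 1))
  calls <- call_reads(sim_reads$reads, design)
  calls <- filter_reads(calls)
  meth_sum <- summarize_methylation(calls)
  classes <- classify_reads(calls)
  pmap <- pattern_map(calls)

  ## --- array arm ----------------------------------------------------
  manifest <- simulate_probe_manifest(n_probes = n_probes,
                                      seed = child_seed(seed, 2))
  withr::with_seed(child_seed(seed, 3), {
    treg_hypo <- sample(manifest$probe_id, 300)
    tet1_hypo <- c(sample(treg_hypo, 100),
                   sample(setdiff(manifest$probe_id, treg_hypo), 50))
  })
  planted <- bind_rows(
    tibble(probe_id = treg_hypo, group = "Treg", delta = -0.45),
    tibble(probe_id = tet1_hypo, group = "TET1", delta = -0.5))
  sim_bm <- simulate_beta_matrix(
    manifest,
    groups = c(Tnaive = 3, mCherry_neg = 3, TET1 = 3, Treg = 3),
    planted = planted, noise_sd = 0.03, seed = child_seed(seed, 4))
  bm <- sim_bm$bm

  tet1_diff <- compare_groups(bm, "mCherry_neg", "TET1",
                              threshold = delta_threshold)
  treg_diff <- compare_groups(bm, "Tnaive", "Treg",
                              threshold = delta_threshold)
  hypo <- diff_set(tet1_diff, "hypo")

  ## --- enrichment arm -----------------------------------------------
  bs_sim <- simulate_region_sets(manifest, enriched_in = tet1_hypo,
                                 odds = 6, n_regions = 150,
                                 seed = child_seed(seed, 5))
  bs_probes <- probes_in_windows(manifest,
                                 extend_windows(bs_sim$windows, flank))
  background <- tet1_diff$table$probe_id
  bs_enrich <- subset_enrichment(intersect(bs_probes, background),
                                 hypo, background)

  ot_sim <- simulate_region_sets(manifest, odds = 1,
                                 n_regions = 12 * top_n_offtargets * 2,
                                 seed = child_seed(seed, 6))
  ot_windows <- select_top_offtargets(ot_sim$scored,
                                      top_n = top_n_offtargets)
  ot_probes <- probes_in_windows(manifest, extend_windows(ot_windows, flank))
  ot_enrich <- subset_enrichment(intersect(ot_probes, background),
                                 hypo, background)

  treg_hypo_called <- diff_set(treg_diff, "hypo")
  treg_enrich <- subset_enrichment(intersect(treg_hypo_called, background),
                                   hypo, background)

  pca <- pca_beta(bm)
  top_cpgs <- topk_loadings(pca, "PC1", k = top_k)
  gene_enr <- gene_enrichment(top_cpgs, manifest)

  ## --- integration arm ----------------------------------------------
  all_genes <- annotate_and_intersect(manifest$probe_id, manifest)$genes[[1]]
  hypo_genes <- annotate_and_intersect(tet1_hypo, manifest)$genes[[1]]
  withr::with_seed(child_seed(seed, 7), {
    de_true <- unique(c(sample(hypo_genes, min(30, length(hypo_genes))),
                        sample(all_genes, 40)))
  })
  sim_expr <- simulate_expression(all_genes, de_genes = de_true,
                                  effect_log2fc = 4, n_per_group = 4,
                                  group_names = c("mCherry_neg", "TET1"),
                                  noise_sd = 0.2,
                                  seed = child_seed(seed, 8))
  de <- simple_de(sim_expr$expr, sim_expr$groups, "mCherry_neg", "TET1")
  intersection <- annotate_and_intersect(hypo, manifest,
                                         list(TET1_de = de_genes(de)))

  ## --- summary -------------------------------------------------------
  truth_tet1 <- tet1_hypo
  sens <- length(intersect(hypo, truth_tet1)) / length(truth_tet1)
  null_probes <- setdiff(background, truth_tet1)
  null_rate <- length(intersect(hypo, null_probes)) / length(null_probes)
  summary <- tibble(
    metric = c("amplicon_overall_meth_pct", "amplicon_reads_retained",
               "frac_fully_demethylated", "n_tet1_hypo", "n_tet1_hyper",
               "hypo_recovery_sensitivity", "hypo_null_call_rate",
               "bindingsite_enrichment_p", "offtarget_enrichment_p",
               "treg_hypo_enrichment_p", "n_de_genes",
               "n_hypo_and_de_genes"),
    value = c(attr(meth_sum, "overall_meth_pct"), nrow(calls),
              classes$fraction[classes$class == "fully_demethylated"],
              glance(tet1_diff)$n_hypo, glance(tet1_diff)$n_hyper,
              sens, null_rate,
              bs_enrich$p_two_sided, ot_enrich$p_two_sided,
              treg_enrich$p_two_sided, glance(de)$n_de,
              intersection$n[intersection$name == "TET1_de"])
  )

  out <- list(design = design, reads = sim_reads, calls = calls,
              methylation = meth_sum, classes = classes,
              pattern_map = pmap, manifest = manifest, bm = bm,
              beta_truth = sim_bm$truth, tet1_diff = tet1_diff,
              treg_diff = treg_diff, bs_enrich = bs_enrich,
              ot_enrich = ot_enrich, treg_enrich = treg_enrich,
              pca = pca, top_cpgs = top_cpgs, gene_enrichment = gene_enr,
              de = de, intersection = intersection, summary = summary,
              seed = seed)

  if (!is.null(dir)) write_demo_outputs(out, dir)
  invisible(out)
}

write_demo_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  meta <- list(seed = out$seed, package = "methedit")
  write_fastq(out$reads$reads, p("reads.fastq"))
  write_design(out$design, p("amplicon.fasta"), p("amplicon.design.tsv"))
  write_tsv_meta(out$reads$truth, p("reads.truth.tsv"), meta)
  write_tsv_meta(as_tibble(out$calls), p("read_calls.tsv"), meta)
  write_tsv_meta(as_tibble(out$methylation), p("methylation_summary.tsv"),
                 c(meta, overall_meth_pct = attr(out$methylation,
                                                 "overall_meth_pct")))
  write_tsv_meta(as_tibble(out$classes), p("read_classes.tsv"), meta)
  write_tsv_meta(as_tibble(out$pattern_map), p("pattern_map.tsv"), meta)
  write_tsv_meta(out$manifest, p("manifest.tsv"), meta)
  write_beta(out$bm, p("beta.tsv"), p("groups.tsv"), meta)
  write_tsv_meta(out$beta_truth, p("beta.truth.tsv"), meta)
  write_tsv_meta(tidy(out$tet1_diff), p("diff_tet1.tsv"),
                 c(meta, threshold = out$tet1_diff$threshold))
  write_tsv_meta(tidy(out$treg_diff), p("diff_treg.tsv"),
                 c(meta, threshold = out$treg_diff$threshold))
  write_tsv_meta(bind_rows(binding_sites = out$bs_enrich,
                           off_targets = out$ot_enrich,
                           treg_hypo = out$treg_enrich, .id = "subset"),
                 p("subset_enrichment.tsv"), meta)
  write_tsv_meta(tidy(out$pca, "scores"), p("pca_scores.tsv"), meta)
  write_tsv_meta(tidy(out$pca, "variance"), p("pca_variance.tsv"), meta)
  write_tsv_meta(tibble(probe_id = out$top_cpgs), p("pc1_top_cpgs.tsv"),
                 meta)
  write_tsv_meta(out$gene_enrichment, p("gene_enrichment.tsv"), meta)
  write_tsv_meta(tidy(out$de), p("differential_expression.tsv"), meta)
  write_tsv_meta(select(out$intersection, -"genes"),
                 p("intersection.tsv"), meta)
  write_tsv_meta(out$summary, p("summary.tsv"), meta)
  invisible(dir)
}
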