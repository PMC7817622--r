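# Synthetic-data generators: fixture geometry, latent-truth
# consistency, determinism, planted-effect realisation.

test_that("TSDR fixture has 15 CpGs with valid geometry and primers", {
  d <- make_tsdr_fixture()
  expect_length(d$cpg_positions, 15)
  bases <- strsplit(d$reference, "")[[1]]
  expect_true(all(bases[d$cpg_positions + 1] == "C"))
  expect_true(all(bases[d$cpg_positions + 2] == "G"))
  expect_false(is.unsorted(d$cpg_positions, strictly = TRUE))
  expect_true(all(d$cpg_positions >= d$primer_fwd[2] &
                    d$cpg_positions < d$primer_rev[1]))
  # the forward primer anneals to the converted reference
  conv <- gsub("C", "T", d$reference)
  fwd <- substr(d$reference, d$primer_fwd[1] + 1, d$primer_fwd[2])
  expect_true(grepl(gsub("C", "T", fwd), conv, fixed = TRUE))
  # no CpG outside the declared ones
  expect_equal(length(gregexpr("CG", d$reference, fixed = TRUE)[[1]]), 15)
})

test_that("amplicon_design rejects malformed CpG annotation", {
  expect_error(
    amplicon_design("x", "TTTTACGTTTTT", c(0, 3), c(9, 12),
                    cpg_positions = 4),
    "CG dinucleotide")
  expect_error(
    amplicon_design("x", "TTTTACGTTTTT", c(0, 3), c(9, 12),
                    cpg_positions = c(4, 4)),
    "strictly increasing")
})

test_that("noise-free read simulation realises the latent states exactly", {
  d <- make_tsdr_fixture()
  bases <- strsplit(d$reference, "")[[1]]
  cpg1 <- d$cpg_positions + 1
  non_cpg_c <- setdiff(which(bases == "C"), cpg1)

  all_m <- simulate_bisulfite_reads(
    d, 5, list(list(weight = 1, p = 1)), seed = 1)
  for (s in all_m$reads$sequence) {
    ch <- strsplit(s, "")[[1]]
    expect_true(all(ch[cpg1] == "C"))
    expect_true(all(ch[non_cpg_c] == "T"))
    expect_equal(ch[-c(cpg1, non_cpg_c)], bases[-c(cpg1, non_cpg_c)])
  }
  all_u <- simulate_bisulfite_reads(
    d, 5, list(list(weight = 1, p = 0)), seed = 1)
  for (s in all_u$reads$sequence) {
    expect_false(grepl("C", s, fixed = TRUE))
  }
  # truth patterns reproduce CpG bases when noise rates are 0
  mix <- simulate_bisulfite_reads(
    d, 40, list(list(weight = 0.5, p = 0.4),
                list(weight = 0.5, p = 0.9)), seed = 5)
  for (i in seq_len(40)) {
    ch <- strsplit(mix$reads$sequence[i], "")[[1]]
    pat <- strsplit(mix$truth$pattern[i], "")[[1]]
    expect_identical(ifelse(ch[cpg1] == "C", "M", "U"), pat)
  }
})

test_that("generators are byte-identical under the same seed", {
  d <- make_tsdr_fixture()
  args <- list(d, 30, list(list(weight = 1, p = 0.5)),
               conversion_failure = 0.01, sequencing_error = 0.01)
  s1 <- do.call(simulate_bisulfite_reads, c(args, seed = 7))
  s2 <- do.call(simulate_bisulfite_reads, c(args, seed = 7))
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)

  m1 <- simulate_probe_manifest(n_probes = 500, seed = 3)
  m2 <- simulate_probe_manifest(n_probes = 500, seed = 3)
  expect_identical(m1, m2)

  b1 <- simulate_beta_matrix(m1, seed = 4)
  b2 <- simulate_beta_matrix(m1, seed = 4)
  expect_identical(b1$bm$beta, b2$bm$beta)

  r1 <- simulate_region_sets(m1, n_regions = 20, seed = 5)
  r2 <- simulate_region_sets(m1, n_regions = 20, seed = 5)
  expect_identical(r1, r2)

  expect_error(simulate_probe_manifest(n_probes = 10), "seed")
})

test_that("manifest positions are sorted unique with conserved annotation", {
  man <- simulate_probe_manifest(n_probes = 2000, n_chrom = 5, seed = 17)
  expect_equal(nrow(man), 2000)
  expect_false(anyDuplicated(man$probe_id) > 0)
  for (ch in unique(man$chrom)) {
    pos <- man$pos[man$chrom == ch]
    expect_false(is.unsorted(pos, strictly = TRUE))
    expect_true(all(pos >= 0))
  }
  # total gene-annotation count equals the sum of per-gene totals
  labels <- unlist(strsplit(man$genes[!is.na(man$genes)], ";"))
  expect_equal(sum(table(labels)), length(labels))
})

test_that("default manifest profile matches the EPIC array scale", {
  expect_equal(formals(simulate_probe_manifest)$n_probes, 865859)
})

test_that("beta simulation respects bounds, planting and missingness", {
  ta <- tiny_array_sim()
  beta <- ta$sim$bm$beta
  expect_true(all(beta >= 0 & beta <= 1, na.rm = TRUE))

  # noise-free planting: group means equal baseline + delta exactly
  sim0 <- simulate_beta_matrix(ta$manifest, groups = c(ctrl = 2, treat = 2),
                               planted = ta$planted, noise_sd = 0, seed = 8)
  b0 <- sim0$bm$beta
  expect_equal(b0[, "ctrl_1"], b0[, "ctrl_2"])
  idx <- match(ta$planted$probe_id, rownames(b0))
  expect_equal(b0[idx, "treat_1"] - b0[idx, "ctrl_1"],
               setNames(ta$planted$delta, ta$planted$probe_id)[rownames(b0)[idx]],
               tolerance = 1e-12)
  # unplanted probes identical across groups
  expect_equal(b0[-idx, "treat_1"], b0[-idx, "ctrl_1"])

  miss <- simulate_beta_matrix(ta$manifest, missing_rate = 0.1, seed = 9)
  expect_gt(mean(is.na(miss$bm$beta)), 0.05)

  expect_error(
    simulate_beta_matrix(ta$manifest,
                         planted = tibble::tibble(probe_id = "nope",
                                                  group = "treat",
                                                  delta = -0.5),
                         seed = 1),
    "not present")
})

test_that("region simulation hits enrichment targets and edge cases", {
  man <- simulate_probe_manifest(n_probes = 1000, n_chrom = 3, seed = 2)
  empty <- simulate_region_sets(man, n_regions = 0, seed = 1)
  expect_equal(nrow(empty$windows), 0)

  rs <- simulate_region_sets(man, enriched_in = man$probe_id[1:100],
                             odds = 10, n_regions = 200, seed = 6)
  expect_equal(nrow(rs$windows), 200)
  expect_true(all(rs$windows$start < rs$windows$end))
  expect_true(all(rs$windows$start >= 0))
  # per-chromosome sorted
  expect_true(all(unlist(tapply(rs$windows$start, rs$windows$chrom,
                                function(v) !is.unsorted(v)))))
  # odds 10 on a 10% stratum: covered probes strongly over-represent it
  expect_gt(mean(rs$truth$enriched), 0.3)
})

test_that("expression simulation plants recoverable effects", {
  genes <- paste0("G", 1:100)
  ex0 <- simulate_expression(genes, de_genes = character(0), seed = 1)
  expect_equal(nrow(ex0$truth), 0)
  ex <- simulate_expression(genes, de_genes = genes[1:10],
                            effect_log2fc = 4, n_per_group = 5,
                            noise_sd = 0.1, seed = 2)
  m <- as.matrix(ex$expr[-1])
  grp2 <- ex$groups$sample[ex$groups$group == "treat"]
  diffs <- rowMeans(m[, grp2]) - rowMeans(m[, setdiff(colnames(m), grp2)])
  expect_true(all(diffs[1:10] > 3))
  expect_true(all(abs(diffs[-(1:10)]) < 1))
  expect_error(simulate_expression(genes, de_genes = "ZZZ", seed = 1),
               "subset")
})
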