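# Window handling, top-N off-target selection, probe membership and the
# Fisher-based enrichment procedures.

test_that("window extension clips at zero and preserves order and count", {
  w <- tibble::tibble(chrom = c("chr1", "chrX"),
                      start = c(500L, 5000L), end = c(700L, 6000L))
  e <- extend_windows(w, 1000)
  expect_equal(e$start, c(0L, 4000L))
  expect_equal(e$end, c(1700L, 7000L))
  expect_equal(extend_windows(w, 0), w)
  expect_equal(nrow(e), nrow(w))
  expect_error(extend_windows(w, -5))
  expect_error(extend_windows(tibble::tibble(chrom = "c", start = 5,
                                             end = 5)),
               "start < end")
})

test_that("BED round-trip preserves half-open coordinates", {
  w <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"),
                      start = c(0L, 100L, 7L), end = c(50L, 170L, 9L),
                      name = c("a", "b", "c"))
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(w, f)
  expect_equal(read_bed(f), w)
})

test_that("top-N off-target selection keeps 50 per sgRNA with tie policy", {
  withr::with_seed(5, {
    preds <- tidyr::expand_grid(sgrna = paste0("sgRNA", 1:12),
                                i = 1:80) |>
      dplyr::mutate(chrom = "chr1", start = 1000L * dplyr::row_number(),
                    end = start + 100L,
                    score = runif(dplyr::n(), 50, 100)) |>
      dplyr::select(-"i")
  })
  top <- select_top_offtargets(preds, top_n = 50)
  expect_equal(nrow(top), 12 * 50)

  # fewer predictions than top_n: everything kept, with a warning
  expect_warning(
    few <- select_top_offtargets(preds[preds$sgrna == "sgRNA1", ][1:30, ]),
    "fewer than 50")
  expect_equal(nrow(few), 30)

  # score ties at the boundary are all retained
  tied <- tibble::tibble(sgrna = "s", chrom = "chr1",
                         start = 100L * (1:10), end = 100L * (1:10) + 50L,
                         score = c(rep(9, 4), rep(5, 6)))
  expect_message(kept <- select_top_offtargets(tied, top_n = 5), "tied")
  expect_equal(nrow(kept), 10)
})

test_that("probe membership uses half-open windows with set semantics", {
  man <- tibble::tibble(probe_id = paste0("p", 1:4),
                        chrom = "chr1",
                        pos = c(1699L, 1700L, 10L, 10L),
                        genes = NA_character_)
  man <- man[1:3, ]
  w <- tibble::tibble(chrom = "chr1", start = c(0L, 5L), end = c(1700L, 20L))
  hit <- probes_in_windows(man, w)
  expect_setequal(hit, c("p1", "p3"))     # 1699 in [0,1700), 1700 out
  # overlapping windows count a probe once
  w2 <- tibble::tibble(chrom = "chr1", start = c(0L, 0L), end = c(50L, 60L))
  expect_equal(probes_in_windows(man, w2), "p3")
  expect_warning(probes_in_windows(man, tibble::tibble(chrom = "chrM",
                                                       start = 0L,
                                                       end = 10L)),
                 "absent")
  expect_equal(nrow(suppressWarnings(
    tibble::tibble(x = probes_in_windows(man,
                                         tibble::tibble(chrom = "chrM",
                                                        start = 0L,
                                                        end = 10L))))), 0)
})

test_that("subset enrichment builds the documented table and directions", {
  bg <- paste0("p", 1:20)
  focal <- bg[1:5]
  r <- subset_enrichment(focal, focal, bg)
  expect_equal(unlist(r[c("a", "b", "c", "d")]),
               c(a = 5L, b = 0L, c = 0L, d = 15L))
  expect_equal(r$p_two_sided, 1 / 15504)
  expect_identical(r$direction, "enriched")

  # disjoint subset with large counts is depleted
  bg2 <- paste0("q", 1:200)
  r2 <- subset_enrichment(bg2[1:80], bg2[81:160], bg2)
  expect_identical(r2$direction, "depleted")

  # table conservation
  expect_equal(r$a + r$b + r$c + r$d, 20L)
  # transposition symmetry: swapping subset and focal
  sub <- bg[3:10]
  p1 <- subset_enrichment(sub, focal, bg)$p_two_sided
  p2 <- subset_enrichment(focal, sub, bg)$p_two_sided
  expect_equal(p1, p2, tolerance = 1e-12)

  expect_error(subset_enrichment("z1", focal, bg), "contained")
  expect_error(subset_enrichment(character(0), character(0), character(0)),
               "empty background")
})

test_that("top-k loadings rank by magnitude with deterministic ties", {
  ta <- tiny_array_sim(seed = 61)
  p <- pca_beta(ta$sim$bm)
  l <- setNames(p$loadings$PC1, p$loadings$probe_id)
  top <- topk_loadings(p, "PC1", k = 25)
  expect_length(top, 25)
  expect_equal(top, names(sort(-abs(l)))[1:25])
  thresh <- min(abs(l[top]))
  expect_true(all(abs(l[setdiff(names(l), top)]) <= thresh))
  # k above the probe count returns everything with a warning
  expect_warning(all_p <- topk_loadings(p, "PC1", k = 1e6), "all probes")
  expect_length(all_p, nrow(p$loadings))
  expect_error(topk_loadings(p, "PC99"), "not present")
  # planted probes dominate PC1
  expect_gt(length(intersect(topk_loadings(p, "PC1", k = 40),
                             ta$planted$probe_id)), 35)
})

test_that("gene enrichment corrects for gene probe totals", {
  # 100 probes, gene G holds 10, focal set of 20 contains 8 of G
  man <- tibble::tibble(
    probe_id = sprintf("p%03d", 1:100),
    chrom = "chr1", pos = 10L * (1:100),
    genes = c(rep("G", 10), rep("H", 30), rep(NA_character_, 60)))
  focal <- c(man$probe_id[1:8], man$probe_id[41:52])
  res <- gene_enrichment(focal, man)
  g <- res[res$gene == "G", ]
  expect_equal(g$hits, 8L)
  expect_equal(g$gene_total, 10L)
  expect_equal(g$odds_ratio, 26)
  expect_equal(g$p_two_sided, 2.37827496403792e-05, tolerance = 1e-12)
  expect_equal(res$q_fdr, bh_fdr(res$p_two_sided))

  expect_equal(nrow(gene_enrichment(character(0), man)), 0)
  expect_error(gene_enrichment("nope", man), "subset")

  # multi-annotated probes hit every annotated gene
  man2 <- man
  man2$genes[1] <- "G;H"
  res2 <- gene_enrichment(focal, man2)
  expect_equal(res2$hits[res2$gene == "H"], 1L)
  expect_equal(res2$hits[res2$gene == "G"], 8L)
})
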