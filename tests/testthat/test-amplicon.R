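# Amplicon layer: conversion, alignment, calling, QC, summaries,
# pattern maps, read classes.

test_that("reference conversion replaces C by T and remembers columns", {
  d <- amplicon_design("t", "TTTACGTTTTACATTTTTAA", c(0, 3), c(17, 20),
                       cpg_positions = 4)
  conv <- convert_reference(d)
  expect_equal(nchar(conv$sequence), nchar(d$reference))
  expect_false(grepl("C", conv$sequence, fixed = TRUE))
  expect_equal(conv$cpg_columns, 5)
  expect_equal(conv$non_cpg_c_columns, 12)

  d2 <- make_tsdr_fixture()
  conv2 <- convert_reference(d2)
  expect_equal(conv2$cpg_columns, d2$cpg_positions + 1)
  expect_length(conv2$non_cpg_c_columns, 15)
})

test_that("perfect and perturbed reads align and call correctly", {
  d <- make_tsdr_fixture()
  conv <- convert_reference(d)
  bases <- strsplit(d$reference, "")[[1]]

  # fully methylated error-free molecule: converted except CpG Cs
  seq_m <- bases
  seq_m[conv$non_cpg_c_columns] <- "T"
  reads <- tibble::tibble(read_id = c("meth", "conv"),
                          sequence = c(paste(seq_m, collapse = ""),
                                       conv$sequence))
  calls <- call_reads(reads, d)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$pattern[calls$read_id == "meth"], strrep("M", 15))
  expect_equal(calls$pattern[calls$read_id == "conv"], strrep("U", 15))
  expect_equal(calls$conversion_rate, c(1, 1))
  expect_equal(calls$identity, c(1, 1))
  expect_equal(calls$cpg_coverage, c(1, 1))

  # one substitution at a non-C, non-CpG column reduces identity by 1/L
  non_c <- which(bases != "C")
  pos <- setdiff(non_c, c(conv$cpg_columns, conv$cpg_columns + 1))[10]
  seq_mut <- seq_m
  # substitute with a non-C base so no spurious cytosine appears
  seq_mut[pos] <- if (seq_mut[pos] == "T") "A" else "T"
  calls2 <- call_reads(tibble::tibble(read_id = "mut",
                                      sequence = paste(seq_mut, collapse = "")),
                       d)
  expect_equal(calls2$identity, (length(non_c) - 1) / length(non_c))

  # junk read is dropped as unalignable
  withr::with_seed(1, junk <- paste(
    sample(c("A", "C", "G", "T"), 290, replace = TRUE), collapse = ""))
  out <- call_reads(tibble::tibble(read_id = "junk", sequence = junk), d)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "dropped")$reason, "unalignable")

  # short read dropped
  out2 <- call_reads(tibble::tibble(read_id = "short", sequence = "ACGTACGT"),
                     d)
  expect_equal(attr(out2, "dropped")$reason, "too_short")
})

test_that("reverse-orientation reads are recovered by the second pass", {
  d <- make_tsdr_fixture()
  conv <- convert_reference(d)
  bases <- strsplit(d$reference, "")[[1]]
  seq_m <- bases
  seq_m[conv$non_cpg_c_columns] <- "T"
  fwd <- paste(seq_m, collapse = "")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  calls <- call_reads(tibble::tibble(read_id = c("f", "r"),
                                     sequence = c(fwd, rc)), d)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$orientation, c("forward", "reverse"))
  expect_equal(calls$pattern, rep(strrep("M", 15), 2))
})

test_that("partial conversion is measured per read", {
  d <- make_tsdr_fixture()
  conv <- convert_reference(d)
  bases <- strsplit(d$reference, "")[[1]]
  seq_u <- bases
  seq_u[conv$cpg_columns] <- "T"
  # convert 9 of 15 non-CpG Cs only -> conversion rate 0.6
  seq_u[conv$non_cpg_c_columns[1:9]] <- "T"
  calls <- call_reads(tibble::tibble(read_id = "x",
                                     sequence = paste(seq_u, collapse = "")),
                      d)
  expect_equal(calls$conversion_rate, 9 / 15)
  filt <- suppressWarnings(filter_reads(calls))
  expect_equal(nrow(filt), 0)
  log <- attr(filt, "filter_log")
  expect_equal(log$n[log$reason == "incomplete_conversion"], 1)
})

test_that("QC filtering conserves reads, is idempotent, honours thresholds", {
  tr <- tiny_read_sim(n = 80, seed = 31, conversion_failure = 0.02)
  calls <- call_reads(tr$sim$reads, tr$design)
  expect_equal(nrow(calls) + nrow(attr(calls, "dropped")), 80)
  filt <- filter_reads(calls)
  expect_true(all(filt$conversion_rate >= 0.95))
  refilt <- filter_reads(filt)
  expect_equal(tibble::tibble(data.frame(refilt)),
               tibble::tibble(data.frame(filt)))
  expect_equal(sum(attr(refilt, "filter_log")$n), 0)
  # thresholds at 0 retain everything alignable
  expect_equal(nrow(filter_reads(calls, 0, 0, 0)), nrow(calls))
})

test_that("methylation summary pools calls correctly", {
  tr <- tiny_read_sim(n = 60, seed = 77)
  calls <- call_reads(tr$sim$reads, tr$design)
  s <- summarize_methylation(calls)
  expect_equal(nrow(s), 15)
  # overall equals the M fraction of the latent truth (noise-free sim)
  truth_m <- mean(strsplit(paste(tr$sim$truth$pattern, collapse = ""),
                           "")[[1]] == "M")
  expect_equal(attr(s, "overall_meth_pct"), 100 * truth_m)
  expect_true(all(s$mean_meth_pct >= 0 & s$mean_meth_pct <= 100))
  # overall invariant under reordering
  s2 <- summarize_methylation(pattern_map(calls))
  expect_equal(attr(s2, "overall_meth_pct"), attr(s, "overall_meth_pct"))
  expect_equal(glance(s)$n_reads, 60)
})

test_that("pattern map reorders without altering the pattern multiset", {
  tr <- tiny_read_sim(n = 40, seed = 13)
  calls <- call_reads(tr$sim$reads, tr$design)
  pm <- pattern_map(calls)
  expect_setequal(pm$pattern, calls$pattern)
  expect_equal(sort(table(pm$pattern)), sort(table(calls$pattern)))
  # fully methylated reads come first under the default order
  frac <- vapply(strsplit(pm$pattern, ""),
                 function(ch) mean(ch == "M"), numeric(1))
  expect_false(is.unsorted(rev(frac)))
  p <- autoplot(pm)
  expect_s3_class(p, "ggplot")
})

test_that("read classification applies the fraction thresholds", {
  d <- make_tsdr_fixture()
  mk <- function(pats) {
    structure(tibble::tibble(read_id = paste0("r", seq_along(pats)),
                             pattern = pats,
                             conversion_rate = 1, identity = 1,
                             cpg_coverage = 1, orientation = "forward",
                             score = 290),
              class = c("read_calls", class(tibble::tibble())),
              cpg_positions = d$cpg_positions, amplicon = d$name,
              dropped = tibble::tibble(read_id = character(0),
                                       reason = character(0)))
  }
  cls <- classify_reads(mk(c(strrep("U", 15), strrep("M", 15),
                             paste0(strrep("M", 7), strrep("U", 8)))))
  expect_equal(cls$n, c(1L, 1L, 1L))
  expect_equal(sum(cls$fraction), 1)
  per <- attr(cls, "per_read")
  expect_equal(per$class,
               c("fully_demethylated", "fully_methylated", "heterogeneous"))
})

test_that("FASTQ and design round-trips are identity", {
  tr <- tiny_read_sim(n = 12, seed = 5)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(tr$sim$reads, fq)
  back <- read_fastq(fq)
  expect_equal(back, tr$sim$reads)

  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_design(tr$design, fa, tsv)
  d2 <- read_design(fa, tsv)
  expect_equal(d2, tr$design)
})
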