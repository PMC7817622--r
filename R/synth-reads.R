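# Bisulfite read simulator: per-molecule methylation patterns drawn from
# a mixture of components, incomplete-conversion and sequencing-error
# noise, with a latent-truth table for every read.

#' Simulate bisulfite amplicon reads with known latent states
#'
#' Each read is generated by (1) drawing a mixture component, (2) drawing
#' per-CpG methylation states from the component's per-CpG probabilities,
#' (3) bisulfite-converting the reference: unmethylated cytosines
#' (CpG or not) read as T except with probability `conversion_failure`
#' they are retained as C; methylated CpG cytosines stay C, and
#' (4) applying uniform substitution errors at `sequencing_error` per
#' base. The truth table records each read's component and latent per-CpG
#' states, so downstream estimates can be checked against ground truth.
#'
#' @param design an [amplicon_design()].
#' @param n_reads number of reads to simulate.
#' @param components list of mixture components, each
#'   `list(weight =, p =)` where `p` is a per-CpG methylation probability
#'   vector (scalars are recycled to the number of CpGs). Weights must
#'   sum to 1.
#' @param conversion_failure probability an unmethylated C escapes
#'   conversion and is read as C.
#' @param sequencing_error per-base substitution probability.
#' @param seed required integer seed.
#' @return list with `reads` (tibble `read_id`, `sequence`), `truth`
#'   (tibble `read_id`, `component`, `pattern` of M/U latent states) and
#'   the configuration.
#' @export
simulate_bisulfite_reads <- function(design, n_reads, components,
                                     conversion_failure = 0,
                                     sequencing_error = 0, seed) {
  stopifnot(inherits(design, "amplicon_design"), is_count(n_reads, 1))
  seed <- assert_seed(seed)
  k <- length(design$cpg_positions)
  w <- vapply(components, function(co) co$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-8) stop("component weights must sum to 1",
                                   call. = FALSE)
  pmat <- do.call(rbind, lapply(components, function(co) {
    p <- rep_len(co$p, k)
    stopifnot(all(p >= 0 & p <= 1))
    p
  }))
  stopifnot(conversion_failure >= 0, conversion_failure <= 1,
            sequencing_error >= 0, sequencing_error <= 1)

  withr::local_seed(seed)
  bases <- strsplit(design$reference, "")[[1]]
  L <- length(bases)
  cpg1 <- design$cpg_positions + 1L                # 1-based CpG columns
  c_cols <- which(bases == "C")
  non_cpg_c <- setdiff(c_cols, cpg1)

  comp <- sample.int(length(components), n_reads, replace = TRUE, prob = w)
  meth <- matrix(runif(n_reads * k), n_reads, k) < pmat[comp, , drop = FALSE]

  M <- matrix(rep(bases, each = n_reads), n_reads, L)
  # non-CpG Cs: always unmethylated; convert to T unless conversion fails
  if (length(non_cpg_c)) {
    keepC <- matrix(runif(n_reads * length(non_cpg_c)) < conversion_failure,
                    n_reads, length(non_cpg_c))
    M[, non_cpg_c] <- ifelse(keepC, "C", "T")
  }
  # CpG Cs: methylated stay C; unmethylated convert unless failure
  keepC <- matrix(runif(n_reads * k) < conversion_failure, n_reads, k)
  M[, cpg1] <- ifelse(meth | keepC, "C", "T")

  if (sequencing_error > 0) {
    err <- which(matrix(runif(n_reads * L) < sequencing_error, n_reads, L))
    if (length(err)) {
      alts <- c("A", "C", "G", "T")
      cur <- M[err]
      M[err] <- vapply(cur, function(b) sample(setdiff(alts, b), 1L),
                       character(1))
    }
  }

  ids <- sprintf("read_%06d", seq_len(n_reads))
  list(
    reads = tibble(read_id = ids,
                   sequence = apply(M, 1L, paste0, collapse = "")),
    truth = tibble(read_id = ids, component = comp,
                   pattern = apply(ifelse(meth, "M", "U"), 1L,
                                   paste0, collapse = "")),
    config = list(n_reads = n_reads, weights = w,
                  conversion_failure = conversion_failure,
                  sequencing_error = sequencing_error, seed = seed)
  )
}

#' Write reads as FASTQ (Phred+33, fixed quality)
#'
#' @param reads tibble with `read_id` and `sequence`.
#' @param path output path (`.gz` accepted).
#' @param quality_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  quals <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (`.gz` accepted).
#' @return tibble with `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = sub("\\s.*$", "", names(seqs)),
         sequence = unname(as.character(seqs)))
}

#' Write an amplicon design to FASTA plus a coordinate table
#'
#' @param design an [amplicon_design()].
#' @param fasta_path,coords_path output paths.
#' @return invisibly, the two paths.
#' @export
write_design <- function(design, fasta_path, coords_path) {
  ref <- Biostrings::DNAStringSet(design$reference)
  names(ref) <- design$name
  Biostrings::writeXStringSet(ref, fasta_path)
  coords <- tibble(
    feature = c("primer_fwd", "primer_rev",
                rep("cpg", length(design$cpg_positions))),
    start = c(design$primer_fwd[1], design$primer_rev[1],
              design$cpg_positions),
    end = c(design$primer_fwd[2], design$primer_rev[2],
            design$cpg_positions + 1L)
  )
  write_tsv_meta(coords, coords_path,
                 meta = list(name = design$name, strand = design$strand,
                             coordinates = "0-based half-open"))
  invisible(c(fasta_path, coords_path))
}

#' Read an amplicon design from FASTA plus a coordinate table
#'
#' @param fasta_path,coords_path paths written by [write_design()].
#' @return an [amplicon_design()].
#' @export
read_design <- function(fasta_path, coords_path) {
  ref <- Biostrings::readDNAStringSet(fasta_path)
  coords <- read_tsv_meta(coords_path)
  meta <- attr(coords, "meta")
  fwd <- coords[coords$feature == "primer_fwd", ]
  rev <- coords[coords$feature == "primer_rev", ]
  cpg <- coords[coords$feature == "cpg", ]
  amplicon_design(
    name = names(ref)[1], reference = as.character(ref[[1]]),
    primer_fwd = c(fwd$start, fwd$end), primer_rev = c(rev$start, rev$end),
    cpg_positions = cpg$start,
    strand = meta$strand %||% "+"
  )
}
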