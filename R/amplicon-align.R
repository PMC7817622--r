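# Three-letter bisulfite alignment: reads and reference are C->T
# converted so alignment is methylation-agnostic; methylation calls are
# read back from the original bases at the reference CpG columns.

#' Three-letter conversion of an amplicon reference
#'
#' Replaces every C of the reference by T and remembers the original
#' cytosine columns: the CpG columns (call-back targets) and the non-CpG
#' C columns (bisulfite conversion-rate witnesses).
#'
#' @param design an [amplicon_design()].
#' @return list with `sequence` (converted reference), `cpg_columns` and
#'   `non_cpg_c_columns` (1-based reference columns).
#' @export
convert_reference <- function(design) {
  stopifnot(inherits(design, "amplicon_design"))
  bases <- strsplit(design$reference, "")[[1]]
  cpg1 <- design$cpg_positions + 1L
  c_cols <- which(bases == "C")
  list(sequence = gsub("C", "T", design$reference, fixed = TRUE),
       cpg_columns = cpg1,
       non_cpg_c_columns = setdiff(c_cols, cpg1))
}

# mapping from one pairwiseAlignment element to per-reference-column
# original read bases; returns character vector of length L (NA = gap or
# uncovered)
aligned_ref_bases <- function(pat_aln, sub_aln, sub_start, oriented_read, L) {
  pchars <- strsplit(pat_aln, "")[[1]]
  schars <- strsplit(sub_aln, "")[[1]]
  ref_idx <- cumsum(schars != "-") + sub_start - 1L
  read_idx <- cumsum(pchars != "-")
  keep <- schars != "-" & pchars != "-"
  out <- rep(NA_character_, L)
  rb <- strsplit(oriented_read, "")[[1]]
  out[ref_idx[keep]] <- rb[read_idx[keep]]
  out
}

#' Align reads to an amplicon design (semi-global, three-letter)
#'
#' Aligns the C->T-converted reads against the C->T-converted reference
#' with free end-gaps on the reference (reads global, reference local);
#' scoring is match +1, mismatch -1, gap -2. When the forward pass fails
#' the score floor, a reverse-orientation pass (reverse complement of
#' the read, then C->T) is attempted and the better-scoring pass wins.
#' Reads whose best score per base falls below `min_score_per_base`, or
#' that are shorter than `min_length`, are dropped with a logged reason.
#'
#' @param reads tibble with `read_id`, `sequence`.
#' @param design an [amplicon_design()].
#' @param min_length minimum read length considered alignable.
#' @param min_score_per_base score floor: best score / read length.
#' @return list with `alignments` (tibble `read_id`, `score`,
#'   `orientation`), `ref_bases` (character matrix, aligned reads x
#'   reference columns, original read bases) and `dropped` (tibble
#'   `read_id`, `reason`).
#' @export
align_reads <- function(reads, design, min_length = 30,
                        min_score_per_base = 0.5) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence") %in% names(reads)),
            inherits(design, "amplicon_design"))
  conv <- convert_reference(design)
  L <- nchar(design$reference)
  subject <- Biostrings::DNAString(conv$sequence)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = 1, mismatch = -1, baseOnly = TRUE)

  too_short <- nchar(reads$sequence) < min_length
  dropped <- tibble(read_id = reads$read_id[too_short],
                    reason = rep("too_short", sum(too_short)))
  reads <- reads[!too_short, , drop = FALSE]
  if (!nrow(reads)) {
    return(list(alignments = tibble(read_id = character(0),
                                    score = numeric(0),
                                    orientation = character(0)),
                ref_bases = matrix(NA_character_, 0, L),
                dropped = dropped))
  }

  fwd_reads <- reads$sequence
  rev_reads <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd_reads)))
  align_pass <- function(orig) {
    patt <- Biostrings::DNAStringSet(gsub("C", "T", orig, fixed = TRUE))
    Biostrings::pairwiseAlignment(
      patt, subject, type = "global-local",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2)
  }
  aln_f <- align_pass(fwd_reads)
  sc_f <- Biostrings::score(aln_f)
  len <- nchar(fwd_reads)
  need_rev <- sc_f / len < min_score_per_base
  sc_r <- rep(-Inf, length(sc_f))
  aln_r <- NULL
  if (any(need_rev)) {
    aln_r <- align_pass(rev_reads[need_rev])
    sc_r[need_rev] <- Biostrings::score(aln_r)
  }
  use_rev <- need_rev & sc_r > sc_f
  best <- pmax(sc_f, sc_r)
  alignable <- best / len >= min_score_per_base

  dropped <- bind_rows(dropped,
                       tibble(read_id = reads$read_id[!alignable],
                              reason = rep("unalignable", sum(!alignable))))

  keep_idx <- which(alignable)
  ref_bases <- matrix(NA_character_, length(keep_idx), L)
  pat_f <- as.character(Biostrings::pattern(aln_f))
  sub_f <- as.character(Biostrings::subject(aln_f))
  st_f <- S4Vectors::start(Biostrings::subject(aln_f))
  if (!is.null(aln_r)) {
    pat_r <- as.character(Biostrings::pattern(aln_r))
    sub_r <- as.character(Biostrings::subject(aln_r))
    st_r <- S4Vectors::start(Biostrings::subject(aln_r))
    rev_pos <- which(need_rev)  # index into reads of each aln_r element
  }
  for (j in seq_along(keep_idx)) {
    i <- keep_idx[j]
    if (use_rev[i]) {
      k <- match(i, rev_pos)
      ref_bases[j, ] <- aligned_ref_bases(pat_r[k], sub_r[k], st_r[k],
                                          rev_reads[i], L)
    } else {
      ref_bases[j, ] <- aligned_ref_bases(pat_f[i], sub_f[i], st_f[i],
                                          fwd_reads[i], L)
    }
  }
  list(
    alignments = tibble(read_id = reads$read_id[keep_idx],
                        score = best[keep_idx],
                        orientation = ifelse(use_rev[keep_idx],
                                             "reverse", "forward")),
    ref_bases = ref_bases,
    dropped = dropped
  )
}
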