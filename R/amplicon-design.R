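# Amplicon design container: reference sequence, primer spans, CpG map.

#' Construct a bisulfite amplicon design
#'
#' Bundles the unconverted reference sequence of one amplicon with its
#' primer annealing spans and the 0-based offsets of the C of every CG
#' dinucleotide between the primers. All coordinates are 0-based
#' half-open on the reference.
#'
#' @param name amplicon label.
#' @param reference unconverted reference sequence (A/C/G/T string).
#' @param primer_fwd,primer_rev integer length-2 vectors `c(start, end)`,
#'   0-based half-open spans of the primer annealing sites.
#' @param cpg_positions strictly increasing 0-based offsets of CpG
#'   cytosines between the primers.
#' @param strand `"+"` or `"-"`.
#' @return an `amplicon_design` object.
#' @export
amplicon_design <- function(name, reference, primer_fwd, primer_rev,
                            cpg_positions, strand = "+") {
  stopifnot(is.character(reference), length(reference) == 1L)
  reference <- toupper(reference)
  if (grepl("[^ACGT]", reference)) {
    stop("reference may contain only A/C/G/T", call. = FALSE)
  }
  L <- nchar(reference)
  stopifnot(length(primer_fwd) == 2L, length(primer_rev) == 2L,
            primer_fwd[1] < primer_fwd[2], primer_rev[1] < primer_rev[2],
            primer_rev[2] <= L, strand %in% c("+", "-"))
  cpg_positions <- as.integer(cpg_positions)
  if (is.unsorted(cpg_positions, strictly = TRUE)) {
    stop("cpg_positions must be strictly increasing", call. = FALSE)
  }
  if (any(cpg_positions < primer_fwd[2]) || any(cpg_positions >= primer_rev[1])) {
    stop("cpg_positions must lie between the primer spans", call. = FALSE)
  }
  bases <- strsplit(reference, "")[[1]]
  ok <- bases[cpg_positions + 1L] == "C" &
    bases[cpg_positions + 2L] == "G"
  if (!all(ok)) {
    stop("every cpg_position must point at the C of a CG dinucleotide",
         call. = FALSE)
  }
  structure(
    list(name = name, reference = reference,
         primer_fwd = as.integer(primer_fwd),
         primer_rev = as.integer(primer_rev),
         cpg_positions = cpg_positions, strand = strand),
    class = "amplicon_design"
  )
}

#' @export
print.amplicon_design <- function(x, ...) {
  cat("<amplicon_design> ", x$name, "\n",
      "  reference: ", nchar(x$reference), " bp (", x$strand, ")\n",
      "  CpGs between primers: ", length(x$cpg_positions), "\n", sep = "")
  invisible(x)
}

#' Packaged TSDR-like amplicon fixture
#'
#' A synthetic amplicon modelled on the human FOXP3 TSDR (CNS2) bisulfite
#' amplicon: the primer annealing sequences are the bisulfite-converted
#' forms compatible with the published human primer pair, and the
#' inter-primer region carries exactly 15 CpG dinucleotides, matching the
#' number of TSDR CpGs covered by the assay. The sequence itself is
#' engineered (marked synthetic), not the genomic hg19 sequence, so no
#' genome download is required; each CpG unit also carries one non-CpG
#' cytosine so that bisulfite conversion rates are estimable per read.
#'
#' @return an [amplicon_design()] with 15 `cpg_positions`.
#' @export
make_tsdr_fixture <- function() {
  # primers are C-free, hence identical before and after conversion
  fwd <- "TTGTTTGGGGGTAGAGGATTTAG"          # forward primer (converted strand)
  rev_rc <- "GGGGTTTTTAAATAGTATAATATTAGG"   # revcomp of the reverse primer
  # 16-mer unit: one non-CpG C (pos 3) and one CpG (pos 8)
  unit <- "ATTCATTACGTGGTTA"
  inner <- strrep(unit, 15L)
  reference <- paste0(fwd, inner, rev_rc)
  cpg <- nchar(fwd) + 16L * (0:14) + 8L
  amplicon_design(
    name = "TSDR_synthetic",
    reference = reference,
    primer_fwd = c(0L, nchar(fwd)),
    primer_rev = c(nchar(fwd) + nchar(inner), nchar(reference)),
    cpg_positions = cpg,
    strand = "+"
  )
}
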