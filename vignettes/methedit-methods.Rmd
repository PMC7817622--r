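---
title: "Models and methods behind methedit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methedit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methedit)
```

## The analysis problem

CRISPR-dCas9 fused to the TET1 catalytic domain can direct active DNA
demethylation to a chosen locus, for example the Treg-specific
demethylated region (TSDR/CNS2) of the *FOXP3* gene, whose demethylated
state marks stable regulatory T cells. Evaluating such an epigenome
editing experiment downstream of the wet lab requires four layers of
computation, and `methedit` implements all of them as tibble-in /
tibble-out functions:

1. **Per-read amplicon methylation** — from bisulfite amplicon
   sequencing reads to per-molecule CpG methylation calls, QC, pattern
   maps, read classes and summary percentages.
2. **Array-scale differential methylation** — from replicate beta-value
   matrices to delta-threshold hypo-/hyper-methylated probe sets,
   locus clustering and PCA.
3. **Enrichment** — two-sided Fisher exact tests of CpG subsets
   (binding-site windows, predicted off-target windows) within the
   differential sets, and per-gene Fisher enrichment of top
   principal-component loadings corrected for gene probe totals, with
   Benjamini–Hochberg FDR.
4. **Integration** — intersection of hypo-CpG-associated genes with
   differential-expression gene sets.

Because the raw study-scale data of such experiments are typically
access-controlled, the package ships seeded generators for every input
with planted ground truth, so the complete pipeline is exercised and
validated end to end on synthetic data.

## Exact statistics

All enrichment p-values come from one audited kernel. The
hypergeometric pmf is computed in log-space (`lchoose`, exponentiated
last) and the two-sided Fisher p-value is the sum of the pmf over all
tables with the observed margins whose probability does not exceed the
observed probability times $1 + 10^{-7}$; the relative tolerance
absorbs floating-point ties among equal-probability tables, matching
common reference implementations. The unconditional odds ratio
$(ad)/(bc)$ is reported with explicit zero-cell conventions: infinite
(enriched) when only $bc = 0$, zero (depleted) when only $ad = 0$,
undefined with direction "none" when both vanish; no Haldane
correction is applied. One-sided and mid-p variants are out of scope.
The study context does not record whether its Fisher tests were one-
or two-sided nor which FDR variant was used; two-sided tests with
Benjamini–Hochberg step-up were adopted as the field default, not
asserted as the original's certainty.

BH-FDR is the literal step-up: with order statistics
$p_{(1)} \le \dots \le p_{(n)}$,
$q_{(i)} = \min_{j \ge i} p_{(j)} \, n / j$, capped at 1, returned in
input order. The test suite checks the kernel against exhaustive
enumeration for every 2×2 table with $N \le 40$ (relative error below
$10^{-12}$) and against an $O(n^2)$ literal-definition oracle and
`p.adjust` for the FDR.

## The amplicon layer

Alignment follows the standard three-letter bisulfite strategy: read
and reference are C→T converted so that methylation state cannot bias
the alignment, then methylation is called from the *original* read
base at each reference CpG column (C → methylated, T → unmethylated,
anything else missing). The semi-global alignment (free end-gaps on
the reference; match +1, mismatch −1, gap −2, score floor 0.5 per
base) is delegated to `Biostrings::pairwiseAlignment`. Reads are
assumed primer-trimmed or full-amplicon; overhangs are absorbed by the
free end-gaps, so no clipping stage exists. A reverse-orientation pass
(reverse complement, then C→T) is attempted when the forward pass
fails the floor, and the better-scoring pass wins.

Per read, three QC statistics are computed: bisulfite conversion rate
(fraction of non-CpG reference cytosines read as T), identity over
non-C reference columns, and CpG coverage. The defaults of
`filter_reads()` — conversion ≥ 0.95, identity ≥ 0.9, coverage ≥ 0.8 —
are deliberate, exposed choices: upstream semi-automated QC tools do
not publish their thresholds, so these are set at values conventional
for amplicon bisulfite QC and can be changed per call. Note that with
only 15 conversion witnesses per read, a 0.95 threshold rejects any
read showing a single conversion failure; at a failure rate of 0.005
this removes about 7% of reads without biasing CpG-level estimates,
because conversion failures at witness and CpG positions are
independent.

Pattern maps sort reads by mean methylation (descending, ties by
pattern string — deterministic); the sorting key of the original
in-house maps is not recorded, so it is configurable. Read classes use
the methylated fraction over non-missing calls with thresholds 0.1/0.9
(`fully_demethylated` / `heterogeneous` / `fully_methylated`),
capturing the distinction between complete editing and the
heterogeneous patterns of partial editing.

## The array layer

Beta values (per-CpG methylated fraction, 0 = unmethylated, 1 = fully
methylated) are consumed already normalised; array preprocessing,
probe filtering and liftover are out of scope. `compare_groups()`
computes per-probe group means and
`delta = mean(reference) − mean(treatment)`, so "hypo in treatment"
is `delta ≥ threshold` (default 0.2, the conventional delta cut). The
sign convention was a genuinely open choice: the source context only
writes "Δ ≥ 0.2" and names the sets "hypo"; defining delta as
reference-minus-treatment makes hypo sets positive, which reads
naturally. Group means over replicates (rather than per-pair deltas)
were assumed. Missing data are handled complete-case per analysis —
no imputation is described anywhere in the source context, and
imputation would blur the planted-truth accounting; dropped probe
counts are always reported (`used + dropped = total`).

PCA treats samples as observations and probes as centred, unscaled
features (the `prcomp` default; no M-value transform is applied as
none is described) but is implemented from the definition via singular
value decomposition, with a deterministic sign convention — the
largest-magnitude loading of each component is made positive — so that
results are reproducible across BLAS implementations. Components whose
singular value falls below $10^{-8}$ of the largest (the direction
consumed by centring) are dropped from the output; variance fractions
are computed over the full spectrum and therefore still sum to one.
`prcomp` itself serves as an independent cross-check in the tests,
never as the implementation. Hierarchical locus clustering uses
Euclidean distances and average linkage by default; linkage is not
recorded in the source context and is exposed as an argument.

## Enrichment procedures

Genomic windows are 0-based half-open throughout; `extend_windows()`
adds a symmetric flank (default 1000 bp, i.e. 1 kb up- and downstream)
with clipping at zero and no merging. Binding-site windows and
predicted off-target windows are handled by the same ±flank extension,
unifying the two phrasings of the source procedure.
`select_top_offtargets()` keeps the 50 highest-scoring predictions per
sgRNA by default; score ties at the boundary are all retained (logged)
rather than broken arbitrarily. `probes_in_windows()` is a half-open
point-in-interval test via GenomicRanges overlap, with set semantics
(overlapping windows count a probe once).

`subset_enrichment()` builds `a = |subset ∩ focal|`,
`b = |subset \ focal|`, `c = |focal \ subset|`, `d` = rest of the
background. The background defaults to all probes surviving the
complete-case filter of the comparison that produced the focal set;
the source context is silent on this, so it is an explicit argument.

`gene_enrichment()` tests, per gene with at least one hit among the
focal CpGs, `a` = hits, `b` = remaining focal CpGs, `c` = remaining
probes of the gene, `d` = remaining manifest probes — correcting each
gene for its total probe representation on the array — then applies
BH-FDR across tested genes and ranks by q, then p, then label. The
exact 2×2 construction is not printed in the source context; this
construction follows its stated intent (correct for the per-gene probe
total) and is flagged as such rather than asserted. "Associated with"
a component is read as absolute loading magnitude (signed alternatives
via the `direction` argument). Probes without gene annotation
participate in backgrounds but never form a tested gene; multi-gene
probes hit each annotated gene.

## Integration

`simple_de()` is a deliberately plain substitute for a count-model
differential-expression engine (which is out of scope): per gene a
Welch t-test on log2 values, BH-FDR, and thresholds `|log2FC| ≥ 1`,
`q ≤ 0.05`. Externally computed gene lists can be passed directly to
`annotate_and_intersect()`, which maps hypo-CpGs to genes via the
manifest and intersects sequentially with each supplied set — no
direction concordance (hypo-methylated ⇒ up-regulated) is required by
default, since none is recorded in the source procedure. Gene matching
is case-sensitive exact, with an opt-in upper-casing flag.

## What the generators emulate — and what they do not

`make_tsdr_fixture()` is an engineered synthetic amplicon: its primer
annealing sequences are compatible with the published human TSDR
bisulfite primer pair (both primers are cytosine-free, hence identical
before and after conversion) and its inter-primer region carries
exactly 15 CpGs — the number covered by the assay — each packaged with
one non-CpG cytosine so conversion rates are estimable. It is *not*
the genomic hg19 sequence; no conclusions about genomic coordinates
should be drawn from it.

`simulate_bisulfite_reads()` draws each molecule from a weighted
mixture of per-CpG methylation-probability components, applies
incomplete conversion (an unmethylated C is retained with the failure
probability, default 0 and set to 0.005 in the validation runs — a
typical residual rate for modern kits) and uniform substitution
errors. It does not model PCR amplification bias, paired-end
structure, indels or quality-score variation; quality is a constant
Phred+33 'I'. Consequently a passing recovery test demonstrates the
correctness of the calling arithmetic, not robustness to all MiSeq
artefacts.

`simulate_probe_manifest()` defaults to the EPIC scale (865,859
probes) on 22 synthetic chromosomes with sorted unique positions
(mean spacing 5 kb), contiguous gene runs (shifted negative-binomial
sizes, mean 8 probes per gene), 15% intergenic probes and 2%
dual-annotated probes. Probe chemistry (type I/II), islands and real
gene geometry are not modelled. `simulate_beta_matrix()` draws
baselines from a bimodal Beta mixture (the classical two-peak array
profile), adds planted signed deltas to the designated group, and adds
Gaussian replicate noise (default sd 0.03, a typical technical
replicate sd for arrays) clamped to [0,1]. Baselines of planted probes
are drawn from the sub-interval of [0,1] that can absorb the full
effect, so planted differences are realised undistorted by clamping —
a generator property, stated here so that recovery results are read
correctly: they quantify the pipeline under effects that truly have
the planted size. Additive Gaussian noise (rather than a Beta noise
model) suffices because the pipeline consumes means and differences
only.

`simulate_region_sets()` places small windows centred on probes drawn
with weight `odds` inside the enriched stratum and 1 outside, giving a
coverage odds equal to the configuration in expectation; `odds = 1` is
an exact null. `simulate_expression()` plants additive log2 effects
with Gaussian replicate noise. Every generator requires a seed —
never defaulted from the clock — and identical seeds give
byte-identical outputs.

## Validation scale and numerical choices

The shipped validation suite runs, on one CPU, at these deliberately
chosen problem sizes: exhaustive Fisher enumeration to table total 40
and pmf normalisation to 60; 100 random FDR vectors up to length
1,000; 5,000 reads for amplicon parameter recovery (estimates within
three binomial standard errors, unmethylated CpGs at the
conversion-failure floor); 10,000 probes with 200 planted deltas of
0.5 at noise sd 0.03 for differential-set recovery (sensitivity ≥
0.99, null calls ≤ 1%); 1,000 null and 200 odds-3 region-set draws for
the size (≤ 7% at α = 0.05 — the Fisher test is conservative) and
power (≥ 90%) of subset enrichment; and a 4,000-probe two-group design
with 10 planted signature genes for the end-to-end
PCA → top-loadings → gene-enrichment recovery. `run_demo()` runs the
whole pipeline at a 20,000-probe scale in well under a minute.

Headline biological numbers of the motivating study (e.g. its count
of edited-hypo CpGs or its intersected gene tally) depend on
access-controlled donor data and are not reproduction targets;
what the synthetic suite establishes is that every procedural step —
the exact tests, the thresholds, the rankings, the intersections —
computes what it claims on inputs whose truth is known.

## Known limitations

* Single-end, indel-light amplicon reads; no paired-end merging and no
  CpG re-positioning beyond alignment columns.
* Enrichment is probe-set based; genomic-region (segment-level)
  enrichment is out of scope.
* `simple_de` is not a replacement for a dispersion-modelling DE
  engine at realistic depths; it exists so the integration logic can
  be validated independently of one.
* The generators model noise as independent across probes, reads and
  replicates; correlated batch or donor structure is not emulated, so
  passing tests do not certify behaviour under such confounding.
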