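---
title: "Methods: detection and characterization of UBTF exon-13 tandem duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection and characterization of UBTF exon-13 tandem duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubtftd)
```

## The problem

Internal tandem duplications of exon 13 of *UBTF* (UBTF-TDs) define a
subtype of acute myeloid leukemia. The lesion is an in-frame insertion:
a segment containing a 21-nt core (c.1306–c.1326 on the coding sequence,
codons 436–442, encoding the leucine-rich ELLTRLA motif of the HMG4
domain) is duplicated in tandem, frequently with a few non-templated
nucleotides at the junction and, especially in duplications larger than
100 bp, small internal deletions in the second copy. TD sizes concentrate
at 48, 51 and 54 bp but range from 39 bp to more than 900 bp. Standard
small-variant callers mis-annotate these events, so detection relies on a
dedicated evidence model: soft-clipped reads at the two junctions,
elevated coverage over the duplicated interval, and the observation that
affected samples always show at least some non-reference signal in the
gene.

`ubtftd` implements this workflow end to end — simulation, screening,
calling, annotation, clonal inference, and the associated contingency
statistics — against a fully synthetic, deterministic locus, so every
stage is testable without access to patient data.

## The synthetic locus

`ubtf_fixture_model()` builds a 2052-bp forward-strand locus holding
exons 12–14 (120 bp each; CDS c.1171–c.1530) with introns of 150 and
142 bp. Design constraints:

* exon 13 carries the ELLTRLA core at codons 436–442 and Trp-Asn-Asp at
  codons 445–447 (the preferred internal-deletion target);
* the exon-12 to exon-14 primer pair spans exactly 617 bp, so a TD of
  total inserted length $L$ yields a mutant amplicon of $617 + L$ bp;
* intron lengths are chosen so that the 598-bp duplication spanning both
  introns carries 306 exonic bases — a multiple of 3, reproducing the
  in-frame exon13–exon13 fusion geometry;
* every 15-mer in the locus is unique (the builder re-seeds until this
  holds), which makes exact-seed breakpoint anchoring unambiguous.

All genomic intervals are 0-based half-open; CDS positions are 1-based
(HGVS style). Conversions happen only in `genomic_to_cds()` /
`cds_to_genomic()`.

## The cohort generator

`sample_cohort()` draws one TD per patient from fixed study conditions:
sizes 48/51/54 with probabilities 18/59, 10/59, 6/59; a log-uniform tail
over 39–950 bp (intra-exonic tail sizes rounded to multiples of 3; large
sizes may gain up to 12 bp from frame phasing); one non-core class in 59
(a 42-bp duplication encoding GLCLRFNQLDLDQA); internal-deletion
probabilities 0.13 below 100 bp and 0.64 above; non-templated inserts of
0–6 nt; allele fractions logit-normal with `mu = logit(0.45)` and
`sigma = 0.335`; co-mutation rates led by *WT1* (0.63) and *FLT3*-ITD
(0.53). The logit-normal cannot match the reported median and both
quartiles simultaneously; the median (0.45) is matched exactly and the
implied quartiles (0.395, 0.506) are accepted as an approximation of the
reported interquartile range.

Two representation conventions keep cohort-level set operations
well-defined:

* **Recurrent breakpoints.** The 48- and 51-bp classes start at the core
  5' edge (c.1306); the 54-bp class crosses the intron-12/exon-13
  boundary and ends at the core 3' edge. Recurrent breakpoints are a
  feature of this mutation class, and they make the cohort intersection
  (below) identifiable: whenever both a 48- and a 54-class patient are
  present, the intersection is exactly c.1306–c.1326.
* **Left-most normal form.** A junction insert whose last base equals
  the reference base preceding the duplication describes the same allele
  as a 1-bp-shifted duplication with a shorter insert; the generator
  redraws such bases, and the caller reports the 5'-most placement with
  the shortest insert, so generator and caller agree on a unique
  representation.

Deletions are drawn as multiples of 3 (frame-preserving), target codons
445–447 when the copy covers them, never touch the core, never straddle
an exon boundary, and sit at least 18 bp from the copy 5' end —
junction-proximal deletions are observationally equivalent to longer
non-templated inserts and therefore not generated.

## Read simulation

`simulate_reads()` emits pre-aligned paired 150-bp reads (SAM
data-frame) from a mixture of haplotypes. Fragments are allocated to
haplotypes proportionally to `fraction x haplotype length`, so per-base
depth is identical across alleles, as in real sequencing. Reads from the
mutant haplotype are mapped back to the reference by an in-silico
aligner that reproduces the signatures a short-read aligner would emit:

* reads wholly inside either copy (or outside) align as plain matches,
  with `D` operations where the second copy carries internal deletions;
* junction-crossing reads whose whole inserted block fits inside the
  read with ≥15 bp anchors become `xM L I yM` records;
* other junction reads are soft-clipped on their minor side, producing a
  right-clip cluster at the duplication 3' end and a left-clip cluster
  at its 5' start;
* reads with fewer than 20 matchable bases are dropped (unmappable).

Substitution errors are added at 0.1%; indel errors are not modeled
(they would confound the caller's evidence model and no error profile is
given for the assay). Read and trace simulation, cohort sampling and
timepoint sampling are all byte-deterministic under their seeds.

Two consequences of this geometry matter downstream. First, the mean
depth over the duplicated interval relative to flanks converges to
`1 + f` (f = allele fraction) only when the TD is much longer than the
read length; for short TDs the duplicated bases ride inside `I`/`S`
segments that do not map to the reference, so the coverage excess is
attenuated. This is why the coverage-based VAF is the fallback for large
TDs only. Second, the mutant allele's second copy rejoins the reference
contiguously, which biases naive junction-based VAFs (next section).

## The caller

`call_tds()` runs four stages:

1. **Suspicion scan** — any soft clip, CIGAR indel, or substitution
   pileup above the error model within exon 13 ± 1500 bp. No call is
   ever emitted without this flag, mirroring the observation that
   TD-positive samples always show at least one mismatch signal.
2. **Soft-clip clustering** — clips ≥10 bp grouped by side and
   breakpoint (±3 bp), majority-vote consensus per cluster, ties to the
   lexicographically smallest base, clusters under 3 reads discarded.
3. **Reconstruction** — each right-clip consensus (and each
   CIGAR-insertion group) starts at the junction `p2` and consists of
   the non-templated insert followed by the second copy. A 15-mer seed
   is matched exactly against the reference window upstream of `p2`,
   trying insert prefixes of 0–12 nt (shortest first, which implements
   the left-most convention); the remainder is walked in 15-mer chunks,
   bridging gaps of up to 120 bp as internal deletions. This yields
   `[p1, p2)`, the insert, the deletions, and the total inserted length
   `(p2 - p1) + |insert| - |deletions|`. Left-clip evidence at `p1`
   (or a CIGAR-insertion record) is required for full support; calls
   without it are flagged `partial_evidence`. A consensus that
   re-anchors at or after `p2`, or not at all, is reported as
   `no-duplication`. Exact seeding was chosen over semi-global
   alignment because ends-free alignment tends to absorb short
   non-templated inserts into mismatching flank alignment, shifting
   `p1`; with unique 15-mers, exact seeding is unambiguous and
   deterministic.
4. **VAF estimation** — two estimators. The junction estimator counts
   junction-supporting reads `s` (clips at either breakpoint plus
   insertion records) and junction-free reads `n` spanning `p2` with
   ≥10 bp mapped on both sides. Because the mutant allele's second copy
   re-enters the reference contiguously, mutant molecules also
   contribute junction-free spanning reads: in expectation
   `s ∝ f·w_j` and `n ∝ (1-f)·w_j + f·w_m`, where
   `w_j = R - 2θ + 1` is the junction-capture window and
   `w_m = min(L - |insert| - θ, R - 2θ) + 1` is the window in which a
   mutant read can span `p2` without junction signal (R = read length,
   θ = spanning anchor, L = inserted length). Solving for `f` gives

   `vaf_breakpoint = s / (n + s·(1 - w_m/w_j))`,

   capped at 1.05. The naive `s/(s+n)` converges to `f/(1+f)` for large
   TDs (0.31 at f = 0.45) and is not used. The coverage estimator is
   `depth(duplicated interval, trimmed by min(R/2, span/4) per side) /
   mean(flank depth) - 1`. The reported VAF is the junction estimate
   when support ≥ 3 reads, else the coverage estimate. The junction
   estimator retains a small (≈1–2 percentage point) downward bias at
   typical settings because clip-representation reads additionally
   require 20 mapped bases while spanning reads require only 10, which
   slightly narrows the effective support window; this is well inside
   the tolerance of all downstream uses. Calls below 1% VAF — the
   assay's stated sensitivity — are suppressed.

## Annotation

`splice_aware_frame()` projects the duplication through the exon model:
retained inserted coding length = exonic overlap of `[p1, p2)` plus the
junction insert when the junction is exonic minus exonic deleted bases.
The TD is in frame iff this length is a multiple of 3. A duplication
containing all of exon 13 is annotated as an exon13–exon13 fused
transcript. Breakpoints inside a splice-site dinucleotide give a
`splice_disrupting` annotation with undefined frame. The reported
peptide is the translation of the codons spanned by the duplicated
coding region (deletions inside calls are not re-projected into the
peptide — a documented simplification). `minimal_duplicated_region()`
intersects the duplicated CDS intervals of core-containing calls;
non-core calls are excluded and listed, and an empty intersection
returns `NA` with pairwise-overlap diagnostics rather than a guess. The
summary reports the computed interval and its length; note that the
coordinates c.1306–c.1326 span 21 nt (7 codons), which is what the
intersection yields here.

## Fragment-analysis screen

`simulate_trace()` renders Gaussian peaks (sd 0.6 bp) at the wild-type
size and at `wt + L`, heights proportional to `1 - f` and `f`, with
optional ±1 bp stutter satellites (8%) and uniform baseline noise.
`call_peaks()` takes local maxima above 5% of the trace maximum, assigns
the peak within ±2 bp of the expected wild-type size as wild-type,
labels ±1 bp satellites under 15% of their neighbour as stutter, and
calls remaining larger peaks as mutant with TD size
`round(size - wt)`. A missing wild-type peak sets a `no_wt` flag
(possible homozygous mutant or failed reaction) instead of erroring;
mutant peaks beyond the 1200-bp sizing standard are flagged. Sizes are
treated as already ladder-calibrated; none of these thresholds are
published for the assay, so all are exposed in the function interface.

## Clonal evolution

Cancer-cell fractions are `VAF x total/mutated copies`: x2 for
diploid-heterozygous variants, x1 for copy-neutral homozygous (UPD)
variants and for mutations with loss of the other allele. Purity is
fixed at 1 (blast-enriched material assumed) — a documented limitation.
Copy-number state is an input per variant and timepoint, not inferred.

`build_clone_tree()` clusters variants into clones when their CCFs agree
within `max(0.1, 3 x pooled binomial SE)` at both timepoints, then
nests clones greedily in descending CCF order: each clone attaches to
the smallest already-placed clone whose CCF contains it within
tolerance 0.1 at both timepoints; when sibling CCFs would exceed the
parent's, the clone is forced into the largest sibling's lineage
(the pigeonhole rule — variants whose CCFs cannot fit side by side must
co-occur). Founding ties prefer the UBTF-TD variant, then diagnosis
CCF, then variant id, making output fully deterministic. Inconsistent
inputs yield an `unresolved` tree listing the violated constraints, not
a silent guess.

Bulk VAFs at two timepoints identify a clone tree only when clones are
well separated and no clone "fits inside" a non-ancestor:
`plant_architecture()` therefore rejection-samples trees whose clones
differ by ≥0.3 CCF at one timepoint or more and in which every
non-ancestral pair shows a dominance swap. This mirrors how
fishplot-style reconstructions from bulk data are made in practice and
defines the population over which recovery is measured (≥90% exact
topology, prevalence MAE ≤0.05 over 50 planted architectures of 2–5
clones at 500x in the test suite).

WT1 status is biallelic when two WT1 variants share one lineage, or one
is UPD-homozygous, or one co-occurs with deletion of the second allele;
relapse patterns follow from which components of the relapse-driving
configuration are detectable (≥1% VAF) at diagnosis
(`bi_alt_preexisting` / `bi_alt_from_mono` / `bi_alt_emergent`), with
`mono_on_flt3` for a monoallelic WT1 hit newly arising inside a
persistent FLT3-ITD clone.

## Contingency statistics

`fisher_exact_two_sided()` implements the exact hypergeometric test with
the probability-mass two-sided rule (sum of all margin-consistent tables
whose probability does not exceed the observed one, within a 1e-7
relative tolerance). This convention reproduces the remission-rate
comparisons printed for the cohort (p = 0.024 for 4/10 vs 10/11 and
p = 0.020 for 4/10 vs 38/48); the test suite additionally checks
agreement with R's reference enumeration over every table with total
≤ 60. Degenerate margins return p = 1 with a flag.
`benjamini_hochberg()` is the standard step-up FDR adjustment, checked
against `p.adjust`. The sample odds ratio `ad/bc` is reported alongside
(the conditional-MLE odds ratio is deliberately not computed).

## Problem sizes and determinism

The test suite runs read-level experiments at scales chosen for a
laptop-class machine: a 40-patient calling cohort at 300x, 50 VAF
replicates at 500x, VAF-accuracy grids at 1000x, depth-ratio checks at
2000x, 50 planted clonal architectures at 500x, and a 5000-patient
generator cohort for distributional checks. All randomness flows through
explicit integer seeds; rerunning any simulation with the same seed
reproduces its output byte for byte.

## What the synthetic tests do and do not show

The generator reproduces the documented size spectrum, junction
structure, allele-fraction distribution, co-mutation frequencies and
paired-timepoint dynamics, but not every property of real data: bases
have uniform quality and only substitution errors; alignment is
idealized (no mapping ambiguity from the paralogous pseudogene, no PCR
duplicates, no strand artifacts); the locus is a scaled-down surrogate
with random intronic/flanking sequence rather than the real repetitive
context; and clonal architectures are restricted to identifiable
configurations. Passing tests therefore demonstrate correctness of the
algorithms under their stated evidence model, not performance on
clinical sequencing data; on real data the caller's thresholds
(`caller_config()`) and the gene model (`read_gene_model()`) are meant
to be supplied by the user.
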