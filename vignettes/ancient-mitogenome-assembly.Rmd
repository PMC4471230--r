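---
title: "Reconstructing an ancient mitochondrial genome: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing an ancient mitochondrial genome: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleomito)
```

## The problem

DNA surviving in subfossil bone is short (tens of nucleotides), scarce
(often well below 1% of the sequenced library), chemically damaged, and
mixed with environmental and modern contaminant DNA. Reconstructing a
mitochondrial genome from such material is nevertheless tractable because
mitochondria are present in hundreds of copies per cell: a shotgun library
that covers the nuclear genome at ~0.01-fold can still cover the
mitogenome at ~10-fold. paleomito implements the full computational
workflow for this setting: simulation of realistic ancient reads,
damage-aware iterative reference-guided consensus assembly, competitive
species identification, misincorporation profiling, polymorphism
classification, annotation transfer and distance-based phylogenetic
placement.

## The damage model

Post-mortem hydrolytic deamination converts cytosine to uracil,
preferentially in the single-stranded overhangs at fragment ends. After
end repair and sequencing this appears as C→T mismatches near the 5' end
of a read and G→A mismatches near the 3' end (the complementary strand's
C→T read through repair). The generative model used by
`simulate_reads()` applies, on the read strand after fragmentation,

* C→T at 5' offset *k* with probability `delta5 * decay^k`,
* G→A at 3' offset *k* with probability `delta3 * decay^k`,
* then a uniform per-base sequencing error `seq_error`.

A single-parameter geometric decay is the simplest shape that reproduces
the characteristic exponential-looking fall-off of published terminal
misincorporation profiles; the published study this package emulates
reports the signature qualitatively but no fitted rates, so the defaults
(`delta5 = delta3 = 0.3`, `decay = 0.5`, `seq_error = 0.001`) are free
parameters chosen to be typical of a Pleistocene bone library, not
estimates of that study's values. `damage_profile()` recovers
`delta * decay^k` from perfectly mapped simulated reads within binomial
error — the round-trip property the test suite pins.

Fragment lengths follow a truncated geometric distribution on
[20, 101] nt (`fragment_model()`); 20 nt is the shortest read retained
after trimming and 101 nt the sequencing read length. The default decay
rate 0.034 puts the mean fragment at 43.3 nt, matching the mean unique
read length implied by the emulated study's printed totals (166,849
aligned bases over 3,851 unique reads).

## Mapping: bounded-edit-distance, ungapped, circular

Reads are aligned with `map_reads()` under an explicit contract rather
than behind an external aligner binary:

* **Ungapped only.** The workflow's aligner settings always disabled gap
  opening; indel alignment is therefore omitted entirely, and length
  differences between sample and reference enter only through PCR
  evidence.
* **Mismatch budget** (`edit_schedule()`): `absolute` (a constant, the
  first assembly pass uses 2), `perfect` (the species screen), or
  `fraction`, the classical short-read rule — the smallest *k* with
  `P(X > k) < n` for `X ~ Poisson(0.02 · read length)`. With `n = 0.1`
  this yields 1 mismatch for 20–26-nt reads rising to 4 for 88–101-nt
  reads.
* **Circularity** by searching the doubled sequence and reducing start
  positions modulo the genome length; alignments longer than the genome
  are rejected.
* **N never matches** anything, in read or reference.
* **Mapping quality** is a three-level proxy for "confidently unique":
  37 when a single placement attains the minimum mismatch count and none
  sits within one mismatch of it, 25 when the best is unique but a
  placement exists at best+1, 0 when the best is tied. The consensus
  policy consumes exactly one bit of this — placement confidence at the
  ≥25 level — so a faithful re-implementation of a full aligner quality
  model would add nothing downstream.

The implementation seeds candidate positions with exact matches of
`bound + 1` disjoint read segments (pigeonhole-complete) and verifies
candidates by Hamming count; the test suite proves equivalence against an
exhaustive sliding-window search on small genomes for every schedule.

Duplicate removal (`deduplicate()`) collapses placements sharing
(reference, start, end, strand) — standard PCR-duplicate semantics.
Whether "unique reads" should instead mean sequence-deduplicated is not
decidable from the emulated study's text; coordinate semantics were
chosen because they are what `samtools markdup` and every modern ancient
DNA pipeline use.

## Consensus calling and the damage rule

`assemble()` performs three rounds. Round 1 maps to the external
reference (absolute budget 2), deduplicates, and calls a provisional
consensus; positions without a call keep the reference base, which keeps
the coordinate frame stable for round 2 and is always either overwritten
by later evidence or reported as a problem position, never silently
accepted. Round 2 remaps all reads to the provisional consensus under the
fraction schedule, recovering reads the stricter first pass rejected.
Round 3 integrates PCR consensus sequences, each as **one** evidence unit
over its placement interval regardless of how many clones were sequenced
(they are single molecules of evidence in the same sense as a read, and
are exempt from the mapping-quality filter since their placement is not
in question).

A position is **called** when at least `min_evidence = 2` concordant
evidences agree and the minority fraction is at most
`discordance_threshold = 0.25`, with a strict majority required — an
exact tie is no consensus. Above the discordance threshold the position
is flagged, **unless** every minority observation reads A where the
majority says G within `damage_window = 10` nt of its read's 3' end, or
the strand-mirrored C/T case at the 5' end, in which case the majority
base is accepted with status `resolved_damage`. This mechanises what the
emulated workflow did by manual inspection; residual flags are routed to
the verification list rather than auto-accepted. Positions with no
evidence form the gap list and positions with one evidence the
single-evidence list; in a real campaign these drive PCR primer design,
and `design_pcr_evidence()` emulates exactly that closure step on
simulated truth.

`verify_fixed_point()` closes the loop: remapping all reads to the final
consensus and re-calling must reproduce the consensus at every called
position. On clean simulations this holds by construction; the test
suite also shows a single corrupted base is detected.

The final consensus is reported on the reference coordinate frame
(circular, origin at the reference's position 1). Because both read and
PCR placement are ungapped, an indel present in the true sample genome
appears as a low-coverage/discordant neighbourhood rather than as a
length change; the package's genome-comparison module, which aligns with
affine gaps, is the instrument that measures indels.

## Genome comparison and polymorphism classification

`pairwise_differences()` globally aligns two same-locus genomes (match
+1, mismatch −1, gap open 4, extend 1, free end gaps — at >99% identity
any sensible scheme gives the same answer, and an exhaustive-DP oracle in
the tests pins the contract). Equal-length high-identity pairs take a
gapless fast path guarded against hidden frame shifts. Gap runs are
left-normalised so placement is deterministic. Each substitution and each
contiguous indel run is one record; a multi-nucleotide deletion is one
difference event. `classify_against_annotation()` adds feature context
(precedence CDS > tRNA/rRNA > D-loop > intergenic), strand- and
frame-aware codon positions, and amino-acid effects under the vertebrate
mitochondrial genetic code (NCBI table 2, in which AGA/AGG are stops).
`specific_polymorphisms()` retains the records whose sample allele no
panel genome carries at the homologous position, and
`region_rate_ratio()` computes the per-nucleotide rate contrast that
shows the control region's accelerated evolution.

The variant generator (`plant_variants()`) resamples any event whose
local context would make the alignment gap placement ambiguous (an
inserted base equal to its neighbours, a deletion extendable into a
homopolymer), so the planted-truth round trip through the aligner is
exact rather than probabilistic.

## Annotation transfer and CDS validation

`lift_annotations()` maps feature boundaries through the global
alignment; a boundary landing in a target gap snaps to the nearest
aligned position, starts rightwards and ends leftwards, so a feature is
never extended into unaligned territory. Fully deleted features are
reported, not dropped. `validate_cds()` then checks each protein-coding
gene: an admissible start (ATG/ATA/ATT/GTG — the mammalian mitochondrial
convention; the accepted set is configurable since usage varies by
taxon), a complete stop (TAA/TAG/AGA/AGG) or an incomplete one (a bare
T or TA completed by polyadenylation, flagged but passing), and no
internal stops.

## Phylogenetic placement

The placement question is topological: does the reconstructed genome
attach outside the clade of modern relatives? `k2p_distance()` (Kimura
two-parameter, which absorbs the strong mitochondrial transition bias),
`nj_tree()` (Saitou–Nei neighbor joining with the standard Q criterion
and deterministic label-order tie-breaking) and `bootstrap_support()`
(site resampling, split frequencies mapped onto the point tree) are
deliberately simple, well-tested components. K2P+NJ stands in for the
composite-likelihood and likelihood machinery a desktop phylogenetics
suite would offer: for mitogenome-scale data at a few percent divergence
every distance/criterion combination recovers the same placement, which
is the only quantity the workflow consumes. This is a method
substitution, documented as such, not an emulation. Supports are mapped
onto the point tree's splits rather than onto a majority-rule consensus
— simpler, and sufficient for reading off one split's support. NJ on
additive matrices is exact (tested against path-distance recovery and an
independent implementation); negative branch lengths, which NJ can
produce on non-additive inputs, are clamped to zero on output and
counted.

## The synthetic study generator

`synthetic_mitogenome()` builds a 16,318-bp circular genome with the
full mammalian mitochondrial complement — 13 protein-coding genes (one
on the minus strand), 22 tRNAs, 2 rRNAs, a 910-nt control region —
whose CDS all validate under the vertebrate code, including three genes
with incomplete terminal stops. `plant_study_profile()` then plants a
fixed event composition emulating an ancient-vs-modern bovine
comparison: 105 transitions and 6 transversions; 24 substitutions plus a
1-bp insertion in the D-loop (25 control-region differences); 73 coding
substitutions at codon positions 1/2/3 in proportions 16/3/54 with
exactly 11 amino-acid changes (all third-position transitions are
synonymous under the mitochondrial code, which is why the planted
third-position events are silent by construction); a 2-bp deletion at a
tRNA-Ser gene end; and a 20-event shared subset for panel construction
leaving 93 sample-specific polymorphisms. These compositions are the
study conditions of the emulated analysis, fixed in the generator, not
tunable test knobs.

What the generator deliberately does **not** model: PCR amplification
bias, indel sequencing errors, base-quality variation (qualities are
written as constant Phred 37 and ignored), microbial taxonomic structure
(contaminants are just reads from user-supplied genomes), and
heterogeneity of damage rates between molecules. Passing tests therefore
demonstrate the pipeline's correctness under its stated model, not
robustness to every artefact of real libraries.

## Problem sizes and numerical choices

The packaged simulations use the emulated study's scale where it
matters: 3,851 reads at a 43.3-nt mean (≈10-fold unique coverage of
16,318 bp), mapping budgets 2 (absolute) and 0.1 (fraction), species
screen at a 30-nt perfect-match threshold, bootstrap from 1,000
replicates in the acceptance script (unit tests use 100–200 replicates
on the same machinery). Mapping-quality, evidence and discordance
thresholds default to 25, 2 and 0.25. Ties are resolved explicitly
everywhere: majority ties are no-consensus, NJ pair ties break by label
order, alignment gap ties are left-normalised, and the damage window is
a strict `offset < 10` on 0-based offsets. Degenerate inputs (empty read
sets, empty panels, features deleted in lift-over, saturated distances)
return explicit statuses or errors rather than silent values.
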