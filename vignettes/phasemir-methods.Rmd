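---
title: "Methods: conserved miRNA analysis for vegetative phase change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved miRNA analysis for vegetative phase change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`phasemir` analyses small-RNA sequencing data from plants at different
maturity states. This vignette documents the models and procedures each
stage implements, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the design choices
made where the design was genuinely open.

## Unique tags

Reads are adapter-trimmed (leftmost exact match of the adapter's first 8
bases; configurable), filtered to the 18–25 nt window that brackets plant
miRNA lengths, and collapsed into unique tags with one count column per
library. Tags whose summed count across *all* libraries is below 5 are
discarded — the threshold is deliberately global rather than per library,
so a tag weakly present in several libraries survives while singleton
sequencing noise does not. Output ordering is deterministic (total count
descending, then sequence) so downstream files diff cleanly.

The minimum length default is 18 nt; 19 nt is a common alternative in
small-RNA work and is available via `run_config(min_len = 19)`.

## Conserved miRNA annotation and isomiR groups

A tag is compared with every reference mature miRNA by enumerating all
ungapped placements in which either tag end overhangs or falls short of the
reference by at most 2 nt; the placement minimising mismatches in the
overlap wins, with at most 2 mismatches tolerated. Overhanging bases are
not mismatches: isomiRs commonly differ from the canonical mature form by
templated or non-templated end bases, and penalising them would conflate
length variation with sequence divergence. Internal gaps are deliberately
excluded here (they are allowed in genome mapping, where indel variation
between species is the relevant process).

Ties are resolved deterministically: fewest mismatches, then smallest total
end offset, then (for family attribution) the lexicographically smallest
family. A tag whose tied best references include two *distinct* mature
sequences is flagged ambiguous, mirroring how near-identical family members
(e.g. miR165 vs miR166) defeat unambiguous annotation in practice.

"IsomiR groups" are the connected components of the bipartite graph linking
tags to their tied best reference mature sequences. This is a finer
partition than the family: two groups of the same family arise when tags
cluster around two sufficiently different reference sequences. The group
consensus takes the majority base per aligned column, after dropping
columns carried by fewer than half of the member tags — otherwise a single
rare 5′-extended isomiR would lengthen the consensus beyond the canonical
span. Group ids are stable, human-readable (`miR156_g1`) and ordered by
family and smallest member accession.

## Differential expression

Counts are normalised to counts per million using per-library totals of
in-window reads. Fold changes use pseudocount-stabilised group means,
`(mean_a + 1 CPM)/(mean_b + 1 CPM)`, reported as a negative reciprocal below
1 so thresholds read symmetrically (≥1.5 or ≤ −1.5). The pseudocount
matters for the weakly expressed families (counts of a few reads) where raw
ratios are unstable.

The default test is a limma moderated t-test on log2(CPM + 1) with a
mean-variance trend, Benjamini–Hochberg corrected within each pairwise
comparison. With 3–4 libraries per group, per-group variance estimates are
noisy; pooling variance information across isomiR groups is the standard
remedy and, in simulations at the generator's default conditions (fold
change 4, negative-binomial dispersion 0.2, four libraries per group), it
raises planted-family recall from roughly 0.8 (Welch's t) to essentially
complete while holding the empirical null false-positive rate near 2% at
FDR < 0.05. Welch's t remains available (`test = "welch"`) as a
dependency-light alternative. FDR is controlled within each comparison,
not jointly across the six, matching how per-comparison DE counts are
conventionally reported.

Rows that are constant across every library receive p = 1 by convention.

## Precursor prediction

Mature sequences (the consensus of each DE-significant group, in the
pipeline) are mapped to genome contigs on both strands allowing up to two
substitutions and one single-nucleotide gap. The search enumerates the
gap-free pattern and all one-base-deleted/inserted variants through
`Biostrings::matchPattern()`, so it is exhaustive within tolerance — a
property the tests verify against a brute-force sliding-window scan.

Around each hit a window of ±100 nt is extracted (clipped at contig edges,
reverse-complemented for minus-strand hits so the mature arm reads 5′→3′)
and folded. The folding engine is pluggable behind a
`(sequence) → (dot-bracket, MFE)` contract:

- `vienna` (default): the RNAfold binary from ViennaRNA, batched per run;
- `stackmax`: a built-in stacking-weighted base-pair maximisation
  (Nussinov-style dynamic program in C++, lone pairs removed, energies as
  stability-weighted scores). It exists so the package remains fully
  functional and testable without external binaries; its energies are
  surrogates, which is why no test asserts exact MFE values from either
  engine.

The miRNA\* span is derived from the pairing partners of the mature arm
shifted by the 2-nt 3′ overhang Dicer leaves on each strand of the duplex;
a star is only accepted when ≥60% of mature positions are paired and the
derived span does not overlap the mature arm. The precursor is then trimmed
by walking the stem outward from the duplex and cutting immediately after
the first bulge or interior loop encountered (the interrupting unpaired run
is included; the terminal loop never triggers trimming), or at the window
edge if the stem runs out cleanly. The trimmed sequence is refolded before
scoring.

Scoring follows the standard hairpin statistics: AMFE = |MFE|/length × 100
and MFEI = AMFE / GC% with GC on the 0–100 scale, so a 100-nt precursor at
−50 kcal/mol and 50% GC has MFEI 1.0. A candidate passes when MFEI ≥ 0.85,
the longest clean helix run is ≥19 nt, both arms are 19–25 nt and the
hairpin has a single terminal loop. MFEI ≥ 0.85 is the conventional
discriminator of miRNA precursors from tRNA/rRNA (whose MFEI fall around
0.6); dinucleotide-shuffled versions of planted precursors drop below the
threshold in the large majority of cases, which the acceptance suite
checks. All candidates are reported with a `passes` flag and a failure
reason rather than silently dropped, since borderline candidates are often
worth manual inspection.

Same-contig passing candidates within 10 kb are chained into clusters
(size ≥ 2), capturing tandemly repeated precursors.

## Target prediction

A miRNA is aligned 5′→3′ against the 3′→5′ reading of a candidate site.
Each column is penalised 0 for a Watson–Crick pair, 0.5 for a G:U wobble,
1 for a mismatch and 2 per gapped position, with penalties doubled at miRNA
positions 2–13 (the seed); the summed penalty is the expectation score.
Sites with expectation ≤ 5 and at most 2 seed mismatches+gaps are reported;
overlapping sites of one miRNA–transcript pair collapse to the best-scoring
one. Gap handling is bounded to one bulge of at most 2 nt per duplex —
enough to honour "bulges allowed" semantics while keeping the search
exhaustive and cheap; the scanner is verified against brute-force duplex
enumeration on short transcripts. The seed multiplier and gap constants are
configurable because published server versions of this scoring family have
varied them.

Translation-inhibition classification of central-site hits is out of scope;
hits are reported score-only.

## qPCR quantification

Technical replicates are averaged per (sample, gene); the two reference
genes are combined by averaging their mean Cts, which equals the geometric
mean of their linear quantities — the natural choice when no combination
rule is specified. ΔCt per sample is target minus combined reference; ΔΔCt
per group subtracts the calibrator group mean; RQ = 2^−ΔΔCt. Error bounds
use the exponent convention RQmin = 2^−(ΔΔCt+SE), RQmax = 2^−(ΔΔCt−SE)
with SE the standard error of ΔCt over *biological* samples in the group
(technical replication is already absorbed by the per-sample mean).
Amplification efficiency is fixed at 2.0. Significance uses one-way ANOVA
on ΔCt plus BH-corrected pairwise Welch t-tests; degenerate (zero-variance)
inputs return p = 1 with a flag.

## The synthetic study

`simulate_study()` builds a complete toy study from one seed. The defaults
*are* the study conditions the rest of the package is validated under:

- four sample groups (REV, IVM, JUV, MAT) × four libraries, ≈20,000 planted
  reads per library (`tiny` preset: ≈3,000);
- 20 planted families, 10 differentially expressed at fold change 4, with
  up-groups balanced across the four states so compositional shifts of CPM
  normalisation stay comparable between libraries;
- negative-binomial counts with dispersion 0.2 — the overdispersion typical
  of small-RNA libraries and the stress the DE test must survive;
- isomiR structure per family: 60% canonical reads, 30% length variants
  within ±2 nt, 10% single-substitution variants;
- a genome of 10 × 50 kb contigs carrying one valid hairpin cassette per
  family (mature/star duplex with ≥19-bp stem, bulged outer stem, one
  family planted as a 3-copy tandem cluster, about a third of loci on the
  minus strand) and 20 decoy loci (the mature sequence in unstructured
  low-GC context);
- transcripts with planted sites of designed expectation 0, 2, 3.5 and 6
  (the last a planted negative above the cutoff);
- Ct tables with two effect-free reference genes and a −2-cycle ΔΔCt
  planted in JUV (biological SD 0.15, technical SD 0.05 cycles).

All generators are pure functions of (parameters, seed): the same seed
reproduces every file byte-identically, which the determinism tests assert.

What the generator does **not** emulate: platform-specific sequencing error
profiles, barcode loss, quality-score structure (qualities are uniform),
multi-locus families with divergent paralogues, or transcriptome-scale
target sets. Passing the recovery tests therefore demonstrates that the
algorithms are implemented correctly under realistic count noise and
planted truth — not that real libraries of a particular platform will
behave identically.

## Problem sizes and numerical choices

The test suite and acceptance script run the `default` preset once
end-to-end (tens of seconds), 200 null DE replicates at 20 groups × 16
libraries, and oracle-equivalence sweeps (1000 matcher cases, ~12 kb oracle
genomes, ~140 nt oracle transcripts). These sizes were chosen so the whole
validation stays desk-scale while every planted effect remains comfortably
detectable at the stated noise levels.

Numerical conventions worth knowing: genomic intervals are 0-based
half-open internally and 1-based inclusive in GFF3; U/T are normalised to
the DNA alphabet internally and back to RNA at the folding boundary and in
written miRNA FASTA; all tie-breaks (placement, family, consensus base,
site dedup) are lexicographic or best-first and therefore
order-independent; the dinucleotide shuffle is an Eulerian-walk shuffle
with a retry budget and a mononucleotide fallback.

## Known limitations

- Exact reproduction of any specific commercial pipeline's DE calls is not
  attempted; the normalisation and test are documented here instead.
- The `stackmax` engine's energies are scores, not calibrated free
  energies; MFEI values from it are comparable within a run but not to
  thermodynamic values.
- Precursor deduplication is by identical trimmed coordinates; nearby hits
  that trim to slightly different bounds are reported separately (all
  carrying the same `passes` decision in practice).
- Ambiguous tags are counted once, under the lexicographically smallest
  family; the alternative (once per tied family) would inflate family read
  counts.
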