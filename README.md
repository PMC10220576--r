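# phasemir

Small-RNA sequencing analysis of conserved microRNAs during plant
vegetative phase change.

Woody plants that have transitioned from the juvenile to the mature phase
are recalcitrant to in vitro propagation, and the transition is coordinated
by deeply conserved microRNAs (the miR156/miR172 axis and relatives such as
miR394, miR396 and miR408). `phasemir` implements the complete analysis a
phase-change small-RNA study needs, as composable tibble-in/tibble-out
functions:

- **Read preprocessing** — adapter trimming, an 18–25 nt length window, and
  collapsing of reads into unique tags with per-library counts (tags with a
  total count below 5 across all libraries are dropped).
- **Conserved miRNA / isomiR annotation** — every tag is compared with
  reference mature miRNAs (miRBase-style FASTA), tolerating 2 mismatches and
  2-nt end overhangs; tags are grouped into isomiR groups (connected
  components of shared best reference sequences) with consensus sequences,
  and ties between reference sequences are flagged as ambiguous.
- **Differential expression** — counts-per-million normalisation, fold
  changes from pseudocount-stabilised group means with the signed
  negative-reciprocal convention, moderated t-tests on log2(CPM+1) and
  Benjamini–Hochberg FDR within each pairwise comparison; a group is called
  at |FC| ≥ 1.5 and FDR < 0.05.
- **Precursor (pre-miRNA) prediction** — mature sequences are mapped to
  genome contigs on both strands (≤2 substitutions, ≤1 single-nucleotide
  gap), ±100 nt flanks are folded (RNAfold by default), the miRNA\* arm is
  placed by the 2-nt 3′-overhang convention, candidates are trimmed at the
  first bulge or loop beyond the miRNA/miRNA\* duplex, and filtered on

  MFEI = AMFE / GC%,  AMFE = |MFE| / length × 100,

  requiring MFEI ≥ 0.85, a ≥19-nt double-stranded segment, 19–25 nt arms and
  a single terminal loop. Tandem precursor clusters on one contig are
  reported.
- **Target prediction** — psRNATarget-style expectation scoring (pair 0,
  G:U 0.5, mismatch 1, gap 2; penalties doubled in the seed, miRNA positions
  2–13), reporting sites with expectation ≤ 5 and ≤2 seed mismatches.
- **qPCR quantification** — 2^−ΔΔCt relative expression against two
  reference genes (actin, cyclophilin) with RQmin/RQmax error bounds and
  ANOVA/t-tests on ΔCt.
- **Synthetic data** — a seeded generator builds a complete toy study
  (genome with planted hairpins and decoys, reference miRNAs, per-library
  FASTQ with isomiR structure and planted fold changes, transcripts with
  planted target sites, Ct tables) plus a ground-truth manifest, so the
  whole pipeline is testable end to end with known answers.

## Worked example

```r
library(phasemir)

st  <- simulate_study(seed = 3, preset = "tiny")  # 16 libraries, 8 families
run <- run_study(st)
run
#> <phasemir_run>
#>   n_reads                  54082
#>   n_tags                   72
#>   n_annotated              72
#>   n_ambiguous              1
#>   n_groups                 8
#>   n_families               8
#>   n_comparisons            6
#>   n_de_union               5
#>   n_precursors_found       50
#>   n_precursors_passing     28
#>   n_clusters               4
#>   n_target_hits            4
#>   ...
```

54,082 reads collapse to 72 unique tags, all of which annotate to the 8
planted families (one tag ties two reference sequences and is flagged
ambiguous). Five isomiR groups are differentially expressed in at least one
of the 6 pairwise comparisons; their consensus sequences yield 50 genomic
precursor candidates of which 28 pass the MFEI ≥ 0.85 hairpin filter
(the decoy loci all fail), including 4 tandem clusters, and 4 transcripts
carry reported target sites. The qPCR stage recovers the planted ΔΔCt:

```r
tidy(run$rq$pre_target)[, c("sample_group", "rq", "rq_min", "rq_max")]
#>   sample_group       rq   rq_min   rq_max
#> 1          IVM 1.421353 1.317229 1.533708
#> 2          JUV 4.801517 4.549646 5.067331
#> 3          MAT 1.000000 0.914038 1.094047
#> 4          REV 2.997629 2.867621 3.133530
```

The juvenile group's RQ ≈ 4 reflects the planted −2-cycle ΔΔCt effect
(2^2 = 4). `autoplot()` methods draw volcano panels for DE objects and RQ
bar charts with error bounds; `tidy()`/`glance()` return tibbles.

A thin command-line wrapper is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/phasemir.R", package="phasemir"))') \
    simulate --out study_dir --seed 3 --preset tiny
Rscript .../cli/phasemir.R run-all --study study_dir --out results_dir
```

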