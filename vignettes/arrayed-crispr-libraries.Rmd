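---
title: "Designing and validating arrayed CRISPR-Cas9 knockout libraries"
author: "crisprArrayKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating arrayed CRISPR-Cas9 knockout libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprArrayKit)
```

## The problem

Pooled genome-scale CRISPR screens read out guide abundance by sequencing,
which rules out microscopy and other high-content assays. A focused,
*arrayed* knockout library — one sgRNA construct per well, with derived
pools — supports both selection screens and well-by-well phenotyping. This
package implements the complete computational workflow around such a
library for SpCas9 (NGG) knockouts:

1. **Isoform-aware target selection.** For each gene the designer targets
   the first translated exon whose genomic CDS interval is *identical* in
   every annotated isoform, so that a frameshift disrupts all isoforms at
   once. When no such exon exists (or cannot support the selection
   policy), the most 5' CDS exon of the designated primary transcript is
   used as a fallback.
2. **Tiered sgRNA selection.** Candidates are every NGG-adjacent 20-mer on
   either strand of the target exons. A specificity score in [0, 100]
   gates selection: guides at or above the preferred threshold (default
   70) rank ahead of "backup" guides in [50, 70), and candidates below the
   backup threshold are never used. Within a score tier, guides cutting
   more 5' in the primary CDS are preferred (they truncate more of the
   protein), then higher score, then protospacer lexicographic order as a
   deterministic tie-break — the procedure is fully reproducible. Five
   designed guides (groups 1–5) are selected per gene; two further guides
   per gene (groups 6–7) are imported from an external, efficacy-oriented
   design and accepted only if they share fewer than 15 bp of genomic span
   with any guide already chosen.
3. **Non-overlap core.** Selection prefers at least three mutually
   non-overlapping designed guides per gene. This is implemented as a
   two-phase greedy: first a core of up to three pairwise-disjoint guides
   is assembled in rank order (skipping candidates that overlap the core),
   then the remaining slots are filled purely by rank. The greedy
   reproduces the intended behaviour on all boundary cases we enumerate in
   the test suite, including swapping in lower-ranked disjoint guides when
   the top-ranked candidates pile onto one locus.
4. **Library construction.** Cloning oligo pairs (overhang + protospacer /
   overhang + reverse complement; the vector supplies the 5' G required
   for U6 transcription), a column-major 96-well arrayed layout, derived
   pools (whole library, per-gene pools arrayed one-gene-per-well, and
   one-guide-per-gene pools for groups 5/6/7), and 2 kb capture-probe
   regions centered on each cleavage site, merged to the exon midpoint
   when several sites share an exon.
5. **Representation counting.** Amplicon reads are assigned to guides by
   exact 20-mer protospacer match (a fixed-offset mode supports defined
   amplicon designs). Diagnostics report detection, the fraction of
   detected guides within 0.5–2x of the mean raw count, dropouts,
   outliers, and per-gene coverage.
6. **Editing quantification.** From an indel-permissive alignment of
   target-enrichment reads: reads in a proper pair whose CIGAR has no
   insertion or deletion are treated as unedited molecules and discarded;
   duplicates and reads with MAPQ below 38 are filtered; in/dels are
   extracted from CIGAR strings; events are kept only inside the cleavage
   window; events whose exact key (chromosome, position, type, length)
   also occurs in an untransduced control are removed; and per-guide
   activity is summarized as the Observed Activity Score.

## The Observed Activity Score

Let $\mu_{ID}$ be the mean number of valid in/del events across biological
replicates for a guide, $sgR$ its raw read count in the pool used for the
infection, and $TR$ the total pool reads. Then

$$\mathrm{OAS} = \frac{\mu_{ID}}{(sgR / TR) \times 100}.$$

Dividing by the percentage representation corrects for unequal guide
abundance: a guide making up 1% of the pool has OAS equal to its mean
in/del count. OAS is invariant under uniform rescaling of the pool counts,
and is undefined (NA) for guides not detected in the pool — percentages of
active guides are therefore computed over pool-detected guides only.

## Coordinate and window conventions

All interfaces use 1-based closed genomic intervals (GTF/SAM convention);
BED output is converted to 0-based half-open on export.

The cleavage site is 6 nt upstream of the end of the guide-plus-PAM, i.e.
between protospacer positions 17 and 18; the reported coordinate is the
base on the PAM-proximal side of the cut (position 17 in guide
orientation). The validity window covers the two scission-flanking bases
plus 2 nt on each side — six bases in total. Because the reported
coordinate is strand-dependent, the window is $[c-2, c+3]$ for a
plus-strand guide and $[c-3, c+2]$ for a minus-strand guide; when strand
is unknown the plus-strand formula applies. Insertions are valid by point
membership of their left-flanking base; deletions by intersection of the
deleted span with the window, so a long deletion starting upstream still
validates. Both choices are configurable; the defaults are the package's
reading of "within 2 nucleotides of the cleavage site".

Control subtraction matches events by the exact key
(chromosome, position, type, length). Fuzzy matching is deliberately out
of scope: with an identically processed control, exact keys remove
germline and recurrent artefactual in/dels without risking removal of
bona-fide editing at neighbouring coordinates.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `scoreThreshold` | 70 | preferred specificity score for designed guides |
| `backupThreshold` | 50 | minimum admissible score |
| `gcBand` | 0.35–0.70 | optimal GC fraction (diagnostic, not a hard filter) |
| `nDesignedPerGene` / `nImportedPerGene` | 5 / 2 | per-gene quotas (groups 1–5, 6–7) |
| `minNonoverlappingDesigned` | 3 | non-overlap core size |
| `importedOverlapLimitBp` | 15 | an import sharing ≥ this many bp is rejected |
| `predictedActivityFlagThreshold` | 0.4 | predicted-activity diagnostic cutoff |
| `mapqMin` (pipeline) | 38 | reads below are excluded from in/del calling |
| window flank | 2 nt | tolerance around the scission |
| indel length cap | 2000 bp | matches the indel-permissive alignment setting |

GC content is reported as a library diagnostic (the fraction of guides in
the optimal band) rather than enforced as a filter: enforcing it would
make some genes undesignable while the band is a soft quality indicator.

The built-in specificity scorer counts genomic NGG-adjacent sites within 3
mismatches of the protospacer by exhaustive scan (compiled, 2-bit packed
XOR/popcount comparison) and maps $k$ off-target sites to the monotone
score $100/(1+k)$. It exists so that thresholding logic runs
self-contained; it does not emulate any published scoring formula, and
externally computed scores supplied as a table always take precedence.

## What the synthetic data emulate — and what they do not

The generator (`simConfig()`, `simulateGenome()`, `simulatePoolReads()`,
`simulateEditing()`) reproduces the *structure* of the study design: 450
genes with two isoforms each (a configurable 10% sharing no CDS exon, to
exercise the fallback tier), guide-dense exons (sequences are redrawn
until each designable exon holds at least 8 NGG candidates and the
external list at least two mutually admissible guides), pooled amplicon
reads as constant flank + protospacer + flank drawn multinomially from a
uniform or log-normal abundance model, and paired 150 bp target-enrichment
reads in which an editing event of 1–20 bp appears in the CIGAR at the cut
site (±2 nt jitter), unedited pairs are proper and gapless, duplicates and
low-MAPQ records are planted at configured fractions, and per-site
background in/dels appear with identical keys in the edited and control
samples.

Per-guide true edit rates default to a mixture — 15% inactive guides, the
rest uniform on 0.05–0.9 — chosen once as a realistic activity mix for a
validated library; they can be overridden per guide. The emulated external
activity prediction is the true rate plus Gaussian noise (sd 0.2, clamped
to [0, 1]), standing in for a partially predictive algorithm so the
OAS-versus-prediction rank correlation is exercised.

Real data differ in ways the generator does not model: sequencing errors
and quality profiles, PCR bias beyond the abundance distribution,
alignment ambiguity around repeats, microhomology-dependent deletion
spectra, and multi-event alleles. Passing tests therefore demonstrate the
correctness of the bookkeeping — classification, extraction, windowing,
subtraction, normalization — not robustness to noisy alignment; the
aligner and duplicate marker remain responsible for their own quality.

Each generator stage derives a fixed sub-stream from the configured seed
(genome: seed; pool reads: seed + 1; editing: seed + 2), so stages are
independently reproducible and emitted files are byte-identical across
runs.

## Numerical and degenerate-input choices

* Probe regions are exactly 2,000 bp: 1,000 bp upstream and 999 bp
  downstream of the centre base under the 1-based closed convention; exon
  midpoints use the floor of the interval mean. Regions are clipped at
  position 1 (shrinking the interval) rather than shifted.
* An empty read set yields an all-zero count table with undefined
  normalized counts, flagged rather than erroring.
* The mean for fold-from-mean is taken over *all* library guides,
  zeros included; computing it over detected guides only would flatter
  libraries with dropouts.
* Ambiguous reads (matching two or more guides) are dropped, never
  fractionally assigned.
* Transcripts whose CDS length is not divisible by 3 are retained with a
  flag — real annotations contain such records and design can proceed.
* CIGAR operations `=` and `X` are treated as `M`; `N` advances the
  reference without emitting an event; `S`, `H`, `P` consume no
  reference. Events longer than 2,000 bp are discarded, matching the
  alignment cap.
* `selectGuides` descends into the fallback exon tier only when the
  shared tier cannot fill the per-gene quota with candidates at or above
  the backup threshold; a shortfall of the non-overlap core alone is
  recorded in the per-gene flags but does not trigger the fallback.
* The ≥15 bp import rule is read as "shared genomic span must be < 15 bp";
  both the limit and the reading are configurable through
  `importedOverlapLimitBp`.

## Problem sizes used in the checks

The full-scale design check runs the complete 450-gene study (3,150
guides); representation is checked on the 450-guide one-guide-per-gene
pool at a depth of 100,000 reads; edit-rate recovery uses four guides at
rates 0/0.05/0.3/0.7 with 500 read pairs per guide per replicate across
20 seeded simulations; the acceptance script scores activity on a
60-gene slice of the group-5 pool at 150 pairs per guide. These sizes
make every check a faithful miniature of the study design while keeping a
complete run on a laptop in the minutes range.

## Known limitations

* The designer assumes SpCas9 NGG; other nucleases and PAMs are out of
  scope.
* Off-target assessment beyond the built-in near-match count (or a
  supplied external score) is not attempted; the built-in score is a
  gating device, not a mature specificity model.
* The pipeline consumes alignments; it neither aligns reads nor calls
  substitutions or HDR outcomes, and it only inspects declared target
  sites.
* Control subtraction is exact-key; a control sequenced much shallower
  than the edited samples will under-subtract recurrent background.
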