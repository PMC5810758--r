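# crisprArrayKit

Design, construction and activity scoring of arrayed CRISPR-Cas9 knockout
sgRNA libraries.

Focused arrayed libraries — one sgRNA construct per 96-well position, with
derived pools — let a lab run both selection screens and high-content,
well-by-well phenotyping on a defined gene set (for example, the
chromatin and epigenetic regulators). This package implements the
computational workflow around such a library end to end:

* **Isoform-aware guide design.** For each gene, candidates are every
  NGG-adjacent 20-mer protospacer in the first CDS exon shared by all
  annotated isoforms (falling back to the most 5' exon of the primary
  transcript when no shared exon can be used). Selection is tiered:
  guides with specificity score ≥ 70 are preferred, scores in [50, 70)
  serve as backups, at least 3 mutually non-overlapping guides are sought
  per gene, and a predicted percentage of remaining peptide prioritizes
  5'-truncating guides. Five designed guides (groups 1–5) plus two
  imported, efficacy-oriented guides (groups 6–7, accepted only when
  sharing < 15 bp with existing guides) give 7 guides per gene.
* **Library construction.** Golden-Gate (BsmBI-style) oligo pairs,
  column-major 96-well layouts, derived pools (whole library, per-gene
  pools, one-guide-per-gene group pools), and 2 kb capture-probe regions
  centered on cleavage sites (merged to the exon midpoint when several
  sites share an exon).
* **Representation counting.** Exact protospacer matching of pooled
  amplicon reads, with detection, 2-fold-band and per-gene coverage
  diagnostics.
* **In/del-based activity scoring.** From indel-permissive alignments:
  proper-paired gapless reads are discarded as unedited, duplicates and
  MAPQ < 38 reads filtered, in/dels extracted from CIGAR strings,
  restricted to a ±2 nt window around the Cas9 scission (6 nt upstream of
  the guide+PAM end), events also seen in an untransduced control
  removed, and per-guide activity reported as the Observed Activity
  Score:

  OAS = μ_ID / ((sgR / TR) × 100)

  where μ_ID is the mean valid in/del count across replicates, sgR the
  guide's raw pool reads and TR the total pool reads — i.e. the in/del
  count normalized by the guide's percentage representation.
* **Synthetic data with ground truth.** A first-class generator emits
  genome FASTA, two-isoform GTF annotation, external guide lists, pooled
  FASTQ reads and edited/control SAM alignments with every planted event
  recorded, so the whole pipeline is testable without any external data.

## Worked example

```r
library(crisprArrayKit)

cfg   <- simConfig(seed = 42, nGenes = 5)
paths <- simulateGenome(cfg, dir = tempfile())
gms   <- loadAnnotation(paths$annotation, paths$genome)
lib   <- designLibrary(gms, read.delim(paths$externalGuides))
lib
#> GuideSet with 35 guides across 5 genes
#>   groups: 1:5 2:5 3:5 4:5 5:5 6:5 7:5
#>   % score >= 70: 100.0 | % GC in band: 82.9

plateLayout(lib)
#> PlateLayout: 35 wells on 1 plate(s)
```

Every gene received its full quota of 7 guides; all designed guides pass
the specificity threshold and 82.9% fall in the optimal 35–70% GC band.
Scoring editing activity on the group-5 pool (one guide per gene), with
simulated true edit rates of 0, 0.25, 0.6, 0.05 and 0.8:

```r
g5    <- subset(as.data.frame(guideTable(lib)), group == 5)
sites <- targetSites(g5)
cfg$editRates <- setNames(c(0, 0.25, 0.6, 0.05, 0.8), sites$guide_id)
ed    <- simulateEditing(sites, gms, cfg, dir = tempfile())
pool  <- simulatePoolReads(g5, cfg)
act   <- scoreActivity(ed$editedPaths, ed$controlPath, sites,
                       countGuides(pool$reads, g5))
as.data.frame(activityTable(act))[, c("guide_id", "mu_id",
                                      "normalized_count", "oas", "active")]
#>   guide_id mu_id normalized_count       oas active
#> 1 G0001_g5   0.0           19.927  0.000000  FALSE
#> 2 G0002_g5 119.0           19.851  5.994660   TRUE
#> 3 G0003_g5 298.5           20.042 14.893723   TRUE
#> 4 G0004_g5  21.5           20.176  1.065623   TRUE
#> 5 G0005_g5 369.5           20.004 18.471306   TRUE
```

The truly inactive guide is called inactive — its planted background
in/dels are removed by control subtraction — and OAS ranks the remaining
guides in the order of their simulated edit rates (0.05 < 0.25 < 0.6 <
0.8). Each guide holds ~20% of the 5-guide pool, so OAS ≈ μ_ID / 20.

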