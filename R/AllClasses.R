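#' @import methods
#' @importFrom S4Vectors DataFrame mcols
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Tuning parameters for sgRNA selection
#'
#' Holds the thresholds of the tiered selection policy: the specificity-score
#' threshold preferred for designed guides, the backup threshold below which a
#' candidate is never used, the GC band considered optimal, per-gene guide
#' quotas, the non-overlap requirement among designed guides, the maximum
#' shared span tolerated when importing externally designed guides, and the
#' predicted-activity level above which a guide is flagged as likely active.
#'
#' @slot scoreThreshold numeric; preferred specificity score (default 70).
#' @slot backupThreshold numeric; minimum admissible score (default 50).
#' @slot gcBand numeric(2); optimal GC fraction band (default 0.35-0.70).
#' @slot nDesignedPerGene integer; designed guides per gene (default 5).
#' @slot nImportedPerGene integer; imported guides per gene (default 2).
#' @slot minNonoverlappingDesigned integer; required mutually non-overlapping
#'   designed guides (default 3).
#' @slot importedOverlapLimitBp integer; an imported guide is rejected when its
#'   protospacer shares at least this many bp with an already selected guide
#'   (default 15).
#' @slot predictedActivityFlagThreshold numeric; predicted-activity diagnostic
#'   cutoff (default 0.4).
#' @export
setClass("DesignParams", representation(
    scoreThreshold = "numeric",
    backupThreshold = "numeric",
    gcBand = "numeric",
    nDesignedPerGene = "integer",
    nImportedPerGene = "integer",
    minNonoverlappingDesigned = "integer",
    importedOverlapLimitBp = "integer",
    predictedActivityFlagThreshold = "numeric"
))

setValidity("DesignParams", function(object) {
    msg <- character()
    if (object@backupThreshold > object@scoreThreshold)
        msg <- c(msg, "backupThreshold must be <= scoreThreshold")
    if (object@scoreThreshold < 0 || object@scoreThreshold > 100)
        msg <- c(msg, "scoreThreshold must be in [0, 100]")
    if (length(object@gcBand) != 2L || any(object@gcBand < 0) ||
        any(object@gcBand > 1) || object@gcBand[1] > object@gcBand[2])
        msg <- c(msg, "gcBand must be an increasing pair in [0, 1]")
    if (object@nDesignedPerGene < 1L)
        msg <- c(msg, "nDesignedPerGene must be >= 1")
    if (object@importedOverlapLimitBp < 1L)
        msg <- c(msg, "importedOverlapLimitBp must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct selection parameters
#'
#' @aliases DesignParams
#'
#' @param scoreThreshold,backupThreshold,gcBand,nDesignedPerGene
#'   see \linkS4class{DesignParams}.
#' @param nImportedPerGene,minNonoverlappingDesigned,importedOverlapLimitBp
#'   see \linkS4class{DesignParams}.
#' @param predictedActivityFlagThreshold see \linkS4class{DesignParams}.
#' @return A \linkS4class{DesignParams} object.
#' @examples
#' DesignParams(scoreThreshold = 80)
#' @export
DesignParams <- function(scoreThreshold = 70, backupThreshold = 50,
                         gcBand = c(0.35, 0.70), nDesignedPerGene = 5L,
                         nImportedPerGene = 2L,
                         minNonoverlappingDesigned = 3L,
                         importedOverlapLimitBp = 15L,
                         predictedActivityFlagThreshold = 0.4) {
    new("DesignParams",
        scoreThreshold = scoreThreshold,
        backupThreshold = backupThreshold,
        gcBand = gcBand,
        nDesignedPerGene = as.integer(nDesignedPerGene),
        nImportedPerGene = as.integer(nImportedPerGene),
        minNonoverlappingDesigned = as.integer(minNonoverlappingDesigned),
        importedOverlapLimitBp = as.integer(importedOverlapLimitBp),
        predictedActivityFlagThreshold = predictedActivityFlagThreshold)
}

#' Isoform-resolved transcript model
#'
#' CDS exons are stored as a \link[GenomicRanges]{GRanges} ordered 5' to 3'
#' in transcript (translation) orientation: ascending genomic coordinates on
#' the plus strand, descending on the minus strand.
#'
#' @slot transcriptId,geneId character identifiers.
#' @slot strand "+" or "-".
#' @slot cds GRanges of CDS exons in translation order.
#' @slot primary logical; is this the primary (variant-1-like) transcript.
#' @slot frameOK logical; FALSE when total CDS length is not divisible by 3
#'   (kept, flagged).
#' @export
setClass("TranscriptModel", representation(
    transcriptId = "character",
    geneId = "character",
    strand = "character",
    cds = "GRanges",
    primary = "logical",
    frameOK = "logical"
))

setValidity("TranscriptModel", function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    n <- length(object@cds)
    if (n == 0L) msg <- c(msg, "transcript must have >= 1 CDS exon")
    if (n > 1L) {
        s <- GenomicRanges::start(object@cds)
        ord <- if (object@strand == "+") all(diff(s) > 0) else all(diff(s) < 0)
        if (!ord) msg <- c(msg, "CDS exons must be in translation order")
        red <- IRanges::reduce(object@cds)
        if (sum(GenomicRanges::width(red)) != sum(GenomicRanges::width(object@cds)))
            msg <- c(msg, "CDS exons must not overlap")
    }
    if (length(msg)) msg else TRUE
})

#' Gene model with one or more isoforms
#'
#' @slot geneId character identifier.
#' @slot symbol gene symbol.
#' @slot category functional class label (free text).
#' @slot transcripts list of \linkS4class{TranscriptModel}; exactly one is
#'   flagged primary.
#' @export
setClass("GeneModel", representation(
    geneId = "character",
    symbol = "character",
    category = "character",
    transcripts = "list"
))

setValidity("GeneModel", function(object) {
    msg <- character()
    if (length(object@transcripts) < 1L)
        msg <- c(msg, "gene must have >= 1 transcript")
    np <- sum(vapply(object@transcripts, function(t) t@primary, logical(1)))
    if (np != 1L)
        msg <- c(msg, "exactly one transcript must be flagged primary")
    if (length(msg)) msg else TRUE
})

#' A set of gene models bound to a genome
#'
#' @slot genes named list of \linkS4class{GeneModel}.
#' @slot genome \link[Biostrings]{DNAStringSet} of chromosome sequences.
#' @export
setClass("GeneModelSet", representation(
    genes = "list",
    genome = "DNAStringSet"
))

setValidity("GeneModelSet", function(object) {
    msg <- character()
    chroms <- names(object@genome)
    for (g in object@genes) {
        for (tx in g@transcripts) {
            sn <- as.character(GenomicRanges::seqnames(tx@cds))
            if (!all(sn %in% chroms)) {
                msg <- c(msg, sprintf("transcript %s uses chromosomes absent from the genome",
                                      tx@transcriptId))
                break
            }
            lens <- Biostrings::width(object@genome)[match(sn, chroms)]
            if (any(GenomicRanges::end(tx@cds) > lens))
                msg <- c(msg, sprintf("transcript %s has CDS beyond chromosome end",
                                      tx@transcriptId))
        }
    }
    if (length(msg)) msg[1] else TRUE
})

#' A designed sgRNA library
#'
#' The central result of \code{\link{designLibrary}}: one row per selected
#' guide (groups 1-5 designed, 6-7 imported), per-gene selection flags, the
#' parameters used and library-wide diagnostics.
#'
#' @slot guides DataFrame with columns guide_id, gene_id, group, protospacer,
#'   pam, chrom, strand, start, end, cut_site, gc_fraction,
#'   specificity_score, predicted_activity, peptide_remaining_pct, tier.
#' @slot geneFlags DataFrame of per-gene selection flags.
#' @slot params the \linkS4class{DesignParams} used.
#' @slot diagnostics list of library-wide summary percentages.
#' @export
setClass("GuideSet", representation(
    guides = "DataFrame",
    geneFlags = "DataFrame",
    params = "DesignParams",
    diagnostics = "list"
))

setValidity("GuideSet", function(object) {
    g <- object@guides
    need <- c("guide_id", "gene_id", "group", "protospacer", "pam", "chrom",
              "strand", "start", "end", "cut_site")
    if (!all(need %in% colnames(g)))
        return(paste("guides must have columns:", paste(need, collapse = ", ")))
    if (nrow(g) == 0L) return(TRUE)
    msg <- character()
    if (any(nchar(g$protospacer) != 20L))
        msg <- c(msg, "protospacers must be 20 nt")
    if (any(substr(g$pam, 2, 3) != "GG"))
        msg <- c(msg, "PAM must be NGG")
    if (any(g$group < 1L | g$group > 7L))
        msg <- c(msg, "group labels must be in 1..7")
    if (any(g$cut_site < g$start | g$cut_site > g$end))
        msg <- c(msg, "cut site must lie inside the protospacer span")
    if (anyDuplicated(g$guide_id))
        msg <- c(msg, "guide ids must be unique")
    if (length(msg)) msg else TRUE
})

#' Arrayed 96-well plate layout
#'
#' @slot assignments DataFrame with columns guide_id, plate, row, column,
#'   well; one guide per well, plates filled column-major (A1, B1, ..., H1,
#'   A2, ...), a plate is filled before the next opens.
#' @slot nPlates integer.
#' @export
setClass("PlateLayout", representation(
    assignments = "DataFrame",
    nPlates = "integer"
))

setValidity("PlateLayout", function(object) {
    a <- object@assignments
    if (anyDuplicated(a$guide_id))
        return("a guide may occupy only one well")
    if (anyDuplicated(paste(a$plate, a$well)))
        return("a well may hold only one guide")
    TRUE
})

#' Derived pools of an arrayed library
#'
#' @slot pools DataFrame in long format: pool_id, pool_kind (whole, gene,
#'   group), guide_id, gene_id.
#' @slot genePoolLayout \linkS4class{PlateLayout} of the per-gene pools
#'   (one well per gene).
#' @slot dropped DataFrame logging genes lacking a group-k guide.
#' @export
setClass("PoolSet", representation(
    pools = "DataFrame",
    genePoolLayout = "PlateLayout",
    dropped = "DataFrame"
))

#' Per-guide read counts with representation diagnostics
#'
#' @slot counts DataFrame: guide_id, gene_id, raw_reads, normalized_count
#'   (100 x raw/total), fold_from_mean (raw over the mean across all library
#'   guides), detected.
#' @slot totalReads integer; assigned + unassigned + ambiguous.
#' @slot unassigned,ambiguous integer read tallies.
#' @export
setClass("GuideCounts", representation(
    counts = "DataFrame",
    totalReads = "integer",
    unassigned = "integer",
    ambiguous = "integer"
))

setValidity("GuideCounts", function(object) {
    cc <- object@counts
    if (nrow(cc) && sum(cc$raw_reads) > 0) {
        if (abs(sum(cc$normalized_count) - 100) > 1e-6)
            return("normalized counts must sum to 100")
    }
    if (any(cc$raw_reads < 0)) return("raw read counts must be non-negative")
    TRUE
})

#' Per-guide editing-activity records
#'
#' @slot records DataFrame: guide_id, gene_id, group, per-replicate valid
#'   in/del counts, mu_id (mean across replicates), sg_reads, total_reads,
#'   normalized_count, oas, detected_in_pool, active.
#' @slot summary list produced by \code{\link{activitySummary}}.
#' @export
setClass("ActivitySet", representation(
    records = "DataFrame",
    summary = "list"
))

setValidity("ActivitySet", function(object) {
    r <- object@records
    if (nrow(r) && any(r$oas < 0, na.rm = TRUE))
        return("OAS must be non-negative")
    TRUE
})
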