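#' Load a genome and an isoform-resolved annotation
#'
#' Reads chromosome sequences from a FASTA file and CDS features from a
#' GTF/GFF3 annotation, and assembles one \linkS4class{GeneModel} per gene
#' with its transcripts' CDS exons ordered 5' to 3' in translation
#' orientation. The primary transcript (the analogue of RefSeq variant 1,
#' used for fallback targeting and peptide-remaining prediction) is
#' identified by an annotation attribute; when no transcript of a gene
#' carries the attribute the lexicographically smallest transcript id is
#' promoted with a warning.
#'
#' @param annotationPath GTF or GFF3 file with CDS features carrying
#'   gene_id and transcript_id attributes.
#' @param genomePath FASTA file of chromosome sequences.
#' @param primaryKey attribute name flagging the primary transcript.
#' @param primaryValue attribute value marking the primary transcript.
#' @param symbolKey,categoryKey optional attribute names for the gene
#'   symbol and functional category.
#' @return A \linkS4class{GeneModelSet}.
#' @details Transcripts declared in the annotation but lacking CDS features
#'   are dropped with a warning; an annotation naming a chromosome absent
#'   from the genome is a hard error. Transcripts whose total CDS length is
#'   not a multiple of 3 are kept and flagged (\code{frameOK = FALSE}).
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 2)
#' paths <- simulateGenome(cfg, dir = tempfile())
#' gms <- loadAnnotation(paths$annotation, paths$genome)
#' gms
#' @export
loadAnnotation <- function(annotationPath, genomePath,
                           primaryKey = "tag", primaryValue = "primary",
                           symbolKey = "gene_name",
                           categoryKey = "gene_category") {
    stopifnot(file.exists(annotationPath), file.exists(genomePath))
    genome <- Biostrings::readDNAStringSet(genomePath)
    names(genome) <- sub("\\s.*$", "", names(genome))

    gr <- rtracklayer::import(annotationPath)
    mc <- S4Vectors::mcols(gr)
    if (!"type" %in% colnames(mc))
        stop("annotation has no feature type column")
    cds <- gr[mc$type == "CDS"]
    if (length(cds) == 0L) stop("annotation contains no CDS features")

    missingChrom <- setdiff(unique(as.character(GenomicRanges::seqnames(cds))),
                            names(genome))
    if (length(missingChrom))
        stop("annotation references chromosomes absent from the genome: ",
             paste(missingChrom, collapse = ", "))

    cm <- S4Vectors::mcols(cds)
    txIds <- as.character(cm$transcript_id)
    geneIds <- as.character(cm$gene_id)
    if (anyNA(txIds) || anyNA(geneIds))
        stop("CDS features must carry gene_id and transcript_id")

    ## transcripts declared but without CDS are dropped with a warning
    declared <- gr[S4Vectors::mcols(gr)$type %in% c("transcript", "mRNA")]
    if (length(declared)) {
        dIds <- as.character(S4Vectors::mcols(declared)$transcript_id)
        noCds <- setdiff(dIds, txIds)
        if (length(noCds))
            warning("dropping transcripts without CDS: ",
                    paste(noCds, collapse = ", "))
    }

    primaryFlag <- if (primaryKey %in% colnames(cm)) {
        as.character(cm[[primaryKey]]) == primaryValue &
            !is.na(cm[[primaryKey]])
    } else rep(FALSE, length(cds))

    genes <- list()
    for (gid in unique(geneIds)) {
        sel <- geneIds == gid
        gTx <- unique(txIds[sel])
        txList <- list()
        primTx <- unique(txIds[sel & primaryFlag])
        if (length(primTx) == 0L) {
            primTx <- sort(gTx)[1]
            warning("gene ", gid, ": no transcript flagged '", primaryValue,
                    "'; using ", primTx)
        } else if (length(primTx) > 1L) {
            primTx <- sort(primTx)[1]
            warning("gene ", gid, ": several primary transcripts; using ",
                    primTx)
        }
        for (tid in gTx) {
            exons <- cds[txIds == tid]
            strand <- as.character(GenomicRanges::strand(exons))[1]
            if (!strand %in% c("+", "-"))
                stop("transcript ", tid, " has no stranded CDS")
            ord <- order(GenomicRanges::start(exons),
                         decreasing = (strand == "-"))
            exons <- GenomicRanges::granges(exons[ord])
            len <- sum(GenomicRanges::width(exons))
            frameOK <- (len %% 3L) == 0L
            if (!frameOK)
                warning("transcript ", tid, ": CDS length ", len,
                        " not divisible by 3 (kept, flagged)")
            txList[[tid]] <- new("TranscriptModel", transcriptId = tid,
                                 geneId = gid, strand = strand, cds = exons,
                                 primary = (tid == primTx),
                                 frameOK = frameOK)
        }
        symbol <- if (symbolKey %in% colnames(cm))
            as.character(cm[[symbolKey]][sel][1]) else NA_character_
        category <- if (categoryKey %in% colnames(cm))
            as.character(cm[[categoryKey]][sel][1]) else NA_character_
        genes[[gid]] <- new("GeneModel", geneId = gid,
                            symbol = if (is.na(symbol)) gid else symbol,
                            category = if (is.na(category)) "unclassified" else category,
                            transcripts = txList)
    }
    new("GeneModelSet", genes = genes, genome = genome)
}

#' Total CDS length of a transcript
#'
#' @param transcript a \linkS4class{TranscriptModel}.
#' @return Integer number of coding nucleotides.
#' @export
cdsLength <- function(transcript) {
    sum(GenomicRanges::width(transcript@cds))
}

#' Map genomic positions to CDS nucleotide offsets
#'
#' Strand-aware walk over the transcript's CDS exons: offset 1 is the first
#' coding base (the genomic start of the first exon on the plus strand, its
#' genomic end on the minus strand).
#'
#' @param genomicPos integer vector of 1-based genomic positions.
#' @param transcript a \linkS4class{TranscriptModel}.
#' @return Integer vector of 1-based offsets in \code{[1, cdsLength]}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 160), "+")
#' tx <- new("TranscriptModel", transcriptId = "t1", geneId = "g1",
#'           strand = "+", cds = gr, primary = TRUE, frameOK = TRUE)
#' cdsOffset(101, tx)  # 1
#' @export
cdsOffset <- function(genomicPos, transcript) {
    out <- cdsOffsetOrNA(genomicPos, transcript)
    if (anyNA(out))
        stop("position ", genomicPos[which(is.na(out))[1]],
             " is outside the CDS of transcript ", transcript@transcriptId)
    out
}

## vectorized variant returning NA for positions outside the CDS
cdsOffsetOrNA <- function(genomicPos, transcript) {
    genomicPos <- as.integer(genomicPos)
    exons <- transcript@cds
    starts <- GenomicRanges::start(exons)
    ends <- GenomicRanges::end(exons)
    widths <- ends - starts + 1L
    cumBefore <- c(0L, cumsum(widths))[seq_along(widths)]
    out <- rep(NA_integer_, length(genomicPos))
    for (k in seq_along(starts)) {
        inExon <- genomicPos >= starts[k] & genomicPos <= ends[k] & is.na(out)
        if (any(inExon)) {
            within <- if (transcript@strand == "+")
                genomicPos[inExon] - starts[k] + 1L
            else ends[k] - genomicPos[inExon] + 1L
            out[inExon] <- cumBefore[k] + within
        }
    }
    out
}

#' CDS exons shared by every isoform of a gene
#'
#' An exon is shared when its genomic CDS interval is identical (same
#' chromosome, start and end) in all transcripts of the gene. For a
#' single-isoform gene all CDS exons are returned. The result is ordered by
#' translation position in the primary transcript.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @return A \link[GenomicRanges]{GRanges}, possibly empty.
#' @export
sharedCdsExons <- function(gene) {
    prim <- primaryTranscript(gene)
    others <- gene@transcripts
    keep <- rep(TRUE, length(prim@cds))
    key <- function(gr) paste(GenomicRanges::seqnames(gr),
                              GenomicRanges::start(gr),
                              GenomicRanges::end(gr))
    pk <- key(prim@cds)
    for (tx in others) {
        keep <- keep & pk %in% key(tx@cds)
    }
    prim@cds[keep]
}

#' Target exons of a gene, in tier order, with their sequences
#'
#' Yields the exons a designer should scan for sgRNA candidates: first the
#' CDS exons shared by all isoforms (5' to 3'), then, as a fallback tier,
#' the primary transcript's CDS exons in translation order (those not
#' already listed as shared). Downstream selection walks the shared tier
#' first and only descends into the fallback tier when the shared tier
#' cannot satisfy the selection policy. Sequences are strand-oriented
#' (reverse-complemented for minus-strand genes).
#'
#' @param gene a \linkS4class{GeneModel}.
#' @param geneModelSet the \linkS4class{GeneModelSet} holding the genome.
#' @param chromStr optional named character vector of chromosome sequences
#'   (a precomputed \code{as.character(genomeSeq(...))}), used to avoid
#'   repeated conversion when many genes are processed in a loop.
#' @return A data.frame with columns tier ("shared" or "fallback"), chrom,
#'   start, end, strand, sequence.
#' @export
targetExonSequences <- function(gene, geneModelSet, chromStr = NULL) {
    prim <- primaryTranscript(gene)
    if (length(prim@cds) == 0L)
        stop("gene ", gene@geneId, " has no CDS")
    shared <- sharedCdsExons(gene)
    sKey <- paste(GenomicRanges::seqnames(shared),
                  GenomicRanges::start(shared), GenomicRanges::end(shared))
    pKey <- paste(GenomicRanges::seqnames(prim@cds),
                  GenomicRanges::start(prim@cds), GenomicRanges::end(prim@cds))
    fallback <- prim@cds[!pKey %in% sKey]
    if (is.null(chromStr)) {
        need <- unique(as.character(GenomicRanges::seqnames(prim@cds)))
        chromStr <- vapply(need, function(ch)
            as.character(geneModelSet@genome[[ch]]), character(1))
    }
    build <- function(gr, tier) {
        if (length(gr) == 0L) return(NULL)
        chrom <- as.character(GenomicRanges::seqnames(gr))
        s <- GenomicRanges::start(gr)
        e <- GenomicRanges::end(gr)
        seqs <- substring(chromStr[chrom], s, e)
        if (prim@strand == "-") seqs <- revcompChr(seqs)
        data.frame(tier = tier, chrom = chrom, start = s, end = e,
                   strand = prim@strand, sequence = unname(seqs),
                   stringsAsFactors = FALSE)
    }
    parts <- Filter(Negate(is.null),
                    list(build(shared, "shared"), build(fallback, "fallback")))
    if (length(parts) == 0L)
        stop("gene ", gene@geneId, " has no target exons")
    do.call(rbind, parts)
}
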