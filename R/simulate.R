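#' Configuration for the synthetic-data generator
#'
#' One object drives every generator stage; the seed fixes all draws, and
#' each stage derives its own deterministic sub-stream so stages can be
#' re-run independently and still reproduce byte-identical files.
#'
#' @param seed integer; mandatory.
#' @param nGenes number of genes (the study design uses 450).
#' @param noSharedFraction fraction of genes whose isoforms share no CDS
#'   exon, exercising the primary-variant fallback tier.
#' @param exonLengths lengths of the three CDS exons in translation order.
#' @param intronLength,spacerLength structural spacing in bp.
#' @param genesPerChrom genes packed per synthetic chromosome.
#' @param minCandidatesPerExon required NGG candidates in each designable
#'   exon; sequences are redrawn until satisfied (designability guarantee).
#' @param poolAbundance "uniform" or "lognormal" per-guide abundance model.
#' @param lognormalSigma sigma of the log-normal abundance model.
#' @param readDepth pool-sequencing depth (reads).
#' @param flanks character(2); constant amplicon flanks around the
#'   protospacer in pool reads.
#' @param readLength target-enrichment read length (bp).
#' @param pairsPerGuide on-target read pairs per guide per replicate.
#' @param replicates biological replicates of the edited sample.
#' @param editRates optional named per-guide true edit fractions in [0,1];
#'   when NULL they are drawn per guide as a mixture of inactive guides
#'   (probability \code{inactiveFraction}) and uniform(0.05, 0.9) actives.
#' @param inactiveFraction probability a guide is truly inactive when
#'   \code{editRates} is NULL.
#' @param backgroundIndelRate per-site probability of a background in/del
#'   shared between edited and control samples.
#' @param dupFraction fraction of edited reads re-emitted as duplicates.
#' @param lowMapqFraction fraction of reads planted with MAPQ below the
#'   filter (drawn from 20/37; passing reads draw from 38/60).
#' @return A validated list of class \code{SimConfig}.
#' @export
simConfig <- function(seed, nGenes = 450L, noSharedFraction = 0.1,
                      exonLengths = c(240L, 180L, 120L),
                      intronLength = 80L, spacerLength = 300L,
                      genesPerChrom = 100L, minCandidatesPerExon = 8L,
                      poolAbundance = c("uniform", "lognormal"),
                      lognormalSigma = 0.5, readDepth = 1e5L,
                      flanks = c("ACGTGGAAAGGACGA", "GTTTTAGAGCTAGAA"),
                      readLength = 150L, pairsPerGuide = 500L,
                      replicates = 2L, editRates = NULL,
                      inactiveFraction = 0.15,
                      backgroundIndelRate = 0.1, dupFraction = 0.05,
                      lowMapqFraction = 0.05) {
    stopifnot(length(seed) == 1L, is.finite(seed), nGenes >= 1L,
              noSharedFraction >= 0, noSharedFraction <= 1,
              length(exonLengths) == 3L, all(exonLengths >= 40L),
              readDepth >= 0, pairsPerGuide >= 0, replicates >= 1L,
              inactiveFraction >= 0, inactiveFraction <= 1,
              backgroundIndelRate >= 0, backgroundIndelRate <= 1,
              dupFraction >= 0, dupFraction <= 1,
              lowMapqFraction >= 0, lowMapqFraction <= 1)
    if (!is.null(editRates))
        stopifnot(all(editRates >= 0), all(editRates <= 1))
    cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
                noSharedFraction = noSharedFraction,
                exonLengths = as.integer(exonLengths),
                intronLength = as.integer(intronLength),
                spacerLength = as.integer(spacerLength),
                genesPerChrom = as.integer(genesPerChrom),
                minCandidatesPerExon = as.integer(minCandidatesPerExon),
                poolAbundance = match.arg(poolAbundance),
                lognormalSigma = lognormalSigma,
                readDepth = as.integer(readDepth), flanks = flanks,
                readLength = as.integer(readLength),
                pairsPerGuide = as.integer(pairsPerGuide),
                replicates = as.integer(replicates),
                editRates = editRates,
                inactiveFraction = inactiveFraction,
                backgroundIndelRate = backgroundIndelRate,
                dupFraction = dupFraction,
                lowMapqFraction = lowMapqFraction)
    class(cfg) <- "SimConfig"
    cfg
}

randSeq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c(0.27, 0.23, 0.23, 0.27)), collapse = "")
}

countCandidates <- function(seqChr) {
    n <- 0L
    g <- gregexpr("(?=GG)", seqChr, perl = TRUE)[[1]]
    if (g[1] != -1L) n <- n + sum(g >= 22L & g + 1L <= nchar(seqChr))
    c2 <- gregexpr("(?=CC)", seqChr, perl = TRUE)[[1]]
    if (c2[1] != -1L) n <- n + sum(c2 + 22L <= nchar(seqChr))
    n
}

#' Simulate a designable genome with isoform-resolved annotation
#'
#' Emits a FASTA genome, a GTF annotation with two isoforms per gene and
#' an external guide list, all with recorded ground truth. Each gene has
#' three CDS exons; the non-primary isoform shares all but the first
#' translated exon, except for a planned fraction of genes whose isoforms
#' share no CDS exon (these exercise the fallback tier). Every designable
#' exon is redrawn until it holds at least \code{minCandidatesPerExon}
#' full-protospacer NGG sites, so a default design run can always select
#' its full per-gene quota. The external list carries at least three
#' admissible guides per gene, located in the last translated exon and
#' hence disjoint from the designed target exons.
#'
#' @param config a \code{\link{simConfig}} object.
#' @param dir output directory (created).
#' @return list with paths (genome, annotation, externalGuides, truth) and
#'   the ground-truth list (gene table, external guides, plan).
#' @export
simulateGenome <- function(config, dir) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    nG <- config$nGenes
    nNoShared <- round(nG * config$noSharedFraction)
    noSharedIdx <- if (nNoShared > 0) sort(sample(nG, nNoShared)) else integer()

    chromOf <- (seq_len(nG) - 1L) %/% config$genesPerChrom + 1L
    chromNames <- paste0("chr", seq_len(max(chromOf)))
    chromSeqs <- setNames(rep("", length(chromNames)), chromNames)

    intr <- config$intronLength
    spc <- config$spacerLength
    geneRows <- list()
    gtfRows <- list()
    extRows <- list()
    for (i in seq_len(nG)) {
        gid <- sprintf("G%04d", i)
        strand <- if (i %% 2L == 1L) "+" else "-"
        noShared <- i %in% noSharedIdx
        ## left-to-right exon lengths; translation order depends on strand
        l2r <- if (strand == "+") config$exonLengths else rev(config$exonLengths)
        locusLen <- spc + sum(l2r) + 2L * intr + spc
        chrom <- chromNames[chromOf[i]]
        offset <- nchar(chromSeqs[[chrom]])

        ## redraw until designable exons have enough NGG candidates
        tries <- 0L
        repeat {
            tries <- tries + 1L
            if (tries > 60L)
                stop("could not generate a designable sequence for ", gid)
            locus <- randSeq(locusLen)
            aS <- spc + 1L; aE <- aS + l2r[1] - 1L
            bS <- aE + intr + 1L; bE <- bS + l2r[2] - 1L
            cS <- bE + intr + 1L; cE <- cS + l2r[3] - 1L
            ## exons in translation order
            ex <- if (strand == "+") rbind(c(aS, aE), c(bS, bE), c(cS, cE))
                  else rbind(c(cS, cE), c(bS, bE), c(aS, aE))
            seqOf <- function(s, e) substr(locus, s, e)
            ## designable exons: first shared exon (translation exon 2) for
            ## shared genes, first translated exon for fallback genes; the
            ## external-guide exon is the last translated one
            need <- c(countCandidates(seqOf(ex[1, 1], ex[1, 2])),
                      countCandidates(seqOf(ex[2, 1], ex[2, 2])),
                      countCandidates(seqOf(ex[3, 1], ex[3, 2])))
            if (!all(need >= config$minCandidatesPerExon)) next
            ## external guides must include >= 2 that are mutually
            ## admissible under the <15 bp shared-span import rule
            lastSeq <- seqOf(ex[3, 1], ex[3, 2])
            extCand <- scanPams(if (strand == "-") revcompChr(lastSeq)
                                else lastSeq,
                                chrom, ex[3, 1], ex[3, 2], strand)
            pick <- integer()
            for (j in seq_len(nrow(extCand))) {
                if (length(pick) >= 3L) break
                ov <- overlapBp(extCand$start[j], extCand$end[j],
                                extCand$start[pick], extCand$end[pick],
                                rep(TRUE, length(pick)))
                if (!length(ov) || all(ov < 15L))
                    pick <- c(pick, j)
            }
            if (length(pick) >= 2L) break
        }
        exG <- ex
        exG[, 1] <- exG[, 1] + offset
        exG[, 2] <- exG[, 2] + offset
        chromSeqs[[chrom]] <- paste0(chromSeqs[[chrom]], locus)

        category <- sample(c("chromatin modification",
                             "chromosome organization",
                             "DNA methylation", "DNA repair",
                             "chromatin reader"), 1L)
        t1 <- paste0(gid, ".t1")
        t2 <- paste0(gid, ".t2")
        mkRow <- function(tid, s, e, tag) data.frame(
            chrom = chrom, start = s, end = e, strand = strand,
            gene_id = gid, transcript_id = tid, gene_name = gid,
            gene_category = category, tag = tag, stringsAsFactors = FALSE)
        for (k in 1:3)
            gtfRows[[length(gtfRows) + 1L]] <-
                mkRow(t1, exG[k, 1], exG[k, 2], "primary")
        ## non-primary isoform
        if (!noShared) {
            ## first translated exon trimmed by 6 nt at its 5' end
            e1 <- exG[1, ]
            if (strand == "+") e1[1] <- e1[1] + 6L else e1[2] <- e1[2] - 6L
            alt <- rbind(e1, exG[2, ], exG[3, ])
        } else {
            ## every exon trimmed by 3 nt at its 5' end: no interval is shared
            alt <- exG
            for (k in 1:3) {
                if (strand == "+") alt[k, 1] <- alt[k, 1] + 3L
                else alt[k, 2] <- alt[k, 2] - 3L
            }
        }
        for (k in 1:3)
            gtfRows[[length(gtfRows) + 1L]] <-
                mkRow(t2, alt[k, 1], alt[k, 2], "alternative")

        ## external guides: the pre-validated compatible picks, shifted to
        ## genomic coordinates
        cand <- extCand[pick, , drop = FALSE]
        cand$start <- cand$start + offset
        cand$end <- cand$end + offset
        cand$cut_site <- cand$cut_site + offset
        cand$gene_id <- gid
        cand$predicted_activity <- round(stats::runif(nrow(cand), 0.3, 0.85), 3)
        extRows[[length(extRows) + 1L]] <- cand

        geneRows[[length(geneRows) + 1L]] <- data.frame(
            gene_id = gid, chrom = chrom, strand = strand,
            no_shared = noShared,
            exon1_start = exG[1, 1], exon1_end = exG[1, 2],
            exon2_start = exG[2, 1], exon2_end = exG[2, 2],
            exon3_start = exG[3, 1], exon3_end = exG[3, 2],
            stringsAsFactors = FALSE)
    }

    genomePath <- file.path(dir, "genome.fa")
    genome <- Biostrings::DNAStringSet(unlist(chromSeqs))
    Biostrings::writeXStringSet(genome, genomePath)

    gtf <- do.call(rbind, gtfRows)
    gr <- GenomicRanges::GRanges(gtf$chrom,
                                 IRanges::IRanges(gtf$start, gtf$end),
                                 strand = gtf$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        source = "sim", type = "CDS", phase = 0L, gene_id = gtf$gene_id,
        transcript_id = gtf$transcript_id, gene_name = gtf$gene_name,
        gene_category = gtf$gene_category, tag = gtf$tag)
    annotationPath <- file.path(dir, "annotation.gtf")
    rtracklayer::export(gr, annotationPath, format = "gtf")

    external <- do.call(rbind, extRows)
    external <- external[, c("gene_id", "protospacer", "pam", "chrom",
                             "start", "end", "strand", "cut_site",
                             "predicted_activity")]
    ## a protospacer duplicated across genes would violate admissibility
    external <- external[!duplicated(external$protospacer), , drop = FALSE]
    externalPath <- file.path(dir, "external_guides.tsv")
    utils::write.table(external, externalPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth <- list(plan = list(n_genes = nG, no_shared_genes = nNoShared,
                              no_shared_ids = sprintf("G%04d", noSharedIdx)),
                  genes = do.call(rbind, geneRows))
    truthPath <- file.path(dir, "truth_genome.json")
    jsonlite::write_json(truth, truthPath, dataframe = "columns",
                         auto_unbox = TRUE, digits = NA)
    list(genome = genomePath, annotation = annotationPath,
         externalGuides = externalPath, truth = truth,
         truthPath = truthPath)
}

#' Simulate pooled-library amplicon reads
#'
#' Reads are constant flank + protospacer + constant flank; per-read guide
#' identity is a multinomial draw from the configured abundance model.
#' True per-guide counts are returned alongside the reads.
#'
#' @param guideTable data.frame (or \linkS4class{GuideSet}) with guide_id
#'   and protospacer.
#' @param config a \code{\link{simConfig}}.
#' @param fastq optional path; when given, reads are written as FASTQ.
#' @param zeroAbundance guide_ids forced to abundance 0 (dropout guides).
#' @return list(reads = DNAStringSet, trueCounts = data.frame, path).
#' @export
simulatePoolReads <- function(guideTable, config, fastq = NULL,
                              zeroAbundance = character()) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1L)
    g <- if (is(guideTable, "GuideSet")) as.data.frame(guideTable@guides)
         else as.data.frame(guideTable)
    n <- nrow(g)
    ab <- switch(config$poolAbundance,
                 uniform = rep(1, n),
                 lognormal = stats::rlnorm(n, 0, config$lognormalSigma))
    ab[g$guide_id %in% zeroAbundance] <- 0
    if (sum(ab) == 0) stop("all abundances are zero")
    counts <- as.integer(stats::rmultinom(1, config$readDepth, ab / sum(ab)))
    seqs <- rep(paste0(config$flanks[1], g$protospacer, config$flanks[2]),
                counts)
    if (length(seqs)) seqs <- sample(seqs)
    reads <- Biostrings::DNAStringSet(seqs)
    if (length(reads))
        names(reads) <- sprintf("read%07d", seq_along(reads))
    if (!is.null(fastq)) {
        Biostrings::writeXStringSet(
            reads, fastq, format = "fastq",
            qualities = Biostrings::BStringSet(
                strrep("I", Biostrings::width(reads))))
    }
    list(reads = reads,
         trueCounts = data.frame(guide_id = g$guide_id, true_reads = counts,
                                 true_abundance = ab,
                                 stringsAsFactors = FALSE),
         path = fastq)
}

#' Externally predicted activity emulation
#'
#' Emulates a partially predictive activity algorithm: the true edit rate
#' plus Gaussian noise, clamped to [0, 1]. Used to exercise the
#' OAS-versus-prediction rank correlation.
#'
#' @param trueRates named numeric vector of true edit rates.
#' @param noiseSd standard deviation of the added noise (default 0.2).
#' @param seed integer seed.
#' @return data.frame: guide_id, activity.
#' @export
simulatePredictedActivity <- function(trueRates, noiseSd = 0.2, seed = 1L) {
    set.seed(seed)
    act <- pmin(1, pmax(0, trueRates + stats::rnorm(length(trueRates), 0,
                                                    noiseSd)))
    data.frame(guide_id = names(trueRates), activity = as.numeric(act),
               stringsAsFactors = FALSE)
}

samFlag <- function(proper, first, dup) {
    base <- if (first) 1L + 64L + 32L else 1L + 128L + 16L
    base + (if (proper) 2L else 0L) + (if (dup) 1024L else 0L)
}

#' Simulate edited and control target-enrichment alignments
#'
#' For every target site, emits paired 150 bp reads spanning the cleavage
#' site. With the guide's true edit rate a pair carries one in/del (length
#' 1-20, position jittered up to 2 nt around the cut) encoded in the first
#' mate's CIGAR, and the pair is flagged not-proper; unedited pairs are
#' proper with gapless CIGARs. A configurable fraction of reads carries a
#' MAPQ below the filter cutoff, and a fraction of edited reads is
#' re-emitted flagged as duplicate. Per-site background in/dels are
#' planted at identical keys in both the edited replicates and the
#' untransduced control, so control subtraction can be exercised. Ground
#' truth records every planted event with its read's fate-determining
#' attributes.
#'
#' @param sites data.frame from \code{\link{targetSites}}.
#' @param geneModelSet the \linkS4class{GeneModelSet} providing reference
#'   sequence.
#' @param config a \code{\link{simConfig}} (editRates drawn here when not
#'   supplied).
#' @param dir output directory for SAM files.
#' @return list(editedPaths, controlPath, truth). truth holds editRates,
#'   an events data.frame (replicate, guide_id, read_id, type, position,
#'   length, mapq, duplicate, background) and the background event keys.
#' @export
simulateEditing <- function(sites, geneModelSet, config, dir) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 2L)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    L <- config$readLength
    genome <- geneModelSet@genome
    chromStr <- setNames(as.character(genome), names(genome))

    rates <- config$editRates
    if (is.null(rates)) {
        inactive <- stats::runif(nrow(sites)) < config$inactiveFraction
        rates <- ifelse(inactive, 0, stats::runif(nrow(sites), 0.05, 0.9))
        names(rates) <- sites$guide_id
    } else {
        stopifnot(all(sites$guide_id %in% names(rates)))
        rates <- rates[sites$guide_id]
    }

    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                        Biostrings::width(genome)))

    drawMapq <- function(n) {
        low <- stats::runif(n) < config$lowMapqFraction
        ifelse(low, sample(c(20L, 37L), n, replace = TRUE),
               sample(c(38L, 60L), n, replace = TRUE, prob = c(0.1, 0.9)))
    }
    samLine <- function(qname, flag, chrom, pos, mapq, cigar, seq) {
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                qname, flag, chrom, pos, mapq, cigar, seq,
                strrep("I", nchar(seq)))
    }

    ## per-site background events, shared between samples
    bgKeys <- list()
    for (i in seq_len(nrow(sites))) {
        if (stats::runif(1) < config$backgroundIndelRate) {
            s <- sites[i, ]
            bgKeys[[length(bgKeys) + 1L]] <- data.frame(
                guide_id = s$guide_id, chrom = s$chrom,
                type = sample(c("insertion", "deletion"), 1L),
                position = s$cut_site + sample(-2:2, 1L),
                length = sample(1:20, 1L), stringsAsFactors = FALSE)
        }
    }
    bg <- if (length(bgKeys)) do.call(rbind, bgKeys)
          else data.frame(guide_id = character(), chrom = character(),
                          type = character(), position = integer(),
                          length = integer(), stringsAsFactors = FALSE)

    refseq <- function(chrom, s, e) substr(chromStr[[chrom]], s, e)

    emitEvent <- function(chrom, pos1, type, epos, elen) {
        ## returns c(cigar, seq) for a read of length L starting at pos1
        if (type == "deletion") {
            x <- epos - pos1
            y <- L - x
            cig <- sprintf("%dM%dD%dM", x, elen, y)
            seq <- paste0(refseq(chrom, pos1, epos - 1L),
                          refseq(chrom, epos + elen, epos + elen + y - 1L))
        } else {
            x <- epos - pos1 + 1L
            y <- L - x - elen
            cig <- sprintf("%dM%dI%dM", x, elen, y)
            seq <- paste0(refseq(chrom, pos1, epos),
                          paste(sample(c("A", "C", "G", "T"), elen,
                                       replace = TRUE), collapse = ""),
                          refseq(chrom, epos + 1L, epos + y))
        }
        c(cig, seq)
    }

    truthEvents <- list()
    editedPaths <- character(config$replicates)
    for (rp in seq_len(config$replicates)) {
        lines <- list(header)
        for (i in seq_len(nrow(sites))) {
            s <- sites[i, ]
            cut <- s$cut_site
            pos1 <- cut - 100L
            pos2 <- cut + 30L
            nP <- config$pairsPerGuide
            if (nP == 0L) next
            edited <- stats::runif(nP) < rates[[s$guide_id]]
            mapq1 <- drawMapq(nP)
            mapq2 <- drawMapq(nP)
            qn <- sprintf("%s_r%d_p%05d", s$guide_id, rp, seq_len(nP))
            siteLines <- list()
            for (p in seq_len(nP)) {
                if (edited[p]) {
                    type <- sample(c("insertion", "deletion"), 1L)
                    elen <- sample(1:20, 1L)
                    epos <- cut + sample(-2:2, 1L)
                    cs <- emitEvent(s$chrom, pos1, type, epos, elen)
                    l1 <- samLine(qn[p], samFlag(FALSE, TRUE, FALSE), s$chrom,
                                  pos1, mapq1[p], cs[1], cs[2])
                    l2 <- samLine(qn[p], samFlag(FALSE, FALSE, FALSE), s$chrom,
                                  pos2, mapq2[p], paste0(L, "M"),
                                  refseq(s$chrom, pos2, pos2 + L - 1L))
                    siteLines[[length(siteLines) + 1L]] <- c(l1, l2)
                    isDup <- stats::runif(1) < config$dupFraction
                    if (isDup) {
                        siteLines[[length(siteLines) + 1L]] <- samLine(
                            paste0(qn[p], "d"), samFlag(FALSE, TRUE, TRUE),
                            s$chrom, pos1, mapq1[p], cs[1], cs[2])
                    }
                    truthEvents[[length(truthEvents) + 1L]] <- data.frame(
                        replicate = rp, guide_id = s$guide_id,
                        read_id = qn[p], chrom = s$chrom, type = type,
                        position = epos, length = elen, mapq = mapq1[p],
                        duplicate = FALSE, background = FALSE,
                        stringsAsFactors = FALSE)
                    if (isDup)
                        truthEvents[[length(truthEvents) + 1L]] <- data.frame(
                            replicate = rp, guide_id = s$guide_id,
                            read_id = paste0(qn[p], "d"), chrom = s$chrom,
                            type = type, position = epos, length = elen,
                            mapq = mapq1[p], duplicate = TRUE,
                            background = FALSE, stringsAsFactors = FALSE)
                } else {
                    l1 <- samLine(qn[p], samFlag(TRUE, TRUE, FALSE), s$chrom,
                                  pos1, mapq1[p], paste0(L, "M"),
                                  refseq(s$chrom, pos1, pos1 + L - 1L))
                    l2 <- samLine(qn[p], samFlag(TRUE, FALSE, FALSE), s$chrom,
                                  pos2, mapq2[p], paste0(L, "M"),
                                  refseq(s$chrom, pos2, pos2 + L - 1L))
                    siteLines[[length(siteLines) + 1L]] <- c(l1, l2)
                }
            }
            ## background reads sharing a key with the control
            bgi <- bg[bg$guide_id == s$guide_id, , drop = FALSE]
            if (nrow(bgi)) {
                cs <- emitEvent(s$chrom, pos1, bgi$type[1], bgi$position[1],
                                bgi$length[1])
                for (b in 1:3) {
                    rid <- sprintf("%s_r%d_bg%02d", s$guide_id, rp, b)
                    siteLines[[length(siteLines) + 1L]] <- samLine(
                        rid, samFlag(FALSE, TRUE, FALSE), s$chrom, pos1,
                        60L, cs[1], cs[2])
                    truthEvents[[length(truthEvents) + 1L]] <- data.frame(
                        replicate = rp, guide_id = s$guide_id,
                        read_id = rid, chrom = s$chrom, type = bgi$type[1],
                        position = bgi$position[1], length = bgi$length[1],
                        mapq = 60L, duplicate = FALSE, background = TRUE,
                        stringsAsFactors = FALSE)
                }
            }
            lines[[length(lines) + 1L]] <- unlist(siteLines)
        }
        editedPaths[rp] <- file.path(dir, sprintf("edited_rep%d.sam", rp))
        writeLines(unlist(lines), editedPaths[rp])
    }

    ## control: unedited proper pairs plus the background events
    lines <- list(header)
    for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        pos1 <- s$cut_site - 100L
        pos2 <- s$cut_site + 30L
        qn <- sprintf("%s_c_p%03d", s$guide_id, 1:10)
        ctl <- character(0)
        for (p in 1:10) {
            ctl <- c(ctl,
                     samLine(qn[p], samFlag(TRUE, TRUE, FALSE), s$chrom, pos1,
                             60L, paste0(L, "M"),
                             refseq(s$chrom, pos1, pos1 + L - 1L)),
                     samLine(qn[p], samFlag(TRUE, FALSE, FALSE), s$chrom, pos2,
                             60L, paste0(L, "M"),
                             refseq(s$chrom, pos2, pos2 + L - 1L)))
        }
        bgi <- bg[bg$guide_id == s$guide_id, , drop = FALSE]
        if (nrow(bgi)) {
            cs <- emitEvent(s$chrom, pos1, bgi$type[1], bgi$position[1],
                            bgi$length[1])
            for (b in 1:5)
                ctl <- c(ctl, samLine(sprintf("%s_c_bg%02d", s$guide_id, b),
                                      samFlag(FALSE, TRUE, FALSE), s$chrom,
                                      pos1, 60L, cs[1], cs[2]))
        }
        lines[[length(lines) + 1L]] <- ctl
    }
    controlPath <- file.path(dir, "control.sam")
    writeLines(unlist(lines), controlPath)

    truth <- list(
        editRates = rates,
        events = if (length(truthEvents)) do.call(rbind, truthEvents)
                 else data.frame(),
        background = bg)
    list(editedPaths = editedPaths, controlPath = controlPath, truth = truth)
}
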