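#' @useDynLib crisprArrayKit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

revcompChr <- function(x) {
    rev1 <- function(s) paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                              collapse = "")
    chartr("ACGTN", "TGCAN",
           vapply(x, rev1, character(1), USE.NAMES = FALSE))
}

#' Enumerate SpCas9 (NGG) guide candidates in an exon window
#'
#' Scans both genomic strands of the window for NGG protospacer-adjacent
#' motifs whose full 20-nt protospacer and PAM lie inside the window, and
#' returns unscored candidates with genomic coordinates, guide-oriented
#' protospacer sequence, GC fraction and cleavage site. Candidates whose
#' protospacer or PAM contains an ambiguous base (N) are dropped and
#' tallied in the \code{"nDropped"} attribute.
#'
#' @param exonSequence character; the window sequence, strand-oriented as
#'   produced by \code{\link{targetExonSequences}}.
#' @param chrom chromosome name.
#' @param exonStart,exonEnd 1-based closed genomic interval of the window.
#' @param strandOfSequence strand of \code{exonSequence} ("+": the sequence
#'   is the genome-forward text; "-": its reverse complement).
#' @return A data.frame with columns protospacer, pam, chrom, strand,
#'   start, end (genomic span of the 20-mer), cut_site.
#' @examples
#' scanPams(paste0(strrep("A", 20), "TGG"), "chr1", 1001, 1023, "+")
#' @export
scanPams <- function(exonSequence, chrom, exonStart, exonEnd,
                     strandOfSequence = "+") {
    stopifnot(nchar(exonSequence) == exonEnd - exonStart + 1L,
              strandOfSequence %in% c("+", "-"))
    exonStart <- as.integer(exonStart)
    exonEnd <- as.integer(exonEnd)
    fwd <- toupper(exonSequence)
    if (strandOfSequence == "-") fwd <- revcompChr(fwd)
    L <- nchar(fwd)
    empty <- data.frame(protospacer = character(), pam = character(),
                        chrom = character(), strand = character(),
                        start = integer(), end = integer(),
                        cut_site = integer(), stringsAsFactors = FALSE)
    attr(empty, "nDropped") <- 0L
    if (L < 23L) return(empty)

    at <- function(pat) {
        m <- gregexpr(pat, fwd, perl = TRUE)[[1]]
        if (m[1] == -1L) integer() else as.integer(m)
    }
    rows <- list()
    ## plus strand: protospacer [i, i+19], PAM [i+20, i+22], GG at i+21
    qG <- at("(?=GG)")
    qG <- qG[qG >= 22L & qG + 1L <= L]
    if (length(qG)) {
        i <- qG - 21L
        rows[[length(rows) + 1L]] <- data.frame(
            protospacer = substring(fwd, i, i + 19L),
            pam = substring(fwd, i + 20L, i + 22L),
            chrom = chrom, strand = "+",
            start = exonStart + i - 1L, end = exonStart + i + 18L,
            stringsAsFactors = FALSE)
    }
    ## minus strand: CC at [q, q+1], PAM base at q+2, protospacer rc [q+3, q+22]
    qC <- at("(?=CC)")
    qC <- qC[qC + 22L <= L]
    if (length(qC)) {
        rows[[length(rows) + 1L]] <- data.frame(
            protospacer = revcompChr(substring(fwd, qC + 3L, qC + 22L)),
            pam = revcompChr(substring(fwd, qC, qC + 2L)),
            chrom = chrom, strand = "-",
            start = exonStart + qC + 2L, end = exonStart + qC + 21L,
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) return(empty)
    out <- do.call(rbind, rows)
    hasN <- grepl("[^ACGT]", paste0(out$protospacer, out$pam))
    nDropped <- sum(hasN)
    out <- out[!hasN, , drop = FALSE]
    out$cut_site <- guideCutSite(out$start, out$end, out$strand)
    rownames(out) <- NULL
    attr(out, "nDropped") <- nDropped
    out
}

#' GC fraction of protospacers
#'
#' @param protospacer character vector of sequences.
#' @return (#G + #C) / length, per sequence.
#' @export
gcContent <- function(protospacer) {
    x <- Biostrings::DNAStringSet(protospacer)
    as.numeric(Biostrings::letterFrequency(x, "GC")) / Biostrings::width(x)
}

#' Cas9 cleavage site of a protospacer span
#'
#' The scission point lies 6 nt upstream of the end of the guide plus PAM;
#' the reported coordinate is the base on the PAM-proximal side of the blunt
#' cut, i.e. protospacer position 17 counted from the guide's 5' end.
#'
#' @param start,end genomic span of the 20-mer protospacer (1-based closed).
#' @param strand "+" or "-" (vectorized).
#' @return Integer genomic coordinate, strictly inside the span.
#' @examples
#' guideCutSite(101, 120, "+")  # 117
#' guideCutSite(121, 140, "-")  # 124
#' @export
guideCutSite <- function(start, end, strand) {
    as.integer(ifelse(strand == "+", start + 16L, end - 16L))
}

#' Predicted percentage of peptide remaining after disruption
#'
#' Assumes a frameshift or nonsense mutation at the final protospacer
#' nucleotide before the PAM and reports the percentage of the primary
#' transcript's CDS upstream of (and including) that base. Guides whose
#' disruption point falls outside the primary CDS get \code{NA}.
#'
#' @param start,end,strand protospacer span and strand (vectorized).
#' @param transcript the primary \linkS4class{TranscriptModel}.
#' @return Numeric vector in [0, 100], NA where outside the CDS.
#' @export
peptideRemaining <- function(start, end, strand, transcript) {
    disruption <- ifelse(strand == "+", end, start)
    100 * cdsOffsetOrNA(disruption, transcript) / cdsLength(transcript)
}

#' Count near-match genomic sites of protospacers
#'
#' Exhaustive scan of both strands of the genome for NGG-adjacent sites
#' within \code{maxMismatch} of each protospacer; the guide's own on-target
#' site is excluded from the returned count.
#'
#' @param protospacers character vector of 20-mers.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param maxMismatch maximum mismatches tolerated (default 3).
#' @return Integer vector of off-target site counts.
#' @export
offTargetCounts <- function(protospacers, genome, maxMismatch = 3L) {
    hits <- cppCountNearMatches(as.character(genome),
                                as.character(protospacers),
                                as.integer(maxMismatch))
    pmax(hits - 1L, 0L)
}

#' Specificity scores for protospacers
#'
#' The built-in scorer maps the off-target count k from
#' \code{\link{offTargetCounts}} to the monotone score 100 / (1 + k): 100
#' for a genome-unique guide, strictly decreasing with every additional
#' near-match site. Externally computed scores (e.g. from a web designer)
#' supplied as a table override the built-in value per protospacer.
#'
#' @param protospacers character vector of 20-mers.
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param external optional data.frame with columns protospacer, score.
#' @param maxMismatch passed to \code{\link{offTargetCounts}}.
#' @return Numeric scores in (0, 100].
#' @export
specificityScores <- function(protospacers, genome, external = NULL,
                              maxMismatch = 3L) {
    score <- 100 / (1 + offTargetCounts(protospacers, genome, maxMismatch))
    if (!is.null(external) && nrow(external)) {
        idx <- match(protospacers, external$protospacer)
        hit <- !is.na(idx)
        score[hit] <- external$score[idx[hit]]
    }
    score
}

rankCandidates <- function(cand, params) {
    scoreTier <- ifelse(cand$specificity_score >= params@scoreThreshold, 0L, 1L)
    pos5 <- ifelse(is.na(cand$cds_pos), .Machine$integer.max, cand$cds_pos)
    order(scoreTier, pos5, -cand$specificity_score, cand$protospacer)
}

spansOverlap <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 & s1 <= e2 & s2 <= e1
}

#' Select designed guides for one gene under the tiered policy
#'
#' Candidates are taken tier by tier (shared exons first, then the
#' primary-variant fallback). Within a tier candidates scoring at least the
#' preferred threshold rank before backups (score in [backup, preferred)),
#' then by more-5' cut position in the primary CDS, then by higher score,
#' then lexicographically by protospacer. Selection is a two-phase greedy:
#' a core of mutually non-overlapping guides (up to the required minimum)
#' is assembled first in rank order, then remaining slots are filled by
#' rank regardless of overlap. Later tiers are consulted only when the
#' quota is unfilled. Candidates below the backup threshold are never used.
#'
#' @param candidates data.frame as from \code{\link{scanPams}} plus columns
#'   tier, specificity_score, cds_pos, gc_fraction, peptide_remaining_pct.
#' @param params \linkS4class{DesignParams}.
#' @param excludeProtospacers protospacers already used elsewhere in the
#'   library (global-uniqueness re-selection).
#' @return list(selected = data.frame with a group column, flags = list).
#' @export
selectGuides <- function(candidates, params = DesignParams(),
                         excludeProtospacers = character()) {
    flags <- list(unreachable = FALSE, all_threshold_met = FALSE,
                  backup_used = FALSE, nonoverlap_met = FALSE,
                  used_fallback = FALSE)
    adm <- candidates[candidates$specificity_score >= params@backupThreshold &
                      !candidates$protospacer %in% excludeProtospacers &
                      !duplicated(candidates$protospacer), , drop = FALSE]
    if (nrow(adm) == 0L) {
        flags$unreachable <- TRUE
        return(list(selected = candidates[0, , drop = FALSE], flags = flags))
    }
    nWant <- params@nDesignedPerGene
    coreWant <- min(params@minNonoverlappingDesigned, nWant)
    selected <- adm[0, , drop = FALSE]
    coreIdx <- integer()

    tiers <- unique(candidates$tier)
    for (tier in tiers) {
        if (nrow(selected) >= nWant) break
        pool <- adm[adm$tier == tier & !adm$protospacer %in% selected$protospacer, ,
                    drop = FALSE]
        if (nrow(pool) == 0L) next
        pool <- pool[rankCandidates(pool, params), , drop = FALSE]
        ## phase A: extend the mutually non-overlapping core
        for (i in seq_len(nrow(pool))) {
            if (length(coreIdx) >= coreWant || nrow(selected) >= nWant) break
            cand <- pool[i, ]
            if (cand$protospacer %in% selected$protospacer) next
            core <- selected[coreIdx, , drop = FALSE]
            if (nrow(core) == 0L ||
                !any(spansOverlap(cand$chrom, cand$start, cand$end,
                                  core$chrom, core$start, core$end))) {
                selected <- rbind(selected, cand)
                coreIdx <- c(coreIdx, nrow(selected))
            }
        }
        ## phase B: fill remaining slots by rank
        for (i in seq_len(nrow(pool))) {
            if (nrow(selected) >= nWant) break
            cand <- pool[i, ]
            if (cand$protospacer %in% selected$protospacer) next
            selected <- rbind(selected, cand)
        }
    }
    if (nrow(selected)) {
        selected$group <- seq_len(nrow(selected))
        flags$all_threshold_met <-
            nrow(selected) == nWant &&
            all(selected$specificity_score >= params@scoreThreshold)
        flags$backup_used <- any(selected$specificity_score < params@scoreThreshold)
        flags$nonoverlap_met <- length(coreIdx) >= min(coreWant, nrow(selected))
        flags$used_fallback <- any(selected$tier == "fallback")
    }
    rownames(selected) <- NULL
    list(selected = selected, flags = flags)
}

overlapBp <- function(s1, e1, s2, e2, sameChrom) {
    ifelse(sameChrom, pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L), 0L)
}

#' Import externally designed guides for one gene
#'
#' Walks the external list in its given priority order and accepts a guide
#' unless its protospacer span shares at least
#' \code{importedOverlapLimitBp} bp (default 15) with any already selected
#' guide, designed or imported, or duplicates a used protospacer. Fills up
#' to \code{nImportedPerGene} slots.
#'
#' @param external data.frame with columns protospacer, pam, chrom, start,
#'   end, strand (priority = row order; optional predicted_activity).
#' @param selected data.frame of already selected guides (chrom/start/end).
#' @param params \linkS4class{DesignParams}.
#' @param excludeProtospacers protospacers already used in the library.
#' @return list(imported = data.frame, underCovered = logical).
#' @export
importExternalGuides <- function(external, selected,
                                 params = DesignParams(),
                                 excludeProtospacers = character()) {
    taken <- external[0, , drop = FALSE]
    occC <- c(as.character(selected$chrom))
    occS <- c(selected$start); occE <- c(selected$end)
    for (i in seq_len(nrow(external))) {
        if (nrow(taken) >= params@nImportedPerGene) break
        g <- external[i, ]
        if (g$protospacer %in% c(excludeProtospacers, taken$protospacer,
                                 selected$protospacer)) next
        ov <- overlapBp(g$start, g$end, occS, occE,
                        as.character(g$chrom) == occC)
        if (length(ov) && any(ov >= params@importedOverlapLimitBp)) next
        taken <- rbind(taken, g)
        occC <- c(occC, as.character(g$chrom))
        occS <- c(occS, g$start); occE <- c(occE, g$end)
    }
    rownames(taken) <- NULL
    list(imported = taken,
         underCovered = nrow(taken) < params@nImportedPerGene)
}

summarizeLibrary <- function(guides, params) {
    hasScore <- !is.na(guides$specificity_score)
    hasPep <- !is.na(guides$peptide_remaining_pct)
    hasAct <- !is.na(guides$predicted_activity)
    perGene <- table(factor(guides$gene_id, levels = unique(guides$gene_id)))
    hist <- table(factor(as.integer(perGene), levels = 1:7))
    list(
        n_guides = nrow(guides),
        n_genes = length(unique(guides$gene_id)),
        pct_score_ge_threshold = if (any(hasScore))
            100 * mean(guides$specificity_score[hasScore] >=
                       params@scoreThreshold) else NA_real_,
        pct_peptide_le25 = if (any(hasPep))
            100 * mean(guides$peptide_remaining_pct[hasPep] <= 25) else NA_real_,
        pct_gc_in_band = 100 * mean(guides$gc_fraction >= params@gcBand[1] &
                                    guides$gc_fraction <= params@gcBand[2]),
        pct_predicted_ge_threshold = if (any(hasAct))
            100 * mean(guides$predicted_activity[hasAct] >=
                       params@predictedActivityFlagThreshold) else NA_real_,
        guides_per_gene = as.integer(perGene),
        genes_with_at_least_k = vapply(1:7, function(k)
            sum(perGene >= k), integer(1)))
}

#' Design a complete sgRNA library
#'
#' Runs the full per-gene design: candidate enumeration over target exons
#' in tier order, specificity scoring (built-in near-match scan unless an
#' external score table is given), peptide-remaining prediction, tiered
#' selection of up to \code{nDesignedPerGene} designed guides (groups 1-5)
#' and import of up to \code{nImportedPerGene} external guides (groups
#' 6-7) under the overlap rule. Protospacer uniqueness is enforced across
#' the whole library: a gene that would reuse a protospacer already taken
#' by an earlier gene re-selects its next-ranked candidate.
#'
#' @param geneModelSet a \linkS4class{GeneModelSet}.
#' @param externalGuides data.frame of importable guides with columns
#'   gene_id, protospacer, pam, chrom, start, end, strand and optionally
#'   predicted_activity; row order within a gene is priority order.
#' @param params \linkS4class{DesignParams}.
#' @param externalScores optional data.frame (protospacer, score)
#'   overriding the built-in specificity scorer.
#' @param predictedActivity optional data.frame (protospacer, activity)
#'   attaching externally predicted activity to designed guides.
#' @param maxMismatch near-match radius of the built-in scorer.
#' @return A \linkS4class{GuideSet}.
#' @examples
#' cfg <- simConfig(seed = 7, nGenes = 3)
#' paths <- simulateGenome(cfg, dir = tempfile())
#' gms <- loadAnnotation(paths$annotation, paths$genome)
#' ext <- utils::read.delim(paths$externalGuides)
#' lib <- designLibrary(gms, ext)
#' lib
#' @export
designLibrary <- function(geneModelSet, externalGuides,
                          params = DesignParams(), externalScores = NULL,
                          predictedActivity = NULL, maxMismatch = 3L) {
    genes <- geneModelSet@genes
    chromStr <- vapply(names(geneModelSet@genome), function(ch)
        as.character(geneModelSet@genome[[ch]]), character(1))
    ## enumerate candidates for every gene first so scoring is one batch
    candList <- vector("list", length(genes))
    names(candList) <- names(genes)
    for (gid in names(genes)) {
        gene <- genes[[gid]]
        prim <- primaryTranscript(gene)
        exons <- targetExonSequences(gene, geneModelSet, chromStr = chromStr)
        rows <- lapply(seq_len(nrow(exons)), function(i) {
            cand <- scanPams(exons$sequence[i], exons$chrom[i],
                             exons$start[i], exons$end[i], exons$strand[i])
            if (nrow(cand)) cand$tier <- exons$tier[i]
            cand
        })
        cand <- do.call(rbind, rows[vapply(rows, nrow, integer(1)) > 0])
        if (is.null(cand) || nrow(cand) == 0L) {
            candList[[gid]] <- NULL
            next
        }
        cand$gene_id <- gid
        cand$gc_fraction <- gcContent(cand$protospacer)
        cand$peptide_remaining_pct <- peptideRemaining(cand$start, cand$end,
                                                       cand$strand, prim)
        disruption <- ifelse(cand$strand == "+", cand$end, cand$start)
        cand$cds_pos <- cdsOffsetOrNA(disruption, prim)
        candList[[gid]] <- cand
    }
    allCand <- do.call(rbind, candList)
    if (is.null(allCand) || nrow(allCand) == 0L)
        stop("no guide candidates found in any gene")
    uniqProto <- unique(allCand$protospacer)
    uScore <- specificityScores(uniqProto, geneModelSet@genome,
                                external = externalScores,
                                maxMismatch = maxMismatch)
    names(uScore) <- uniqProto

    used <- character()
    selRows <- list()
    flagRows <- list()
    for (gid in names(genes)) {
        cand <- candList[[gid]]
        selectedDesigned <- NULL
        if (!is.null(cand) && nrow(cand)) {
            cand$specificity_score <- unname(uScore[cand$protospacer])
            sel <- selectGuides(cand, params, excludeProtospacers = used)
            selectedDesigned <- sel$selected
            flags <- sel$flags
        } else {
            flags <- list(unreachable = TRUE, all_threshold_met = FALSE,
                          backup_used = FALSE, nonoverlap_met = FALSE,
                          used_fallback = FALSE)
        }
        nDes <- if (is.null(selectedDesigned)) 0L else nrow(selectedDesigned)
        if (nDes) used <- c(used, selectedDesigned$protospacer)

        ext <- externalGuides[externalGuides$gene_id == gid, , drop = FALSE]
        selSpans <- if (nDes) selectedDesigned[, c("chrom", "start", "end",
                                                   "protospacer")]
                    else data.frame(chrom = character(), start = integer(),
                                    end = integer(), protospacer = character())
        imp <- importExternalGuides(ext, selSpans, params,
                                    excludeProtospacers = used)
        nImp <- nrow(imp$imported)
        if (nImp) used <- c(used, imp$imported$protospacer)

        prim <- primaryTranscript(genes[[gid]])
        mk <- function(df, groups, tier) {
            if (is.null(df) || nrow(df) == 0L) return(NULL)
            data.frame(
                guide_id = sprintf("%s_g%d", gid, groups),
                gene_id = gid, group = as.integer(groups),
                protospacer = df$protospacer, pam = df$pam,
                chrom = as.character(df$chrom), strand = df$strand,
                start = df$start, end = df$end,
                cut_site = guideCutSite(df$start, df$end, df$strand),
                gc_fraction = gcContent(df$protospacer),
                specificity_score = if ("specificity_score" %in% names(df))
                    df$specificity_score else NA_real_,
                predicted_activity = if ("predicted_activity" %in% names(df))
                    df$predicted_activity else NA_real_,
                peptide_remaining_pct = peptideRemaining(df$start, df$end,
                                                         df$strand, prim),
                tier = tier, stringsAsFactors = FALSE)
        }
        desRow <- if (nDes) mk(selectedDesigned,
                               selectedDesigned$group,
                               selectedDesigned$tier) else NULL
        impRow <- if (nImp) mk(imp$imported,
                               params@nDesignedPerGene + seq_len(nImp),
                               "imported") else NULL
        selRows[[gid]] <- rbind(desRow, impRow)
        flagRows[[gid]] <- data.frame(
            gene_id = gid, n_designed = nDes, n_imported = nImp,
            unreachable = flags$unreachable,
            all_threshold_met = flags$all_threshold_met,
            backup_used = flags$backup_used,
            nonoverlap_met = flags$nonoverlap_met,
            used_fallback = flags$used_fallback,
            under_covered = imp$underCovered || nDes < params@nDesignedPerGene,
            stringsAsFactors = FALSE)
    }
    guides <- do.call(rbind, selRows)
    rownames(guides) <- NULL
    if (!is.null(predictedActivity) && nrow(predictedActivity)) {
        idx <- match(guides$protospacer, predictedActivity$protospacer)
        hit <- !is.na(idx) & is.na(guides$predicted_activity)
        guides$predicted_activity[hit] <- predictedActivity$activity[idx[hit]]
    }
    if (anyDuplicated(guides$protospacer))
        stop("internal error: duplicate protospacers in library")
    new("GuideSet", guides = DataFrame(guides),
        geneFlags = DataFrame(do.call(rbind, flagRows)),
        params = params,
        diagnostics = summarizeLibrary(guides, params))
}

#' Attach externally predicted activity scores to a designed library
#'
#' @param guideSet a \linkS4class{GuideSet}.
#' @param predictedActivity data.frame with columns protospacer, activity.
#' @return The updated \linkS4class{GuideSet} with refreshed diagnostics.
#' @export
attachPredictedActivity <- function(guideSet, predictedActivity) {
    g <- as.data.frame(guideSet@guides)
    idx <- match(g$protospacer, predictedActivity$protospacer)
    hit <- !is.na(idx)
    g$predicted_activity[hit] <- predictedActivity$activity[idx[hit]]
    initialize(guideSet, guides = DataFrame(g),
               diagnostics = summarizeLibrary(g, guideSet@params))
}
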