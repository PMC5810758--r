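#' Read target-enrichment alignments from SAM or BAM
#'
#' SAM input is converted on the fly with \code{\link[Rsamtools]{asBam}}.
#' Pairing, duplicate and unmapped status are taken from the SAM flag
#' field, as set by the upstream aligner and duplicate marker.
#'
#' @param path SAM or BAM file.
#' @return data.frame: read_id, chrom, pos, mapq, cigar, proper_pair,
#'   duplicate, unmapped.
#' @export
readTargetAlignments <- function(path) {
    stopifnot(file.exists(path))
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
        dest <- tempfile()
        path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                                 indexDestination = FALSE)
    }
    res <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar")))[[1]]
    flag <- res$flag
    data.frame(read_id = res$qname,
               chrom = as.character(res$rname),
               pos = res$pos,
               mapq = res$mapq,
               cigar = res$cigar,
               proper_pair = bitwAnd(flag, 2L) > 0L,
               duplicate = bitwAnd(flag, 1024L) > 0L,
               unmapped = bitwAnd(flag, 4L) > 0L,
               stringsAsFactors = FALSE)
}

#' Retain reads informative for in/del calling
#'
#' Applies the read-classification rule of the two-phase alignment
#' strategy, collapsed onto a single indel-permissive alignment: reads
#' aligned in a proper pair whose CIGAR contains no insertion or deletion
#' are unedited (or correctly repaired) molecules and are discarded; of
#' the remainder, duplicates and reads below the mapping-quality cutoff
#' are filtered. Unmapped records are skipped and counted.
#'
#' @param alignments data.frame from \code{\link{readTargetAlignments}}.
#' @param mapqMin minimum mapping quality retained (default 38; a read at
#'   exactly 38 is kept, 37 is dropped).
#' @return The retained rows, with a \code{"stats"} attribute tallying
#'   each discard reason.
#' @export
classifyReads <- function(alignments, mapqMin = 38L) {
    a <- alignments
    unmapped <- a$unmapped | is.na(a$pos) | is.na(a$cigar)
    a <- a[!unmapped, , drop = FALSE]
    gapless <- !grepl("[ID]", a$cigar)
    properGapless <- a$proper_pair & gapless
    a <- a[!properGapless, , drop = FALSE]
    dup <- a$duplicate
    lowq <- a$mapq < mapqMin
    keep <- a[!(dup | lowq), , drop = FALSE]
    attr(keep, "stats") <- list(n_unmapped = sum(unmapped),
                                n_proper_gapless = sum(properGapless),
                                n_duplicate = sum(dup & !lowq),
                                n_low_mapq = sum(lowq),
                                n_retained = nrow(keep))
    keep
}

#' Extract in/del events from CIGAR strings
#'
#' Walks each read's CIGAR along the reference: M, =, X, D and N advance
#' the reference position (N as a skip, emitting nothing); S, H and P
#' consume no reference. Each I op yields an insertion positioned at the
#' base immediately left of the inserted sequence; each D op yields a
#' deletion positioned at its first deleted base.
#'
#' @param alignments data.frame with read_id, chrom, pos, cigar (typically
#'   the output of \code{\link{classifyReads}}).
#' @param maxLength events longer than this are dropped (default 2000 bp,
#'   the indel-permissive alignment cap).
#' @return data.frame: read_id, chrom, type ("insertion"/"deletion"),
#'   position, length.
#' @examples
#' aln <- data.frame(read_id = "r1", chrom = "chr1", pos = 100,
#'                   cigar = "10M2I8M")
#' extractIndels(aln)  # insertion, length 2, position 109
#' @export
extractIndels <- function(alignments, maxLength = 2000L) {
    a <- alignments
    empty <- data.frame(read_id = character(), chrom = character(),
                        type = character(), position = integer(),
                        length = integer(), stringsAsFactors = FALSE)
    if (nrow(a) == 0L) return(empty)
    bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", a$cigar)
    if (any(bad))
        stop("malformed CIGAR for read(s): ",
             paste(utils::head(a$read_id[bad], 5), collapse = ", "))
    opsL <- GenomicAlignments::explodeCigarOps(a$cigar)
    lenL <- GenomicAlignments::explodeCigarOpLengths(a$cigar)
    out <- vector("list", nrow(a))
    for (i in seq_len(nrow(a))) {
        ops <- opsL[[i]]
        lens <- lenL[[i]]
        refpos <- a$pos[i]
        types <- character(); posv <- integer(); lenv <- integer()
        for (j in seq_along(ops)) {
            op <- ops[j]; l <- lens[j]
            if (op == "I") {
                types <- c(types, "insertion")
                posv <- c(posv, refpos - 1L)
                lenv <- c(lenv, l)
            } else if (op == "D") {
                types <- c(types, "deletion")
                posv <- c(posv, refpos)
                lenv <- c(lenv, l)
                refpos <- refpos + l
            } else if (op %in% c("M", "=", "X", "N")) {
                refpos <- refpos + l
            }
        }
        if (length(types))
            out[[i]] <- data.frame(read_id = a$read_id[i], chrom = a$chrom[i],
                                   type = types, position = posv,
                                   length = lenv, stringsAsFactors = FALSE)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) return(empty)
    ev <- do.call(rbind, out)
    ev <- ev[ev$length <= maxLength, , drop = FALSE]
    rownames(ev) <- NULL
    ev
}

#' Target sites and their cleavage-window intervals
#'
#' The validity window spans the two scission-flanking bases plus
#' \code{flank} nt on each side (6 bp for the default flank of 2). With
#' the reported cleavage coordinate on the PAM-proximal side of the cut,
#' this is [cut - 2, cut + 3] for a plus-strand guide and
#' [cut - 3, cut + 2] for a minus-strand guide; unknown strand falls back
#' to the plus formula.
#'
#' @param guideSet a \linkS4class{GuideSet}, or a data.frame with
#'   guide_id, gene_id, chrom, cut_site and optionally strand and group.
#' @param flank nt tolerated on each side of the scission (default 2).
#' @return data.frame: guide_id, gene_id, group, chrom, strand, cut_site,
#'   window_start, window_end.
#' @export
targetSites <- function(guideSet, flank = 2L) {
    g <- if (is(guideSet, "GuideSet")) as.data.frame(guideSet@guides)
         else as.data.frame(guideSet)
    strand <- if ("strand" %in% names(g)) g$strand else rep("+", nrow(g))
    ws <- ifelse(strand == "-", g$cut_site - flank - 1L, g$cut_site - flank)
    we <- ifelse(strand == "-", g$cut_site + flank, g$cut_site + flank + 1L)
    data.frame(guide_id = g$guide_id,
               gene_id = if ("gene_id" %in% names(g)) g$gene_id else NA,
               group = if ("group" %in% names(g)) g$group else NA,
               chrom = g$chrom, strand = strand, cut_site = g$cut_site,
               window_start = as.integer(ws), window_end = as.integer(we),
               stringsAsFactors = FALSE)
}

#' Keep in/del events valid for their target site
#'
#' An insertion is valid when its position lies inside the site's window;
#' a deletion when its deleted span intersects the window. Events are
#' checked against every site and returned annotated with the matching
#' guide_id (an event validating several sites appears once per site).
#'
#' @param events data.frame from \code{\link{extractIndels}}.
#' @param sites data.frame from \code{\link{targetSites}} (one or more rows).
#' @return The valid events with a guide_id column.
#' @export
windowFilter <- function(events, sites) {
    out <- vector("list", nrow(sites))
    for (i in seq_len(nrow(sites))) {
        s <- sites[i, ]
        e <- events[events$chrom == s$chrom, , drop = FALSE]
        if (nrow(e) == 0L) next
        ins <- e$type == "insertion" & e$position >= s$window_start &
            e$position <= s$window_end
        del <- e$type == "deletion" & e$position <= s$window_end &
            (e$position + e$length - 1L) >= s$window_start
        e <- e[ins | del, , drop = FALSE]
        if (nrow(e)) {
            e$guide_id <- s$guide_id
            out[[i]] <- e
        }
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) {
        ev <- events[0, , drop = FALSE]
        ev$guide_id <- character()
        return(ev)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Remove events also observed in an untransduced control
#'
#' The control sample is run through the same classification and
#' extraction steps (but not the window filter); any event whose key
#' (chrom, position, type, length) occurs in the control set is removed.
#'
#' @param events data.frame of sample events.
#' @param controlEvents data.frame of control events.
#' @return The surviving events.
#' @export
subtractControl <- function(events, controlEvents) {
    if (nrow(events) == 0L || nrow(controlEvents) == 0L) return(events)
    key <- function(e) paste(e$chrom, e$position, e$type, e$length)
    out <- events[!key(events) %in% key(controlEvents), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Observed Activity Score
#'
#' OAS normalizes the mean valid in/del count across replicates by the
#' guide's percentage representation in the pool:
#' \deqn{OAS = \mu_{ID} / ((sgR / TR) \times 100)}
#' where sgR is the guide's raw pool read count and TR the total pool
#' reads. A guide with a normalized count of 1 (i.e. 1 percent of the
#' pool) therefore has OAS equal to its mean in/del count. Guides not
#' detected in the pool (sgR = 0) get NA.
#'
#' @param muID mean in/del count across replicates (vectorized).
#' @param sgR raw pool reads for the guide.
#' @param TR total pool reads.
#' @return Numeric OAS values.
#' @examples
#' computeOAS(50, 1000, 100000)  # 50
#' computeOAS(10, 2000, 100000)  # 5
#' @export
computeOAS <- function(muID, sgR, TR) {
    stopifnot(all(TR > 0))
    ifelse(sgR > 0, muID / ((sgR / TR) * 100), NA_real_)
}

#' Kendall rank correlation (tau-b)
#'
#' Tau-b with tie correction, as implemented by
#' \code{\link[stats]{cor}(method = "kendall")}; NA pairs are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @return tau-b, or NA when fewer than 2 complete pairs remain.
#' @export
kendallTauB <- function(x, y) {
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 2L) return(NA_real_)
    suppressWarnings(stats::cor(x[ok], y[ok], method = "kendall"))
}

#' Score editing activity of a guide pool
#'
#' End-to-end in/del quantification: every replicate alignment file is
#' classified and its in/dels extracted; events are restricted to each
#' guide's cleavage window, events also present in the untransduced
#' control (classified and extracted identically, no window filter) are
#' subtracted, counts are averaged across replicates, and the OAS is
#' computed from the guide's pool representation.
#'
#' @param editedPaths character vector of SAM/BAM files, one per replicate.
#' @param controlPath SAM/BAM of the untransduced control.
#' @param sites data.frame from \code{\link{targetSites}}.
#' @param poolCounts a \linkS4class{GuideCounts} for the pool (or a
#'   data.frame with guide_id and raw_reads).
#' @param mapqMin mapping-quality cutoff (default 38).
#' @param predicted optional data.frame (guide_id, activity) of externally
#'   predicted activity for the summary correlation.
#' @return An \linkS4class{ActivitySet}.
#' @export
scoreActivity <- function(editedPaths, controlPath, sites, poolCounts,
                          mapqMin = 38L, predicted = NULL) {
    controlEvents <- extractIndels(classifyReads(
        readTargetAlignments(controlPath), mapqMin = mapqMin))
    repCounts <- matrix(0L, nrow = nrow(sites), ncol = length(editedPaths),
                        dimnames = list(sites$guide_id,
                                        paste0("rep", seq_along(editedPaths))))
    for (r in seq_along(editedPaths)) {
        ev <- extractIndels(classifyReads(
            readTargetAlignments(editedPaths[r]), mapqMin = mapqMin))
        valid <- windowFilter(ev, sites)
        valid <- subtractControl(valid, controlEvents)
        if (nrow(valid)) {
            tb <- table(factor(valid$guide_id, levels = sites$guide_id))
            repCounts[, r] <- as.integer(tb)
        }
    }
    muID <- rowMeans(repCounts)
    pc <- if (is(poolCounts, "GuideCounts")) as.data.frame(poolCounts@counts)
          else as.data.frame(poolCounts)
    sgR <- pc$raw_reads[match(sites$guide_id, pc$guide_id)]
    sgR[is.na(sgR)] <- 0L
    TR <- sum(pc$raw_reads)
    oas <- computeOAS(muID, sgR, TR)
    rec <- data.frame(guide_id = sites$guide_id, gene_id = sites$gene_id,
                      group = sites$group, stringsAsFactors = FALSE)
    for (r in seq_len(ncol(repCounts)))
        rec[[paste0("indels_rep", r)]] <- repCounts[, r]
    rec$mu_id <- muID
    rec$sg_reads <- sgR
    rec$total_reads <- TR
    rec$normalized_count <- 100 * sgR / TR
    rec$oas <- oas
    rec$detected_in_pool <- sgR > 0
    rec$active <- rec$detected_in_pool & muID > 0
    rec$predicted_activity <- if (!is.null(predicted))
        predicted$activity[match(rec$guide_id, predicted$guide_id)]
        else NA_real_
    aset <- new("ActivitySet", records = DataFrame(rec), summary = list())
    aset@summary <- activitySummary(aset)
    aset
}

#' Summarize editing activity per guide group
#'
#' Per group: the percentage of active guides among guides detected in the
#' pool (the denominator the screen can actually assess). Overall: the
#' percentage of genes (with at least one pool-detected guide) edited by
#' at least one active guide, and the Kendall tau-b between OAS and
#' externally predicted activity over guides carrying both values.
#'
#' @param activitySet an \linkS4class{ActivitySet}.
#' @return list with per_group data.frame, pct_genes_edited, kendall_tau_b.
#' @export
activitySummary <- function(activitySet) {
    r <- as.data.frame(activitySet@records)
    det <- r[r$detected_in_pool, , drop = FALSE]
    perGroup <- do.call(rbind, lapply(split(det, det$group), function(d) {
        data.frame(group = d$group[1], n_detected = nrow(d),
                   n_active = sum(d$active),
                   pct_active = 100 * mean(d$active))
    }))
    rownames(perGroup) <- NULL
    geneActive <- tapply(det$active, det$gene_id, any)
    tau <- kendallTauB(det$oas, det$predicted_activity)
    list(per_group = perGroup,
         pct_active_overall = if (nrow(det)) 100 * mean(det$active)
                              else NA_real_,
         pct_genes_edited = if (length(geneActive))
             100 * mean(geneActive) else NA_real_,
         kendall_tau_b = tau)
}
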