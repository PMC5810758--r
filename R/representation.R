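#' Count sgRNA reads from pooled-library amplicon sequencing
#'
#' Each read is assigned to the single guide whose 20-nt protospacer it
#' contains exactly. With \code{offset} set, the protospacer is read at a
#' fixed position (constant-flank trimming of a defined amplicon); without
#' it, reads are scanned for any protospacer occurrence. Reads matching no
#' guide are tallied as unassigned, reads matching two or more distinct
#' guides as ambiguous; neither contributes to counts.
#'
#' @param reads a \link[Biostrings]{DNAStringSet} or path to a FASTQ file
#'   (optionally gzipped).
#' @param guideSet a \linkS4class{GuideSet}, or a data.frame/DataFrame with
#'   guide_id, gene_id and protospacer columns.
#' @param offset optional 1-based position of the protospacer within each
#'   read (exact-position mode).
#' @return A \linkS4class{GuideCounts}. normalized_count is
#'   100 x raw / total assigned reads; fold_from_mean is raw over the mean
#'   raw count across all library guides (zeros included).
#' @examples
#' reads <- Biostrings::DNAStringSet(c("AAACCCGGGTTTAAACCCGG"))
#' @export
countGuides <- function(reads, guideSet, offset = NULL) {
    if (is.character(reads))
        reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
    g <- if (is(guideSet, "GuideSet")) as.data.frame(guideSet@guides)
         else as.data.frame(guideSet)
    if (anyDuplicated(g$protospacer))
        stop("guide protospacers must be unique")
    n <- length(reads)
    raw <- integer(nrow(g))
    unassigned <- 0L
    ambiguous <- 0L
    if (n > 0L) {
        if (!is.null(offset)) {
            ok <- Biostrings::width(reads) >= offset + 19L
            sub <- as.character(Biostrings::subseq(reads[ok], offset,
                                                   offset + 19L))
            idx <- match(sub, g$protospacer)
            unassigned <- sum(is.na(idx)) + sum(!ok)
            raw <- tabulate(idx, nbins = nrow(g))
        } else {
            pd <- Biostrings::PDict(g$protospacer)
            hits <- Biostrings::vwhichPDict(pd, reads)
            nh <- lengths(hits)
            uh <- vapply(hits, function(h) length(unique(h)), integer(1))
            unassigned <- sum(nh == 0L)
            ambiguous <- sum(uh >= 2L)
            one <- uh == 1L
            raw <- tabulate(vapply(hits[one], `[`, integer(1), 1L),
                            nbins = nrow(g))
        }
    }
    total <- sum(raw)
    normalized <- if (total > 0) 100 * raw / total else rep(NA_real_, nrow(g))
    fold <- if (mean(raw) > 0) raw / mean(raw) else rep(NA_real_, nrow(g))
    cc <- DataFrame(guide_id = g$guide_id, gene_id = g$gene_id,
                    raw_reads = raw, normalized_count = normalized,
                    fold_from_mean = fold, detected = raw > 0L)
    new("GuideCounts", counts = cc, totalReads = as.integer(n),
        unassigned = as.integer(unassigned), ambiguous = as.integer(ambiguous))
}

#' Representation diagnostics of a counted pool
#'
#' Summarizes how evenly the library is represented: the percentage of
#' guides detected at all, the percentage of detected guides within a fold
#' band around the mean (default 0.5-2x, i.e. less than 2-fold away from
#' the mean in either direction), undetected guides, strong outliers, and per-gene
#' coverage (how many genes retain at least \code{minGuidesPerGene}
#' detected guides).
#'
#' @param guideCounts a \linkS4class{GuideCounts}.
#' @param foldBand numeric(2) open interval for the fold-from-mean band.
#' @param outlierFold guides at or above this fold-from-mean are listed as
#'   outliers (default 10).
#' @param minGuidesPerGene per-gene coverage threshold (default 4).
#' @return A list of summary statistics.
#' @export
representationStats <- function(guideCounts, foldBand = c(0.5, 2),
                                outlierFold = 10, minGuidesPerGene = 4L) {
    cc <- as.data.frame(guideCounts@counts)
    if (nrow(cc) == 0L) stop("empty count table")
    det <- cc$detected
    inBand <- det & cc$fold_from_mean > foldBand[1] &
        cc$fold_from_mean < foldBand[2]
    perGene <- tapply(det, cc$gene_id, sum)
    list(
        n_guides = nrow(cc),
        pct_detected = 100 * mean(det),
        pct_detected_in_band = if (any(det)) 100 * sum(inBand) / sum(det)
                               else NA_real_,
        undetected = cc$guide_id[!det],
        outliers = cc$guide_id[det & cc$fold_from_mean >= outlierFold],
        genes_detected_hist = table(perGene),
        pct_genes_min_guides = 100 * mean(perGene >= minGuidesPerGene),
        reads_assigned = sum(cc$raw_reads),
        reads_unassigned = guideCounts@unassigned,
        reads_ambiguous = guideCounts@ambiguous)
}
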