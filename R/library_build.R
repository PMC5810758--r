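#' Golden-Gate cloning oligos for each guide
#'
#' Forward oligo = forward overhang + protospacer; reverse oligo = reverse
#' overhang + reverse complement of the protospacer, so the annealed duplex
#' core is a perfect 20-bp duplex with single-stranded vector-compatible
#' overhangs. No 5' G is added here: the expression vector supplies it
#' during cloning.
#'
#' @param guideSet a \linkS4class{GuideSet} (or data.frame with guide_id
#'   and protospacer).
#' @param overhangs named character(2): \code{forward} and \code{reverse}
#'   5' overhangs. The defaults are the common U6/BsmBI pair and are a
#'   configurable assumption, not a published value.
#' @return DataFrame: guide_id, forward_oligo, reverse_oligo.
#' @export
makeOligos <- function(guideSet,
                       overhangs = c(forward = "ACCG", reverse = "AAAC")) {
    if (is.null(overhangs) || length(overhangs) != 2L ||
        any(!nzchar(overhangs)) || anyNA(overhangs))
        stop("vector overhangs must be two non-empty sequences")
    g <- if (is(guideSet, "GuideSet")) as.data.frame(guideSet@guides)
         else as.data.frame(guideSet)
    DataFrame(guide_id = g$guide_id,
              forward_oligo = paste0(overhangs[["forward"]], g$protospacer),
              reverse_oligo = paste0(overhangs[["reverse"]],
                                     revcompChr(g$protospacer)))
}

wellGrid <- function(n, rows = 8L, cols = 12L) {
    per <- rows * cols
    j <- seq_len(n) - 1L
    plate <- j %/% per + 1L
    k <- j %% per
    col <- k %/% rows + 1L
    row <- LETTERS[k %% rows + 1L]
    DataFrame(plate = plate, row = row, column = col,
              well = paste0(row, col))
}

#' Arrayed 96-well layout of a guide library
#'
#' Guides are placed in their table order (genes in design order, groups
#' 1-7 within a gene), filling each plate column-major (A1, B1, ..., H1,
#' A2, ...) before opening the next; the plate count is
#' \code{ceiling(n / 96)}.
#'
#' @param guideSet a \linkS4class{GuideSet} or a character vector of ids.
#' @return A \linkS4class{PlateLayout}.
#' @export
plateLayout <- function(guideSet) {
    ids <- if (is(guideSet, "GuideSet")) guideSet@guides$guide_id
           else as.character(guideSet)
    grid <- wellGrid(length(ids))
    a <- DataFrame(guide_id = ids, grid)
    new("PlateLayout", assignments = a,
        nPlates = if (length(ids)) max(grid$plate) else 0L)
}

#' Derived pools of an arrayed library
#'
#' Builds the whole-library pool, one pool per gene (arrayed into 96-well
#' plates, one gene per well) and one pool per guide group k in 5, 6, 7,
#' each holding the group-k guide of every gene that has one. Genes
#' lacking a group-k guide are omitted from pool k and logged.
#'
#' @param guideSet a \linkS4class{GuideSet}.
#' @param groupPools integer groups pooled one-guide-per-gene (default 5:7).
#' @return A \linkS4class{PoolSet}.
#' @export
buildPools <- function(guideSet, groupPools = 5:7) {
    g <- as.data.frame(guideSet@guides)
    geneOrder <- unique(g$gene_id)
    gOrd <- g[order(match(g$gene_id, geneOrder)), , drop = FALSE]
    pools <- list(
        DataFrame(pool_id = "whole", pool_kind = "whole",
                  guide_id = g$guide_id, gene_id = g$gene_id),
        DataFrame(pool_id = paste0("gene:", gOrd$gene_id),
                  pool_kind = "gene", guide_id = gOrd$guide_id,
                  gene_id = gOrd$gene_id))
    dropped <- list()
    for (k in groupPools) {
        sel <- g$group == k
        pools[[length(pools) + 1L]] <-
            DataFrame(pool_id = paste0("group:", k), pool_kind = "group",
                      guide_id = g$guide_id[sel], gene_id = g$gene_id[sel])
        missing <- setdiff(geneOrder, g$gene_id[sel])
        if (length(missing))
            dropped[[length(dropped) + 1L]] <-
                DataFrame(pool_id = paste0("group:", k), gene_id = missing)
    }
    genePoolGrid <- wellGrid(length(geneOrder))
    genePoolLayout <- new("PlateLayout",
                          assignments = DataFrame(guide_id = geneOrder,
                                                  genePoolGrid),
                          nPlates = if (length(geneOrder))
                              max(genePoolGrid$plate) else 0L)
    new("PoolSet", pools = do.call(rbind, pools),
        genePoolLayout = genePoolLayout,
        dropped = if (length(dropped)) do.call(rbind, dropped)
                  else DataFrame(pool_id = character(), gene_id = character()))
}

#' Capture-probe regions around target sites
#'
#' Emits one 2,000 bp interval per target site, centered on the cleavage
#' site (1,000 bp upstream, 999 bp downstream under the 1-based closed
#' convention). When two or more target sites fall in the same CDS exon of
#' the gene's primary transcript, a single interval centered on the exon
#' midpoint (floor of the interval mean) replaces them. Intervals are
#' clipped at position 1 and returned sorted.
#'
#' @param guideSet a \linkS4class{GuideSet}.
#' @param geneModelSet the matching \linkS4class{GeneModelSet}.
#' @param regionWidth total width in bp (default 2000).
#' @return list(regions = sorted \link[GenomicRanges]{GRanges} with mcols
#'   region_id and n_sites, assignment = DataFrame mapping guide_id to
#'   region_id).
#' @export
probeRegions <- function(guideSet, geneModelSet, regionWidth = 2000L) {
    g <- as.data.frame(guideSet@guides)
    up <- regionWidth %/% 2L          # 1000 upstream of the centre base
    down <- regionWidth - up - 1L     # 999 downstream
    key <- character(nrow(g))
    center <- integer(nrow(g))
    exonMid <- rep(NA_integer_, nrow(g))
    for (i in seq_len(nrow(g))) {
        prim <- primaryTranscript(geneModelSet@genes[[g$gene_id[i]]])
        exons <- prim@cds
        hit <- which(as.character(GenomicRanges::seqnames(exons)) == g$chrom[i] &
                     GenomicRanges::start(exons) <= g$cut_site[i] &
                     GenomicRanges::end(exons) >= g$cut_site[i])
        if (length(hit) == 1L) {
            key[i] <- paste0(g$gene_id[i], ":exon:",
                             GenomicRanges::start(exons)[hit], "-",
                             GenomicRanges::end(exons)[hit])
            exonMid[i] <- (GenomicRanges::start(exons)[hit] +
                           GenomicRanges::end(exons)[hit]) %/% 2L
        } else {
            key[i] <- paste0("site:", g$guide_id[i])
        }
        center[i] <- g$cut_site[i]
    }
    regRows <- list()
    assign <- list()
    for (k in unique(key)) {
        idx <- which(key == k)
        ctr <- if (length(idx) >= 2L && !is.na(exonMid[idx[1]]))
            exonMid[idx[1]] else center[idx[1]]
        start <- max(1L, ctr - up)
        end <- ctr + down
        rid <- sprintf("region_%03d", length(regRows) + 1L)
        regRows[[rid]] <- data.frame(chrom = g$chrom[idx[1]], start = start,
                                     end = end, region_id = rid,
                                     n_sites = length(idx))
        assign[[rid]] <- DataFrame(guide_id = g$guide_id[idx], region_id = rid)
    }
    rr <- do.call(rbind, regRows)
    gr <- GenomicRanges::GRanges(rr$chrom,
                                 IRanges::IRanges(rr$start, rr$end),
                                 region_id = rr$region_id,
                                 n_sites = rr$n_sites)
    gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
    list(regions = gr, assignment = do.call(rbind, assign))
}

#' Export library artifacts as plain-text files
#'
#' \code{exportLibraryTable} writes the per-guide table as TSV;
#' \code{exportOligoSheets} writes forward and reverse order sheets
#' (plate, well, oligo name, sequence) mirroring a two-sheet plate order;
#' \code{exportProbeBed} writes probe regions as BED (0-based half-open,
#' converted by rtracklayer).
#'
#' @param guideSet,oligos,layout,regions the objects to export.
#' @param path,dir output file or directory.
#' @return The written path(s), invisibly.
#' @name exporters
NULL

#' @rdname exporters
#' @export
exportLibraryTable <- function(guideSet, path) {
    utils::write.table(as.data.frame(guideSet@guides), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname exporters
#' @export
exportOligoSheets <- function(oligos, layout, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    a <- as.data.frame(layout@assignments)
    o <- as.data.frame(oligos)
    m <- merge(a, o, by = "guide_id", sort = FALSE)
    m <- m[order(m$plate, m$column, m$row), ]
    fwd <- data.frame(plate = m$plate, well = m$well,
                      oligo = paste0(m$guide_id, "_F"),
                      sequence = m$forward_oligo)
    rev <- data.frame(plate = m$plate, well = m$well,
                      oligo = paste0(m$guide_id, "_R"),
                      sequence = m$reverse_oligo)
    fp <- file.path(dir, "oligos_forward.tsv")
    rp <- file.path(dir, "oligos_reverse.tsv")
    utils::write.table(fwd, fp, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rev, rp, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fp, rp))
}

#' @rdname exporters
#' @export
exportProbeBed <- function(regions, path) {
    gr <- regions
    names(gr) <- S4Vectors::mcols(gr)$region_id
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}
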