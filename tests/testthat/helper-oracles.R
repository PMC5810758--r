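# Independent oracles and in-code fixtures shared across the suite.

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rcOracle <- function(x) {
    vapply(x, function(s) {
        comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

makeTx <- function(chrom, exons, strand, id = "t1", gene = "g1",
                   primary = TRUE) {
    gr <- GenomicRanges::GRanges(
        chrom, IRanges::IRanges(vapply(exons, `[`, numeric(1), 1),
                                vapply(exons, `[`, numeric(1), 2)),
        strand = strand)
    if (strand == "-") gr <- gr[order(GenomicRanges::start(gr),
                                      decreasing = TRUE)]
    len <- sum(GenomicRanges::width(gr))
    new("TranscriptModel", transcriptId = id, geneId = gene, strand = strand,
        cds = gr, primary = primary, frameOK = (len %% 3L) == 0L)
}

makeGene <- function(transcripts, gene = "g1") {
    new("GeneModel", geneId = gene, symbol = gene, category = "test",
        transcripts = transcripts)
}

makeGms <- function(genes, genomeSeqs) {
    new("GeneModelSet", genes = genes,
        genome = Biostrings::DNAStringSet(genomeSeqs))
}

# Brute-force near-match NGG site counter (character comparison, both
# strands), independent of the compiled scanner.
bruteOffTargets <- function(proto, genomeSeqs, maxMM = 3L) {
    countIn <- function(text, pat) {
        hits <- 0L
        n <- nchar(text)
        for (i in seq_len(max(0L, n - 22L))) {
            if (substr(text, i + 21L, i + 22L) != "GG") next
            w <- strsplit(substr(text, i, i + 19L), "")[[1]]
            p <- strsplit(pat, "")[[1]]
            if (sum(w != p) <= maxMM) hits <- hits + 1L
        }
        hits
    }
    total <- 0L
    for (chromSeq in genomeSeqs)
        total <- total + countIn(chromSeq, proto) +
            countIn(rcOracle(chromSeq), proto)
    max(0L, total - 1L)
}

# Independent CIGAR walk used as the extraction oracle: tokenizes with
# regmatches and re-derives reference spans from scratch.
indelWalkOracle <- function(pos, cigar, chrom = "chr1", read_id = "r") {
    toks <- regmatches(cigar, gregexpr("[0-9]+[A-Z=]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]", "", toks))
    ops <- sub("[0-9]+", "", toks)
    ref <- pos
    out <- list()
    for (j in seq_along(ops)) {
        if (ops[j] == "I") {
            out[[length(out) + 1L]] <- data.frame(
                read_id = read_id, chrom = chrom, type = "insertion",
                position = ref - 1L, length = lens[j],
                stringsAsFactors = FALSE)
        } else if (ops[j] == "D") {
            out[[length(out) + 1L]] <- data.frame(
                read_id = read_id, chrom = chrom, type = "deletion",
                position = ref, length = lens[j], stringsAsFactors = FALSE)
            ref <- ref + lens[j]
        } else if (ops[j] %in% c("M", "=", "X", "N")) {
            ref <- ref + lens[j]
        }
    }
    if (length(out)) do.call(rbind, out) else NULL
}

# random plausible CIGAR: alternating matched blocks and indel/clip ops
randomCigar <- function() {
    parts <- sprintf("%dM", sample(5:60, 1))
    nOps <- sample(0:3, 1)
    for (k in seq_len(nOps)) {
        op <- sample(c("I", "D", "N", "X", "="), 1)
        parts <- c(parts, sprintf("%d%s", sample(1:15, 1), op),
                   sprintf("%dM", sample(5:60, 1)))
    }
    if (runif(1) < 0.3) parts <- c(sprintf("%dS", sample(1:10, 1)), parts)
    if (runif(1) < 0.3) parts <- c(parts, sprintf("%dS", sample(1:10, 1)))
    paste(parts, collapse = "")
}

# all-pairs Kendall tau-b with tie correction
tauBOracle <- function(x, y) {
    n <- length(x)
    nc <- 0L; nd <- 0L; tx <- 0L; ty <- 0L
    for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
            dx <- x[j] - x[i]; dy <- y[j] - y[i]
            if (dx == 0 && dy == 0) { tx <- tx + 1L; ty <- ty + 1L }
            else if (dx == 0) tx <- tx + 1L
            else if (dy == 0) ty <- ty + 1L
            else if (sign(dx) == sign(dy)) nc <- nc + 1L
            else nd <- nd + 1L
        }
    }
    n0 <- n * (n - 1) / 2
    (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

writeSamFile <- function(records, path, chroms = c(chr1 = 100000L)) {
    header <- c("@HD\tVN:1.6",
                sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), chroms))
    body <- vapply(records, function(r) {
        seqlen <- sum(as.integer(
            sub("[A-Z=]", "", regmatches(r$cigar,
                gregexpr("[0-9]+[MIS=X]", r$cigar))[[1]])))
        seq <- strrep("A", max(1L, seqlen))
        sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                r$qname, r$flag, r$chrom, r$pos, r$mapq, r$cigar, seq,
                strrep("I", nchar(seq)))
    }, character(1))
    writeLines(c(header, body), path)
    path
}

# candidate-table row builder for selection-policy fixtures
candRow <- function(proto, start, score, tier = "shared", strand = "+",
                    chrom = "chr1", cdsPos = start) {
    data.frame(protospacer = proto, pam = "AGG", chrom = chrom,
               strand = strand, start = start, end = start + 19L,
               cut_site = start + 16L, tier = tier,
               gc_fraction = 0.5, specificity_score = score,
               cds_pos = cdsPos, peptide_remaining_pct = 50,
               stringsAsFactors = FALSE)
}

# distinct dummy 20-mers: AAA...A with a base-4 index-encoding suffix
proto20 <- function(i) {
    l <- c("A", "C", "G", "T")
    d <- character(10)
    for (k in 1:10) { d[k] <- l[i %% 4 + 1]; i <- i %/% 4 }
    paste0(strrep("A", 10), paste(d, collapse = ""))
}
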