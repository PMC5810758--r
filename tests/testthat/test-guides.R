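test_that("scanPams finds every NGG site on both strands", {
    ## single plus-strand PAM
    one <- scanPams(paste0(strrep("A", 20), "TGG"), "chr1", 1001, 1023, "+")
    expect_identical(nrow(one), 1L)
    expect_identical(one$strand, "+")
    expect_identical(one$protospacer, strrep("A", 20))
    expect_identical(one$pam, "TGG")
    expect_identical(one$start, 1001L)
    expect_identical(one$end, 1020L)

    ## no GG or CC dinucleotide anywhere
    none <- scanPams(paste(rep("AT", 15), collapse = ""), "chr1", 1, 30, "+")
    expect_identical(nrow(none), 0L)
})

test_that("scanPams candidate count and coordinates match a brute-force scan", {
    set.seed(7)
    for (k in 1:5) {
        s <- randomDna(250)
        cand <- scanPams(s, "chr1", 501, 750, "+")
        ## brute force: slide over every 23-mer window on each strand
        expPlus <- 0L; expMinus <- 0L
        for (i in 1:(nchar(s) - 22)) {
            w <- substr(s, i, i + 22)
            if (substr(w, 22, 23) == "GG") expPlus <- expPlus + 1L
            if (substr(w, 1, 2) == "CC") expMinus <- expMinus + 1L
        }
        expect_identical(sum(cand$strand == "+"), expPlus)
        expect_identical(sum(cand$strand == "-"), expMinus)
        ## every candidate's protospacer is the genome text of its span,
        ## in guide orientation
        for (j in seq_len(nrow(cand))) {
            txt <- substr(s, cand$start[j] - 500, cand$end[j] - 500)
            expect_identical(cand$protospacer[j],
                             if (cand$strand[j] == "+") txt else rcOracle(txt))
        }
    }
})

test_that("candidates containing N are dropped and tallied", {
    s <- paste0(strrep("A", 10), "N", strrep("A", 9), "TGG")
    out <- scanPams(s, "chr1", 1, nchar(s), "+")
    expect_identical(nrow(out), 0L)
    expect_identical(attr(out, "nDropped"), 1L)
})

test_that("gcContent is the G+C fraction", {
    expect_equal(gcContent("ATATATATATATATATATAT"), 0)
    expect_equal(gcContent("GCGCGCGCGCGCGCGCGCGC"), 1)
    expect_equal(gcContent(paste0(strrep("G", 10), strrep("A", 10))), 0.5)
})

test_that("cleavage site is 6 nt upstream of the guide+PAM end", {
    expect_identical(guideCutSite(101L, 120L, "+"), 117L)
    expect_identical(guideCutSite(121L, 140L, "-"), 124L)
    ## always strictly inside the protospacer span
    set.seed(3)
    cand <- scanPams(randomDna(200), "chr1", 1, 200, "+")
    expect_true(all(cand$cut_site > cand$start & cand$cut_site < cand$end))
})

test_that("peptideRemaining is the CDS percentile of the disruption point", {
    tx <- makeTx("chr1", list(c(1001, 1300)), "+")
    ## disruption at protospacer end (final nt before PAM)
    expect_equal(peptideRemaining(1011, 1030, "+", tx), 10)
    expect_equal(peptideRemaining(1281, 1300, "+", tx), 100)
    expect_true(is.na(peptideRemaining(2000, 2019, "+", tx)))
    ## non-decreasing along the transcript
    starts <- seq(1001, 1251, by = 10)
    vals <- peptideRemaining(starts, starts + 19, "+", tx)
    expect_true(all(diff(vals) >= 0))
})

test_that("built-in specificity score is 100 for unique guides and drops with duplicates", {
    set.seed(11)
    uniqGenome <- randomDna(3000)
    cand <- scanPams(uniqGenome, "chr1", 1, 3000, "+")
    proto <- cand$protospacer[1]
    g1 <- Biostrings::DNAStringSet(c(chr1 = uniqGenome))
    expect_equal(offTargetCounts(proto, g1), 0L)
    expect_equal(specificityScores(proto, g1), 100)

    ## duplicate the whole site (protospacer + PAM context) elsewhere
    site <- substr(uniqGenome, cand$start[1], cand$end[1] + 3)
    g2 <- Biostrings::DNAStringSet(c(chr1 = paste0(uniqGenome,
                                                   strrep("T", 50), site)))
    expect_gt(offTargetCounts(proto, g2), 0L)
    expect_lt(specificityScores(proto, g2), 100)
})

test_that("off-target counts equal the brute-force character-scan oracle", {
    set.seed(23)
    genome <- c(chr1 = randomDna(1500), chr2 = paste0(randomDna(300), "N",
                                                      randomDna(300)))
    cand <- scanPams(genome[["chr1"]], "chr1", 1, 1500, "+")
    protos <- cand$protospacer[seq(1, nrow(cand), length.out = 12)]
    got <- offTargetCounts(protos, Biostrings::DNAStringSet(genome))
    want <- vapply(protos, bruteOffTargets, integer(1), genomeSeqs = genome)
    expect_identical(as.integer(got), unname(want))
})

test_that("external score tables override the built-in scorer", {
    g <- Biostrings::DNAStringSet(c(chr1 = randomDna(500)))
    p <- strrep("ACGT", 5)
    sc <- specificityScores(p, g, external = data.frame(
        protospacer = p, score = 83, stringsAsFactors = FALSE))
    expect_equal(sc, 83)
})

test_that("unconstrained selection takes the top five by rank", {
    cand <- do.call(rbind, lapply(1:8, function(i)
        candRow(proto20(i), 1000L + 30L * i, 90 - i)))
    sel <- selectGuides(cand, DesignParams())
    expect_identical(nrow(sel$selected), 5L)
    ## rank: all >= 70, so 5' position (ascending cds_pos) wins
    expect_identical(sel$selected$protospacer,
                     vapply(1:5, proto20, character(1)))
    expect_true(sel$flags$all_threshold_met)
    expect_false(sel$flags$backup_used)
    expect_true(sel$flags$nonoverlap_met)
})

test_that("backups in [50, 70) fill the quota and set the backup flag", {
    cand <- rbind(
        do.call(rbind, lapply(1:4, function(i)
            candRow(proto20(i), 1000L + 30L * i, 85))),
        candRow(proto20(5), 1200L, 65),
        candRow(proto20(6), 1300L, 55))
    sel <- selectGuides(cand, DesignParams())
    expect_identical(nrow(sel$selected), 5L)
    expect_identical(sum(sel$selected$specificity_score < 70), 1L)
    ## the better backup is chosen
    expect_true(proto20(5) %in% sel$selected$protospacer)
    expect_false(proto20(6) %in% sel$selected$protospacer)
    expect_true(sel$flags$backup_used)
    expect_false(sel$flags$all_threshold_met)
})

test_that("selection swaps in lower-ranked disjoint guides to honour the non-overlap core", {
    ## four top-ranked candidates all mutually overlapping at one locus,
    ## two disjoint lower-scoring candidates further 3'
    overl <- do.call(rbind, lapply(1:4, function(i)
        candRow(proto20(i), 1000L + 2L * i, 95, cdsPos = 10L + i)))
    disj <- rbind(candRow(proto20(5), 1500L, 75, cdsPos = 500L),
                  candRow(proto20(6), 1600L, 75, cdsPos = 600L))
    sel <- selectGuides(rbind(overl, disj), DesignParams())
    expect_identical(nrow(sel$selected), 5L)
    expect_true(all(c(proto20(5), proto20(6)) %in% sel$selected$protospacer))
    expect_true(sel$flags$nonoverlap_met)
    ## verify a mutually non-overlapping triple really exists in the output
    s <- sel$selected
    triples <- utils::combn(nrow(s), 3)
    anyDisjoint <- any(apply(triples, 2, function(ix) {
        all(utils::combn(ix, 2, function(p)
            s$end[p[1]] < s$start[p[2]] || s$end[p[2]] < s$start[p[1]]))
    }))
    expect_true(anyDisjoint)
})

test_that("genes with no admissible candidate are reported unreachable", {
    cand <- do.call(rbind, lapply(1:4, function(i)
        candRow(proto20(i), 1000L + 30L * i, 40)))
    sel <- selectGuides(cand, DesignParams())
    expect_true(sel$flags$unreachable)
    expect_identical(nrow(sel$selected), 0L)
})

test_that("import honours the 15 bp overlap limit at its boundary", {
    selected <- data.frame(chrom = "chr1", start = 1000L, end = 1019L,
                           protospacer = proto20(99),
                           stringsAsFactors = FALSE)
    extAt <- function(start, i) data.frame(
        gene_id = "g1", protospacer = proto20(i), pam = "TGG",
        chrom = "chr1", start = start, end = start + 19L, strand = "+",
        stringsAsFactors = FALSE)
    p <- DesignParams()
    ## disjoint: accepted
    imp <- importExternalGuides(extAt(2000L, 1), selected, p)
    expect_identical(nrow(imp$imported), 1L)
    ## sharing exactly 15 bp: rejected
    imp15 <- importExternalGuides(extAt(1005L, 2), selected, p)
    expect_identical(nrow(imp15$imported), 0L)
    ## sharing 14 bp: accepted
    imp14 <- importExternalGuides(extAt(1006L, 3), selected, p)
    expect_identical(nrow(imp14$imported), 1L)
    ## empty list: zero imported, under-covered flag
    imp0 <- importExternalGuides(extAt(2000L, 1)[0, ], selected, p)
    expect_identical(nrow(imp0$imported), 0L)
    expect_true(imp0$underCovered)
})

test_that("designLibrary yields grouped guides and is deterministic", {
    cfg <- simConfig(seed = 5, nGenes = 3, noSharedFraction = 0)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    ext <- utils::read.delim(paths$externalGuides)
    lib1 <- designLibrary(gms, ext)
    g <- as.data.frame(guideTable(lib1))
    expect_identical(nrow(g), 21L)
    expect_identical(sort(unique(g$group)), 1:7)
    expect_identical(anyDuplicated(g$protospacer), 0L)
    expect_true(all(substr(g$pam, 2, 3) == "GG"))
    ## designed guides come from the shared tier and cut inside a shared exon
    des <- g[g$group <= 5, ]
    for (i in seq_len(nrow(des))) {
        sh <- sharedCdsExons(geneModels(gms)[[des$gene_id[i]]])
        hit <- any(GenomicRanges::start(sh) <= des$cut_site[i] &
                   GenomicRanges::end(sh) >= des$cut_site[i])
        expect_true(hit)
    }
    ## byte-identical re-run
    lib2 <- designLibrary(gms, ext)
    expect_identical(as.data.frame(guideTable(lib1)),
                     as.data.frame(guideTable(lib2)))
})

test_that("a protospacer duplicated across genes is selected only once", {
    ## two single-isoform genes with identical exon sequence
    set.seed(9)
    exonSeq <- randomDna(150)
    genome <- paste0(randomDna(200), exonSeq, randomDna(200), exonSeq,
                     randomDna(200))
    t1 <- makeTx("chr1", list(c(201, 350)), "+", "t1", "gA")
    t2 <- makeTx("chr1", list(c(551, 700)), "+", "t2", "gB")
    gms <- makeGms(list(gA = makeGene(list(t1), "gA"),
                        gB = makeGene(list(t2), "gB")),
                   c(chr1 = genome))
    ext <- data.frame(gene_id = character(), protospacer = character(),
                      pam = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE)
    lib <- designLibrary(gms, ext)
    g <- as.data.frame(guideTable(lib))
    expect_identical(anyDuplicated(g$protospacer), 0L)
    expect_setequal(unique(g$gene_id), c("gA", "gB"))
})

test_that("library diagnostics match manual counting on the guide table", {
    cfg <- simConfig(seed = 13, nGenes = 4)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    ext <- utils::read.delim(paths$externalGuides)
    lib <- designLibrary(gms, ext)
    g <- as.data.frame(guideTable(lib))
    d <- libraryDiagnostics(lib)
    hasScore <- !is.na(g$specificity_score)
    expect_equal(d$pct_score_ge_threshold,
                 100 * mean(g$specificity_score[hasScore] >= 70))
    expect_equal(d$pct_gc_in_band,
                 100 * mean(g$gc_fraction >= 0.35 & g$gc_fraction <= 0.70))
    hasPep <- !is.na(g$peptide_remaining_pct)
    expect_equal(d$pct_peptide_le25,
                 100 * mean(g$peptide_remaining_pct[hasPep] <= 25))
    expect_equal(d$genes_with_at_least_k[7],
                 sum(table(g$gene_id) >= 7))
})
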