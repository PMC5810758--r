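alnRow <- function(read_id = "r1", chrom = "chr1", pos = 100L, mapq = 60L,
                   cigar = "150M", proper = FALSE, dup = FALSE,
                   unmapped = FALSE) {
    data.frame(read_id = read_id, chrom = chrom, pos = pos, mapq = mapq,
               cigar = cigar, proper_pair = proper, duplicate = dup,
               unmapped = unmapped, stringsAsFactors = FALSE)
}

test_that("read classification follows the documented truth table", {
    aln <- rbind(
        alnRow("properGapless", proper = TRUE, cigar = "150M", mapq = 60),
        alnRow("properGapped", proper = TRUE, cigar = "70M5D80M", mapq = 60),
        alnRow("looseGapless", proper = FALSE, cigar = "150M", mapq = 60),
        alnRow("looseGapped", proper = FALSE, cigar = "70M5D80M", mapq = 60),
        alnRow("boundary38", proper = FALSE, cigar = "70M5D80M", mapq = 38),
        alnRow("boundary37", proper = FALSE, cigar = "70M5D80M", mapq = 37),
        alnRow("dup", proper = FALSE, cigar = "70M5D80M", mapq = 60,
               dup = TRUE),
        alnRow("unmapped", unmapped = TRUE))
    keep <- classifyReads(aln)
    expect_setequal(keep$read_id, c("properGapped", "looseGapless",
                                    "looseGapped", "boundary38"))
    st <- attr(keep, "stats")
    expect_identical(st$n_unmapped, 1L)
    expect_identical(st$n_proper_gapless, 1L)
    expect_identical(st$n_duplicate, 1L)
    expect_identical(st$n_low_mapq, 1L)
})

test_that("CIGAR walk emits indels at the SAM leftmost convention", {
    ins <- extractIndels(alnRow("r1", pos = 100L, cigar = "10M2I8M"))
    expect_identical(ins$type, "insertion")
    expect_identical(ins$position, 109L)
    expect_identical(ins$length, 2L)

    del <- extractIndels(alnRow("r2", pos = 50L, cigar = "5M3D15M"))
    expect_identical(del$type, "deletion")
    expect_identical(del$position, 55L)
    expect_identical(del$length, 3L)

    expect_identical(nrow(extractIndels(alnRow("r3", pos = 10L,
                                               cigar = "20M"))), 0L)
    expect_error(extractIndels(alnRow("bad", cigar = "10M2Q")), "bad")
})

test_that("soft clips and skips consume the right amount of reference", {
    ev <- extractIndels(alnRow("r1", pos = 100L,
                               cigar = "5S10M100N10M1I5M2D10M3H"))
    ## 5S consumes nothing; 10M + 100N + 10M advance to 220 for the I
    expect_identical(ev$position[ev$type == "insertion"], 219L)
    expect_identical(ev$position[ev$type == "deletion"], 225L)
})

test_that("events above the alignment length cap are dropped", {
    ev <- extractIndels(alnRow("r1", pos = 100L, cigar = "10M2500D10M"))
    expect_identical(nrow(ev), 0L)
    ev2 <- extractIndels(alnRow("r1", pos = 100L, cigar = "10M1999D10M"))
    expect_identical(ev2$length, 1999L)
})

test_that("extraction equals the brute-force reference walk on random reads", {
    set.seed(99)
    n <- 10000L
    aln <- data.frame(read_id = sprintf("r%05d", seq_len(n)),
                      chrom = "chr1",
                      pos = sample(1:100000, n, replace = TRUE),
                      cigar = vapply(seq_len(n), function(i) randomCigar(),
                                     character(1)),
                      stringsAsFactors = FALSE)
    got <- extractIndels(aln)
    want <- do.call(rbind, Filter(Negate(is.null),
        lapply(seq_len(n), function(i)
            indelWalkOracle(aln$pos[i], aln$cigar[i],
                            read_id = aln$read_id[i]))))
    rownames(want) <- NULL
    expect_identical(got, want)
})

test_that("window filtering follows point-membership for insertions and span-intersection for deletions", {
    site <- data.frame(guide_id = "g", gene_id = "gene", group = 5L,
                       chrom = "chr1", strand = "+", cut_site = 117L,
                       window_start = 115L, window_end = 120L,
                       stringsAsFactors = FALSE)
    ev <- function(type, pos, len) data.frame(
        read_id = "r", chrom = "chr1", type = type, position = pos,
        length = len, stringsAsFactors = FALSE)
    expect_identical(nrow(windowFilter(ev("deletion", 116L, 2L), site)), 1L)
    expect_identical(nrow(windowFilter(ev("insertion", 113L, 1L), site)), 0L)
    expect_identical(nrow(windowFilter(ev("insertion", 115L, 1L), site)), 1L)
    expect_identical(nrow(windowFilter(ev("insertion", 120L, 1L), site)), 1L)
    expect_identical(nrow(windowFilter(ev("insertion", 121L, 1L), site)), 0L)
    ## long deletion starting well upstream intersects the window
    expect_identical(nrow(windowFilter(ev("deletion", 110L, 10L), site)), 1L)
    expect_identical(nrow(windowFilter(ev("deletion", 110L, 4L), site)), 0L)
    ## wrong chromosome never validates
    evx <- ev("deletion", 116L, 2L); evx$chrom <- "chr2"
    expect_identical(nrow(windowFilter(evx, site)), 0L)
})

test_that("the cleavage window is strand-aware around the scission", {
    gs <- data.frame(guide_id = c("p", "m"), gene_id = "g", group = 5L,
                     chrom = "chr1", strand = c("+", "-"),
                     cut_site = c(117L, 124L), stringsAsFactors = FALSE)
    s <- targetSites(gs)
    expect_identical(s$window_start, c(115L, 121L))
    expect_identical(s$window_end, c(120L, 126L))
    expect_identical(s$window_end - s$window_start + 1L, c(6L, 6L))
})

test_that("control subtraction removes events by exact key only", {
    ev <- data.frame(read_id = c("a", "b", "c"), chrom = "chr1",
                     type = "deletion", position = c(117L, 117L, 200L),
                     length = c(3L, 5L, 3L), stringsAsFactors = FALSE)
    ctl <- data.frame(read_id = "x", chrom = "chr1", type = "deletion",
                      position = 117L, length = 3L, stringsAsFactors = FALSE)
    out <- subtractControl(ev, ctl)
    expect_setequal(out$read_id, c("b", "c"))     # same pos, other length kept
    expect_identical(subtractControl(ev, ctl[0, ]), ev)
})

test_that("OAS normalizes mean indel counts by pool representation", {
    expect_equal(computeOAS(0, 1000, 100000), 0)
    expect_equal(computeOAS(50, 1000, 100000), 50)
    expect_equal(computeOAS(10, 2000, 100000), 5)
    ## scale invariance in the pool counts
    expect_equal(computeOAS(12.5, 300, 45000),
                 computeOAS(12.5, 300 * 17, 45000 * 17))
    expect_true(is.na(computeOAS(10, 0, 100000)))
})

test_that("kendallTauB equals the all-pairs brute force, with ties", {
    expect_equal(kendallTauB(1:6, 1:6), 1)
    expect_equal(kendallTauB(1:6, 6:1), -1)
    x <- c(1, 2, 2, 3, 5, 4); y <- c(2, 1, 3, 3, 6, 5)
    expect_equal(kendallTauB(x, y), tauBOracle(x, y))
    set.seed(5)
    for (k in 1:20) {
        n <- sample(3:12, 1)
        a <- sample(1:6, n, replace = TRUE)
        b <- sample(1:6, n, replace = TRUE)
        if (length(unique(a)) < 2 || length(unique(b)) < 2) next
        expect_equal(kendallTauB(a, b), tauBOracle(a, b))
    }
    expect_true(is.na(kendallTauB(1, 2)))
})

test_that("filter chain is monotone on simulated alignments", {
    cfg <- simConfig(seed = 77, nGenes = 2, pairsPerGuide = 60L,
                     replicates = 1L)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    ext <- utils::read.delim(paths$externalGuides)
    lib <- designLibrary(gms, ext)
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    aln <- readTargetAlignments(ed$editedPaths[1])
    kept <- classifyReads(aln)
    ev <- extractIndels(kept)
    valid <- windowFilter(ev, sites)
    clean <- subtractControl(valid, extractIndels(classifyReads(
        readTargetAlignments(ed$controlPath))))
    expect_lte(nrow(kept), nrow(aln))
    expect_lte(nrow(valid), nrow(ev))
    expect_lte(nrow(clean), nrow(valid))
})
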