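test_that("the generator is deterministic: same seed, identical files", {
    cfg <- simConfig(seed = 101, nGenes = 3)
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p1 <- simulateGenome(cfg, d1)
    p2 <- simulateGenome(cfg, d2)
    for (f in c("genome", "annotation", "externalGuides"))
        expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
    lib <- data.frame(guide_id = c("a", "b"),
                      protospacer = c(proto20(1), proto20(2)),
                      stringsAsFactors = FALSE)
    r1 <- simulatePoolReads(lib, cfg)
    r2 <- simulatePoolReads(lib, cfg)
    expect_identical(as.character(r1$reads), as.character(r2$reads))
})

test_that("every gene of a generated genome is fully designable", {
    cfg <- simConfig(seed = 102, nGenes = 20, noSharedFraction = 0.1)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    ext <- utils::read.delim(paths$externalGuides)
    lib <- designLibrary(gms, ext)
    g <- as.data.frame(guideTable(lib))
    expect_identical(nrow(g), 140L)                 # 20 genes x 7 guides
    expect_identical(anyDuplicated(g$protospacer), 0L)
    ## the planned no-shared genes, and only they, use the fallback tier
    fl <- as.data.frame(geneFlags(lib))
    expect_setequal(fl$gene_id[fl$used_fallback],
                    paths$truth$plan$no_shared_ids)
    expect_identical(sum(fl$used_fallback), 2L)
})

test_that("emitted SAM records are valid and CIGARs consume the read length", {
    cfg <- simConfig(seed = 103, nGenes = 2, pairsPerGuide = 40L,
                     replicates = 2L)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    lib <- designLibrary(gms, utils::read.delim(paths$externalGuides))
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    for (f in c(ed$editedPaths, ed$controlPath)) {
        ## Rsamtools validates the format while converting
        expect_silent(aln <- readTargetAlignments(f))
        body <- grep("^@", readLines(f), invert = TRUE, value = TRUE)
        fields <- strsplit(body, "\t")
        qlen <- vapply(fields, function(x) {
            toks <- regmatches(x[6], gregexpr("[0-9]+[MIS=X]", x[6]))[[1]]
            sum(as.integer(sub("[A-Z=]", "", toks)))
        }, integer(1))
        seqlen <- vapply(fields, function(x) nchar(x[10]), integer(1))
        expect_identical(qlen, seqlen)
    }
})

test_that("with zero edit rates and no background, every guide is inactive", {
    cfg <- simConfig(seed = 104, nGenes = 3, pairsPerGuide = 50L,
                     backgroundIndelRate = 0)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    lib <- designLibrary(gms, utils::read.delim(paths$externalGuides))
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    cfg$editRates <- setNames(rep(0, nrow(sites)), sites$guide_id)
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    pool <- data.frame(guide_id = sites$guide_id, raw_reads = 1000L)
    act <- scoreActivity(ed$editedPaths, ed$controlPath, sites, pool)
    r <- as.data.frame(activityTable(act))
    expect_false(any(r$active))
    expect_true(all(r$oas == 0))
})

test_that("valid-event fraction tracks the simulated edit rate (binomial bound)", {
    cfg <- simConfig(seed = 105, nGenes = 1, pairsPerGuide = 500L,
                     replicates = 1L, backgroundIndelRate = 0,
                     dupFraction = 0, lowMapqFraction = 0)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    lib <- designLibrary(gms, utils::read.delim(paths$externalGuides))
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    cfg$editRates <- setNames(0.5, sites$guide_id)
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    ev <- windowFilter(extractIndels(classifyReads(
        readTargetAlignments(ed$editedPaths[1]))), sites)
    frac <- nrow(ev) / 500
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 500))
})

test_that("planted background events appear raw and vanish after control subtraction", {
    cfg <- simConfig(seed = 106, nGenes = 4, pairsPerGuide = 30L,
                     backgroundIndelRate = 1)   # background at every site
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    lib <- designLibrary(gms, utils::read.delim(paths$externalGuides))
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    cfg$editRates <- setNames(rep(0, nrow(sites)), sites$guide_id)
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    bg <- ed$truth$background
    expect_identical(nrow(bg), nrow(sites))
    rawEv <- extractIndels(classifyReads(
        readTargetAlignments(ed$editedPaths[1])))
    key <- function(e) paste(e$chrom, e$position, e$type, e$length)
    expect_true(all(key(bg) %in% key(rawEv)))
    ctlEv <- extractIndels(classifyReads(
        readTargetAlignments(ed$controlPath)))
    clean <- subtractControl(rawEv, ctlEv)
    expect_false(any(key(bg) %in% key(clean)))
    ## and therefore no guide is called active
    act <- scoreActivity(ed$editedPaths, ed$controlPath, sites,
                         data.frame(guide_id = sites$guide_id,
                                    raw_reads = 500L))
    expect_false(any(as.data.frame(activityTable(act))$active))
})

test_that("pipeline per-guide counts are recomputable from ground truth alone", {
    ## closure: duplicates, low-MAPQ reads and background all planted
    cfg <- simConfig(seed = 107, nGenes = 6, pairsPerGuide = 80L,
                     backgroundIndelRate = 0.5, dupFraction = 0.2,
                     lowMapqFraction = 0.2)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    lib <- designLibrary(gms, utils::read.delim(paths$externalGuides))
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    act <- scoreActivity(ed$editedPaths, ed$controlPath, sites,
                         data.frame(guide_id = sites$guide_id,
                                    raw_reads = 500L))
    r <- as.data.frame(activityTable(act))
    tr <- ed$truth$events
    bg <- ed$truth$background
    bgKey <- paste(bg$chrom, bg$position, bg$type, bg$length)
    for (rep in 1:2) {
        for (i in seq_len(nrow(sites))) {
            e <- tr[tr$replicate == rep & tr$guide_id == sites$guide_id[i], ]
            expected <- sum(!e$duplicate & e$mapq >= 38 &
                            !paste(e$chrom, e$position, e$type, e$length)
                             %in% bgKey)
            expect_identical(r[[paste0("indels_rep", rep)]][i], expected)
        }
    }
})

test_that("OAS rank order recovers simulated edit-rate order", {
    cfg <- simConfig(seed = 108, nGenes = 3, pairsPerGuide = 300L)
    paths <- simulateGenome(cfg, dir = withr::local_tempdir())
    gms <- loadAnnotation(paths$annotation, paths$genome)
    lib <- designLibrary(gms, utils::read.delim(paths$externalGuides))
    g <- as.data.frame(guideTable(lib))
    sites <- targetSites(g[g$group == 5L, ])
    rates <- c(0.1, 0.7, 0.4)
    cfg$editRates <- setNames(rates, sites$guide_id)
    ed <- simulateEditing(sites, gms, cfg, dir = withr::local_tempdir())
    act <- scoreActivity(ed$editedPaths, ed$controlPath, sites,
                         data.frame(guide_id = sites$guide_id,
                                    raw_reads = 500L))
    r <- as.data.frame(activityTable(act))
    expect_identical(order(r$oas), order(rates))
})
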