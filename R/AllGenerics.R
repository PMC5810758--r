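#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' \code{guideTable} returns the per-guide table of a \linkS4class{GuideSet};
#' \code{geneFlags} the per-gene selection flags; \code{designParams} the
#' parameters used; \code{libraryDiagnostics} the library-wide summary;
#' \code{layoutTable} the well assignments of a \linkS4class{PlateLayout};
#' \code{poolTable} the long-format pool membership of a
#' \linkS4class{PoolSet}; \code{countTable} the per-guide counts of a
#' \linkS4class{GuideCounts}; \code{activityTable} the per-guide records of
#' an \linkS4class{ActivitySet}.
#'
#' @param x the object.
#' @return A \link[S4Vectors]{DataFrame} (or list for
#'   \code{libraryDiagnostics}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("guideTable", function(x) standardGeneric("guideTable"))
#' @rdname accessors
#' @export
setGeneric("geneFlags", function(x) standardGeneric("geneFlags"))
#' @rdname accessors
#' @export
setGeneric("designParams", function(x) standardGeneric("designParams"))
#' @rdname accessors
#' @export
setGeneric("libraryDiagnostics", function(x) standardGeneric("libraryDiagnostics"))
#' @rdname accessors
#' @export
setGeneric("layoutTable", function(x) standardGeneric("layoutTable"))
#' @rdname accessors
#' @export
setGeneric("poolTable", function(x) standardGeneric("poolTable"))
#' @rdname accessors
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))
#' @rdname accessors
#' @export
setGeneric("activityTable", function(x) standardGeneric("activityTable"))

#' @rdname accessors
#' @export
setMethod("guideTable", "GuideSet", function(x) x@guides)
#' @rdname accessors
#' @export
setMethod("geneFlags", "GuideSet", function(x) x@geneFlags)
#' @rdname accessors
#' @export
setMethod("designParams", "GuideSet", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("libraryDiagnostics", "GuideSet", function(x) x@diagnostics)
#' @rdname accessors
#' @export
setMethod("layoutTable", "PlateLayout", function(x) x@assignments)
#' @rdname accessors
#' @export
setMethod("poolTable", "PoolSet", function(x) x@pools)
#' @rdname accessors
#' @export
setMethod("countTable", "GuideCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("activityTable", "ActivitySet", function(x) x@records)

#' @describeIn accessors genes of a \linkS4class{GeneModelSet} (named list).
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setMethod("geneModels", "GeneModelSet", function(x) x@genes)

#' @describeIn accessors genome of a \linkS4class{GeneModelSet}.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setMethod("genomeSeq", "GeneModelSet", function(x) x@genome)

#' @describeIn accessors primary transcript of a \linkS4class{GeneModel}.
#' @export
setGeneric("primaryTranscript", function(x) standardGeneric("primaryTranscript"))
#' @rdname accessors
#' @export
setMethod("primaryTranscript", "GeneModel", function(x) {
    x@transcripts[[which(vapply(x@transcripts, function(t) t@primary, logical(1)))]]
})

setMethod("show", "GeneModelSet", function(object) {
    nt <- sum(vapply(object@genes, function(g) length(g@transcripts), integer(1)))
    cat("GeneModelSet with", length(object@genes), "genes,", nt,
        "transcripts on", length(object@genome), "chromosomes\n")
})

setMethod("show", "GuideSet", function(object) {
    g <- object@guides
    cat("GuideSet with", nrow(g), "guides across",
        length(unique(g$gene_id)), "genes\n")
    if (nrow(g)) {
        cat("  groups:", paste(sprintf("%d:%d", sort(unique(g$group)),
            as.integer(table(g$group))), collapse = " "), "\n")
    }
    d <- object@diagnostics
    if (length(d))
        cat(sprintf("  %% score >= %g: %.1f | %% GC in band: %.1f\n",
                    object@params@scoreThreshold,
                    d$pct_score_ge_threshold, d$pct_gc_in_band))
})

setMethod("show", "PlateLayout", function(object) {
    cat("PlateLayout:", nrow(object@assignments), "wells on",
        object@nPlates, "plate(s)\n")
})

setMethod("show", "PoolSet", function(object) {
    p <- object@pools
    cat("PoolSet:", length(unique(p$pool_id)), "pools (",
        paste(names(table(p$pool_kind[!duplicated(p$pool_id)])),
              table(p$pool_kind[!duplicated(p$pool_id)]), collapse = ", "),
        ")\n")
})

setMethod("show", "GuideCounts", function(object) {
    cc <- object@counts
    cat("GuideCounts:", nrow(cc), "guides;", sum(cc$raw_reads),
        "assigned /", object@unassigned, "unassigned /", object@ambiguous,
        "ambiguous reads\n")
})

setMethod("show", "ActivitySet", function(object) {
    r <- object@records
    cat("ActivitySet:", nrow(r), "guides;",
        sum(r$active, na.rm = TRUE), "active\n")
})
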