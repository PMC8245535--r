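#' Accessors for lakecycle classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x a lakecycle object.
#' @param ... unused.
#' @return `genomeIds()`: character vector of genome ids. `genomeSizes()`,
#'   `completeness()`, `contamination()`: named numeric vectors.
#'   `taxonomy()`: the metadata `DataFrame` (GenomeSet) or a named character
#'   vector at one rank. `aniValues()`: the symmetric numeric matrix with
#'   `NA` for below-floor pairs. `aniFloor()`: the reporting floor.
#'   `clusterMembers()`: the membership data.frame. `representatives()`:
#'   character vector of representative genome ids.
#' @name accessors
#' @aliases genomeIds genomeSizes completeness contamination taxonomy
#'   aniValues aniFloor clusterMembers representatives
#' @examples
#' gs <- exampleGenomeSet()
#' genomeIds(gs)
#' completeness(gs)
NULL

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setGeneric("genomeSizes", function(x) standardGeneric("genomeSizes"))
#' @rdname accessors
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))
#' @rdname accessors
#' @export
setGeneric("contamination", function(x) standardGeneric("contamination"))
#' @rdname accessors
#' @param rank optional taxonomy column to extract (e.g. "phylum",
#'   "lineage", or a flag such as "is_cpr").
#' @export
setGeneric("taxonomy", function(x, rank = NULL) standardGeneric("taxonomy"))
#' @rdname accessors
#' @export
setGeneric("aniValues", function(x) standardGeneric("aniValues"))
#' @rdname accessors
#' @export
setGeneric("aniFloor", function(x) standardGeneric("aniFloor"))
#' @rdname accessors
#' @export
setGeneric("clusterMembers", function(x) standardGeneric("clusterMembers"))
#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))

#' @rdname accessors
setMethod("genomeIds", "GenomeSet", function(x) names(x@sequences))

#' @rdname accessors
setMethod("genomeSizes", "GenomeSet", function(x) {
    stats::setNames(as.numeric(x@metadata$genome_size), genomeIds(x))
})

.meta_numeric <- function(x, col) {
    v <- if (col %in% colnames(x@metadata)) x@metadata[[col]] else
        rep(NA_real_, length(x@sequences))
    stats::setNames(as.numeric(v), genomeIds(x))
}

#' @rdname accessors
setMethod("completeness", "GenomeSet",
    function(x) .meta_numeric(x, "completeness"))

#' @rdname accessors
setMethod("contamination", "GenomeSet",
    function(x) .meta_numeric(x, "contamination"))

#' @rdname accessors
setMethod("taxonomy", "GenomeSet", function(x, rank = NULL) {
    if (is.null(rank)) return(x@metadata)
    if (!rank %in% colnames(x@metadata))
        stop(sprintf("taxonomy rank '%s' not present", rank))
    stats::setNames(x@metadata[[rank]], genomeIds(x))
})

#' @rdname accessors
setMethod("aniValues", "ANIMatrix", function(x) x@values)

#' @rdname accessors
setMethod("aniFloor", "ANIMatrix", function(x) x@floor)

#' @rdname accessors
setMethod("clusterMembers", "ClusterSet", function(x) x@members)

#' @rdname accessors
setMethod("representatives", "ClusterSet", function(x) {
    m <- x@members
    m$genome_id[m$is_representative]
})

#' Extract scaffold sequences of one genome
#'
#' @param x a GenomeSet.
#' @param id genome id.
#' @return a \code{DNAStringSet} of scaffolds.
#' @export
scaffolds <- function(x, id) {
    stopifnot(methods::is(x, "GenomeSet"))
    if (!id %in% genomeIds(x)) stop(sprintf("unknown genome '%s'", id))
    x@sequences[[id]]
}

#' @describeIn GenomeSet-class number of genomes
#' @param x a GenomeSet.
#' @export
setMethod("length", "GenomeSet", function(x) length(x@sequences))

#' @describeIn GenomeSet-class subset by genome id or index
#' @param i genome ids (character) or indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "GenomeSet", function(x, i, j, ..., drop = FALSE) {
    ids <- genomeIds(x)
    idx <- if (is.character(i)) {
        bad <- setdiff(i, ids)
        if (length(bad)) stop(sprintf("unknown genome ids: %s",
            paste(bad, collapse = ", ")))
        match(i, ids)
    } else i
    methods::new("GenomeSet", sequences = x@sequences[idx],
        metadata = x@metadata[idx, , drop = FALSE])
})

setMethod("show", "GenomeSet", function(object) {
    cat(sprintf("GenomeSet with %d genome(s)\n", length(object)))
    if (length(object)) {
        sz <- genomeSizes(object)
        cat(sprintf("  total size: %.2f Mbp (range %.0f-%.0f bp)\n",
            sum(sz) / 1e6, min(sz), max(sz)))
        cm <- completeness(object)
        if (any(!is.na(cm)))
            cat(sprintf("  completeness: median %.1f%% (%d unknown)\n",
                stats::median(cm, na.rm = TRUE), sum(is.na(cm))))
        cat("  metadata columns:",
            paste(colnames(object@metadata), collapse = ", "), "\n")
    }
})

setMethod("show", "CoverageTable", function(object) {
    e <- object@entries
    cat(sprintf(paste0("CoverageTable: %d entries, %d scaffold(s), ",
        "%d sample(s), %d binned scaffold(s)\n"),
        nrow(e), length(unique(e$scaffold)), length(unique(e$sample)),
        length(object@scaffoldToGenome)))
})

setMethod("show", "Sketch", function(object) {
    cat(sprintf("Sketch of '%s': k=%d, %d/%d hashes\n", object@genomeId,
        object@k, length(object@hashes), object@sketchSize))
})

setMethod("show", "ANIMatrix", function(object) {
    n <- nrow(object@values)
    off <- object@values[upper.tri(object@values)]
    cat(sprintf("ANIMatrix: %d genome(s), floor %.1f%%; %d/%d pairs reported\n",
        n, object@floor, sum(!is.na(off)), length(off)))
})

setMethod("show", "ClusterSet", function(object) {
    m <- object@members
    cat(sprintf("ClusterSet: %d genome(s) in %d cluster(s) at ANI >= %.1f%%\n",
        nrow(m), length(unique(m$cluster_id)), object@threshold))
})

setMethod("show", "MarkerAlignment", function(object) {
    len <- if (length(object@rows)) nchar(object@rows[[1]]) else 0L
    cat(sprintf("MarkerAlignment '%s': %d row(s), %d column(s)\n",
        object@markerId, length(object@rows), len))
})

setMethod("show", "Supermatrix", function(object) {
    cat(sprintf("Supermatrix: %d genome(s), %d partition(s), %d column(s)\n",
        length(object@rows), nrow(object@partitions),
        if (nrow(object@partitions)) object@partitions$end[
            nrow(object@partitions)] else 0L))
})

setMethod("show", "SyntheticTruth", function(object) {
    cat(sprintf(paste0("SyntheticTruth: %d genome(s), %d sample(s), ",
        "%d reaction(s), seed %d\n"), length(object@genomes),
        nrow(object@samples), ncol(object@functions), object@seed))
})
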