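#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importFrom Rcpp sourceCpp
#' @useDynLib lakecycle, .registration = TRUE
NULL

#' GenomeSet: a collection of MAGs with per-genome metadata
#'
#' Holds one \code{\link[Biostrings]{DNAStringSet}} of scaffolds per genome
#' together with a metadata \code{DataFrame} (completeness, contamination,
#' taxonomy ranks, lineage flags, source label). The central container for
#' quality filtering, sketching, dereplication and abundance mapping.
#'
#' @slot sequences named list of \code{DNAStringSet}, one element per genome;
#'   element names are genome ids, sequence names within are scaffold ids.
#' @slot metadata \code{DataFrame} with one row per genome (rownames are
#'   genome ids); always contains \code{genome_size}; may contain
#'   \code{completeness}, \code{contamination}, taxonomy ranks
#'   (\code{domain} ... \code{species}), \code{lineage}, logical flags
#'   \code{is_cpr}, \code{is_dpann}, \code{is_archaea}, and
#'   \code{source_label}. Unknown values are \code{NA}, never 0.
#'
#' @seealso [readGenomes()], [qualityFilter()], [sketchGenome()]
#' @exportClass GenomeSet
setClass("GenomeSet",
    representation(sequences = "list", metadata = "DataFrame"))

setValidity("GenomeSet", function(object) {
    ids <- names(object@sequences)
    if (length(object@sequences) && (is.null(ids) || anyNA(ids) ||
        any(ids == "")))
        return("all genomes must be named")
    if (anyDuplicated(ids))
        return(sprintf("duplicate genome_id: %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (!identical(rownames(object@metadata), ids))
        return("metadata rownames must match genome ids, in order")
    for (id in ids) {
        x <- object@sequences[[id]]
        if (!methods::is(x, "DNAStringSet"))
            return(sprintf("genome '%s' is not a DNAStringSet", id))
        if (length(x) == 0L)
            return(sprintf("genome '%s' has no sequences", id))
        sid <- names(x)
        if (is.null(sid) || anyDuplicated(sid))
            return(sprintf("genome '%s' has missing/duplicate scaffold ids", id))
    }
    if (!"genome_size" %in% colnames(object@metadata))
        return("metadata must contain genome_size")
    sizes <- vapply(object@sequences, function(x) sum(Biostrings::width(x)), 0)
    if (length(ids) && !isTRUE(all.equal(unname(sizes),
        as.numeric(object@metadata$genome_size))))
        return("genome_size must equal the sum of scaffold lengths")
    cm <- object@metadata$completeness
    if (!is.null(cm) && any(!is.na(cm) & (cm < 0 | cm > 100)))
        return("completeness must be in [0, 100]")
    ct <- object@metadata$contamination
    if (!is.null(ct) && any(!is.na(ct) & ct < 0))
        return("contamination must be >= 0")
    TRUE
})

#' CoverageTable: per-scaffold per-sample mean fold coverage
#'
#' Long-format coverage entries as produced by read mapping plus pileup
#' summaries, with scaffold lengths and the (possibly partial) scaffold to
#' genome assignment from binning.
#'
#' @slot entries data.frame with columns \code{scaffold}, \code{sample},
#'   \code{coverage} (mean fold coverage, x, >= 0).
#' @slot lengths named numeric, scaffold id -> length in bp.
#' @slot scaffoldToGenome named character, scaffold id -> genome id;
#'   unbinned scaffolds are simply absent.
#'
#' @seealso [readCoverageTable()], [genomeCoverage()]
#' @exportClass CoverageTable
setClass("CoverageTable",
    representation(entries = "data.frame", lengths = "numeric",
        scaffoldToGenome = "character"))

setValidity("CoverageTable", function(object) {
    e <- object@entries
    if (!all(c("scaffold", "sample", "coverage") %in% colnames(e)))
        return("entries needs columns scaffold, sample, coverage")
    if (any(e$coverage < 0)) return("coverage must be >= 0")
    missing_len <- setdiff(unique(e$scaffold), names(object@lengths))
    if (length(missing_len))
        return(sprintf("scaffolds with coverage but no length: %s",
            paste(utils::head(missing_len, 5), collapse = ", ")))
    if (any(object@lengths <= 0)) return("scaffold lengths must be positive")
    TRUE
})

#' Sketch: MinHash sketch of one genome
#'
#' The \code{sketchSize} smallest distinct hash values over canonical
#' (strand-symmetric) k-mers of a genome's scaffolds. Ambiguity codes are
#' excluded from k-mers; the hash seed is a fixed package constant so
#' sketches are reproducible and mutually comparable.
#'
#' @slot genomeId character scalar.
#' @slot k k-mer size (default 21).
#' @slot sketchSize maximum number of retained hashes (default 5000).
#' @slot hashes strictly increasing numeric vector of <= sketchSize hashes.
#'
#' @seealso [sketchGenome()], [aniFromSketches()]
#' @exportClass Sketch
setClass("Sketch",
    representation(genomeId = "character", k = "integer",
        sketchSize = "integer", hashes = "numeric"))

setValidity("Sketch", function(object) {
    if (length(object@hashes) > object@sketchSize)
        return("more hashes than sketchSize")
    if (is.unsorted(object@hashes, strictly = TRUE))
        return("hashes must be strictly increasing")
    TRUE
})

#' ANIMatrix: pairwise average nucleotide identity estimates
#'
#' Symmetric matrix of ANI percentages with 100 on the diagonal. Pairs whose
#' estimate falls below the reliability floor (default 75%) or that share no
#' sketch hashes are stored as \code{NA} ("below floor").
#'
#' @slot values symmetric numeric matrix, dimnames = genome ids; NA marks
#'   below-floor pairs.
#' @slot floor percent below which estimates are not reported.
#'
#' @seealso [pairwiseANI()], [dereplicate()], [compareGroups()]
#' @exportClass ANIMatrix
setClass("ANIMatrix",
    representation(values = "matrix", floor = "numeric"))

setValidity("ANIMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v) || !identical(rownames(v), colnames(v)))
        return("values must be square with matching dimnames")
    if (!isTRUE(all.equal(unname(diag(v)), rep(100, nrow(v)))))
        return("diagonal must be 100")
    if (!isTRUE(all.equal(v, t(v)))) return("matrix must be symmetric")
    ok <- v[!is.na(v)]
    if (any(ok < object@floor - 1e-9 | ok > 100 + 1e-9))
        return("reported ANI values must lie in [floor, 100]")
    TRUE
})

#' ClusterSet: result of greedy ANI dereplication
#'
#' A partition of genomes into ANI clusters, one representative per cluster,
#' with the quality score used to rank candidates.
#'
#' @slot members data.frame with columns \code{genome_id},
#'   \code{cluster_id}, \code{is_representative}, \code{score}.
#' @slot threshold ANI percent used to join clusters.
#'
#' @seealso [dereplicate()]
#' @exportClass ClusterSet
setClass("ClusterSet",
    representation(members = "data.frame", threshold = "numeric"))

setValidity("ClusterSet", function(object) {
    m <- object@members
    need <- c("genome_id", "cluster_id", "is_representative", "score")
    if (!all(need %in% colnames(m)))
        return("members needs genome_id, cluster_id, is_representative, score")
    if (anyDuplicated(m$genome_id))
        return("clusters must partition the genomes (duplicate member)")
    reps <- table(m$cluster_id[m$is_representative])
    cl <- unique(m$cluster_id)
    if (!setequal(names(reps), cl) || any(reps != 1L))
        return("each cluster must have exactly one representative")
    TRUE
})

#' MarkerAlignment: one aligned single-copy marker across genomes
#'
#' Aligned residues for one ribosomal-protein marker, at most one row per
#' genome once copies have been resolved. Gap character is '-'.
#'
#' @slot markerId marker name, e.g. "rpL2".
#' @slot rows named character vector (genome id -> aligned string), all of
#'   equal length.
#'
#' @seealso [resolveCopies()], [maskColumns()], [concatenateMarkers()]
#' @exportClass MarkerAlignment
setClass("MarkerAlignment",
    representation(markerId = "character", rows = "character"))

setValidity("MarkerAlignment", function(object) {
    if (length(object@rows)) {
        if (is.null(names(object@rows)) || any(names(object@rows) == ""))
            return("rows must be named by genome id")
        if (anyDuplicated(names(object@rows)))
            return("at most one row per genome (resolve copies first)")
        if (length(unique(nchar(object@rows))) != 1L)
            return("all rows must have equal length")
    }
    TRUE
})

#' Supermatrix: concatenated marker alignment with partitions
#'
#' Row-per-genome concatenation of masked marker alignments. Partitions give
#' 1-based inclusive coordinates of each marker block; they tile
#' \code{[1, total_length]} without overlap.
#'
#' @slot rows named character vector (genome id -> concatenated residues).
#' @slot partitions data.frame with columns \code{marker}, \code{start},
#'   \code{end}.
#'
#' @seealso [concatenateMarkers()], [writePartitions()]
#' @exportClass Supermatrix
setClass("Supermatrix",
    representation(rows = "character", partitions = "data.frame"))

setValidity("Supermatrix", function(object) {
    p <- object@partitions
    if (!all(c("marker", "start", "end") %in% colnames(p)))
        return("partitions needs marker, start, end")
    if (nrow(p)) {
        if (p$start[1] != 1L) return("partitions must start at 1")
        if (any(p$end < p$start)) return("partition end < start")
        if (nrow(p) > 1L && any(p$start[-1L] != p$end[-nrow(p)] + 1L))
            return("partitions must tile without gaps or overlap")
        total <- p$end[nrow(p)]
        if (length(object@rows) && any(nchar(object@rows) != total))
            return("row lengths must equal total partition length")
    }
    TRUE
})

#' SyntheticTruth: a simulated stratified community with ground truth
#'
#' Bundle returned by [simulateCommunity()]: the generated genomes, planted
#' abundance / function / ANI-cluster / guild truth, sample metadata, and
#' paths of the emitted pipeline-dialect files.
#'
#' @slot genomes GenomeSet of simulated MAGs.
#' @slot abundance genome x sample matrix of planted relative abundances
#'   (columns sum to 1).
#' @slot functions genome x reaction 0/1 matrix of planted capabilities.
#' @slot clusters named character: genome id -> planted ANI cluster id.
#' @slot guilds named character: genome id -> "surface", "deep" or
#'   "generalist".
#' @slot samples data.frame of sample metadata (sample_id, station, depth_m,
#'   date, total_reads).
#' @slot files named character of emitted file paths.
#' @slot seed integer seed used.
#' @slot config list of generator settings.
#'
#' @seealso [simulateCommunity()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
    representation(genomes = "GenomeSet", abundance = "matrix",
        functions = "matrix", clusters = "character", guilds = "character",
        samples = "data.frame", files = "character", seed = "integer",
        config = "list"))

setValidity("SyntheticTruth", function(object) {
    if (ncol(object@abundance) &&
        any(abs(colSums(object@abundance) - 1) > 1e-8))
        return("abundance columns must sum to 1")
    if (length(object@functions) && !all(object@functions %in% c(0, 1)))
        return("function truth must be 0/1")
    TRUE
})
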