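#' Aggregate scaffold coverage to genome-level coverage
#'
#' Two aggregation modes. `"sum"` (default): per genome per sample, the sum
#' of per-scaffold mean fold coverages — the convention used when coverage
#' tables are combined by MAG identifier, but sensitive to how fragmented a
#' genome is. `"length_weighted"`: the length-weighted mean
#' \eqn{\sum c_i l_i / \sum l_i}, the statistically preferable estimate of
#' genome-wide depth; this is the mode recovery checks use. Scaffolds
#' without a genome assignment are ignored (their count and coverage mass
#' are reported via a message). A detection floor zeroes genome-level
#' values below `detectionFloor` (x) to suppress sub-read-level mapping
#' noise; set 0 to disable.
#'
#' @param cov a [CoverageTable-class] with `scaffoldToGenome` set for the
#'   binned scaffolds.
#' @param mode `"sum"` or `"length_weighted"`.
#' @param detectionFloor genome-level coverage below this is set to 0
#'   (default 0.01).
#' @return numeric matrix genome x sample of coverage (x), attribute
#'   `mode`.
#' @export
genomeCoverage <- function(cov, mode = c("sum", "length_weighted"),
        detectionFloor = 0.01) {
    stopifnot(methods::is(cov, "CoverageTable"))
    mode <- match.arg(mode)
    e <- cov@entries
    map <- cov@scaffoldToGenome
    binned <- e$scaffold %in% names(map)
    if (any(!binned))
        message(sprintf("ignoring %d coverage entries on %d unbinned scaffold(s)",
            sum(!binned), length(unique(e$scaffold[!binned]))))
    e <- e[binned, , drop = FALSE]
    genomes <- sort(unique(unname(map)))
    samples <- sort(unique(cov@entries$sample))
    out <- matrix(0, length(genomes), length(samples),
        dimnames = list(genomes, samples))
    if (nrow(e)) {
        g <- map[e$scaffold]
        len <- cov@lengths[e$scaffold]
        if (any(is.na(len)))
            stop("scaffold with coverage but no recorded length")
        key <- interaction(g, e$sample, drop = FALSE)
        if (mode == "sum") {
            agg <- tapply(e$coverage, list(g, e$sample), sum)
        } else {
            num <- tapply(e$coverage * len, list(g, e$sample), sum)
            den <- tapply(len, list(g, e$sample), sum)
            agg <- num / den
        }
        agg[is.na(agg)] <- 0
        out[rownames(agg), colnames(agg)] <- agg
    }
    if (detectionFloor > 0) out[out < detectionFloor] <- 0
    attr(out, "mode") <- mode
    out
}

#' Normalize genome coverage by per-sample read counts
#'
#' Divides each sample's coverage column by that sample's total read count
#' (the per-metagenome normalization), so samples of different sequencing
#' depth become comparable.
#'
#' @param gc genome x sample coverage matrix from [genomeCoverage()].
#' @param samples data.frame with `sample_id` and `total_reads` (> 0); must
#'   cover every sample column.
#' @return genome x sample matrix of read-normalized coverage.
#' @export
normalizeByReads <- function(gc, samples) {
    missing <- setdiff(colnames(gc), samples$sample_id)
    if (length(missing))
        stop(sprintf("no metadata for sample(s): %s",
            paste(missing, collapse = ", ")))
    reads <- stats::setNames(samples$total_reads, samples$sample_id)
    if (any(reads[colnames(gc)] <= 0)) stop("total_reads must be > 0")
    sweep(gc, 2L, reads[colnames(gc)], `/`)
}

#' Convert normalized coverage to relative read abundance (RAR)
#'
#' Per sample, each genome's normalized coverage is divided by the column
#' sum over all genomes (MAG-relative denominator) and multiplied by 100,
#' so every non-empty column sums to 100%. A sample where no genome is
#' detected stays an all-zero column, with a warning.
#'
#' @param normalized genome x sample matrix from [normalizeByReads()].
#' @return genome x sample percent matrix with attribute `denominator`
#'   (the per-sample column sums used).
#' @export
#' @examples
#' m <- matrix(c(3e-5, 1e-5), 2, 1, dimnames = list(c("a", "b"), "s"))
#' toRAR(m)  # 75 / 25
toRAR <- function(normalized) {
    if (any(normalized < 0)) stop("normalized coverage must be >= 0")
    sums <- colSums(normalized)
    empty <- sums == 0
    if (any(empty))
        warning(sprintf("no genomes detected in sample(s): %s",
            paste(colnames(normalized)[empty], collapse = ", ")))
    denom <- ifelse(empty, 1, sums)
    rar <- sweep(normalized, 2L, denom, `/`) * 100
    attr(rar, "denominator") <- sums
    rar
}

#' Aggregate a RAR matrix by taxon
#'
#' Sums member-genome RAR within each taxon label, per sample; column sums
#' are preserved exactly.
#'
#' @param rar genome x sample percent matrix from [toRAR()].
#' @param taxonomy named character (genome id -> label) or a GenomeSet plus
#'   `groupBy`.
#' @param groupBy taxonomy column when `taxonomy` is a GenomeSet (a rank or
#'   a flag such as `is_cpr`).
#' @return taxon x sample percent matrix.
#' @export
taxonRAR <- function(rar, taxonomy, groupBy = NULL) {
    if (methods::is(taxonomy, "GenomeSet")) {
        if (is.null(groupBy)) stop("groupBy required with a GenomeSet")
        taxonomy <- taxonomy(taxonomy, groupBy)
    }
    lab <- taxonomy[rownames(rar)]
    bad <- rownames(rar)[is.na(lab)]
    if (length(bad))
        stop(sprintf("unlabeled genome(s): %s", paste(bad, collapse = ", ")))
    out <- rowsum(rar, group = as.character(lab))
    out[order(rownames(out)), , drop = FALSE]
}

#' Write a RAR matrix (wide and long forms)
#'
#' @param rar genome x sample matrix.
#' @param path output path for the wide table; the long form is written to
#'   `<path>.long.tsv` when `long = TRUE`.
#' @param long also write a long-format table (genome, sample, rar).
#' @return `path`, invisibly.
#' @export
writeRAR <- function(rar, path, long = FALSE) {
    wide <- data.frame(genome_id = rownames(rar), rar, check.names = FALSE)
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    if (long) {
        d <- data.frame(genome_id = rep(rownames(rar), ncol(rar)),
            sample = rep(colnames(rar), each = nrow(rar)),
            rar = as.vector(rar))
        utils::write.table(d, paste0(path, ".long.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
    }
    invisible(path)
}
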