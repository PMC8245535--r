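#' MinHash-sketch a genome
#'
#' Builds a bottom sketch: the `sketchSize` smallest distinct hash values
#' over canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) across all scaffolds. Ambiguity codes terminate
#' k-mer runs, so only ACGT k-mers contribute. The hash seed is a fixed
#' package constant, making sketches deterministic and comparable.
#'
#' @param genome a [GenomeSet-class] (sketches every genome, returns a
#'   list), a `DNAStringSet`, or a character vector of sequences.
#' @param k k-mer size, default 21.
#' @param sketchSize sketch size, default 5000.
#' @param genomeId id recorded in the sketch (required unless `genome` is a
#'   GenomeSet).
#' @return a [Sketch-class], or a named list of sketches for a GenomeSet.
#' @export
#' @examples
#' sk <- sketchGenome(exampleGenomeSet())
#' sk[["g1"]]
sketchGenome <- function(genome, k = 21L, sketchSize = 5000L,
        genomeId = "genome") {
    if (methods::is(genome, "GenomeSet")) {
        out <- lapply(genomeIds(genome), function(id)
            sketchGenome(genome@sequences[[id]], k = k,
                sketchSize = sketchSize, genomeId = id))
        names(out) <- genomeIds(genome)
        return(out)
    }
    seqs <- if (methods::is(genome, "DNAStringSet"))
        as.character(genome) else as.character(genome)
    hashes <- cpp_minhash_sketch(seqs, as.integer(k), as.integer(sketchSize))
    if (!length(hashes))
        stop(sprintf("genome too short: '%s' has no valid %d-mer",
            genomeId, k))
    methods::new("Sketch", genomeId = genomeId, k = as.integer(k),
        sketchSize = as.integer(sketchSize), hashes = hashes)
}

#' Estimate ANI from two MinHash sketches
#'
#' The Jaccard index J of the two k-mer sets is estimated from the merged
#' bottom sketch (the s smallest hashes of the union, s = sketch size),
#' and converted through the Mash distance
#' \deqn{D = -\frac{1}{k}\,\ln\frac{2J}{1+J}, \qquad ANI = 100\,(1 - D)}
#' clamped to [0, 100]. Estimates below the reliability floor, or with
#' J = 0, are reported as `NA` ("below floor").
#'
#' @param a,b [Sketch-class] objects with equal `k`.
#' @param floor percent below which the estimate is unreliable (default 75).
#' @return ANI percent, or `NA_real_` when below floor.
#' @export
aniFromSketches <- function(a, b, floor = 75) {
    stopifnot(methods::is(a, "Sketch"), methods::is(b, "Sketch"))
    if (a@k != b@k)
        stop(sprintf("mismatched k: %d vs %d", a@k, b@k))
    j <- .sketch_jaccard(a@hashes, b@hashes,
        min(a@sketchSize, b@sketchSize))
    .jaccard_to_ani(j, a@k, floor)
}

.sketch_jaccard <- function(ha, hb, s) {
    u <- sort(unique(c(ha, hb)))
    if (length(u) > s) u <- u[seq_len(s)]
    shared <- sum(u %in% ha & u %in% hb)
    shared / length(u)
}

.jaccard_to_ani <- function(j, k, floor) {
    if (is.na(j) || j <= 0) return(NA_real_)
    d <- -(1 / k) * log(2 * j / (1 + j))
    ani <- 100 * (1 - d)
    ani <- min(max(ani, 0), 100)
    if (ani < floor) NA_real_ else ani
}

#' All-vs-all sketch ANI matrix
#'
#' @param genomes a [GenomeSet-class] or a named list of [Sketch-class].
#' @param k,sketchSize sketch parameters (used when sketching a GenomeSet).
#' @param floor reporting floor percent (default 75); below-floor pairs are
#'   stored as `NA`.
#' @return an [ANIMatrix-class]: symmetric, diagonal 100.
#' @export
pairwiseANI <- function(genomes, k = 21L, sketchSize = 5000L, floor = 75) {
    sketches <- if (methods::is(genomes, "GenomeSet"))
        sketchGenome(genomes, k = k, sketchSize = sketchSize) else genomes
    stopifnot(length(sketches) >= 2L)
    ids <- names(sketches)
    n <- length(ids)
    v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
    diag(v) <- 100
    for (i in seq_len(n - 1L)) {
        for (jj in seq((i + 1L), n)) {
            ani <- aniFromSketches(sketches[[i]], sketches[[jj]],
                floor = floor)
            v[i, jj] <- ani
            v[jj, i] <- ani
        }
    }
    methods::new("ANIMatrix", values = v, floor = floor)
}

#' Write an ANI matrix as a long-format table
#'
#' Columns query, target, ani, status (`ok` or `below_floor`), one row per
#' unordered pair (upper triangle).
#'
#' @param ani an [ANIMatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeANIMatrix <- function(ani, path) {
    v <- aniValues(ani)
    idx <- which(upper.tri(v), arr.ind = TRUE)
    d <- data.frame(query = rownames(v)[idx[, 1L]],
        target = colnames(v)[idx[, 2L]], ani = v[idx],
        status = ifelse(is.na(v[idx]), "below_floor", "ok"))
    d$ani <- ifelse(is.na(d$ani), "", sprintf("%.4f", d$ani))
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
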