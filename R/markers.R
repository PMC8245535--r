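#' Construct a MarkerAlignment
#'
#' @param markerId marker name (e.g. "rpL2").
#' @param rows named character vector of equal-length aligned strings
#'   (gap character '-'), at most one per genome.
#' @return a [MarkerAlignment-class].
#' @export
MarkerAlignment <- function(markerId, rows) {
    methods::new("MarkerAlignment", markerId = markerId,
        rows = toupper(rows))
}

#' Read one aligned-FASTA marker alignment
#'
#' Sequence headers are `genome_id` or `genome_id|copyN` when a genome
#' carries several candidate copies; with `resolve = TRUE` multi-copy
#' genomes are collapsed through [resolveCopies()].
#'
#' @param path aligned FASTA file.
#' @param markerId marker name (default: file name without extension).
#' @param resolve collapse multiple copies per genome (default TRUE).
#' @param overlapTolerance passed to [resolveCopies()].
#' @return a [MarkerAlignment-class].
#' @export
readMarkerAlignment <- function(path, markerId = NULL, resolve = TRUE,
        overlapTolerance = 0.1) {
    if (!file.exists(path)) stop(sprintf("alignment not found: %s", path))
    if (is.null(markerId))
        markerId <- sub("\\.[^.]*$", "", basename(path))
    x <- Biostrings::readAAStringSet(path)
    rows <- toupper(as.character(x))
    genome <- sub("\\|.*$", "", names(rows))
    if (anyDuplicated(genome)) {
        if (!resolve)
            stop(sprintf("duplicate genome row(s) in marker '%s': %s",
                markerId, paste(unique(genome[duplicated(genome)]),
                    collapse = ", ")))
        resolved <- vapply(unique(genome), function(g)
            resolveCopies(unname(rows[genome == g]),
                overlapTolerance = overlapTolerance), "")
        rows <- resolved
    } else {
        names(rows) <- genome
    }
    MarkerAlignment(markerId, rows)
}

#' Resolve multiple aligned copies of one marker in one genome
#'
#' All candidates are aligned to the same model columns. If the candidates
#' occupy disjoint column ranges (their pairwise non-gap overlap is at most
#' `overlapTolerance` times the smaller candidate's non-gap length) they are
#' fragments of a split protein and are merged column-wise into one
#' sequence. Otherwise they are overlapping copies and the one covering the
#' most non-gap columns is retained (ties: first input). A single candidate
#' is returned unchanged; an empty input yields `NA` (marker absent).
#'
#' @param candidates character vector of equal-length aligned strings.
#' @param overlapTolerance fraction of the smaller fragment's non-gap length
#'   tolerated as overlap while still merging (default 0.1; ragged fragment
#'   ends make exact disjointness unrealistic).
#' @return a single aligned string, or `NA_character_` for empty input.
#' @export
resolveCopies <- function(candidates, overlapTolerance = 0.1) {
    candidates <- candidates[!is.na(candidates)]
    if (!length(candidates)) return(NA_character_)
    if (length(unique(nchar(candidates))) != 1L)
        stop("candidates must be aligned to the same model columns")
    if (length(candidates) == 1L) return(candidates[[1L]])
    chars <- strsplit(candidates, "")
    nongap <- lapply(chars, function(x) x != "-")
    counts <- vapply(nongap, sum, 0L)
    disjoint <- TRUE
    for (i in seq_len(length(candidates) - 1L)) {
        for (j in seq((i + 1L), length(candidates))) {
            overlap <- sum(nongap[[i]] & nongap[[j]])
            if (overlap > overlapTolerance * min(counts[i], counts[j])) {
                disjoint <- FALSE
                break
            }
        }
        if (!disjoint) break
    }
    if (disjoint) {
        # split protein: merge column-wise; earlier fragment wins conflicts
        merged <- rep("-", nchar(candidates[[1L]]))
        for (i in rev(seq_along(candidates)))
            merged[nongap[[i]]] <- chars[[i]][nongap[[i]]]
        paste(merged, collapse = "")
    } else {
        candidates[[which.max(counts)]]
    }
}

#' Remove high-gap alignment columns
#'
#' With `semantics = "gap_fraction"` (default) every column whose gap
#' fraction exceeds `maxGapFraction` is removed — so an "X% masking" of 0.9
#' is permissive, removing only columns that are >90% gaps. With
#' `semantics = "occupancy"` the same number is read as a minimum
#' occupancy: only columns whose non-gap fraction is at least
#' `maxGapFraction` are kept, which at 0.9 is stringent. Both readings of
#' a percent-masking parameter occur in practice; the default follows the
#' gap-fraction convention. Row order is preserved. Idempotent.
#'
#' @param aln a [MarkerAlignment-class].
#' @param maxGapFraction threshold in `[0, 1]` (0.5 reproduces the usual
#'   50% gap mask).
#' @param semantics see above.
#' @return a masked [MarkerAlignment-class].
#' @export
maskColumns <- function(aln, maxGapFraction = 0.5,
        semantics = c("gap_fraction", "occupancy")) {
    stopifnot(methods::is(aln, "MarkerAlignment"),
        maxGapFraction >= 0, maxGapFraction <= 1)
    semantics <- match.arg(semantics)
    if (!length(aln@rows)) return(aln)
    m <- do.call(rbind, strsplit(aln@rows, ""))
    gapfrac <- colMeans(m == "-")
    keep <- if (semantics == "gap_fraction") gapfrac <= maxGapFraction else
        (1 - gapfrac) >= maxGapFraction
    rows <- apply(m[, keep, drop = FALSE], 1L, paste, collapse = "")
    names(rows) <- names(aln@rows)
    MarkerAlignment(aln@markerId, rows)
}

#' Concatenate marker alignments into a supermatrix
#'
#' Markers are concatenated in the given order; a genome missing a marker is
#' padded with gaps across that partition. Genomes present in fewer than
#' `minMarkers` alignments are dropped (their ids are reported in the
#' `dropped` attribute). A duplicate genome row within one marker is an
#' error — copies must be resolved first.
#'
#' @param alignments ordered list of [MarkerAlignment-class].
#' @param genomes genome ids to include (default: union over alignments).
#' @param minMarkers minimum number of markers a genome must carry
#'   (default 8, i.e. half of the classic 16-marker ribosomal set).
#' @return a [Supermatrix-class] with attribute `dropped`.
#' @export
concatenateMarkers <- function(alignments, genomes = NULL, minMarkers = 8L) {
    stopifnot(length(alignments) >= 1L)
    for (aln in alignments)
        stopifnot(methods::is(aln, "MarkerAlignment"))
    ids <- names(alignments)
    if (is.null(ids)) {
        ids <- vapply(alignments, function(a) a@markerId, "")
        names(alignments) <- ids
    }
    if (anyDuplicated(ids)) stop("duplicate marker ids")
    if (is.null(genomes))
        genomes <- sort(unique(unlist(lapply(alignments,
            function(a) names(a@rows)))))
    n_markers <- vapply(genomes, function(g)
        sum(vapply(alignments, function(a) g %in% names(a@rows), TRUE)), 0L)
    dropped <- genomes[n_markers < minMarkers]
    if (length(dropped))
        message(sprintf("dropping %d genome(s) with < %d markers: %s",
            length(dropped), minMarkers,
            paste(utils::head(dropped, 5), collapse = ", ")))
    genomes <- genomes[n_markers >= minMarkers]
    lens <- vapply(alignments, function(a)
        if (length(a@rows)) nchar(a@rows[[1L]]) else 0L, 0L)
    ends <- cumsum(lens)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    partitions <- data.frame(marker = ids, start = as.integer(starts),
        end = as.integer(ends), stringsAsFactors = FALSE)
    rows <- vapply(genomes, function(g) {
        paste(vapply(seq_along(alignments), function(i) {
            a <- alignments[[i]]
            if (g %in% names(a@rows)) a@rows[[g]] else
                strrep("-", lens[i])
        }, ""), collapse = "")
    }, "")
    sm <- methods::new("Supermatrix", rows = rows, partitions = partitions)
    attr(sm, "dropped") <- dropped
    sm
}

#' Split a supermatrix back into per-marker alignments
#'
#' Inverse of [concatenateMarkers()] over the retained genomes: extracting
#' each partition recovers the masked marker rows (gap padding where a
#' genome lacked the marker).
#'
#' @param sm a [Supermatrix-class].
#' @return named list of [MarkerAlignment-class].
#' @export
splitSupermatrix <- function(sm) {
    stopifnot(methods::is(sm, "Supermatrix"))
    out <- lapply(seq_len(nrow(sm@partitions)), function(i) {
        p <- sm@partitions[i, ]
        MarkerAlignment(p$marker, vapply(sm@rows, substr, "", p$start, p$end))
    })
    names(out) <- sm@partitions$marker
    out
}

#' Write a supermatrix as aligned FASTA
#'
#' @param sm a [Supermatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSupermatrix <- function(sm, path) {
    x <- Biostrings::AAStringSet(sm@rows)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Write a RAxML-style partition file
#'
#' One line per marker: `PROT, <marker> = <start>-<end>`.
#'
#' @param sm a [Supermatrix-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePartitions <- function(sm, path) {
    p <- sm@partitions
    writeLines(sprintf("PROT, %s = %d-%d", p$marker, p$start, p$end), path)
    invisible(path)
}
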