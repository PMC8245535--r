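#' Classify samples into depth zones
#'
#' Oxygen-saturation zonation of a stratified water column, parameterized by
#' depth bounds: `oxic` below `oxicMax` metres of depth, `sub_oxic` from
#' there to `suboxMax`, `anoxic` deeper. The defaults (50 / 120 m) reflect a
#' steep oxycline between ~50 and ~100 m with 0% saturation around 100 m;
#' both bounds are configuration, not constants.
#'
#' @param depth numeric depths in metres (>= 0), or a data.frame with a
#'   `depth_m` column.
#' @param oxicMax upper bound of the oxic zone (exclusive), default 50.
#' @param suboxMax upper bound of the sub-oxic zone (exclusive), default 120.
#' @return factor with levels oxic, sub_oxic, anoxic.
#' @export
#' @examples
#' classifyZone(c(0, 80, 1200))
classifyZone <- function(depth, oxicMax = 50, suboxMax = 120) {
    if (is.data.frame(depth)) depth <- depth$depth_m
    if (any(is.na(depth)) || any(depth < 0)) stop("depth must be >= 0")
    factor(ifelse(depth < oxicMax, "oxic",
        ifelse(depth < suboxMax, "sub_oxic", "anoxic")),
        levels = c("oxic", "sub_oxic", "anoxic"))
}

#' Per-reaction genome counts and community abundance
#'
#' For each reaction: the number of genomes in the whole set with the
#' capability (`n_genomes`, a global count over the dereplicated set), and
#' per requested sample the summed RAR of those genomes (`rar_<sample>`,
#' percent). A per-sample detected-genome count (`n_detected_<sample>`,
#' capable genomes with RAR > 0) is also emitted.
#'
#' @param fm genome x reaction 0/1 matrix from [buildFunctionMatrix()].
#' @param rar genome x sample percent matrix from [toRAR()]; must share
#'   genome ids with `fm`.
#' @param samples sample ids to profile (default: all columns of `rar`).
#' @param cycles optional named character (reaction id -> cycle) used to
#'   annotate rows; taken from `pathways$reactions` when given a
#'   [readPathways()] result.
#' @return data.frame, one row per reaction.
#' @export
reactionProfile <- function(fm, rar, samples = colnames(rar),
        cycles = NULL) {
    common <- intersect(rownames(fm), rownames(rar))
    if (!length(common)) stop("fm and rar share no genome ids")
    missing <- setdiff(samples, colnames(rar))
    if (length(missing))
        stop(sprintf("sample(s) absent from RAR matrix: %s",
            paste(missing, collapse = ", ")))
    fm <- fm[common, , drop = FALSE]
    rar <- rar[common, , drop = FALSE]
    if (methods::is(cycles, "list") && !is.null(cycles$reactions))
        cycles <- vapply(cycles$reactions, `[[`, "", "cycle")
    out <- data.frame(reaction_id = colnames(fm), stringsAsFactors = FALSE)
    out$cycle <- if (is.null(cycles)) NA_character_ else
        unname(cycles[out$reaction_id])
    out$n_genomes <- as.integer(colSums(fm))
    for (s in samples) {
        out[[paste0("rar_", s)]] <- as.vector(crossprod(fm, rar[, s]))
        out[[paste0("n_detected_", s)]] <-
            as.integer(colSums(fm == 1L & rar[, s] > 0))
    }
    out
}

#' Presence/absence of reactions within taxonomic groups
#'
#' A taxon has a reaction iff at least one member genome has it — the
#' filled/open circle summary of capabilities across selected taxa.
#'
#' @param fm genome x reaction 0/1 matrix.
#' @param taxonomy named character (genome id -> taxon label), or a
#'   GenomeSet plus `groupBy`.
#' @param taxa taxa to report (default: all observed labels); an unknown
#'   taxon is an error.
#' @param reactions reactions to report (default: all columns of `fm`).
#' @param groupBy taxonomy column when `taxonomy` is a GenomeSet.
#' @return integer 0/1 matrix taxon x reaction.
#' @export
taxonFunctionPresence <- function(fm, taxonomy, taxa = NULL,
        reactions = colnames(fm), groupBy = NULL) {
    if (methods::is(taxonomy, "GenomeSet")) {
        if (is.null(groupBy)) stop("groupBy required with a GenomeSet")
        taxonomy <- taxonomy(taxonomy, groupBy)
    }
    lab <- taxonomy[rownames(fm)]
    observed <- unique(as.character(lab[!is.na(lab)]))
    if (is.null(taxa)) taxa <- sort(observed)
    unknown <- setdiff(taxa, observed)
    if (length(unknown))
        stop(sprintf("unknown taxon/taxa: %s", paste(unknown, collapse = ", ")))
    bad <- setdiff(reactions, colnames(fm))
    if (length(bad))
        stop(sprintf("unknown reaction(s): %s", paste(bad, collapse = ", ")))
    out <- matrix(0L, length(taxa), length(reactions),
        dimnames = list(taxa, reactions))
    for (tx in taxa) {
        members <- rownames(fm)[!is.na(lab) & lab == tx]
        out[tx, ] <- as.integer(colSums(fm[members, reactions,
            drop = FALSE]) > 0)
    }
    out
}

#' Write a reaction profile table
#'
#' @param profile data.frame from [reactionProfile()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReactionProfile <- function(profile, path) {
    utils::write.table(profile, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
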