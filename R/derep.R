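#' Greedy dereplication of genomes into ANI clusters
#'
#' Genomes are ranked by a quality score (default
#' \eqn{completeness - 5 \times contamination}, the dRep-style default;
#' weights configurable). The highest-scoring unassigned genome founds a
#' cluster and becomes its representative; every unassigned genome with
#' ANI >= `aniThreshold` to that representative joins the cluster. Ties in
#' score are broken by larger genome size, then lexicographic genome id.
#'
#' @param genomes a [GenomeSet-class] (completeness/contamination must be
#'   known for scoring; unknown values score as 0 with a warning).
#' @param ani an [ANIMatrix-class] covering all genomes.
#' @param aniThreshold cluster-joining threshold percent (default 99).
#' @param scoreWeights numeric `c(completeness, contamination)` weights,
#'   default `c(1, -5)`.
#' @return a [ClusterSet-class].
#' @export
dereplicate <- function(genomes, ani, aniThreshold = 99,
        scoreWeights = c(completeness = 1, contamination = -5)) {
    stopifnot(methods::is(genomes, "GenomeSet"), methods::is(ani, "ANIMatrix"))
    ids <- genomeIds(genomes)
    v <- aniValues(ani)
    if (!all(ids %in% rownames(v)))
        stop("ANI matrix does not cover all genomes")
    cm <- completeness(genomes)
    ct <- contamination(genomes)
    if (any(is.na(cm) | is.na(ct))) {
        warning("unknown completeness/contamination scored as 0")
        cm[is.na(cm)] <- 0
        ct[is.na(ct)] <- 0
    }
    score <- scoreWeights[[1L]] * cm + scoreWeights[[2L]] * ct
    sizes <- genomeSizes(genomes)
    ord <- ids[order(-score[ids], -sizes[ids], ids)]
    cluster <- stats::setNames(rep(NA_character_, length(ids)), ids)
    rep_of <- character()
    for (g in ord) {
        if (!is.na(cluster[[g]])) next
        cid <- sprintf("cluster_%03d", length(rep_of) + 1L)
        rep_of[[cid]] <- g
        cluster[[g]] <- cid
        mates <- ids[is.na(cluster) & !is.na(v[g, ids]) &
            v[g, ids] >= aniThreshold]
        cluster[mates] <- cid
    }
    members <- data.frame(genome_id = ids, cluster_id = unname(cluster[ids]),
        is_representative = ids %in% rep_of, score = unname(score[ids]),
        stringsAsFactors = FALSE)
    methods::new("ClusterSet", members = members,
        threshold = aniThreshold)
}

#' Write a ClusterSet as a table
#'
#' @param clusters a [ClusterSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeClusterSet <- function(clusters, path) {
    utils::write.table(clusterMembers(clusters), path, sep = "\t",
        quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Cross-group ANI comparison (e.g. two lakes)
#'
#' Splits all genome pairs by group label into within-A, within-B and cross
#' categories and summarises each: mean ANI over non-self pairs at or above
#' the floor (below-floor pairs and self-pairs are excluded), a histogram in
#' fixed 0.5-percentage-point bins, the maximum cross-group pair, and counts
#' of pairs above reference thresholds (75% and 97%).
#'
#' @param ani an [ANIMatrix-class].
#' @param labels named character/factor (genome id -> group); exactly two
#'   distinct groups.
#' @return list with elements `groups` (the two labels), `means` (named:
#'   within each group and `cross`; `NA` when a category has no eligible
#'   pair), `histogram` (data.frame category, bin_low, bin_high, count),
#'   `max_cross` (list genome_a, genome_b, ani), `counts_above` (matrix
#'   category x threshold).
#' @export
compareGroups <- function(ani, labels) {
    v <- aniValues(ani)
    ids <- rownames(v)
    if (!all(ids %in% names(labels)))
        stop(sprintf("unlabeled genome(s): %s",
            paste(utils::head(setdiff(ids, names(labels)), 5),
                collapse = ", ")))
    lab <- as.character(labels[ids])
    groups <- sort(unique(lab))
    if (length(groups) != 2L)
        stop("compareGroups expects exactly two groups")
    idx <- which(upper.tri(v), arr.ind = TRUE)
    pair <- data.frame(a = ids[idx[, 1L]], b = ids[idx[, 2L]],
        ani = v[idx], la = lab[idx[, 1L]], lb = lab[idx[, 2L]])
    pair$category <- ifelse(pair$la == pair$lb,
        paste0("within_", pair$la), "cross")
    eligible <- pair[!is.na(pair$ani), , drop = FALSE]
    cats <- c(paste0("within_", groups), "cross")
    means <- vapply(cats, function(ca) {
        x <- eligible$ani[eligible$category == ca]
        if (length(x)) mean(x) else NA_real_
    }, 0)
    bins <- seq(floor(aniFloor(ani) / 0.5) * 0.5, 100, by = 0.5)
    hist_list <- lapply(cats, function(ca) {
        x <- eligible$ani[eligible$category == ca]
        cut_idx <- findInterval(x, bins, rightmost.closed = TRUE)
        counts <- tabulate(cut_idx, nbins = length(bins) - 1L)
        data.frame(category = ca, bin_low = bins[-length(bins)],
            bin_high = bins[-1L], count = counts)
    })
    cross <- eligible[eligible$category == "cross", , drop = FALSE]
    max_cross <- if (nrow(cross)) {
        i <- which.max(cross$ani)
        list(genome_a = cross$a[i], genome_b = cross$b[i], ani = cross$ani[i])
    } else list(genome_a = NA_character_, genome_b = NA_character_,
        ani = NA_real_)
    thresholds <- c(`75` = 75, `97` = 97)
    counts_above <- vapply(thresholds, function(th) vapply(cats,
        function(ca) sum(eligible$ani[eligible$category == ca] >= th), 0L),
        integer(length(cats)))
    list(groups = groups, means = means,
        histogram = do.call(rbind, hist_list), max_cross = max_cross,
        counts_above = counts_above)
}

#' Taxon overlap between two genome sets
#'
#' Compares the distinct taxon labels of two sets at one rank, optionally
#' after dropping low-abundance genomes, and reports the fraction of taxa
#' unique to each set and the shared labels (endemism summary).
#'
#' @param taxaA,taxaB per-genome taxon labels: a character vector, or a
#'   data.frame with a `rank` column.
#' @param rank column name when data.frames are given.
#' @param abundanceA,abundanceB optional per-genome abundances aligned with
#'   the labels.
#' @param minAbundance genomes below this abundance are dropped before
#'   comparing (default 0 = keep all).
#' @return list with `unique_a`, `unique_b` (fractions of each set's
#'   distinct taxa), `shared` (character vector), `taxa_a`, `taxa_b`.
#' @export
taxonOverlap <- function(taxaA, taxaB, rank = NULL, abundanceA = NULL,
        abundanceB = NULL, minAbundance = 0) {
    pick <- function(x, which) {
        if (is.data.frame(x)) {
            if (is.null(rank)) stop("rank required for data.frame input")
            if (!rank %in% colnames(x))
                stop(sprintf("rank '%s' absent from taxonomy table (%s)",
                    rank, which))
            x <- x[[rank]]
        }
        as.character(x)
    }
    ta <- pick(taxaA, "A")
    tb <- pick(taxaB, "B")
    if (!is.null(abundanceA)) ta <- ta[abundanceA >= minAbundance]
    if (!is.null(abundanceB)) tb <- tb[abundanceB >= minAbundance]
    sa <- unique(ta[!is.na(ta)])
    sb <- unique(tb[!is.na(tb)])
    shared <- intersect(sa, sb)
    list(unique_a = if (length(sa)) length(setdiff(sa, sb)) / length(sa)
            else NA_real_,
        unique_b = if (length(sb)) length(setdiff(sb, sa)) / length(sb)
            else NA_real_,
        shared = shared, taxa_a = sa, taxa_b = sb)
}
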