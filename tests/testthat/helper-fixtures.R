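# Shared fixtures and independent oracles used across test files.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
    replace = TRUE), collapse = "")

write_fasta <- function(path, seqs) {
    con <- file(path, "w")
    on.exit(close(con))
    for (nm in names(seqs))
        writeLines(c(paste0(">", nm), seqs[[nm]]), con)
    path
}

# a genome directory + metadata sidecar with chosen quality values
make_genome_dir <- function(dir, genomes, metadata = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(genomes))
        write_fasta(file.path(dir, paste0(id, ".fna")), genomes[[id]])
    if (!is.null(metadata)) {
        f <- file.path(dir, "metadata.tsv")
        write.table(metadata, f, sep = "\t", quote = FALSE,
            row.names = FALSE)
        attr(dir, "metadata") <- f
    }
    dir
}

# independent positional-identity oracle for the ANI estimator
positional_identity <- function(a, b) {
    x <- strsplit(a, "")[[1]]
    y <- strsplit(b, "")[[1]]
    stopifnot(length(x) == length(y))
    100 * mean(x == y)
}

# independent brute-force evaluation of an AND-of-OR-groups formula over a
# set of present genes (deliberately naive double loop)
brute_formula <- function(logic, present) {
    for (group in logic) {
        found <- FALSE
        for (gene in group) if (gene %in% present) found <- TRUE
        if (!found) return(0L)
    }
    1L
}

# brute-force soundness checker for greedy dereplication results
check_derep_sound <- function(clusters, ani_values, threshold) {
    m <- clusterMembers(clusters)
    reps <- m$genome_id[m$is_representative]
    rep_of <- setNames(
        m$genome_id[m$is_representative][match(unique(m$cluster_id),
            m$cluster_id[m$is_representative])], unique(m$cluster_id))
    # every non-representative joins a representative at >= threshold
    for (i in seq_len(nrow(m))) {
        if (m$is_representative[i]) next
        r <- rep_of[[m$cluster_id[i]]]
        a <- ani_values[m$genome_id[i], r]
        if (is.na(a) || a < threshold) return(FALSE)
    }
    # founding order = score desc (ties: id); an earlier representative must
    # be < threshold from every later one, else the later would have joined
    ord <- reps[order(-m$score[match(reps, m$genome_id)], reps)]
    if (length(ord) > 1L)
        for (i in seq_len(length(ord) - 1L))
            for (j in seq((i + 1L), length(ord))) {
                a <- ani_values[ord[i], ord[j]]
                if (!is.na(a) && a >= threshold) return(FALSE)
            }
    TRUE
}

# brute-force group means over all labeled non-self pairs
brute_group_means <- function(ani_values, labels) {
    ids <- rownames(ani_values)
    acc <- list()
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (j <= i) next
        v <- ani_values[i, j]
        if (is.na(v)) next
        la <- labels[[ids[i]]]; lb <- labels[[ids[j]]]
        key <- if (la == lb) paste0("within_", la) else "cross"
        acc[[key]] <- c(acc[[key]], v)
    }
    vapply(acc, mean, 0)
}

# tiny deterministic community for pipeline-level tests (fast: small
# genomes, few samples; structure identical to the default generator)
small_sim_config <- function() list(
    n_genomes = 16L, n_clusters = 3L, cluster_size = 3L,
    genome_length_range = c(4e4, 8e4), scaffolds_range = c(1L, 4L),
    depths = c(0, 100, 1200))
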