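.with_seed <- function(seed, expr) {
    # isolate the generator's RNG stream from the caller's; the seed promise
    # must be forced before the state snapshot or a seed drawn from the
    # caller's stream would be un-drawn by the restore
    force(seed)
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(if (exists(".Random.seed", envir = globalenv(),
            inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

#' Generate a random genome sequence
#'
#' IID nucleotides at a target GC content; deterministic for a given
#' (length, gc, seed).
#'
#' @param length sequence length in bp (>= 1).
#' @param gc target GC fraction in (0, 1).
#' @param seed integer seed.
#' @return a single character string of A/C/G/T.
#' @export
genGenome <- function(length, gc = 0.5, seed = 1L) {
    stopifnot(length >= 1)
    if (is.na(gc) || gc <= 0 || gc >= 1)
        stop("gc must be strictly between 0 and 1")
    .with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
        replace = TRUE, prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = ""))
}

#' Mutate a sequence to a target average nucleotide identity
#'
#' Each site is independently substituted with probability
#' `1 - targetANI/100` to one of the three other bases, chosen uniformly.
#' Length is preserved; non-ACGT characters are left untouched.
#'
#' @param seq nucleotide string.
#' @param targetANI percent in (0, 100].
#' @param seed integer seed.
#' @return mutated sequence string.
#' @export
evolveToANI <- function(seq, targetANI, seed = 1L) {
    stopifnot(targetANI > 0, targetANI <= 100)
    p <- 1 - targetANI / 100
    if (p == 0) return(seq)
    .with_seed(seed, {
        x <- strsplit(seq, "")[[1L]]
        bases <- c("A", "C", "G", "T")
        code <- match(x, bases)
        hit <- stats::runif(length(x)) < p & !is.na(code)
        n <- sum(hit)
        if (n) {
            offset <- sample.int(3L, n, replace = TRUE)
            x[hit] <- bases[((code[hit] - 1L + offset) %% 4L) + 1L]
        }
        paste(x, collapse = "")
    })
}

.sim_defaults <- function() list(
    n_genomes = 50L,
    n_clusters = 5L,           # planted multi-member ANI clusters ...
    cluster_size = 3L,         # ... of this size; the rest are singletons
    within_cluster_ani = 99.5,
    depths = c(0, 10, 50, 80, 120, 150, 600, 1200),
    noise_sigma = 0,           # multiplicative coverage noise
    genome_length_range = c(1e5, 5e5),
    gc_range = c(0.4, 0.6),
    scaffolds_range = c(2L, 10L),
    coverage_scale = 50,       # mean fold coverage at abundance 1, 1M reads
    guild_fractions = c(surface = 0.4, deep = 0.4, generalist = 0.2),
    surface_reactions = c("co2_fixation", "organic_carbon_oxidation"),
    deep_reactions = c("methanogenesis", "sulfite_reduction", "anammox"),
    background_prob = 0.15,    # per non-guild reaction, per genome
    decoy_rate = 3,            # Poisson mean of sub-cutoff decoy hits
    marker_ids = c("rpL2", "rpL3", "rpL4", "rpL5", "rpL6", "rpL14",
        "rpL15", "rpL16", "rpL18", "rpL22", "rpL24", "rpS3", "rpS8",
        "rpS10", "rpS17", "rpS19"),
    marker_length = 120L,
    split_fraction = 0.1,      # genome-marker pairs emitted as split copies
    duplicate_fraction = 0.1,  # ... emitted with a shorter duplicate
    gap_column_fraction = 0.2,
    pathways = NULL)           # default: the shipped definitions

.sim_taxa <- list(
    surface = data.frame(
        phylum = c("Cyanobacteria", "Actinobacteria", "Alphaproteobacteria",
            "Bacteroidetes", "Verrucomicrobia"),
        is_archaea = FALSE, is_cpr = FALSE, is_dpann = FALSE),
    deep = data.frame(
        phylum = c("Chlorobi", "Thaumarchaeota", "Euryarchaeota",
            "Desulfobacterota", "Pacearchaeota", "CP_Shapirobacteria"),
        is_archaea = c(FALSE, TRUE, TRUE, FALSE, TRUE, FALSE),
        is_cpr = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
        is_dpann = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)),
    generalist = data.frame(
        phylum = c("Chloroflexi", "Gammaproteobacteria", "Planctomycetes"),
        is_archaea = FALSE, is_cpr = FALSE, is_dpann = FALSE))

#' Simulate a depth-stratified lake community with full ground truth
#'
#' Generates a synthetic MAG set with planted ANI clusters, depth-niche
#' structured abundances, guild-linked metabolic capabilities, marker
#' alignments with split/duplicate copies, and emits every file dialect the
#' pipeline readers consume (genome FASTAs, metadata and sample tables,
#' long-format coverage, hit table, per-marker aligned FASTAs) together
#' with the truth tables and a JSON manifest.
#'
#' Each genome g gets a Gaussian depth niche: abundance at depth d is
#' proportional to \eqn{b_g \exp(-(d - \mu_g)^2 / (2\sigma_g^2))} with
#' log-normal baseline \eqn{b_g}, renormalized per sample. Surface-guild
#' genomes centre above the oxycline and carry the surface reactions;
#' deep-guild genomes centre in the anoxic zone and carry the deep
#' reactions; generalists span the column. Scaffold coverage is abundance
#' times a per-sample sequencing-depth factor times multiplicative Gaussian
#' noise (sd `noise_sigma`), floored at 0. Hit tables contain one
#' above-cutoff hit per required gene of every planted reaction plus decoy
#' hits at half the cutoff. Function truth is computed by the generator's
#' own closure over planted gene sets (independently of the pathway
#' engine).
#'
#' @param config named list overriding the defaults (see
#'   `lakecycle:::.sim_defaults()` for the full set: genome counts and
#'   lengths, planted cluster layout, depths, noise, guild composition,
#'   marker-alignment corruption rates).
#' @param seed integer seed; identical (config, seed) pairs produce
#'   byte-identical output files.
#' @param outDir directory to emit files into (created if needed); `NULL`
#'   skips file emission.
#' @return a [SyntheticTruth-class].
#' @export
simulateCommunity <- function(config = list(), seed = 1L, outDir = NULL) {
    cfg <- utils::modifyList(.sim_defaults(), config)
    if (length(cfg$depths) == 0L) stop("config needs at least one sample depth")
    if (cfg$n_genomes < 1L) stop("config needs at least one genome")
    n_clustered <- cfg$n_clusters * cfg$cluster_size
    if (n_clustered > cfg$n_genomes)
        stop("planted clusters exceed n_genomes")
    pathways <- if (is.null(cfg$pathways)) readPathways(lakecyclePathways())
        else cfg$pathways
    .with_seed(seed, {
        truth <- .sim_build(cfg, pathways)
        files <- if (is.null(outDir)) character() else
            .sim_emit(truth, cfg, outDir, seed)
    })
    methods::new("SyntheticTruth", genomes = truth$genomes,
        abundance = truth$abundance, functions = truth$functions,
        clusters = truth$clusters, guilds = truth$guilds,
        samples = truth$samples, files = files, seed = as.integer(seed),
        config = cfg)
}

.sim_build <- function(cfg, pathways) {
    n <- cfg$n_genomes
    ids <- sprintf("g%03d", seq_len(n))
    ## planted ANI clusters: first n_clusters*cluster_size genomes come in
    ## groups mutated from a shared base at within_cluster_ani; the rest are
    ## independent (between-cluster identity ~ background, far below 95%)
    cluster_of <- character(n)
    k <- 0L
    for (cl in seq_len(cfg$n_clusters))
        for (m in seq_len(cfg$cluster_size)) {
            k <- k + 1L
            cluster_of[k] <- sprintf("p%02d", cl)
        }
    if (k < n) cluster_of[(k + 1L):n] <- sprintf("p%02d",
        cfg$n_clusters + seq_len(n - k))
    ## guilds, then niches
    guild_pool <- rep(names(cfg$guild_fractions),
        times = round(cfg$guild_fractions * n))
    guild_pool <- c(guild_pool, rep("generalist", max(0, n -
        length(guild_pool))))[seq_len(n)]
    ## members of one planted cluster share guild and taxonomy
    guilds <- character(n)
    phyla <- character(n)
    flags <- matrix(FALSE, n, 3L,
        dimnames = list(ids, c("is_archaea", "is_cpr", "is_dpann")))
    seen <- new.env()
    shuffled <- sample(guild_pool)
    for (i in seq_len(n)) {
        cl <- cluster_of[i]
        if (!is.null(seen[[cl]])) {
            guilds[i] <- seen[[cl]]$guild
            phyla[i] <- seen[[cl]]$phylum
            flags[i, ] <- seen[[cl]]$flags
        } else {
            guilds[i] <- shuffled[i]
            tx <- .sim_taxa[[guilds[i]]]
            row <- tx[sample.int(nrow(tx), 1L), ]
            phyla[i] <- row$phylum
            flags[i, ] <- c(row$is_archaea, row$is_cpr, row$is_dpann)
            seen[[cl]] <- list(guild = guilds[i], phylum = phyla[i],
                flags = flags[i, ])
        }
    }
    ## sequences
    lens <- round(stats::runif(n, cfg$genome_length_range[1L],
        cfg$genome_length_range[2L]))
    gcs <- stats::runif(n, cfg$gc_range[1L], cfg$gc_range[2L])
    base_seq <- new.env()
    seqs <- character(n)
    for (i in seq_len(n)) {
        cl <- cluster_of[i]
        sd <- sample.int(.Machine$integer.max, 1L)
        if (is.null(base_seq[[cl]])) {
            seqs[i] <- genGenome(lens[i], gcs[i], seed = sd)
            base_seq[[cl]] <- seqs[i]
        } else {
            # half the divergence per derived member: pairwise identity
            # between any two cluster members then sits at the target ANI
            seqs[i] <- evolveToANI(base_seq[[cl]],
                (100 + cfg$within_cluster_ani) / 2, seed = sd)
        }
    }
    ## scaffold splits
    sequences <- vector("list", n)
    names(sequences) <- ids
    for (i in seq_len(n)) {
        L <- nchar(seqs[i])
        n_scaf <- sample(seq(cfg$scaffolds_range[1L],
            cfg$scaffolds_range[2L]), 1L)
        n_scaf <- min(n_scaf, max(1L, L %/% 1000L))
        cuts <- sort(sample.int(L - 1L, n_scaf - 1L))
        starts <- c(1L, cuts + 1L)
        ends <- c(cuts, L)
        sc <- substring(seqs[i], starts, ends)
        names(sc) <- sprintf("%s_s%02d", ids[i], seq_along(sc))
        sequences[[i]] <- sc
    }
    metadata <- data.frame(genome_id = ids,
        completeness = round(stats::runif(n, 55, 100), 1),
        contamination = round(stats::runif(n, 0, 9.5), 1),
        domain = ifelse(flags[, "is_archaea"], "Archaea", "Bacteria"),
        phylum = phyla, lineage = phyla,
        is_cpr = flags[, "is_cpr"], is_dpann = flags[, "is_dpann"],
        is_archaea = flags[, "is_archaea"],
        source_label = "Tanganyika_sim", stringsAsFactors = FALSE)
    genomes <- GenomeSet(sequences, metadata = metadata)
    ## niches and abundances
    depths <- cfg$depths
    mu <- numeric(n); sig <- numeric(n)
    for (i in seq_len(n)) {
        if (guilds[i] == "surface") {
            mu[i] <- stats::runif(1, 0, 60); sig[i] <- stats::runif(1, 30, 80)
        } else if (guilds[i] == "deep") {
            mu[i] <- stats::runif(1, 500, 1200)
            sig[i] <- stats::runif(1, 100, 400)
        } else {
            mu[i] <- stats::runif(1, 0, 1200)
            sig[i] <- stats::runif(1, 400, 800)
        }
    }
    base <- stats::rlnorm(n, 0, 1)
    samples <- data.frame(
        sample_id = sprintf("KigCas%d", round(depths)),
        station = "Kigoma", depth_m = depths, date = "2015-07-25",
        total_reads = round(stats::runif(length(depths), 2e7, 8e7)),
        stringsAsFactors = FALSE)
    ab <- outer(seq_len(n), seq_along(depths), function(i, s)
        base[i] * exp(-(depths[s] - mu[i])^2 / (2 * sig[i]^2)))
    dimnames(ab) <- list(ids, samples$sample_id)
    ab <- sweep(ab, 2L, colSums(ab), `/`)
    ## planted functions: guild reactions + background over the rest
    rxn <- names(pathways$reactions)
    guild_rxn <- list(surface = intersect(cfg$surface_reactions, rxn),
        deep = intersect(cfg$deep_reactions, rxn), generalist = character())
    other <- setdiff(rxn, c(cfg$surface_reactions, cfg$deep_reactions,
        "comammox"))  # comammox only ever arises via amo+nxr gene sets
    planted <- matrix(0L, n, length(rxn), dimnames = list(ids, rxn))
    for (i in seq_len(n)) {
        planted[i, guild_rxn[[guilds[i]]]] <- 1L
        bg <- other[stats::runif(length(other)) < cfg$background_prob]
        planted[i, bg] <- 1L
    }
    ## gene sets: one gene per OR-group of each planted reaction
    genes <- stats::setNames(vector("list", n), ids)
    for (i in seq_len(n)) {
        g <- character()
        for (r in rxn[planted[i, ] == 1L])
            for (group in pathways$reactions[[r]]$logic)
                g <- c(g, group[sample.int(length(group), 1L)])
        genes[[i]] <- unique(g)
    }
    ## function truth: generator's own closure over the planted gene sets
    functions <- matrix(0L, n, length(rxn), dimnames = list(ids, rxn))
    for (i in seq_len(n))
        for (r in rxn)
            functions[i, r] <- as.integer(all(vapply(
                pathways$reactions[[r]]$logic,
                function(group) any(group %in% genes[[i]]), TRUE)))
    list(genomes = genomes, abundance = ab, functions = functions,
        clusters = stats::setNames(cluster_of, ids),
        guilds = stats::setNames(guilds, ids), samples = samples,
        genes = genes, pathways = pathways)
}

.sim_emit <- function(truth, cfg, outDir, seed) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (d in c("genomes", "markers", "truth"))
        dir.create(file.path(outDir, d), showWarnings = FALSE)
    files <- character()
    genomes <- truth$genomes
    ids <- genomeIds(genomes)
    for (id in ids) {
        f <- file.path(outDir, "genomes", paste0(id, ".fna"))
        Biostrings::writeXStringSet(scaffolds(genomes, id), f)
        files[paste0("genome_", id)] <- f
    }
    f <- file.path(outDir, "metadata.tsv")
    md <- as.data.frame(genomes@metadata)
    md <- data.frame(genome_id = ids, md[setdiff(colnames(md),
        "genome_size")], stringsAsFactors = FALSE)
    utils::write.table(md, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files["metadata"] <- f
    f <- file.path(outDir, "samples.tsv")
    utils::write.table(truth$samples, f, sep = "\t", quote = FALSE,
        row.names = FALSE)
    files["samples"] <- f
    ## coverage: per-scaffold mean fold = abundance x depth factor x noise
    entries <- list(); lengths <- numeric(); s2g <- character()
    for (i in seq_along(ids)) {
        sc <- scaffolds(genomes, ids[i])
        lens <- stats::setNames(Biostrings::width(sc), names(sc))
        lengths <- c(lengths, lens)
        s2g <- c(s2g, stats::setNames(rep(ids[i], length(sc)), names(sc)))
        for (s in seq_len(nrow(truth$samples))) {
            depth_factor <- truth$samples$total_reads[s] / 1e6 *
                cfg$coverage_scale
            cov <- truth$abundance[ids[i], s] * depth_factor
            noise <- if (cfg$noise_sigma > 0)
                pmax(0, 1 + stats::rnorm(length(sc), 0, cfg$noise_sigma))
                else rep(1, length(sc))
            entries[[length(entries) + 1L]] <- data.frame(
                scaffold = names(sc),
                sample = truth$samples$sample_id[s],
                coverage = cov * noise, stringsAsFactors = FALSE)
        }
    }
    cov <- methods::new("CoverageTable",
        entries = do.call(rbind, entries), lengths = lengths,
        scaffoldToGenome = s2g)
    f <- file.path(outDir, "coverage.tsv")
    writeCoverageTable(cov, f)
    files["coverage"] <- f
    f <- file.path(outDir, "scaffold_map.tsv")
    utils::write.table(data.frame(scaffold = names(s2g),
        genome = unname(s2g)), f, sep = "\t", quote = FALSE,
        row.names = FALSE)
    files["scaffold_map"] <- f
    ## hit table: planted genes above cutoff + decoys at half cutoff
    pw <- truth$pathways
    all_models <- unique(unlist(lapply(pw$reactions, function(r)
        unlist(r$logic))))
    cutoff_of <- .model_cutoff(all_models, pw$cutoffs, pw$default_cutoff)
    rows <- list()
    for (id in ids) {
        p <- 0L
        for (gene in truth$genes[[id]]) {
            p <- p + 1L
            alen <- sample(80:120, 1L)
            rows[[length(rows) + 1L]] <- data.frame(genome_id = id,
                protein_id = sprintf("%s_p%03d", id, p), model_id = gene,
                bit_score = 2 * cutoff_of[[gene]],
                e_value = 10^(-stats::runif(1, 20, 60)), model_from = 1L,
                model_to = alen, ali_length = alen)
        }
        n_decoy <- stats::rpois(1L, cfg$decoy_rate)
        for (d in seq_len(n_decoy)) {
            p <- p + 1L
            gene <- all_models[sample.int(length(all_models), 1L)]
            alen <- sample(40:80, 1L)
            rows[[length(rows) + 1L]] <- data.frame(genome_id = id,
                protein_id = sprintf("%s_p%03d", id, p), model_id = gene,
                bit_score = 0.5 * cutoff_of[[gene]],
                e_value = 10^(-stats::runif(1, 2, 8)), model_from = 1L,
                model_to = alen, ali_length = alen)
        }
    }
    f <- file.path(outDir, "hits.tsv")
    writeHitTable(do.call(rbind, rows), f)
    files["hits"] <- f
    ## marker alignments with planted gap columns, split and duplicate copies
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
    for (m in cfg$marker_ids) {
        L <- cfg$marker_length
        ancestral <- sample(aa, L, replace = TRUE)
        gap_cols <- which(stats::runif(L) < cfg$gap_column_fraction)
        out <- character(); headers <- character()
        for (id in ids) {
            row <- ancestral
            subst <- stats::runif(L) < 0.1
            row[subst] <- sample(aa, sum(subst), replace = TRUE)
            if (length(gap_cols)) {
                gappy <- gap_cols[stats::runif(length(gap_cols)) < 0.5]
                row[gappy] <- "-"
            }
            u <- stats::runif(1)
            if (u < cfg$split_fraction) {
                cut <- sample(seq(L %/% 3, 2 * L %/% 3), 1L)
                frag1 <- row; frag1[(cut + 1L):L] <- "-"
                frag2 <- row; frag2[1:cut] <- "-"
                headers <- c(headers, paste0(id, "|1"), paste0(id, "|2"))
                out <- c(out, paste(frag1, collapse = ""),
                    paste(frag2, collapse = ""))
            } else if (u < cfg$split_fraction + cfg$duplicate_fraction) {
                trunc <- row
                keep_to <- sample(seq(L %/% 2, L - 10L), 1L)
                trunc[(keep_to + 1L):L] <- "-"
                headers <- c(headers, paste0(id, "|1"), paste0(id, "|2"))
                out <- c(out, paste(row, collapse = ""),
                    paste(trunc, collapse = ""))
            } else {
                headers <- c(headers, id)
                out <- c(out, paste(row, collapse = ""))
            }
        }
        f <- file.path(outDir, "markers", paste0(m, ".fasta"))
        Biostrings::writeXStringSet(
            Biostrings::AAStringSet(stats::setNames(out, headers)), f)
        files[paste0("marker_", m)] <- f
    }
    ## truth bundle
    f <- file.path(outDir, "truth", "abundance.tsv")
    ab <- truth$abundance
    utils::write.table(data.frame(genome_id = rownames(ab),
        apply(ab, 2L, function(x) sprintf("%.17g", x)),
        check.names = FALSE), f, sep = "\t", quote = FALSE,
        row.names = FALSE)
    files["truth_abundance"] <- f
    f <- file.path(outDir, "truth", "functions.tsv")
    utils::write.table(data.frame(genome_id = rownames(truth$functions),
        truth$functions, check.names = FALSE), f, sep = "\t",
        quote = FALSE, row.names = FALSE)
    files["truth_functions"] <- f
    f <- file.path(outDir, "truth", "clusters.tsv")
    utils::write.table(data.frame(genome_id = ids,
        cluster = unname(truth$clusters[ids]),
        guild = unname(truth$guilds[ids])), f, sep = "\t", quote = FALSE,
        row.names = FALSE)
    files["truth_clusters"] <- f
    f <- file.path(outDir, "truth", "manifest.json")
    cfg_out <- cfg
    cfg_out$pathways <- NULL
    jsonlite::write_json(list(generator = "lakecycle::simulateCommunity",
        seed = seed, config = cfg_out), f, auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
    files["truth_manifest"] <- f
    files
}
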