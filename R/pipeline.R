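.pipeline_defaults <- function() list(
    min_completeness = 50, max_contamination = 10,
    sketch_k = 21L, sketch_size = 5000L, ani_floor = 75,
    ani_threshold = 99,
    coverage_mode = "sum", detection_floor = 0.01,
    oxic_max = 50, subox_max = 120,
    profile_samples = NULL)   # default: all samples

#' Run the full genome-resolved profiling pipeline
#'
#' Executes the stages in dependency order: read genomes and metadata ->
#' quality selection -> sketching and all-vs-all ANI -> greedy
#' dereplication -> genome coverage, read normalization and RAR (on the
#' representative set) -> function matrix from the hit table (plus optional
#' curation overrides) -> depth-zone classification and reaction profiles.
#' Every output table is written under `output` and listed in
#' `manifest.json` with md5 checksums, the configuration, the seed and the
#' package version; fixed inputs, config and seed give byte-identical
#' outputs.
#'
#' @param config a named list or path to a YAML file with elements `input`
#'   (paths: `genomes` dir, `metadata`, `samples`, `coverage` (long
#'   dialect), `scaffold_map`, `hits`; optional `pathways`, `overrides`),
#'   `output` (directory), optional `thresholds` (see
#'   `lakecycle:::.pipeline_defaults()`), optional `seed`.
#' @return invisibly, a list with `status` (0 on success), `manifest`
#'   (path) and `outputs` (named character of written files).
#' @export
runPipeline <- function(config) {
    if (is.character(config)) {
        if (!file.exists(config))
            stop(.missing_input(sprintf("config file not found: %s", config)))
        config <- yaml::read_yaml(config)
    }
    inp <- config$input
    if (is.null(inp) || is.null(config$output))
        stop("config needs 'input' and 'output'")
    need <- c("genomes", "metadata", "samples", "coverage", "scaffold_map",
        "hits")
    for (key in need) {
        p <- inp[[key]]
        if (is.null(p) || !file.exists(p))
            stop(.missing_input(sprintf("missing input '%s': %s", key,
                if (is.null(p)) "(not configured)" else p)))
    }
    th <- utils::modifyList(.pipeline_defaults(),
        if (is.null(config$thresholds)) list() else config$thresholds)
    seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
    outDir <- config$output
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    partial <- file.path(outDir, "RUN.partial")
    file.create(partial)  # removed on success; marks interrupted runs
    outputs <- character()

    genomes <- readGenomes(inp$genomes, metadata = inp$metadata)
    samples <- readSampleTable(inp$samples)
    kept <- qualityFilter(genomes, th$min_completeness,
        th$max_contamination)
    if (length(kept) < 2L)
        stop("fewer than two genomes pass quality selection")

    ani <- pairwiseANI(kept, k = th$sketch_k, sketchSize = th$sketch_size,
        floor = th$ani_floor)
    outputs["ani"] <- writeANIMatrix(ani, file.path(outDir, "ani.tsv"))
    clusters <- dereplicate(kept, ani, aniThreshold = th$ani_threshold)
    outputs["clusters"] <- writeClusterSet(clusters,
        file.path(outDir, "clusters.tsv"))
    reps <- kept[representatives(clusters)]

    cov <- readCoverageTable(inp$coverage, dialect = "long",
        scaffoldToGenome = inp$scaffold_map)
    keep_scaf <- cov@scaffoldToGenome[cov@scaffoldToGenome %in%
        genomeIds(reps)]
    cov@scaffoldToGenome <- keep_scaf
    gc <- genomeCoverage(cov, mode = th$coverage_mode,
        detectionFloor = th$detection_floor)
    rar <- toRAR(normalizeByReads(gc, samples))
    outputs["rar"] <- writeRAR(rar, file.path(outDir, "rar.tsv"),
        long = TRUE)

    pathways <- readPathways(if (is.null(inp$pathways)) lakecyclePathways()
        else inp$pathways)
    hits <- readHitTable(inp$hits)
    fm <- buildFunctionMatrix(hits, reps, pathways)
    if (!is.null(inp$overrides))
        fm <- applyOverrides(fm, hits, readOverrides(inp$overrides),
            pathways)
    outputs["function_matrix"] <- file.path(outDir, "function_matrix.tsv")
    utils::write.table(data.frame(genome_id = rownames(fm), fm,
        check.names = FALSE), outputs["function_matrix"], sep = "\t",
        quote = FALSE, row.names = FALSE)

    samples$zone <- as.character(classifyZone(samples$depth_m,
        th$oxic_max, th$subox_max))
    outputs["zones"] <- file.path(outDir, "zones.tsv")
    utils::write.table(samples, outputs["zones"], sep = "\t", quote = FALSE,
        row.names = FALSE)
    prof_samples <- if (is.null(th$profile_samples)) colnames(rar) else
        th$profile_samples
    profile <- reactionProfile(fm, rar, samples = prof_samples,
        cycles = pathways)
    outputs["reaction_profile"] <- writeReactionProfile(profile,
        file.path(outDir, "reaction_profile.tsv"))

    manifest_path <- file.path(outDir, "manifest.json")
    manifest <- list(
        package = "lakecycle",
        version = as.character(utils::packageVersion("lakecycle")),
        seed = seed,
        thresholds = th,
        inputs = as.list(unlist(inp)),
        outputs = lapply(stats::setNames(nm = names(outputs)), function(k)
            list(path = unname(outputs[[k]]),
                md5 = unname(tools::md5sum(outputs[[k]])))))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
        pretty = TRUE, digits = NA)
    unlink(partial)
    invisible(list(status = 0L, manifest = manifest_path,
        outputs = outputs))
}

.missing_input <- function(msg) {
    structure(class = c("lakecycle_missing_input", "error", "condition"),
        list(message = msg, call = NULL, status = 2L))
}
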