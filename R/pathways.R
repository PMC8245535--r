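#' Read pathway (reaction) definitions
#'
#' Structured YAML config. Top level: `default_cutoff` (global bit-score
#' floor applied to models without their own cutoff), `cutoffs` (mapping
#' model id -> trusted-cutoff bit score), and `reactions`, a list of entries
#' with `id`, `cycle` (carbon/nitrogen/sulfur/other), `label`, `substrate`,
#' `product`, and `logic`: a list of OR-groups (each a list of model ids),
#' combined by AND — a genome has the reaction iff every group contributes
#' at least one qualifying hit. The shipped default set
#' (`lakecyclePathways()`) covers the classic carbon/nitrogen/sulfur water
#' column reactions with METABOLIC-style marker genes; gene lists are
#' configuration, not code, and are meant to be edited.
#'
#' @param path YAML file.
#' @return list with `reactions` (named list of definitions), `cutoffs`
#'   (named numeric) and `default_cutoff`.
#' @export
readPathways <- function(path) {
    if (!file.exists(path)) stop(sprintf("pathway file not found: %s", path))
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg$reactions) || !length(cfg$reactions))
        stop("pathway file defines no reactions")
    reactions <- list()
    for (r in cfg$reactions) {
        if (is.null(r$id)) stop("reaction without id")
        if (is.null(r$logic) || !length(r$logic))
            stop(sprintf("reaction '%s' has empty logic", r$id))
        logic <- lapply(r$logic, function(g) as.character(unlist(g)))
        if (any(lengths(logic) == 0L))
            stop(sprintf("reaction '%s' has an empty OR-group", r$id))
        reactions[[r$id]] <- list(reaction_id = r$id,
            cycle = if (is.null(r$cycle)) "other" else r$cycle,
            label = if (is.null(r$label)) r$id else r$label,
            substrate = r$substrate, product = r$product, logic = logic)
    }
    cutoffs <- if (is.null(cfg$cutoffs)) numeric() else
        unlist(cfg$cutoffs)
    list(reactions = reactions, cutoffs = cutoffs,
        default_cutoff = if (is.null(cfg$default_cutoff)) NULL else
            as.numeric(cfg$default_cutoff))
}

#' Path of the shipped default pathway definition file
#'
#' @return file path of the packaged `pathways.yml`.
#' @export
lakecyclePathways <- function() {
    system.file("extdata", "pathways.yml", package = "lakecycle",
        mustWork = TRUE)
}

.model_cutoff <- function(models, cutoffs, default_cutoff) {
    out <- cutoffs[models]
    names(out) <- models
    miss <- is.na(out)
    if (any(miss)) {
        if (is.null(default_cutoff))
            stop(sprintf("no cutoff defined for model(s): %s",
                paste(models[miss], collapse = ", ")))
        out[miss] <- default_cutoff
    }
    out
}

#' Evaluate one reaction for one genome
#'
#' Implements the one-copy-per-gene rule: the reaction is present (1) iff
#' every AND-term (OR-group) of the definition's logic has at least one hit
#' whose bit score meets its model's cutoff; otherwise absent (0). Copy
#' number beyond one is irrelevant.
#'
#' @param hits data.frame of hit rows for one genome (columns `model_id`,
#'   `bit_score`).
#' @param pd one reaction definition (an element of
#'   `readPathways(...)$reactions`).
#' @param cutoffs named numeric of per-model trusted cutoffs.
#' @param defaultCutoff global bit-score floor for models without a cutoff;
#'   if `NULL`, a referenced model with no cutoff is an error.
#' @return integer 0 or 1.
#' @export
#' @examples
#' pw <- readPathways(lakecyclePathways())
#' hits <- data.frame(model_id = c("nifH", "nifD"), bit_score = c(200, 200))
#' evaluateReaction(hits, pw$reactions$nitrogen_fixation, pw$cutoffs,
#'     pw$default_cutoff)  # 0: nifK missing
evaluateReaction <- function(hits, pd, cutoffs = numeric(),
        defaultCutoff = 50) {
    present <- character()
    if (nrow(hits)) {
        cut <- .model_cutoff(unique(hits$model_id), cutoffs, defaultCutoff)
        ok <- hits$bit_score >= cut[hits$model_id]
        present <- unique(hits$model_id[ok])
    }
    # make sure every referenced model has a resolvable cutoff
    .model_cutoff(unique(unlist(pd$logic)), cutoffs, defaultCutoff)
    for (group in pd$logic)
        if (!any(group %in% present)) return(0L)
    1L
}

#' Build the genome x reaction function matrix
#'
#' Evaluates every reaction for every genome over a study-wide hit table,
#' producing the binary capability matrix. Deterministic and complete:
#' genomes with no hits get all-zero rows.
#'
#' @param hits hit table data.frame (from [readHitTable()]), columns
#'   `genome_id`, `model_id`, `bit_score`.
#' @param genomes a [GenomeSet-class] or character vector of genome ids.
#' @param pathways result of [readPathways()].
#' @return integer 0/1 matrix, rows = genomes, columns = reaction ids.
#' @export
buildFunctionMatrix <- function(hits, genomes, pathways) {
    ids <- if (methods::is(genomes, "GenomeSet")) genomeIds(genomes) else
        as.character(genomes)
    rxn <- names(pathways$reactions)
    fm <- matrix(0L, length(ids), length(rxn), dimnames = list(ids, rxn))
    split_hits <- split(hits[c("model_id", "bit_score")], hits$genome_id)
    for (g in ids) {
        h <- split_hits[[g]]
        if (is.null(h))
            h <- data.frame(model_id = character(), bit_score = numeric())
        for (r in rxn)
            fm[g, r] <- evaluateReaction(h, pathways$reactions[[r]],
                pathways$cutoffs, pathways$default_cutoff)
    }
    fm
}

#' Read a curation override table
#'
#' Tab-separated columns: `genome_id`, `target` (a model id for `relabel`, a
#' reaction id for forcing), `action` (`force_present`, `force_absent`,
#' `relabel`), `new_label`, `reason`. This mechanism reproduces manual
#' curations such as re-assigning ambiguous amoA/pmoA hits or annotating
#' nxr, without any phylogenetic machinery.
#'
#' @param path input file.
#' @return data.frame.
#' @export
readOverrides <- function(path) {
    if (!file.exists(path)) stop(sprintf("override table not found: %s", path))
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("genome_id", "target", "action")
    if (!all(need %in% colnames(d)))
        stop("override table needs genome_id, target, action")
    if (!"new_label" %in% colnames(d)) d$new_label <- NA_character_
    if (!"reason" %in% colnames(d)) d$reason <- NA_character_
    bad <- !d$action %in% c("force_present", "force_absent", "relabel")
    if (any(bad)) stop(sprintf("unknown override action '%s'",
        d$action[bad][1L]))
    if (any(d$action == "relabel" & (is.na(d$new_label) | d$new_label == "")))
        stop("relabel requires new_label")
    d
}

#' Apply curation overrides to a function matrix
#'
#' `relabel` changes the model id of the targeted genome's hits and
#' re-evaluates every reaction whose logic mentions the old or new model;
#' `force_present` / `force_absent` set cells directly. Every changed cell
#' is recorded in the `override_log` attribute (genome, reaction, old, new,
#' action, reason).
#'
#' @param fm function matrix from [buildFunctionMatrix()].
#' @param hits the hit table the matrix was built from.
#' @param overrides data.frame from [readOverrides()].
#' @param pathways result of [readPathways()].
#' @return the updated matrix with attribute `override_log`.
#' @export
applyOverrides <- function(fm, hits, overrides, pathways) {
    log <- list()
    rxn <- names(pathways$reactions)
    for (i in seq_len(nrow(overrides))) {
        o <- overrides[i, ]
        if (!o$genome_id %in% rownames(fm))
            stop(sprintf("override references unknown genome '%s'",
                o$genome_id))
        if (o$action == "relabel") {
            sel <- hits$genome_id == o$genome_id & hits$model_id == o$target
            if (!any(sel))
                stop(sprintf(
                    "override: genome '%s' has no hit for model '%s'",
                    o$genome_id, o$target))
            hits$model_id[sel] <- o$new_label
            affected <- rxn[vapply(pathways$reactions, function(pd)
                any(c(o$target, o$new_label) %in% unlist(pd$logic)), TRUE)]
            h <- hits[hits$genome_id == o$genome_id, , drop = FALSE]
            for (r in affected) {
                new <- evaluateReaction(h, pathways$reactions[[r]],
                    pathways$cutoffs, pathways$default_cutoff)
                if (new != fm[o$genome_id, r]) {
                    log[[length(log) + 1L]] <- data.frame(
                        genome_id = o$genome_id, reaction_id = r,
                        old = fm[o$genome_id, r], new = new,
                        action = "relabel", reason = o$reason)
                    fm[o$genome_id, r] <- new
                }
            }
        } else {
            if (!o$target %in% rxn)
                stop(sprintf("override references unknown reaction '%s'",
                    o$target))
            new <- if (o$action == "force_present") 1L else 0L
            if (new != fm[o$genome_id, o$target]) {
                log[[length(log) + 1L]] <- data.frame(
                    genome_id = o$genome_id, reaction_id = o$target,
                    old = fm[o$genome_id, o$target], new = new,
                    action = o$action, reason = o$reason)
                fm[o$genome_id, o$target] <- new
            }
        }
    }
    attr(fm, "override_log") <- if (length(log)) do.call(rbind, log) else
        data.frame(genome_id = character(), reaction_id = character(),
            old = integer(), new = integer(), action = character(),
            reason = character())
    fm
}

#' Per-genome CAZyme class counts and density
#'
#' Counts carbohydrate-active enzyme hits per CAZy class (GH, GT, PL, CE,
#' AA, CBM, from the family prefix) and computes the genome-size-normalized
#' density, hits per Mbp.
#'
#' @param cazymeHits data.frame with `genome_id` and `family` (e.g.
#'   "GH13", "CBM50").
#' @param genomeSizes named numeric, genome id -> size in bp (> 0).
#' @return data.frame: genome_id, one column per class, `total`,
#'   `density_per_mbp`.
#' @export
#' @examples
#' cazymeDensity(data.frame(genome_id = "g", family = c("GH1", "GT2")),
#'     c(g = 2e6))
cazymeDensity <- function(cazymeHits, genomeSizes) {
    if (any(genomeSizes <= 0)) stop("genome_size must be > 0")
    classes <- c("GH", "GT", "PL", "CE", "AA", "CBM")
    ids <- names(genomeSizes)
    cls <- sub("^(GH|GT|PL|CE|AA|CBM).*$", "\\1", cazymeHits$family)
    cls[!cls %in% classes] <- "other"
    out <- data.frame(genome_id = ids, stringsAsFactors = FALSE)
    for (cl in classes)
        out[[cl]] <- vapply(ids, function(g)
            sum(cazymeHits$genome_id == g & cls == cl), 0L)
    out$total <- vapply(ids, function(g) sum(cazymeHits$genome_id == g), 0L)
    out$density_per_mbp <- out$total / (unname(genomeSizes[ids]) / 1e6)
    out
}
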