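#' Construct a GenomeSet from sequences and metadata
#'
#' @param sequences named list of `DNAStringSet` (or named character vectors
#'   of scaffold sequences), one element per genome.
#' @param metadata optional data.frame/DataFrame with a `genome_id` column or
#'   rownames matching the genome ids; recognised columns are
#'   `completeness`, `contamination`, taxonomy ranks (`domain`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`), `lineage`, `is_cpr`,
#'   `is_dpann`, `is_archaea`, `source_label`. Missing fields become `NA`
#'   ("unknown"), never 0.
#' @return a [GenomeSet-class].
#' @export
#' @examples
#' gs <- GenomeSet(list(g1 = c(s1 = "ACGTACGTAC")),
#'     metadata = data.frame(genome_id = "g1", completeness = 95,
#'         contamination = 1))
#' genomeSizes(gs)
GenomeSet <- function(sequences, metadata = NULL) {
    sequences <- lapply(sequences, function(x) {
        if (is.character(x))
            x <- Biostrings::DNAStringSet(toupper(x))
        x
    })
    ids <- names(sequences)
    md <- .align_metadata(metadata, ids)
    md$genome_size <- vapply(sequences,
        function(x) sum(Biostrings::width(x)), 0)
    methods::new("GenomeSet", sequences = sequences, metadata = md)
}

.meta_cols <- c("completeness", "contamination", "domain", "phylum", "class",
    "order", "family", "genus", "species", "lineage", "is_cpr", "is_dpann",
    "is_archaea", "source_label")

.align_metadata <- function(metadata, ids) {
    md <- S4Vectors::DataFrame(row.names = ids)
    if (!is.null(metadata)) {
        metadata <- as.data.frame(metadata)
        if ("genome_id" %in% colnames(metadata)) {
            if (anyDuplicated(metadata$genome_id))
                stop("duplicate genome_id in metadata")
            rownames(metadata) <- metadata$genome_id
            metadata$genome_id <- NULL
        }
        keep <- intersect(rownames(metadata), ids)
        for (col in setdiff(colnames(metadata), "genome_size")) {
            v <- rep(NA, length(ids))
            v[match(keep, ids)] <- metadata[keep, col]
            md[[col]] <- v
        }
    }
    for (col in c("completeness", "contamination"))
        if (!col %in% colnames(md)) md[[col]] <- NA_real_
    md
}

#' Read a directory of genome FASTA files into a GenomeSet
#'
#' One FASTA file per MAG; the genome id is the file name without its
#' extension. Sequences are uppercased; ambiguity codes are kept (they count
#' towards genome size but are excluded later from k-mer sketching).
#'
#' @param dir directory containing `.fa`/`.fasta`/`.fna` files.
#' @param metadata optional path to a tab-separated sidecar (CheckM-style)
#'   with a `genome_id` column, or a data.frame; see [GenomeSet()].
#'   Completeness/contamination are read from here, never recomputed.
#' @return a [GenomeSet-class].
#' @export
readGenomes <- function(dir, metadata = NULL) {
    if (!dir.exists(dir)) stop(sprintf("genome directory not found: %s", dir))
    files <- list.files(dir, pattern = "\\.(fa|fasta|fna)$", full.names = TRUE)
    if (!length(files)) stop(sprintf("no FASTA files in %s", dir))
    if (is.character(metadata)) {
        if (!file.exists(metadata))
            stop(sprintf("metadata file not found: %s", metadata))
        metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
    }
    seqs <- list()
    for (f in files) {
        id <- sub("\\.(fa|fasta|fna)$", "", basename(f))
        x <- tryCatch(Biostrings::readDNAStringSet(f),
            error = function(e) stop(sprintf(
                "failed to read FASTA '%s': %s", f, conditionMessage(e))))
        if (length(x) == 0L)
            stop(sprintf("no sequences in FASTA '%s'", f))
        # keep only the first whitespace-delimited token of each header
        names(x) <- vapply(strsplit(names(x), "\\s+"), `[`, "", 1L)
        if (id %in% names(seqs))
            stop(sprintf("duplicate genome_id '%s'", id))
        seqs[[id]] <- Biostrings::DNAStringSet(toupper(x))
    }
    GenomeSet(seqs, metadata = metadata)
}

#' Select medium- and high-quality genomes
#'
#' Retains exactly the genomes with completeness >= `minCompleteness` and
#' contamination strictly below `maxContamination` (the MIMAG medium-quality
#' rule: >= 50% complete, < 10% contaminated). Genomes with unknown
#' completeness or contamination are excluded with a warning — unknown never
#' defaults to passing.
#'
#' @param genomes a [GenomeSet-class].
#' @param minCompleteness percent, inclusive lower bound (default 50).
#' @param maxContamination percent, exclusive upper bound (default 10).
#' @return the retained subset, a [GenomeSet-class] (possibly empty).
#' @export
#' @examples
#' gs <- exampleGenomeSet()
#' length(qualityFilter(gs))
qualityFilter <- function(genomes, minCompleteness = 50,
        maxContamination = 10) {
    stopifnot(methods::is(genomes, "GenomeSet"))
    cm <- completeness(genomes)
    ct <- contamination(genomes)
    unknown <- is.na(cm) | is.na(ct)
    if (any(unknown))
        warning(sprintf(
            "excluding %d genome(s) with unknown completeness/contamination: %s",
            sum(unknown), paste(utils::head(names(cm)[unknown], 5),
                collapse = ", ")))
    keep <- !unknown & cm >= minCompleteness & ct < maxContamination
    genomes[which(keep)]
}

#' A small example GenomeSet
#'
#' Deterministic three-genome toy set used in documentation examples.
#'
#' @return a [GenomeSet-class] with three genomes.
#' @export
exampleGenomeSet <- function() {
    set.seed(7L)
    mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
        collapse = "")
    GenomeSet(
        list(g1 = c(s1 = mk(800), s2 = mk(400)),
             g2 = c(s1 = mk(1000)),
             g3 = c(s1 = mk(600))),
        metadata = data.frame(genome_id = c("g1", "g2", "g3"),
            completeness = c(95, 60, 45), contamination = c(1, 4, 2),
            phylum = c("Cyanobacteria", "Chlorobi", "Thaumarchaeota")))
}
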