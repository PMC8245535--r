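#' Read per-scaffold coverage tables
#'
#' Two dialects are supported. `"pileup"`: one file per sample in the BBMap
#' pileup summary format, a tab-separated table whose header line starts with
#' `#ID` and contains at least `Avg_fold` and `Length` columns; sample ids
#' are taken from `samples` or from file names. `"long"`: a single
#' tab-separated file with columns `scaffold`, `sample`, `coverage`,
#' `length`. Per-sample tables are merged on scaffold id; a scaffold must
#' have the same length everywhere.
#'
#' @param path file path (long dialect) or vector of file paths (pileup).
#' @param dialect `"pileup"` or `"long"`.
#' @param samples sample ids for pileup files (default: file names without
#'   extension).
#' @param scaffoldToGenome optional named character (scaffold -> genome), or
#'   path to a two-column tab-separated file (`scaffold`, `genome`); may
#'   cover only a subset of scaffolds (unbinned scaffolds are allowed).
#' @return a [CoverageTable-class].
#' @export
readCoverageTable <- function(path, dialect = c("long", "pileup"),
        samples = NULL, scaffoldToGenome = character()) {
    dialect <- match.arg(dialect)
    if (is.character(scaffoldToGenome) && length(scaffoldToGenome) == 1L &&
        is.null(names(scaffoldToGenome)) && file.exists(scaffoldToGenome)) {
        map <- utils::read.delim(scaffoldToGenome, stringsAsFactors = FALSE)
        scaffoldToGenome <- stats::setNames(as.character(map[[2L]]),
            as.character(map[[1L]]))
    }
    if (dialect == "long") {
        stopifnot(length(path) == 1L)
        if (!file.exists(path)) stop(sprintf("coverage file not found: %s",
            path))
        d <- utils::read.delim(path, stringsAsFactors = FALSE)
        need <- c("scaffold", "sample", "coverage", "length")
        if (!all(need %in% colnames(d)))
            stop("long-format coverage needs columns scaffold, sample, ",
                "coverage, length")
        entries <- data.frame(scaffold = as.character(d$scaffold),
            sample = as.character(d$sample),
            coverage = as.numeric(d$coverage), stringsAsFactors = FALSE)
        lengths <- .consistent_lengths(d$scaffold, d$length)
    } else {
        if (is.null(samples))
            samples <- sub("\\.[^.]*$", "", basename(path))
        stopifnot(length(samples) == length(path))
        parts <- vector("list", length(path))
        for (i in seq_along(path)) {
            if (!file.exists(path[i]))
                stop(sprintf("coverage file not found: %s", path[i]))
            header <- readLines(path[i], n = 1L)
            if (!startsWith(header, "#ID"))
                stop(sprintf("not a pileup table (header must start '#ID'): %s",
                    path[i]))
            cols <- strsplit(sub("^#", "", header), "\t")[[1L]]
            d <- utils::read.delim(path[i], skip = 1L, header = FALSE,
                stringsAsFactors = FALSE)
            colnames(d) <- cols[seq_len(ncol(d))]
            if (!all(c("ID", "Avg_fold", "Length") %in% colnames(d)))
                stop(sprintf("pileup table %s lacks ID/Avg_fold/Length",
                    path[i]))
            parts[[i]] <- data.frame(scaffold = as.character(d$ID),
                sample = samples[i], coverage = as.numeric(d$Avg_fold),
                length = as.numeric(d$Length), stringsAsFactors = FALSE)
        }
        all <- do.call(rbind, parts)
        entries <- all[c("scaffold", "sample", "coverage")]
        lengths <- .consistent_lengths(all$scaffold, all$length)
    }
    if (any(is.na(entries$coverage)))
        stop("non-numeric coverage value")
    if (any(entries$coverage < 0))
        stop("negative coverage value")
    rownames(entries) <- NULL
    methods::new("CoverageTable", entries = entries, lengths = lengths,
        scaffoldToGenome = scaffoldToGenome)
}

.consistent_lengths <- function(scaffold, length) {
    scaffold <- as.character(scaffold)
    length <- as.numeric(length)
    first <- !duplicated(scaffold)
    ref <- stats::setNames(length[first], scaffold[first])
    if (any(length != ref[scaffold]))
        stop(sprintf("conflicting lengths for scaffold(s): %s",
            paste(utils::head(unique(scaffold[length != ref[scaffold]]), 5),
                collapse = ", ")))
    ref
}

#' Write a CoverageTable in the long dialect
#'
#' Canonical long format (scaffold, sample, coverage, length), sorted by
#' scaffold then sample, so that write-then-read round-trips.
#'
#' @param cov a [CoverageTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCoverageTable <- function(cov, path) {
    stopifnot(methods::is(cov, "CoverageTable"))
    e <- cov@entries
    e <- e[order(e$scaffold, e$sample), , drop = FALSE]
    e$length <- unname(cov@lengths[e$scaffold])
    e$coverage <- sprintf("%.17g", e$coverage)
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read an HMM hit table
#'
#' Whitespace-delimited table in a reduced hmmsearch tblout dialect: comment
#' lines start with `#`; data rows carry the columns `genome_id`,
#' `protein_id`, `model_id`, `bit_score`, `e_value`, `model_from`,
#' `model_to`, `ali_length` in that order. One protein may hit several
#' models and vice versa.
#'
#' @param path input file.
#' @return data.frame with the eight columns above, types enforced.
#' @export
readHitTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("hit table not found: %s", path))
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    rows <- which(keep)
    if (!length(rows))
        return(data.frame(genome_id = character(), protein_id = character(),
            model_id = character(), bit_score = numeric(),
            e_value = numeric(), model_from = integer(),
            model_to = integer(), ali_length = integer(),
            stringsAsFactors = FALSE))
    fields <- strsplit(trimws(lines[rows]), "\\s+")
    nf <- lengths(fields)
    if (any(nf != 8L))
        stop(sprintf("malformed hit row at line %d: expected 8 columns, got %d",
            rows[which(nf != 8L)[1L]], nf[nf != 8L][1L]))
    m <- do.call(rbind, fields)
    hits <- data.frame(genome_id = m[, 1L], protein_id = m[, 2L],
        model_id = m[, 3L], bit_score = as.numeric(m[, 4L]),
        e_value = as.numeric(m[, 5L]), model_from = as.integer(m[, 6L]),
        model_to = as.integer(m[, 7L]), ali_length = as.integer(m[, 8L]),
        stringsAsFactors = FALSE)
    if (any(is.na(hits$bit_score)) || any(is.na(hits$e_value)))
        stop("non-numeric bit_score/e_value in hit table")
    if (any(hits$e_value < 0)) stop("negative e_value in hit table")
    if (any(hits$model_from < 1L)) stop("model_from must be >= 1")
    bad <- hits$model_from > hits$model_to
    if (any(bad))
        stop(sprintf("model_from > model_to at line %d",
            rows[which(bad)[1L]]))
    hits
}

#' Write an HMM hit table in the dialect read by [readHitTable()]
#'
#' @param hits data.frame with the eight hit-table columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# lakecycle hit table",
        "# genome_id protein_id model_id bit_score e_value model_from model_to ali_length"),
        con)
    if (nrow(hits))
        writeLines(sprintf("%s %s %s %.6g %.6g %d %d %d", hits$genome_id,
            hits$protein_id, hits$model_id, hits$bit_score, hits$e_value,
            hits$model_from, hits$model_to, hits$ali_length), con)
    invisible(path)
}

#' Read sample metadata
#'
#' Tab-separated table with columns `sample_id`, `station`, `depth_m`,
#' `date`, `total_reads`. Total read counts must be positive: they are the
#' per-metagenome normalization denominators. Whether they are raw,
#' quality-filtered or mapped totals is a documented property of the input,
#' not inferred here.
#'
#' @param path input file.
#' @return data.frame, one row per sample.
#' @export
readSampleTable <- function(path) {
    if (!file.exists(path)) stop(sprintf("sample table not found: %s", path))
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("sample_id", "depth_m", "total_reads")
    if (!all(need %in% colnames(d)))
        stop("sample table needs columns sample_id, depth_m, total_reads")
    if (anyDuplicated(d$sample_id)) stop("duplicate sample_id")
    if (any(d$total_reads <= 0)) stop("total_reads must be > 0")
    if (any(d$depth_m < 0)) stop("depth_m must be >= 0")
    d
}
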