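test_that("readGenomes computes genome sizes and handles case/ambiguity", {
    dir <- withr::local_tempdir()
    make_genome_dir(dir, list(
        gA = list(s1 = strrep("ACGT", 250), s2 = strrep("AC", 1500)),
        gB = list(c1 = "acgtNacgta")))
    gs <- readGenomes(dir)
    expect_s4_class(gs, "GenomeSet")
    expect_setequal(genomeIds(gs), c("gA", "gB"))
    expect_equal(unname(genomeSizes(gs)[["gA"]]), 4000)
    # lowercase and ambiguity codes are uppercased and count towards size
    expect_equal(unname(genomeSizes(gs)[["gB"]]), 10)
    expect_equal(as.character(scaffolds(gs, "gB")[[1]]), "ACGTNACGTA")
    # unknown metadata stays NA, never 0
    expect_true(all(is.na(completeness(gs))))
})

test_that("readGenomes rejects empty FASTA and missing directories", {
    dir <- withr::local_tempdir()
    writeLines(character(), file.path(dir, "empty.fna"))
    expect_error(readGenomes(dir), "no sequences|failed to read")
    expect_error(readGenomes(file.path(dir, "nope")), "not found")
})

test_that("metadata sidecar attaches quality and taxonomy by genome_id", {
    dir <- withr::local_tempdir()
    md <- data.frame(genome_id = c("gA", "gB"),
        completeness = c(88.5, 51), contamination = c(3.2, 9.9),
        phylum = c("Chlorobi", "Cyanobacteria"))
    make_genome_dir(dir, list(gA = list(s1 = random_seq(500)),
        gB = list(s1 = random_seq(300))), metadata = md)
    gs <- readGenomes(dir, metadata = file.path(dir, "metadata.tsv"))
    expect_equal(unname(completeness(gs)[c("gA", "gB")]), c(88.5, 51))
    expect_equal(unname(taxonomy(gs, "phylum")[["gB"]]), "Cyanobacteria")
})

test_that("quality selection applies >=50% / <10% exactly at boundaries", {
    mk <- function(cm, ct) GenomeSet(
        setNames(list(c(s1 = random_seq(100))), paste0("g", cm, "_", ct)),
        metadata = data.frame(
            genome_id = paste0("g", cm, "_", ct),
            completeness = cm, contamination = ct))
    # inclusive on completeness, strict on contamination
    expect_length(qualityFilter(mk(50.0, 9.9)), 1L)
    expect_length(qualityFilter(mk(49.9, 0)), 0L)
    expect_length(qualityFilter(mk(100, 10.0)), 0L)
})

test_that("quality selection is idempotent, order-independent, excludes unknowns", {
    set.seed(31)
    n <- 20
    ids <- sprintf("g%02d", 1:n)
    seqs <- setNames(lapply(ids, function(i) c(s1 = random_seq(60))), ids)
    md <- data.frame(genome_id = ids,
        completeness = round(runif(n, 30, 100), 1),
        contamination = round(runif(n, 0, 15), 1))
    md$completeness[3] <- NA
    gs <- GenomeSet(seqs, metadata = md)
    expect_warning(kept <- qualityFilter(gs), "unknown")
    expect_lte(length(kept), length(gs))
    expect_true(all(completeness(kept) >= 50))
    expect_true(all(contamination(kept) < 10))
    expect_false("g03" %in% genomeIds(kept))
    # idempotent
    expect_identical(genomeIds(qualityFilter(kept)), genomeIds(kept))
    # order-independent
    perm <- sample(ids)
    expect_warning(kept2 <- qualityFilter(gs[perm]), "unknown")
    expect_setequal(genomeIds(kept2), genomeIds(kept))
})

test_that("long-format coverage reader parses, validates and round-trips", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("scaffold\tsample\tcoverage\tlength",
        "s1\tA\t10.0\t1000"), f)
    cov <- readCoverageTable(f, dialect = "long")
    expect_equal(nrow(cov@entries), 1L)
    expect_equal(cov@entries$coverage, 10)
    expect_equal(unname(cov@lengths[["s1"]]), 1000)
    # negative coverage rejected
    writeLines(c("scaffold\tsample\tcoverage\tlength",
        "s1\tA\t-1\t1000"), f)
    expect_error(readCoverageTable(f, dialect = "long"), "egative")
    # conflicting lengths rejected
    writeLines(c("scaffold\tsample\tcoverage\tlength",
        "s1\tA\t1\t1000", "s1\tB\t2\t999"), f)
    expect_error(readCoverageTable(f, dialect = "long"), "onflicting")
})

test_that("coverage write/read round-trips on canonical tables", {
    set.seed(5)
    n <- 40
    e <- data.frame(
        scaffold = sample(sprintf("s%02d", 1:12), n, replace = TRUE),
        sample = sample(c("A", "B", "C"), n, replace = TRUE),
        coverage = round(runif(n, 0, 50), 6))
    e <- e[!duplicated(e[c("scaffold", "sample")]), ]
    lens <- setNames(sample(500:5000, 12), sprintf("s%02d", 1:12))
    cov <- new("CoverageTable", entries = e,
        lengths = lens[unique(e$scaffold)], scaffoldToGenome = character())
    f <- withr::local_tempfile(fileext = ".tsv")
    writeCoverageTable(cov, f)
    cov2 <- readCoverageTable(f, dialect = "long")
    canon <- function(x) {
        d <- x@entries[order(x@entries$scaffold, x@entries$sample), ]
        rownames(d) <- NULL
        d
    }
    expect_equal(canon(cov2), canon(cov))
    expect_equal(cov2@lengths[names(cov@lengths)], cov@lengths)
})

test_that("pileup dialect merges per-sample files on scaffold id", {
    d <- withr::local_tempdir()
    hdr <- "#ID\tAvg_fold\tLength\tRef_GC\tCovered_percent"
    writeLines(c(hdr, "s1\t12.5\t1000\t0.5\t99", "s2\t3\t2000\t0.4\t80"),
        file.path(d, "A.txt"))
    writeLines(c(hdr, "s1\t7.25\t1000\t0.5\t98"), file.path(d, "B.txt"))
    cov <- readCoverageTable(file.path(d, c("A.txt", "B.txt")),
        dialect = "pileup", samples = c("A", "B"))
    e <- cov@entries
    expect_equal(nrow(e), 3L)
    expect_equal(sort(unique(e$sample)), c("A", "B"))
    expect_equal(e$coverage[e$scaffold == "s1" & e$sample == "B"], 7.25)
    expect_equal(sum(e$scaffold == "s1"), 2L)
})

test_that("hit table parser skips comments, parses e-values, validates coords", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("# comment", "# another",
        "g1 p1 nifH 120.5 1e-30 1 100 100"), f)
    h <- readHitTable(f)
    expect_equal(nrow(h), 1L)
    expect_equal(h$e_value, 1e-30)
    expect_equal(h$bit_score, 120.5)
    writeLines("g1 p1 nifH 120.5 1e-30 50 10 100", f)
    expect_error(readHitTable(f), "model_from > model_to")
    writeLines("g1 p1 nifH 120.5", f)
    expect_error(readHitTable(f), "line 1")
    # round trip through the writer
    h2f <- withr::local_tempfile(fileext = ".tsv")
    writeHitTable(h, h2f)
    expect_equal(readHitTable(h2f), h)
})

test_that("GenomeSet validity rejects duplicates and inconsistent sizes", {
    expect_error(GenomeSet(list(g1 = c(s1 = "ACGT", s1 = "ACGT"))),
        "scaffold")
    gs <- exampleGenomeSet()
    bad <- gs
    bad@metadata$genome_size[1] <- 1
    expect_error(validObject(bad), "genome_size")
})
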