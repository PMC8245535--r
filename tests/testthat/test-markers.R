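test_that("copy resolution merges split fragments and keeps longer overlaps", {
    # fragments covering columns 1-6 and 7-12 of a 12-column model
    frag1 <- "MKLVAE------"
    frag2 <- "------GHIKLM"
    expect_equal(resolveCopies(c(frag1, frag2)), "MKLVAEGHIKLM")
    # overlapping copies: the one with more non-gap columns is retained
    full <- "MKLVAEGHIKLM"
    short <- "MKLVAEGH----"
    expect_equal(resolveCopies(c(short, full)), full)
    # single candidate unchanged; empty input absent
    expect_equal(resolveCopies(full), full)
    expect_true(is.na(resolveCopies(character())))
    expect_error(resolveCopies(c("AB-", "ABCD")), "aligned")
})

test_that("resolution never exceeds the union of input non-gap columns", {
    set.seed(8)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (rep in 1:30) {
        L <- sample(20:60, 1)
        row <- sample(aa, L, replace = TRUE)
        n_copy <- sample(2:3, 1)
        copies <- vapply(seq_len(n_copy), function(i) {
            x <- row
            gaps <- runif(L) < runif(1, 0.2, 0.7)
            x[gaps] <- "-"
            paste(x, collapse = "")
        }, "")
        out <- resolveCopies(copies)
        union_nongap <- Reduce(`|`, lapply(strsplit(copies, ""),
            function(x) x != "-"))
        out_nongap <- strsplit(out, "")[[1]] != "-"
        expect_lte(sum(out_nongap), sum(union_nongap))
        expect_equal(nchar(out), L)
    }
})

test_that("gap masking removes exactly the over-threshold columns", {
    rows <- c(g1 = "MK-VA-", g2 = "MK-V--", g3 = "M--V-E", g4 = "MKLV--")
    aln <- MarkerAlignment("rpL2", rows)
    masked <- maskColumns(aln, 0.5)
    # brute-force per-column census: gap fractions 0,.25,.75,0,.75,.75
    expect_equal(unname(masked@rows),
        c("MKV", "MKV", "M-V", "MKV")[match(names(rows), names(rows))])
    # all-gap columns vanish at any threshold < 1
    aln2 <- MarkerAlignment("x", c(a = "A-B", b = "C-D"))
    expect_equal(unname(maskColumns(aln2, 0.99)@rows), c("AB", "CD"))
    # occupancy semantics: 0.9 keeps only near-full columns
    aln3 <- MarkerAlignment("x", c(a = "AB", b = "A-"))  # col2 gap frac 0.5
    expect_equal(nchar(maskColumns(aln3, 0.9)@rows[[1]]), 2L)
    expect_equal(nchar(maskColumns(aln3, 0.9,
        semantics = "occupancy")@rows[[1]]), 1L)
    aln4 <- MarkerAlignment("x", c(a = "AB", b = "A-", c = "A-"))
    expect_equal(nchar(maskColumns(aln4, 1/3)@rows[[1]]), 1L)
})

test_that("masking is idempotent and monotone in the threshold", {
    set.seed(15)
    aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], rep("-", 12))
    for (rep in 1:20) {
        n <- sample(3:8, 1); L <- sample(10:40, 1)
        rows <- vapply(seq_len(n), function(i)
            paste(sample(aa, L, replace = TRUE), collapse = ""), "")
        names(rows) <- sprintf("g%d", seq_len(n))
        aln <- MarkerAlignment("m", rows)
        m5 <- maskColumns(aln, 0.5)
        expect_identical(maskColumns(m5, 0.5)@rows, m5@rows)
        expect_lte(nchar(m5@rows[[1]]), L)
        # brute-force census oracle
        cols <- do.call(rbind, strsplit(rows, ""))
        keep <- colMeans(cols == "-") <= 0.5
        expect_equal(nchar(m5@rows[[1]]), sum(keep))
        # higher threshold never removes more columns
        m9 <- maskColumns(aln, 0.9)
        expect_gte(nchar(m9@rows[[1]]), nchar(m5@rows[[1]]))
    }
})

test_that("concatenation tiles partitions, pads absences, drops sparse rows", {
    a1 <- MarkerAlignment("rpL2",
        c(g1 = "MKLV", g2 = "MRLV", g3 = "MKIV"))
    a2 <- MarkerAlignment("rpL3", c(g1 = "ACDEFG", g2 = "ACDEFG"))
    sm <- concatenateMarkers(list(a1, a2), minMarkers = 1L)
    expect_equal(sm@partitions$start, c(1L, 5L))
    expect_equal(sm@partitions$end, c(4L, 10L))
    # hand-checked rows; missing marker padded with gaps
    expect_equal(unname(sm@rows["g1"]), "MKLVACDEFG")
    expect_equal(unname(sm@rows["g3"]), "MKIV------")
    # min_markers drops under-covered genomes with a message
    expect_message(sm2 <- concatenateMarkers(list(a1, a2), minMarkers = 2L),
        "dropping")
    expect_false("g3" %in% names(sm2@rows))
    expect_equal(attr(sm2, "dropped"), "g3")
    # partition file format
    f <- withr::local_tempfile()
    writePartitions(sm, f)
    expect_equal(readLines(f),
        c("PROT, rpL2 = 1-4", "PROT, rpL3 = 5-10"))
})

test_that("splitting a supermatrix recovers each masked alignment exactly", {
    set.seed(23)
    aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], rep("-", 5))
    genomes <- sprintf("g%d", 1:6)
    alns <- lapply(1:4, function(i) {
        present <- sample(genomes, sample(3:6, 1))
        L <- sample(8:20, 1)
        rows <- vapply(present, function(g)
            paste(sample(aa, L, replace = TRUE), collapse = ""), "")
        maskColumns(MarkerAlignment(paste0("m", i), rows), 0.5)
    })
    names(alns) <- paste0("m", 1:4)
    sm <- concatenateMarkers(alns, minMarkers = 0L)
    back <- splitSupermatrix(sm)
    for (i in 1:4) {
        orig <- alns[[i]]@rows
        rec <- back[[i]]@rows[names(orig)]
        expect_identical(unname(rec), unname(orig))
    }
    # round trip through FASTA
    f <- withr::local_tempfile(fileext = ".fasta")
    writeSupermatrix(sm, f)
    x <- Biostrings::readAAStringSet(f)
    expect_identical(as.character(x), sm@rows)
})

test_that("aligned-FASTA reader resolves multi-copy genomes", {
    f <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">g1|1", "MKLV----", ">g1|2", "----GHIK",
        ">g2", "MKLVGHIK"), f)
    aln <- readMarkerAlignment(f, markerId = "rpL5")
    expect_equal(unname(aln@rows["g1"]), "MKLVGHIK")
    expect_equal(length(aln@rows), 2L)
    expect_error(readMarkerAlignment(f, markerId = "rpL5", resolve = FALSE),
        "duplicate genome")
})
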