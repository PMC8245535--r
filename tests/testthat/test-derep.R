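make_ani <- function(ids, pairs, floor = 75) {
    v <- matrix(NA_real_, length(ids), length(ids),
        dimnames = list(ids, ids))
    diag(v) <- 100
    for (p in pairs) {
        v[p[[1]], p[[2]]] <- as.numeric(p[[3]])
        v[p[[2]], p[[1]]] <- as.numeric(p[[3]])
    }
    new("ANIMatrix", values = v, floor = floor)
}

make_gs <- function(ids, cm, ct, size = NULL) {
    if (is.null(size)) size <- rep(100L, length(ids))
    seqs <- setNames(lapply(size, function(n)
        c(s1 = strrep("ACGT", ceiling(n / 4)))), ids)
    GenomeSet(seqs, metadata = data.frame(genome_id = ids,
        completeness = cm, contamination = ct))
}

test_that("greedy dereplication follows score ranking and threshold", {
    # A(90,2) score 80 founds; B(80,1) score 75 joins at ANI 99.5; C apart
    gs <- make_gs(c("A", "B", "C"), c(90, 80, 70), c(2, 1, 0))
    ani <- make_ani(c("A", "B", "C"), list(list("A", "B", 99.5),
        list("A", "C", 90), list("B", "C", 90)))
    cl <- dereplicate(gs, ani, aniThreshold = 99)
    m <- clusterMembers(cl)
    expect_equal(m$cluster_id[m$genome_id == "A"],
        m$cluster_id[m$genome_id == "B"])
    expect_setequal(representatives(cl), c("A", "C"))
    expect_equal(m$score, c(80, 75, 70))
})

test_that("all-below-threshold input yields singleton representatives", {
    gs <- make_gs(c("A", "B", "C"), c(90, 80, 70), c(0, 0, 0))
    ani <- make_ani(c("A", "B", "C"), list(list("A", "B", 90)))
    cl <- dereplicate(gs, ani, aniThreshold = 99)
    expect_length(representatives(cl), 3L)
})

test_that("ties break by larger genome size then lexicographic id", {
    gs <- make_gs(c("bb", "aa"), c(80, 80), c(1, 1), size = c(400L, 800L))
    ani <- make_ani(c("bb", "aa"), list(list("aa", "bb", 100)))
    cl <- dereplicate(gs, ani)
    expect_equal(representatives(cl), "aa")   # larger genome wins
    gs2 <- make_gs(c("bb", "aa"), c(80, 80), c(1, 1), size = c(400L, 400L))
    cl2 <- dereplicate(gs2, ani)
    expect_equal(representatives(cl2), "aa")  # then lexicographic id
})

test_that("dereplication is sound on random small instances", {
    # oracle: independent brute-force soundness checker
    for (seed in 1:25) {
        set.seed(seed)
        n <- sample(4:10, 1)
        ids <- sprintf("g%02d", 1:n)
        v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
        diag(v) <- 100
        for (i in seq_len(n - 1)) for (j in (i + 1):n) {
            if (runif(1) < 0.5) next
            a <- runif(1, 75, 100)
            v[i, j] <- a; v[j, i] <- a
        }
        ani <- new("ANIMatrix", values = v, floor = 75)
        gs <- make_gs(ids, round(runif(n, 50, 100), 1),
            round(runif(n, 0, 10), 1))
        cl <- dereplicate(gs, ani, aniThreshold = 99)
        expect_true(check_derep_sound(cl, v, 99))
        m <- clusterMembers(cl)
        expect_setequal(m$genome_id, ids)  # partition covers the input
    }
})

test_that("group comparison matches hand-computed and brute-force means", {
    ids <- c("t1", "t2", "b1", "b2")
    v <- make_ani(ids, list(
        list("t1", "t2", 92), list("b1", "b2", 96),
        list("t1", "b1", 80), list("t1", "b2", 78),
        list("t2", "b1", 84)))  # t2-b2 below floor
    labels <- c(t1 = "T", t2 = "T", b1 = "B", b2 = "B")
    gc <- compareGroups(v, labels)
    expect_equal(unname(gc$means["within_T"]), 92)
    expect_equal(unname(gc$means["within_B"]), 96)
    expect_equal(unname(gc$means["cross"]), mean(c(80, 78, 84)))
    expect_equal(gc$max_cross$ani, 84)
    expect_setequal(c(gc$max_cross$genome_a, gc$max_cross$genome_b),
        c("t2", "b1"))
    # brute-force loop agrees
    bf <- brute_group_means(aniValues(v), as.list(labels))
    expect_equal(gc$means[names(bf)], bf)
    # histogram bins are 0.5 wide and count every eligible pair
    expect_true(all(gc$histogram$bin_high - gc$histogram$bin_low == 0.5))
    expect_equal(sum(gc$histogram$count), 5L)
})

test_that("a group with no eligible pair reports an undefined mean", {
    v <- make_ani(c("a1", "b1"), list(list("a1", "b1", 90)))
    gc <- compareGroups(v, c(a1 = "A", b1 = "B"))
    expect_equal(unname(gc$means["cross"]), 90)
    expect_true(is.na(gc$means["within_A"]))
    expect_true(is.na(gc$means["within_B"]))
})

test_that("compareGroups means agree with brute force on random matrices", {
    for (seed in 1:5) {
        set.seed(100 + seed)
        n <- 8
        ids <- sprintf("g%d", 1:n)
        v <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
        diag(v) <- 100
        for (i in 1:(n - 1)) for (j in (i + 1):n)
            if (runif(1) < 0.7) v[i, j] <- v[j, i] <- runif(1, 75, 100)
        labels <- setNames(sample(c("X", "Y"), n, replace = TRUE), ids)
        if (length(unique(labels)) < 2) labels[1] <- setdiff(c("X", "Y"),
            labels[1])
        gc <- compareGroups(new("ANIMatrix", values = v, floor = 75),
            labels)
        bf <- brute_group_means(v, as.list(labels))
        expect_equal(gc$means[names(bf)], bf)
    }
})

test_that("taxon overlap fractions follow set arithmetic", {
    ov <- taxonOverlap(c("x", "y"), c("y", "z"))
    expect_equal(ov$unique_a, 0.5)
    expect_equal(ov$unique_b, 0.5)
    expect_equal(ov$shared, "y")
    # identical sets: nothing unique
    ov2 <- taxonOverlap(c("x", "y"), c("y", "x"))
    expect_equal(ov2$unique_a, 0)
    expect_equal(ov2$unique_b, 0)
    # abundance filter removes y from A: unique fraction 0.5
    ov3 <- taxonOverlap(c("x", "y", "z"), "z",
        abundanceA = c(1, 0.01, 2), minAbundance = 0.5)
    expect_equal(ov3$unique_a, 0.5)
    # rank column lookup on data.frames, with error on a missing rank
    ta <- data.frame(phylum = c("P1", "P2"))
    tb <- data.frame(phylum = "P2")
    expect_equal(taxonOverlap(ta, tb, rank = "phylum")$shared, "P2")
    expect_error(taxonOverlap(ta, tb, rank = "order"), "rank 'order'")
})
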