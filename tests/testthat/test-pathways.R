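pw <- readPathways(lakecyclePathways())

hits_for <- function(models, scores = NULL) {
    if (is.null(scores))
        scores <- unname(lakecycle:::.model_cutoff(models, pw$cutoffs,
            pw$default_cutoff))
    data.frame(model_id = models, bit_score = scores)
}

test_that("the shipped definitions parse with non-empty AND-of-OR logic", {
    expect_gte(length(pw$reactions), 20L)
    expect_true(all(vapply(pw$reactions, function(r)
        length(r$logic) > 0 && all(lengths(r$logic) > 0), TRUE)))
    expect_setequal(unique(vapply(pw$reactions, `[[`, "", "cycle")),
        c("carbon", "nitrogen", "sulfur"))
    expect_equal(pw$default_cutoff, 50)
})

test_that("one-copy-per-gene rule: every AND-term needs a qualifying hit", {
    nif <- pw$reactions$nitrogen_fixation
    expect_equal(evaluateReaction(hits_for(c("nifH", "nifD")), nif,
        pw$cutoffs, pw$default_cutoff), 0L)
    expect_equal(evaluateReaction(hits_for(c("nifH", "nifD", "nifK")), nif,
        pw$cutoffs, pw$default_cutoff), 1L)
    # OR-groups: (narG|napA) AND (narH|napB) satisfied across alternatives
    nar <- pw$reactions$nitrate_reduction
    expect_equal(evaluateReaction(hits_for(c("napA", "narH")), nar,
        pw$cutoffs, pw$default_cutoff), 1L)
    expect_equal(evaluateReaction(hits_for(c("napA", "glk")), nar,
        pw$cutoffs, pw$default_cutoff), 0L)
    # sub-cutoff hits never qualify
    expect_equal(evaluateReaction(
        hits_for(c("nifH", "nifD", "nifK"), scores = c(200, 200, 10)), nif,
        pw$cutoffs, pw$default_cutoff), 0L)
    # a model without any resolvable cutoff is an error
    expect_error(evaluateReaction(hits_for("nifH"), nif, numeric(), NULL),
        "no cutoff")
})

test_that("evaluateReaction matches exhaustive formula evaluation", {
    # oracle: naive brute-force evaluation over every subset of the genes
    for (r in pw$reactions) {
        genes <- unique(unlist(r$logic))
        if (length(genes) > 12) next
        for (mask in 0:(2^length(genes) - 1)) {
            present <- genes[bitwAnd(mask, 2^(seq_along(genes) - 1)) > 0]
            got <- evaluateReaction(hits_for(present), r, pw$cutoffs,
                pw$default_cutoff)
            expect_identical(got, brute_formula(r$logic, present))
        }
    }
})

test_that("adding a qualifying hit never flips a cell to absent", {
    set.seed(12)
    genes <- unique(unlist(lapply(pw$reactions, function(r)
        unlist(r$logic))))
    for (rep in 1:20) {
        present <- sample(genes, sample(0:8, 1))
        extra <- sample(setdiff(genes, present), 1)
        for (r in pw$reactions[sample(length(pw$reactions), 5)]) {
            before <- evaluateReaction(hits_for(present), r, pw$cutoffs,
                pw$default_cutoff)
            after <- evaluateReaction(hits_for(c(present, extra)), r,
                pw$cutoffs, pw$default_cutoff)
            expect_gte(after, before)
        }
    }
})

test_that("function matrix equals cell-by-cell evaluation and is idempotent", {
    hits <- data.frame(
        genome_id = c("g1", "g1", "g1", "g2", "g2"),
        protein_id = paste0("p", 1:5),
        model_id = c("nifH", "nifD", "nifK", "mcrA", "nifH"),
        bit_score = c(100, 100, 100, 100, 100),
        e_value = 1e-20, model_from = 1L, model_to = 50L,
        ali_length = 50L)
    fm <- buildFunctionMatrix(hits, c("g1", "g2", "g3"), pw)
    expect_equal(fm["g1", "nitrogen_fixation"], 1L)
    expect_equal(fm["g2", "nitrogen_fixation"], 0L)
    expect_equal(sum(fm["g3", ]), 0L)  # no hits -> all-zero row
    # duplicate hit rows change nothing (one copy suffices)
    fm2 <- buildFunctionMatrix(rbind(hits, hits), c("g1", "g2", "g3"), pw)
    expect_identical(fm2, fm)
    # cell-by-cell oracle
    for (g in rownames(fm)) {
        h <- hits[hits$genome_id == g, c("model_id", "bit_score")]
        for (r in colnames(fm))
            expect_identical(fm[g, r], evaluateReaction(h,
                pw$reactions[[r]], pw$cutoffs, pw$default_cutoff))
    }
})

test_that("overrides relabel hits and force cells, with provenance", {
    hits <- data.frame(
        genome_id = "g1", protein_id = c("p1", "p2"),
        model_id = c("amoA", "amoB"), bit_score = c(200, 200),
        e_value = 1e-30, model_from = 1L, model_to = 60L, ali_length = 60L)
    fm <- buildFunctionMatrix(hits, "g1", pw)
    expect_equal(fm["g1", "ammonia_oxidation"], 1L)
    expect_equal(fm["g1", "methanotrophy"], 0L)
    ov <- data.frame(genome_id = "g1", target = "amoA",
        action = "relabel", new_label = "pmoA", reason = "amo/pmo curation")
    fm2 <- applyOverrides(fm, hits, ov, pw)
    # ammonia oxidation loses its amoA; methanotrophy gains pmoA
    expect_equal(fm2["g1", "ammonia_oxidation"], 0L)
    expect_equal(fm2["g1", "methanotrophy"], 1L)
    log <- attr(fm2, "override_log")
    expect_setequal(log$reaction_id,
        c("ammonia_oxidation", "methanotrophy"))
    expect_true(all(log$action == "relabel"))
    # force_absent flips a present cell; empty table is identity
    ov2 <- data.frame(genome_id = "g1", target = "methanotrophy",
        action = "force_absent", new_label = NA, reason = NA)
    fm3 <- applyOverrides(fm2, hits, ov2, pw)
    expect_equal(fm3["g1", "methanotrophy"], 0L)
    fm4 <- applyOverrides(fm, hits, ov[0, ], pw)
    expect_equal(unclass(fm4)[, ], unclass(fm)[, ])
    # unknown targets are errors
    expect_error(applyOverrides(fm, hits, data.frame(genome_id = "gX",
        target = "amoA", action = "relabel", new_label = "pmoA",
        reason = NA), pw), "unknown genome")
    expect_error(applyOverrides(fm, hits, data.frame(genome_id = "g1",
        target = "not_a_reaction", action = "force_present",
        new_label = NA, reason = NA), pw), "unknown reaction")
})

test_that("CAZyme density is hits per Mbp by class", {
    hits <- data.frame(
        genome_id = c(rep("g1", 30), "g2", "g2"),
        family = c(rep("GH13", 20), rep("GT2", 10), "PL1", "CBM50"))
    prof <- cazymeDensity(hits, c(g1 = 3e6, g2 = 1e6))
    expect_equal(prof$density_per_mbp[prof$genome_id == "g1"], 10)
    expect_equal(prof$GH[prof$genome_id == "g1"], 20L)
    expect_equal(prof$CBM[prof$genome_id == "g2"], 1L)
    # zero hits -> density 0; equal hits at double size halves density
    prof2 <- cazymeDensity(hits[0, ], c(g1 = 2e6))
    expect_equal(prof2$density_per_mbp, 0)
    prof3 <- cazymeDensity(data.frame(genome_id = c("a", "b"),
        family = "GH1"), c(a = 2e6, b = 4e6))
    expect_equal(prof3$density_per_mbp[1] / prof3$density_per_mbp[2], 2)
    expect_error(cazymeDensity(hits, c(g1 = 0)), "genome_size")
})
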