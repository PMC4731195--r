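# Profile search, the four-cutoff filter, iterative recruitment.

test_that("a profile recovers its own sequence perfectly", {
    ps <- mini_proteome()
    prof <- buildProfile(sequences(ps)["root"])
    hits <- searchProfile(prof, ps)
    self <- hits[hits$subject_gene_id == "root", ]
    expect_equal(self$identity, 1)
    expect_equal(self$positives, 1)
    expect_equal(self$coverage, 1)
    expect_equal(self$uncovered, 0L)
})

test_that("subjects scoring non-positive everywhere yield no hits", {
    prof <- buildProfile(Biostrings::AAStringSet(
        c(q = strrep("W", 40))))
    db <- Biostrings::AAStringSet(c(s1 = strrep("P", 40),
                                    s2 = strrep("G", 40)))
    expect_equal(nrow(searchProfile(prof, db)), 0L)
    expect_equal(nrow(searchProfile(prof, Biostrings::AAStringSet())),
                 0L)
})

test_that("a planted 40%-identity homolog is found near its true identity", {
    ps <- mini_proteome(identity = 0.40, len = 200, seed = 7)
    prof <- buildProfile(sequences(ps)["root"])
    hits <- searchProfile(prof, ps)
    hom <- hits[hits$subject_gene_id == "hom", ]
    expect_equal(nrow(hom), 1L)
    expect_lt(abs(hom$identity - 0.40), 0.08)
    expect_gte(hom$positives, hom$identity)   # identical pairs count
    expect_gt(hom$coverage, 0.8)
})

test_that("hit identity never exceeds positives", {
    ps <- mini_proteome(identity = 0.3, n_background = 8, seed = 21)
    prof <- buildProfile(sequences(ps)["root"])
    hits <- searchProfile(prof, ps)
    expect_true(all(hits$identity <= hits$positives + 1e-12))
    expect_true(all(hits$uncovered ==
                    profileLength(prof) - hits$n_aligned))
})

make_hit <- function(identity, positives, coverage, uncovered) {
    data.frame(subject_gene_id = "s", score = 10, identity = identity,
               positives = positives, coverage = coverage,
               uncovered = uncovered, q_start = 0L, q_end = 1L,
               s_start = 0L, s_end = 1L, n_aligned = 1L,
               stringsAsFactors = FALSE)
}

test_that("the four retention cutoffs are enforced with inclusive bounds", {
    crit <- filterCriteria()   # uncovered 100 / coverage .60 / id .15 / pos .30
    # identity fractionally below the gate: rejected
    expect_equal(nrow(filterHits(make_hit(0.14, 0.50, 0.90, 10), crit)),
                 0L)
    # exactly at every boundary: accepted (all inclusive)
    expect_equal(nrow(filterHits(make_hit(0.15, 0.30, 0.60, 100), crit)),
                 1L)
    # each cutoff individually violated by the smallest step
    expect_equal(nrow(filterHits(make_hit(0.15, 0.299, 0.90, 10), crit)),
                 0L)
    expect_equal(nrow(filterHits(make_hit(0.50, 0.60, 0.599, 10), crit)),
                 0L)
    expect_equal(nrow(filterHits(make_hit(0.50, 0.60, 0.90, 101), crit)),
                 0L)
    # a perfect self-hit passes any valid criteria
    expect_equal(nrow(filterHits(make_hit(1, 1, 1, 0),
                                 filterCriteria(0, 1, 1, 1))), 1L)
})

test_that("relaxing criteria never shrinks the kept set", {
    set.seed(31)
    hits <- do.call(rbind, replicate(200, make_hit(
        runif(1), runif(1), runif(1), sample(0:200, 1)),
        simplify = FALSE))
    hits$positives <- pmax(hits$positives, hits$identity)
    for (rep in 1:20) {
        strict <- filterCriteria(sample(0:150, 1), runif(1),
                                 runif(1), runif(1))
        relaxed <- filterCriteria(
            strict@maxUncovered + sample(0:50, 1),
            strict@minCoverage * runif(1),
            strict@minIdentity * runif(1),
            strict@minPositives * runif(1))
        kept_strict <- filterHits(hits, strict)
        kept_relaxed <- filterHits(hits, relaxed)
        expect_true(all(rownames(kept_strict) %in%
                        rownames(kept_relaxed)))
    }
})

test_that("a database holding only the root yields a singleton tree", {
    ps <- mini_proteome()["root"]
    tr <- iterateSearch("root", ps)
    expect_identical(treeMembers(tr), "root")
    expect_equal(tr@members$identity, 1)
})

test_that("a one-round search equals the explicit stage composition", {
    ps <- mini_proteome(identity = 0.45, seed = 13)
    rc <- defaultRounds()[[1]]
    tr <- iterateSearch("root", ps, rounds = list(rc), newick = FALSE)
    aln <- trimAlignment(clusterRepresentatives(
        alignSequences(sequences(ps)["root"]), rc@clusterIdentity),
        rc@trimOccupancy)
    hits <- filterHits(searchProfile(buildProfile(aln), ps),
                       rc@criteria)
    expect_setequal(treeMembers(tr),
                    union("root", hits$subject_gene_id))
})

test_that("stepping-stone homologs need the multi-round search", {
    set.seed(77)
    root <- random_seq(200)
    A <- mutateSequence(root, 0.5, seed = 101)
    B <- mutateSequence(A, 0.5, seed = 102)
    bg <- setNames(replicate(6, random_seq(200)), paste0("bg", 1:6))
    ann <- data.frame(
        gene_id = c("root", "A", "B", names(bg)),
        organism_id = c("orgA", "orgB", "orgC", rep("orgA", 6)),
        stringsAsFactors = FALSE)
    ann$functions <- I(as.list(paste0("fn_", ann$gene_id)))
    ann$is_metabolic <- TRUE
    ps <- ProteomeSet(c(root = root, A = A, B = B, bg), ann)

    multi <- iterateSearch("root", ps, newick = FALSE)
    strict1 <- iterateSearch("root", ps, rounds = defaultRounds()[1],
                             newick = FALSE)
    expect_true("B" %in% treeMembers(multi))
    expect_true("A" %in% treeMembers(multi))
    # a single strict round sees A but not the twice-removed B
    expect_true("A" %in% treeMembers(strict1))
    expect_false("B" %in% treeMembers(strict1))
    # ... and the stringent single-sequence control sees neither B
    ctrl <- blastControlPairs(ps, "root")
    expect_false("B" %in% ctrl$replacer_gene)
})

test_that("round criteria must relax monotonically", {
    bad <- list(roundConfig(filterCriteria(100, 0.6, 0.15, 0.30)),
                roundConfig(filterCriteria(50, 0.7, 0.30, 0.45)))
    ps <- mini_proteome()
    expect_error(iterateSearch("root", ps, rounds = bad),
                 "stricter")
})

test_that("identical inputs give byte-identical tree serializations", {
    ps <- mini_proteome(identity = 0.4, seed = 3)
    f1 <- tempfile(); f2 <- tempfile()
    writeGeneTrees(list(iterateSearch("root", ps)), f1)
    writeGeneTrees(list(iterateSearch("root", ps)), f2)
    expect_identical(readLines(f1), readLines(f2))
})
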