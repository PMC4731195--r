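# Direct pair prediction, descriptive statistics, BLAST-style control.

matrix_fixture <- function(entries, primaries, metabolic = NULL) {
    genes <- unique(c(entries$root_gene, primaries$gene_id))
    if (is.null(metabolic)) metabolic <- genes
    n <- nrow(entries)
    new("PromiscuityMatrix",
        entries = cbind(entries,
                        data.frame(evidence_gene = rep("ev", n),
                                   evidence_organism = rep("shi", n),
                                   identity = rep(0.4, n),
                                   positives = rep(0.6, n),
                                   coverage = rep(0.9, n),
                                   stringsAsFactors = FALSE)),
        primaries = primaries,
        geneInfo = data.frame(gene_id = genes, organism_id = "eco",
                              is_metabolic = genes %in% metabolic,
                              stringsAsFactors = FALSE))
}

test_that("a promiscuous function matching another gene's primary makes a pair", {
    pm <- matrix_fixture(
        data.frame(root_gene = "eco1", function_id = "fn4",
                   stringsAsFactors = FALSE),
        data.frame(gene_id = c("eco1", "eco2"),
                   function_id = c("fnA", "fn4"),
                   stringsAsFactors = FALSE))
    pairs <- predictDirectPairs(pm)
    expect_equal(nrow(pairs), 1L)
    expect_equal(pairs$target_gene, "eco2")
    expect_equal(pairs$replacer_gene, "eco1")
    expect_equal(pairs$mode, "direct")
    expect_false(pairs$isozyme_by_annotation)
})

test_that("empty matrices, out-of-scope and non-metabolic genes give no pairs", {
    pm0 <- matrix_fixture(
        data.frame(root_gene = character(), function_id = character()),
        data.frame(gene_id = "eco2", function_id = "fn4"))
    expect_equal(nrow(predictDirectPairs(pm0)), 0L)

    pm <- matrix_fixture(
        data.frame(root_gene = "eco1", function_id = "fn4"),
        data.frame(gene_id = c("eco1", "eco2"),
                   function_id = c("fnA", "fn4")),
        metabolic = "eco1")      # target not metabolic
    expect_equal(nrow(predictDirectPairs(pm)), 0L)

    pm2 <- matrix_fixture(
        data.frame(root_gene = "eco1", function_id = "fn4"),
        data.frame(gene_id = c("eco1", "eco2"),
                   function_id = c("fnA", "fn4")))
    expect_equal(nrow(predictDirectPairs(pm2, scope = "eco1")), 0L)
})

test_that("a four-gene fixture yields exactly the enumerated pairs", {
    # e1 promiscuous {f2, f3}; e4 promiscuous {f2}
    # primaries: e1:f1, e2:f2, e3:f3, e4:f4
    # oracle cross-product: (e2,e1), (e3,e1), (e2,e4)
    pm <- matrix_fixture(
        data.frame(root_gene = c("e1", "e1", "e4"),
                   function_id = c("f2", "f3", "f2"),
                   stringsAsFactors = FALSE),
        data.frame(gene_id = c("e1", "e2", "e3", "e4"),
                   function_id = c("f1", "f2", "f3", "f4"),
                   stringsAsFactors = FALSE))
    pairs <- predictDirectPairs(pm)
    expect_setequal(paste(pairs$target_gene, pairs$replacer_gene),
                    c("e2 e1", "e3 e1", "e2 e4"))
    # every pair is witnessed by the matrix
    e <- matrixEntries(pm)
    p <- pm@primaries
    for (i in seq_len(nrow(pairs)))
        expect_true(any(e$root_gene == pairs$replacer_gene[i] &
                        e$function_id == pairs$promiscuous_function[i]) &&
                    any(p$gene_id == pairs$target_gene[i] &
                        p$function_id == pairs$promiscuous_function[i]))
})

test_that("shared primaries flag annotation-level isozymes", {
    pm <- matrix_fixture(
        data.frame(root_gene = "e1", function_id = "f2",
                   stringsAsFactors = FALSE),
        data.frame(gene_id = c("e1", "e1", "e2", "e2"),
                   function_id = c("f1", "fshared", "f2", "fshared"),
                   stringsAsFactors = FALSE))
    pairs <- predictDirectPairs(pm)
    expect_true(pairs$isozyme_by_annotation)
})

test_that("adding matrix entries never removes pairs", {
    base <- data.frame(root_gene = "e1", function_id = "f2",
                       stringsAsFactors = FALSE)
    prim <- data.frame(gene_id = c("e1", "e2", "e3"),
                       function_id = c("f1", "f2", "f3"),
                       stringsAsFactors = FALSE)
    p1 <- predictDirectPairs(matrix_fixture(base, prim))
    more <- rbind(base, data.frame(root_gene = "e2",
                                   function_id = "f3"))
    p2 <- predictDirectPairs(matrix_fixture(more, prim))
    expect_true(all(paste(p1$target_gene, p1$replacer_gene) %in%
                    paste(p2$target_gene, p2$replacer_gene)))
})

test_that("replacers per target counts distinct replacers", {
    empty <- replacersPerTarget(emptyPairs())
    expect_length(empty$counts, 0L)
    pairs <- data.frame(target_gene = c("t1", "t1", "t2", "t1"),
                        replacer_gene = c("r1", "r2", "r1", "r1"),
                        stringsAsFactors = FALSE)
    rpt <- replacersPerTarget(pairs)
    expect_equal(rpt$counts[["t1"]], 2L)
    expect_equal(rpt$counts[["t2"]], 1L)
    expect_equal(sum(rpt$histogram$n_targets), 2L)
    # planted hub dominates
    hub <- rbind(pairs, data.frame(target_gene = "hub",
                                   replacer_gene = paste0("r", 1:5)))
    expect_equal(names(which.max(replacersPerTarget(hub)$counts)),
                 "hub")
})

test_that("reciprocal pairs require both orientations", {
    expect_equal(nrow(findReciprocal(data.frame(
        target_gene = "a", replacer_gene = "b"))), 0L)
    rec <- findReciprocal(data.frame(
        target_gene = c("a", "b"), replacer_gene = c("b", "a")))
    expect_equal(nrow(rec), 1L)
    expect_equal(rec$gene_a, "a")
    # five-pair fixture with two planted reciprocal pairs
    pairs <- data.frame(
        target_gene = c("a", "b", "c", "d", "e"),
        replacer_gene = c("b", "a", "d", "c", "a"),
        stringsAsFactors = FALSE)
    rec2 <- findReciprocal(pairs)
    expect_setequal(paste(rec2$gene_a, rec2$gene_b),
                    c("a b", "c d"))
})

test_that("within-set pair enumeration counts unordered combinations", {
    expect_equal(nrow(withinSetPairs(list(c("x", "y")))), 1L)
    expect_equal(nrow(withinSetPairs(list(letters[1:4]))), 6L)
    expect_equal(nrow(withinSetPairs(list("solo"))), 0L)
})

test_that("the control search returns stringent single-sequence matches only", {
    expect_equal(nrow(blastControlPairs(mini_proteome(), character(0))),
                 0L)
    ps <- mini_proteome(identity = 0.95, seed = 15)
    ctrl <- blastControlPairs(ps, "root")
    expect_true("hom" %in% ctrl$replacer_gene)
    expect_true(all(ctrl$mode == "blast_control"))
    # a 20%-identity homolog is invisible to the stringent control ...
    ps20 <- mini_proteome(identity = 0.20, len = 200, seed = 33)
    ctrl20 <- blastControlPairs(ps20, "root")
    expect_false("hom" %in% ctrl20$replacer_gene)
    # ... but recruited by the relaxed iterative search
    tr <- iterateSearch("root", ps20, newick = FALSE)
    expect_true("hom" %in% treeMembers(tr))
})
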