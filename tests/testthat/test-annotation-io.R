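# Readers/writers: FASTA + annotation loading, model JSON, pair tables.

write_fixture_files <- function(dir = tempfile()) {
    dir.create(dir)
    fasta <- file.path(dir, "p.fasta")
    writeLines(c(">eco1|eco", "MKVLITGASGFIG",
                 ">shi4|shi", "MKVLITGASGYIG"), fasta)
    tsv <- file.path(dir, "a.tsv")
    writeLines(c(paste("gene_id", "organism_id", "function_id",
                       "function_name", "reaction_ids", sep = "\t"),
                 paste("eco1", "eco", "fnA", "A", "rxnA", sep = "\t"),
                 paste("shi4", "shi", "fn4", "four", "rxn4", sep = "\t")),
               tsv)
    list(dir = dir, fasta = fasta, tsv = tsv)
}

test_that("proteome loading attaches annotations and keeps every record", {
    fx <- write_fixture_files()
    ps <- loadProteome(fx$fasta, fx$tsv)
    expect_s4_class(ps, "ProteomeSet")
    expect_equal(length(ps), 2L)
    expect_setequal(geneIds(ps), c("eco1", "shi4"))
    expect_equal(primaryFunctions(ps, "eco1"), "fnA")
    expect_true(all(annotations(ps)$is_metabolic))
})

test_that("FASTA records without annotation rows get empty function sets", {
    fx <- write_fixture_files()
    cat(">orphan|eco\nMKWWL\n", file = fx$fasta, append = TRUE)
    ps <- loadProteome(fx$fasta, fx$tsv)
    expect_equal(length(ps), 3L)
    expect_identical(primaryFunctions(ps, "orphan"), character(0))
    expect_false(annotations(ps)["orphan", "is_metabolic"])
    # organism recovered from the header
    expect_equal(annotations(ps)["orphan", "organism_id"], "eco")
})

test_that("annotation rows without sequences warn but are retained", {
    fx <- write_fixture_files()
    cat(paste("ghost", "eco", "fnG", "G", "", sep = "\t"), "\n",
        sep = "", file = fx$tsv, append = TRUE)
    expect_warning(ps <- loadProteome(fx$fasta, fx$tsv),
                   "lack a FASTA record")
    expect_true("ghost" %in% annotations(ps)$gene_id)
    expect_equal(length(ps), 2L)   # still only two sequence records
    expect_false(annotations(ps)["ghost", "is_metabolic"])
})

test_that("duplicate gene ids and bad residues are hard errors", {
    fx <- write_fixture_files()
    cat(">eco1|eco\nMKWWL\n", file = fx$fasta, append = TRUE)
    expect_error(loadProteome(fx$fasta, fx$tsv), "duplicate gene_id")
    fx2 <- write_fixture_files()
    # U (selenocysteine) survives the FASTA parser but is outside the
    # 20-letter + X alphabet the engine scores
    cat(">badseq|eco\nMKUWL\n", file = fx2$fasta, append = TRUE)
    expect_error(loadProteome(fx2$fasta, fx2$tsv), "badseq")
})

test_that("is_metabolic follows the reaction catalog when one is given", {
    fx <- write_fixture_files()
    catalog <- list(fnA = list(list(id = "r1",
                                    stoichiometry = list(A = -1, B = 1),
                                    lower_bound = 0, upper_bound = 1)))
    ps <- loadProteome(fx$fasta, fx$tsv, catalog = catalog)
    expect_true(annotations(ps)["eco1", "is_metabolic"])
    expect_false(annotations(ps)["shi4", "is_metabolic"])  # fn4 not in catalog
})

test_that("proteome write/load round-trips sequences and annotations", {
    fx <- generateProteome(fixtureSpec(seed = 3, nOrganisms = 2,
                                       nGenesPerOrganism = 10,
                                       seqLength = 40,
                                       steppingStone = FALSE,
                                       plantedLinks = data.frame(
        root = "org1_g001", foreign = "org2_g005", identity = 0.5,
        function_id = "fn_x", target = "org1_g002",
        stringsAsFactors = FALSE)), dir = tempfile())
    ps2 <- loadProteome(fx$paths[["fasta"]], fx$paths[["annotations"]])
    ps1 <- fx$proteome
    expect_identical(as.character(sequences(ps2)),
                     as.character(sequences(ps1)))
    expect_identical(annotations(ps2)$is_metabolic,
                     annotations(ps1)$is_metabolic)
    expect_identical(lapply(annotations(ps2)$functions, sort),
                     lapply(annotations(ps1)$functions, sort))
})

test_that("model loading enforces schema invariants", {
    gem <- generateToyGem(dir = tempfile())
    m <- loadModel(gem$paths[["model"]])
    expect_s4_class(m, "MetabolicModel")
    expect_equal(length(m@rxns), 9L)
    expect_equal(m@biomass, "Biomass")
    expect_setequal(names(m@media), c("M9", "rich"))

    js <- jsonlite::fromJSON(gem$paths[["model"]], simplifyVector = FALSE)
    js$media <- NULL
    f <- tempfile(); writeLines(jsonlite::toJSON(js, auto_unbox = TRUE), f)
    expect_error(loadModel(f), "media")

    js2 <- jsonlite::fromJSON(gem$paths[["model"]],
                              simplifyVector = FALSE)
    js2$biomass_reaction <- NULL
    f2 <- tempfile(); writeLines(jsonlite::toJSON(js2, auto_unbox = TRUE),
                                 f2)
    expect_error(loadModel(f2), "biomass")

    js3 <- jsonlite::fromJSON(gem$paths[["model"]],
                              simplifyVector = FALSE)
    js3$reactions[[4]]$lower_bound <- 5
    js3$reactions[[4]]$upper_bound <- 1
    f3 <- tempfile(); writeLines(jsonlite::toJSON(js3, auto_unbox = TRUE),
                                 f3)
    expect_error(loadModel(f3), "lower_bound > upper_bound")
})

test_that("dead-end metabolites only warn", {
    expect_warning(makeModel(list(
        list(id = "EX_A", stoichiometry = list(A = -1),
             lower_bound = -1, upper_bound = 0),
        list(id = "R1", stoichiometry = list(A = -1, D = 1),
             lower_bound = 0, upper_bound = 1)),
        biomass = "R1", media = list(M9 = c(EX_A = 1))),
        "dead end")
})

test_that("pair tables round-trip through TSV, sorted and header-only when empty", {
    f <- tempfile()
    writePairs(emptyPairs(), f)
    expect_length(readLines(f), 1L)   # header only
    p <- emptyPairs()[0, ]
    p <- rbind(p, data.frame(target_gene = c("t2", "t1"),
                             replacer_gene = c("r1", "r9"),
                             mode = "direct",
                             promiscuous_function = c("f1", "f2"),
                             evidence_gene = "e", evidence_organism = "o",
                             identity = c(0.5, 0.25), positives = 0.75,
                             coverage = 1, rescued_growth = NA_real_,
                             isozyme_by_annotation = FALSE))
    writePairs(p, f)
    back <- readPairs(f)
    expect_equal(back$target_gene, c("t1", "t2"))   # sorted
    expect_equal(nrow(back), 2L)
    expect_equal(back$identity, c(0.25, 0.5))
    expect_identical(back$isozyme_by_annotation, c(FALSE, FALSE))
})

test_that("complex definitions need at least two subunit roles", {
    f <- tempfile()
    writeLines(c("function_id\tsubunit_role_id",
                 "cplx1\troleA", "cplx1\troleB", "cplx2\tonly"), f)
    expect_error(loadComplexes(f), "cplx2")
    writeLines(c("function_id\tsubunit_role_id",
                 "cplx1\troleA", "cplx1\troleB"), f)
    cx <- loadComplexes(f)
    expect_equal(cx$cplx1, c("roleA", "roleB"))
})
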