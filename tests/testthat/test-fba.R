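# Flux-balance analysis core: LP oracle cases, GPR semantics, media,
# essentiality, reaction addition.

test_that("linear-chain objectives match hand LP solutions", {
    s <- fba(chain_model(uptake = 10))
    expect_equal(s@status, "optimal")
    expect_equal(s@objective, 10, tolerance = 1e-9)
    expect_equal(fba(chain_model(uptake = 10, cap = 4))@objective, 4,
                 tolerance = 1e-9)
})

test_that("biomass needing an unproducible metabolite gives zero growth", {
    m <- makeModel(list(
        list(id = "EX_A", stoichiometry = list(A = -1),
             lower_bound = -10, upper_bound = 0),
        list(id = "R1", stoichiometry = list(A = -1, B = 1),
             lower_bound = 0, upper_bound = 1000),
        list(id = "BIO", stoichiometry = list(B = -1, V = -1, BM = 1),
             lower_bound = 0, upper_bound = 1000),
        list(id = "EX_BM", stoichiometry = list(BM = -1),
             lower_bound = 0, upper_bound = 1000),
        list(id = "SINK_V", stoichiometry = list(V = -1),
             lower_bound = 0, upper_bound = 1000)),
        biomass = "BIO", media = list(M9 = c(EX_A = 10)))
    expect_equal(fba(m)@objective, 0, tolerance = 1e-9)
})

test_that("optimal solutions satisfy mass balance and bounds", {
    gem <- generateToyGem()
    for (medium in c("M9", "rich")) {
        m <- applyMedium(gem$model, medium)
        s <- fba(m)
        expect_equal(s@status, "optimal")
        expect_lte(max(abs(as.matrix(m@S) %*% s@fluxes)), 1e-9)
        expect_true(all(s@fluxes >= m@lb - 1e-9))
        expect_true(all(s@fluxes <= m@ub + 1e-9))
    }
})

test_that("GPR boolean semantics drive knockouts", {
    rxn <- function(gpr) makeModel(list(
        list(id = "EX_A", stoichiometry = list(A = -1),
             lower_bound = -10, upper_bound = 0),
        list(id = "R", stoichiometry = list(A = -1, B = 1),
             lower_bound = 0, upper_bound = 1000, gpr = gpr),
        list(id = "EX_B", stoichiometry = list(B = -1),
             lower_bound = 0, upper_bound = 1000)),
        biomass = "R", media = list(M9 = c(EX_A = 10)))

    closed <- function(m) m@ub[m@rxns == "R"] == 0
    expect_true(closed(knockoutGenes(rxn("g1 and g2"), "g1")))
    expect_false(closed(knockoutGenes(rxn("g1 or g2"), "g1")))
    expect_true(closed(knockoutGenes(rxn("(g1 and g2) or g3"),
                                     c("g1", "g3"))))
    expect_false(closed(knockoutGenes(rxn("(g1 and g2) or g3"), "g1")))
    # case-insensitive keywords; empty GPR untouched
    expect_false(closed(knockoutGenes(rxn("g1 OR g2"), "g1")))
    expect_warning(m_empty <- knockoutGenes(rxn(""), "g1"),
                   "absent from every")
    expect_false(closed(m_empty))
})

test_that("knockouts behave as set operations", {
    gem <- generateToyGem()
    m <- gem$model
    expect_identical(knockoutGenes(m, character(0))@ub, m@ub)
    ab <- knockoutGenes(knockoutGenes(m, "org1_g020"), "org1_g021")
    ba <- knockoutGenes(knockoutGenes(m, "org1_g021"), "org1_g020")
    expect_identical(ab@ub, ba@ub)
    expect_identical(ab@lb, ba@lb)
    expect_warning(knockoutGenes(m, "nosuchgene"), "absent from every")
})

test_that("media application closes uptake, keeps secretion, is idempotent", {
    gem <- generateToyGem()
    m1 <- applyMedium(gem$model, "M9")
    i <- match("EX_V", m1@rxns)
    expect_equal(m1@lb[i], 0)            # vitamin uptake closed on M9
    expect_equal(m1@ub[i], 1000)         # secretion untouched
    m2 <- applyMedium(m1, "M9")
    expect_identical(m1@lb, m2@lb)
    expect_identical(m1@ub, m2@ub)
    expect_error(applyMedium(gem$model, "broth"), "unknown medium")
})

test_that("essentiality classes cover the three planted cases", {
    gem <- generateToyGem()
    expect_equal(essentialityClass(gem$model, "org1_g021"),
                 "conditionally_essential")
    expect_equal(essentialityClass(gem$model, "org1_g020"),
                 "nonessential")          # isozyme-redundant step
    suppressWarnings(
        expect_equal(essentialityClass(gem$model, "org1_g019"),
                     "always_essential"))
    # ordering of reactions in the model must not matter
    perm <- rev(seq_along(gem$model@rxns))
    m2 <- gem$model
    m2@rxns <- m2@rxns[perm]; m2@S <- m2@S[, perm]
    m2@lb <- m2@lb[perm]; m2@ub <- m2@ub[perm]; m2@gpr <- m2@gpr[perm]
    expect_equal(essentialityClass(m2, "org1_g021"),
                 "conditionally_essential")
})

test_that("a baseline that cannot grow is an explicit error", {
    gem <- generateToyGem()
    m <- gem$model
    m@ub[match("EX_A", m@rxns)] <- 0
    m@media$M9 <- c(EX_A = 0)
    expect_error(essentialityClass(m, "org1_g021"),
                 "infeasible baseline")
})

test_that("reaction addition is pure and respects metabolite declarations", {
    gem <- generateToyGem()
    m <- applyMedium(gem$model, "M9")
    base <- fba(m)@objective
    # zero-bounded addition changes nothing
    z <- addReaction(m, list(id = "Rz",
                             stoichiometry = list(A = -1, V = 1),
                             lower_bound = 0, upper_bound = 0))
    expect_equal(fba(z)@objective, base, tolerance = 1e-9)
    # duplicate of an existing reaction changes nothing
    d <- addReaction(m, list(id = "R_v1",
                             stoichiometry = list(A = -1, I1 = 1),
                             lower_bound = 0, upper_bound = 1000))
    expect_true("R_v1_added" %in% d@rxns)   # fresh id on collision
    expect_equal(fba(d)@objective, base, tolerance = 1e-9)
    # unknown metabolites are an error unless declared new
    bad <- list(id = "Rq", stoichiometry = list(QQ = -1, A = 1),
                lower_bound = 0, upper_bound = 10)
    expect_error(addReaction(m, bad), "QQ")
    ok <- addReaction(m, bad, allowNewMetabolites = TRUE)
    expect_true("QQ" %in% ok@mets)
    # the original model is untouched (pure operation)
    expect_equal(length(m@rxns), length(applyMedium(gem$model,
                                                    "M9")@rxns))
})

test_that("a bypass restores a broken chain to its capacity", {
    ko <- applyMedium(knockoutGenes(generateToyGem()$model,
                                    "org1_g021"), "M9")
    expect_equal(fba(ko)@objective, 0, tolerance = 1e-9)
    fixed <- addReaction(ko, list(id = "R_p5ps",
                                  stoichiometry = list(A = -1, V = 1),
                                  lower_bound = 0, upper_bound = 1000))
    expect_equal(fba(fixed)@objective, 10 / 1.1, tolerance = 1e-6)
})

test_that("adding a reaction never lowers the optimum", {
    set.seed(19)
    suppressWarnings(for (rep in 1:40) {
        m <- applyMedium(generateToyGem(uptake = runif(1, 1, 20))$model,
                         sample(c("M9", "rich"), 1))
        mets <- sample(m@mets, 2)
        r <- list(id = paste0("rnd", rep),
                  stoichiometry = setNames(list(-1, sample(c(1, 2), 1)),
                                           mets),
                  lower_bound = 0, upper_bound = runif(1, 0, 50))
        before <- fba(m)@objective
        after <- fba(addReaction(m, r))@objective
        expect_gte(after, before - 1e-9)
    })
})
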