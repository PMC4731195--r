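# Deterministic generators for every input class: multi-organism
# proteomes with planted homology structure, annotation tables, complex
# definitions, reaction catalogs, and a toy metabolic model with a
# conditionally essential vitamin pathway plus a planted bypass
# reaction. Everything is a pure function of (spec, seed), so the whole
# pipeline is testable with no downloads.

#' Fixture specification
#'
#' Defaults define the package's reference study conditions: 3
#' organisms x 50 genes of length 200, background sequences i.i.d.
#' uniform over the 20 residues (expected mutual identity ~5\%, far
#' below the 0.15 identity gate), four planted direct links at
#' identities 0.45/0.35/0.25/0.20 with matching planted targets, one
#' planted foreign bypass function (vitamin-synthase-like, feeding the
#' toy model), two decoy links whose functions map to non-rescuing
#' catalog reactions, and a stepping-stone chain (root-A 0.5, A-B 0.5,
#' root-B ~0.25) that only multi-round search can traverse.
#'
#' @param seed integer master seed.
#' @param nOrganisms,nGenesPerOrganism,seqLength fixture dimensions.
#' @param plantedLinks data.frame with columns root, foreign,
#'   identity, function_id, target (NA when the planted function has no
#'   in-scope target gene); NULL for the defaults above.
#' @param steppingStone include the stepping-stone chain.
#' @return A list of class "FixtureSpec".
#' @export
fixtureSpec <- function(seed = 1, nOrganisms = 3, nGenesPerOrganism = 50,
                        seqLength = 200, plantedLinks = NULL,
                        steppingStone = TRUE) {
    stopifnot(nOrganisms >= 2, nGenesPerOrganism >= 10, seqLength >= 30)
    if (is.null(plantedLinks))
        plantedLinks <- data.frame(
            root = c("org1_g001", "org1_g002", "org1_g003", "org1_g004",
                     "org1_g005", "org1_g006", "org1_g007"),
            foreign = c("org2_g031", "org2_g032", "org3_g033",
                        "org3_g034", "org2_g035", "org2_g036",
                        "org3_g037"),
            identity = c(0.45, 0.35, 0.25, 0.20, 0.40, 0.45, 0.45),
            function_id = c("fn_d1", "fn_d2", "fn_d3", "fn_d4",
                            "fn_p5ps", "fn_decoy_deadend",
                            "fn_decoy_duplicate"),
            target = c("org1_g011", "org1_g012", "org1_g013",
                       "org1_g014", NA, NA, NA),
            stringsAsFactors = FALSE)
    structure(list(seed = as.integer(seed), nOrganisms = nOrganisms,
                   nGenesPerOrganism = nGenesPerOrganism,
                   seqLength = seqLength, plantedLinks = plantedLinks,
                   steppingStone = steppingStone),
              class = "FixtureSpec")
}

.randomSeq <- function(n) paste0(sample(.AA20, n, replace = TRUE),
                                 collapse = "")

#' Mutate a sequence toward a target percent identity
#'
#' Each position is substituted independently with probability
#' \code{1 - targetIdentity}, so the realized identity is binomially
#' concentrated around the target. Replacement residues are drawn
#' BLOSUM62-conditionally (P(b | a) proportional to
#' exp(0.3 s(a, b)), b != a), emulating the conservative substitutions
#' of real divergent homologs; uniform replacement would depress the
#' positive-match fraction far below what homologs at the same identity
#' show. Deterministic per seed; the caller's RNG state is untouched.
#'
#' @param seq amino-acid string.
#' @param targetIdentity fraction in (0, 1].
#' @param seed integer seed.
#' @return Mutated sequence of the same length.
#' @export
#' @examples
#' s <- paste(rep("ACDEFGHIKL", 3), collapse = "")
#' mutateSequence(s, 1.0, 7) == s
mutateSequence <- function(seq, targetIdentity, seed) {
    stopifnot(targetIdentity > 0, targetIdentity <= 1)
    if (targetIdentity == 1) return(seq)
    b62 <- .blosum62()[.AA20, .AA20]
    W <- exp(0.3 * b62)
    diag(W) <- 0
    .withSeed(seed, {
        chars <- strsplit(seq, "")[[1L]]
        hit <- runif(length(chars)) > targetIdentity
        for (i in which(hit)) {
            a <- chars[i]
            if (!a %in% .AA20) next       # leave X untouched
            chars[i] <- sample(.AA20, 1L, prob = W[a, ])
        }
        paste0(chars, collapse = "")
    })
}

#' Generate a synthetic annotated proteome with planted homology
#'
#' Background genes get i.i.d. uniform random sequences and unique
#' metabolic background functions; planted foreign genes are mutated
#' copies of their root at the specified identity and carry the planted
#' function; planted targets keep random sequences but take the planted
#' function as their primary annotation. Organism 1 is the in-scope
#' ("E. coli-like") organism. Two organism-1 genes are left
#' non-metabolic to exercise scope filtering. When \code{dir} is given,
#' proteome.fasta, annotations.tsv and complexes.tsv are written there
#' (byte-identical across runs with the same spec).
#'
#' @param spec a [fixtureSpec()].
#' @param dir optional output directory.
#' @return list: \code{proteome} ([ProteomeSet-class]), \code{truth}
#'   (data.frame of planted elements: kind, root/replacer, foreign,
#'   target, function_id, identity), \code{paths} (when \code{dir}
#'   given).
#' @export
generateProteome <- function(spec = fixtureSpec(), dir = NULL) {
    stopifnot(inherits(spec, "FixtureSpec"))
    orgs <- paste0("org", seq_len(spec$nOrganisms))
    ids <- unlist(lapply(orgs, function(o)
        sprintf("%s_g%03d", o, seq_len(spec$nGenesPerOrganism))))
    orgOf <- rep(orgs, each = spec$nGenesPerOrganism)
    names(orgOf) <- ids

    seqs <- .withSeed(spec$seed, {
        vapply(ids, function(i) .randomSeq(spec$seqLength), "")
    })
    pl <- spec$plantedLinks
    stopifnot(all(c(pl$root, pl$foreign, pl$target[!is.na(pl$target)])
                  %in% ids))
    for (k in seq_len(nrow(pl)))
        seqs[pl$foreign[k]] <- mutateSequence(
            seqs[pl$root[k]], pl$identity[k],
            seed = (as.numeric(spec$seed) * 1009 + k) %% 2147483647)

    truth <- data.frame(kind = rep("direct_link", nrow(pl)),
                        root = pl$root,
                        foreign = pl$foreign, target = pl$target,
                        function_id = pl$function_id,
                        identity = pl$identity, stringsAsFactors = FALSE)
    truth$kind[grepl("^fn_decoy", truth$function_id)] <- "decoy_link"
    truth$kind[truth$function_id == "fn_p5ps"] <- "indirect_link"

    stoneIds <- character()
    if (isTRUE(spec$steppingStone)) {
        stone <- c(root = "org1_g008",
                   A = sprintf("org2_g%03d", spec$nGenesPerOrganism - 1L),
                   B = sprintf("org%d_g%03d", spec$nOrganisms,
                               spec$nGenesPerOrganism))
        seqs[stone["A"]] <- mutateSequence(
            seqs[stone["root"]], 0.5,
            seed = (as.numeric(spec$seed) * 1009 + 101) %% 2147483647)
        seqs[stone["B"]] <- mutateSequence(
            seqs[stone["A"]], 0.5,
            seed = (as.numeric(spec$seed) * 1009 + 102) %% 2147483647)
        truth <- rbind(truth, data.frame(
            kind = "stepping_stone", root = stone["root"],
            foreign = stone["B"], target = NA_character_,
            function_id = "fn_stone", identity = 0.25))
        stoneIds <- stone
    }

    fns <- paste0("fn_bg_", ids)          # unique background functions
    names(fns) <- ids
    for (k in seq_len(nrow(pl))) {
        fns[pl$foreign[k]] <- pl$function_id[k]
        if (!is.na(pl$target[k])) fns[pl$target[k]] <- pl$function_id[k]
    }
    if (length(stoneIds)) {
        fns[stoneIds["A"]] <- "fn_stoneA"
        fns[stoneIds["B"]] <- "fn_stone"
    }
    nonMetabolic <- c("org1_g015", "org1_g016")
    ann <- data.frame(gene_id = ids, organism_id = orgOf[ids],
                      stringsAsFactors = FALSE)
    ann$functions <- I(as.list(fns[ids]))
    ann$is_metabolic <- !(ids %in% nonMetabolic)
    proteome <- ProteomeSet(seqs, ann)
    rownames(truth) <- NULL

    out <- list(proteome = proteome, truth = truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        fasta <- file.path(dir, "proteome.fasta")
        annF <- file.path(dir, "annotations.tsv")
        cplxF <- file.path(dir, "complexes.tsv")
        writeProteome(proteome, fasta, annF)
        .writeTsv(data.frame(
            function_id = c("fn_cplx", "fn_cplx"),
            subunit_role_id = c("fn_cplx_su1", "fn_cplx_su2")), cplxF)
        .writeTsv(truth, file.path(dir, "truth_proteome.tsv"))
        out$paths <- c(fasta = fasta, annotations = annF,
                       complexes = cplxF)
    }
    out
}

#' Generate the toy metabolic model with a planted bypass
#'
#' Topology modelled on a conditionally essential vitamin-biosynthesis
#' pathway: carbon enters through EX_A, biomass consumes an activated
#' carbon species P0 plus 0.1 unit of vitamin V, and V is made by the
#' three-step chain A -> I1 -> I2 -> V (genes org1_g020/21/22). The
#' rich medium also supplies V directly (EX_V), so knocking out the
#' middle chain gene (org1_g021, the planted target) kills growth
#' on M9 only: conditional essentiality by construction. The catalog
#' holds exactly one rescuing reaction - the planted one-step bypass
#' A -> V under the foreign function fn_p5ps - plus decoys that cannot
#' rescue (a dead-end product, a duplicate of a native step, and a
#' reaction over unknown metabolites). Redundant isozyme reactions make
#' org1_g020 nonessential, and the carbon-activation gene org1_g019 is
#' essential on both media.
#'
#' @param dir optional output directory (writes model.json,
#'   catalog.json, truth_gem.tsv; byte-identical across runs).
#' @param uptake carbon/vitamin uptake bound magnitude.
#' @return list: \code{model} ([MetabolicModel-class]), \code{catalog}
#'   (as from [loadReactionCatalog()]), \code{truth} (data.frame with
#'   the planted target gene, bypass function and expected objectives).
#' @export
generateToyGem <- function(dir = NULL, uptake = 10) {
    rx <- function(id, st, lb, ub, gpr = NULL) {
        r <- list(id = id, stoichiometry = as.list(st), lower_bound = lb,
                  upper_bound = ub)
        if (!is.null(gpr)) r$gpr <- gpr
        r
    }
    reactions <- list(
        rx("EX_A",    c(A = -1),                0, 1000),
        rx("EX_V",    c(V = -1),                0, 1000),
        rx("EX_BM",   c(BM = -1),               0, 1000),
        rx("R_act",   c(A = -1, P0 = 1),        0, 1000, "org1_g019"),
        rx("R_v1",    c(A = -1, I1 = 1),        0, 1000, "org1_g020"),
        rx("R_v1b",   c(A = -1, I1 = 1),        0, 1000, "org1_g023"),
        rx("R_v2",    c(I1 = -1, I2 = 1),       0, 1000, "org1_g021"),
        rx("R_v3",    c(I2 = -1, V = 1),        0, 1000, "org1_g022"),
        rx("Biomass", c(P0 = -1, V = -0.1, BM = 1), 0, 1000))
    media <- list(M9 = c(EX_A = uptake),
                  rich = c(EX_A = uptake, EX_V = uptake))
    model <- makeModel(reactions, biomass = "Biomass", media = media)
    catalog <- list(
        fn_p5ps = list(rx("R_p5ps", c(A = -1, V = 1), 0, 1000)),
        fn_decoy_deadend = list(rx("R_deadend", c(I1 = -1, D1 = 1),
                                   0, 1000)),
        fn_decoy_duplicate = list(rx("R_dup", c(A = -1, I1 = 1),
                                     0, 1000)),
        fn_decoy_unknown = list(rx("R_unknown", c(Z1 = -1, Z2 = 1),
                                   0, 1000)))
    truth <- data.frame(
        target_gene = "org1_g021", replacer_function = "fn_p5ps",
        bypass_reaction = "R_p5ps",
        wildtype_m9_objective = uptake / 1.1,
        rescued_m9_objective = uptake / 1.1,
        stringsAsFactors = FALSE)
    out <- list(model = model, catalog = catalog, truth = truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        modelF <- file.path(dir, "model.json")
        catF <- file.path(dir, "catalog.json")
        writeModel(model, modelF)
        writeLines(jsonlite::toJSON(catalog, auto_unbox = TRUE,
                                    digits = NA, pretty = TRUE), catF)
        .writeTsv(truth, file.path(dir, "truth_gem.tsv"))
        out$paths <- c(model = modelF, catalog = catF)
    }
    out
}
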