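#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#'   pairwiseAlignment alignedPattern alignedSubject
#' @importFrom S4Vectors isEmpty
#' @importFrom Matrix sparseMatrix colSums rowSums
#' @importFrom ape nj write.tree
#' @importFrom jsonlite fromJSON toJSON
#' @importFrom yaml write_yaml
#' @importFrom stats runif phyper as.dist setNames
#' @importFrom utils read.delim write.table combn data head
#' @useDynLib PromiScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' ProteomeSet: annotated protein sequences from one or more organisms
#'
#' Container pairing an \code{AAStringSet} of protein sequences (named by
#' gene id) with a per-gene annotation table. Annotation rows without a
#' sequence are allowed (they still contribute functions to the
#' promiscuity matrix); every sequence must have an annotation row.
#'
#' The annotation table has columns \code{gene_id}, \code{organism_id},
#' \code{functions} (list column of function-id character vectors) and
#' \code{is_metabolic} (TRUE when at least one function maps to a
#' metabolic reaction).
#'
#' @slot sequences AAStringSet, names are gene ids (unique).
#' @slot annotations data.frame as described above, one row per gene.
#' @seealso [loadProteome()], [generateProteome()]
#' @exportClass ProteomeSet
setClass("ProteomeSet",
    representation(sequences = "AAStringSet", annotations = "data.frame"))

setValidity("ProteomeSet", function(object) {
    msg <- character()
    ids <- names(object@sequences)
    if (length(ids) && anyDuplicated(ids))
        msg <- c(msg, "duplicate gene ids in sequences")
    ann <- object@annotations
    need <- c("gene_id", "organism_id", "functions", "is_metabolic")
    if (!all(need %in% colnames(ann)))
        msg <- c(msg, paste("annotations must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (anyDuplicated(ann$gene_id))
            msg <- c(msg, "duplicate gene ids in annotations")
        if (!all(ids %in% ann$gene_id))
            msg <- c(msg, "every sequence needs an annotation row")
    }
    if (length(object@sequences)) {
        ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$",
                    as.character(object@sequences))
        if (!all(ok))
            msg <- c(msg, paste0("non-amino-acid characters in record(s): ",
                paste(ids[!ok], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' FilterCriteria: the four hit-retention cutoffs of a search round
#'
#' A hit is kept iff \code{uncovered <= maxUncovered} AND
#' \code{coverage >= minCoverage} AND \code{identity >= minIdentity} AND
#' \code{positives >= minPositives}; all four boundaries are inclusive.
#' Defaults are the final-round cutoffs (uncovered region of the query
#' at most 100 residues, at least 60\% of the query covered, identity at
#' least 0.15, positive-scoring aligned pairs at least 0.30 with
#' identical pairs counted as positives).
#'
#' @slot maxUncovered numeric(1), residues of the query profile left
#'   uncovered by the local alignment.
#' @slot minCoverage,minIdentity,minPositives numeric(1) fractions in
#'   \[0, 1\].
#' @exportClass FilterCriteria
setClass("FilterCriteria",
    representation(maxUncovered = "numeric", minCoverage = "numeric",
                   minIdentity = "numeric", minPositives = "numeric"))

setValidity("FilterCriteria", function(object) {
    msg <- character()
    for (s in c("maxUncovered", "minCoverage", "minIdentity",
                "minPositives")) {
        v <- slot(object, s)
        if (length(v) != 1L || is.na(v)) msg <- c(msg, paste(s, "must be a single number"))
    }
    if (!length(msg)) {
        if (object@maxUncovered < 0) msg <- c(msg, "maxUncovered must be >= 0")
        for (s in c("minCoverage", "minIdentity", "minPositives")) {
            v <- slot(object, s)
            if (v < 0 || v > 1) msg <- c(msg, paste(s, "must be in [0, 1]"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn FilterCriteria-class Constructor.
#' @param maxUncovered,minCoverage,minIdentity,minPositives cutoffs, see
#'   slot descriptions.
#' @return A \code{FilterCriteria} object.
#' @export
#' @examples
#' filterCriteria()                      # final-round defaults
#' filterCriteria(minIdentity = 0.30)    # a stricter first round
filterCriteria <- function(maxUncovered = 100, minCoverage = 0.60,
                           minIdentity = 0.15, minPositives = 0.30) {
    new("FilterCriteria", maxUncovered = as.numeric(maxUncovered),
        minCoverage = as.numeric(minCoverage),
        minIdentity = as.numeric(minIdentity),
        minPositives = as.numeric(minPositives))
}

#' RoundConfig: per-round parameters of the iterative search
#'
#' @slot criteria a [FilterCriteria-class] object.
#' @slot clusterIdentity fraction; members at or above this pairwise
#'   ungapped identity to a retained representative are collapsed before
#'   profile building (redundancy reduction).
#' @slot trimOccupancy fraction; terminal alignment columns whose
#'   non-gap occupancy is below this are trimmed (non-conserved ends).
#' @exportClass RoundConfig
setClass("RoundConfig",
    representation(criteria = "FilterCriteria", clusterIdentity = "numeric",
                   trimOccupancy = "numeric"))

setValidity("RoundConfig", function(object) {
    msg <- character()
    if (object@clusterIdentity <= 0 || object@clusterIdentity > 1)
        msg <- c(msg, "clusterIdentity must be in (0, 1]")
    if (object@trimOccupancy < 0 || object@trimOccupancy > 1)
        msg <- c(msg, "trimOccupancy must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @describeIn RoundConfig-class Constructor.
#' @param criteria a [FilterCriteria-class] object.
#' @param clusterIdentity,trimOccupancy see slot descriptions.
#' @return A \code{RoundConfig} object.
#' @export
roundConfig <- function(criteria = filterCriteria(), clusterIdentity = 0.90,
                        trimOccupancy = 0.50) {
    new("RoundConfig", criteria = criteria,
        clusterIdentity = as.numeric(clusterIdentity),
        trimOccupancy = as.numeric(trimOccupancy))
}

#' Default three-round schedule of the iterative search
#'
#' Round cutoffs relax monotonically; only the final round's cutoffs are
#' canonical (identity 0.15, positives 0.30, coverage 0.60, uncovered
#' 100), the earlier rounds are configurable package defaults.
#'
#' @return A list of three [RoundConfig-class] objects.
#' @export
#' @examples
#' length(defaultRounds())
defaultRounds <- function() {
    list(
        roundConfig(filterCriteria(50,  0.70, 0.30, 0.45)),
        roundConfig(filterCriteria(75,  0.65, 0.22, 0.37)),
        roundConfig(filterCriteria(100, 0.60, 0.15, 0.30)))
}

#' SearchProfile: position-specific scoring matrix with column consensus
#'
#' Built from a trimmed multiple alignment; one row per retained
#' alignment column, one column per canonical residue. The consensus
#' residue of each column (majority residue, alphabetical tie-break) is
#' the reference against which hit identity and positives are measured.
#'
#' @slot scores numeric matrix, profile length x 20 (log-odds, bits).
#' @slot consensus character vector of consensus residues per column.
#' @slot sourceGenes gene ids of the alignment rows the profile was
#'   built from.
#' @seealso [buildProfile()], [searchProfile()]
#' @exportClass SearchProfile
setClass("SearchProfile",
    representation(scores = "matrix", consensus = "character",
                   sourceGenes = "character"))

setValidity("SearchProfile", function(object) {
    msg <- character()
    if (nrow(object@scores) < 1L) msg <- c(msg, "profile length must be >= 1")
    if (ncol(object@scores) != 20L)
        msg <- c(msg, "profile must score all 20 residues per column")
    if (length(object@consensus) != nrow(object@scores))
        msg <- c(msg, "consensus length must equal profile length")
    if (length(msg)) msg else TRUE
})

#' GeneTree: homologs recruited around a root gene
#'
#' The member table records, for every recruited gene, the statistics of
#' the profile hit under which it was (last) accepted; the root carries
#' a perfect self-hit. The optional Newick topology is decorative:
#' downstream steps consume only the member set.
#'
#' @slot root root gene id.
#' @slot members data.frame with columns gene_id, organism_id, identity,
#'   positives, coverage, uncovered, score.
#' @slot newick single Newick string (possibly NA).
#' @seealso [iterateSearch()]
#' @exportClass GeneTree
setClass("GeneTree",
    representation(root = "character", members = "data.frame",
                   newick = "character"))

setValidity("GeneTree", function(object) {
    msg <- character()
    need <- c("gene_id", "organism_id", "identity", "positives",
              "coverage", "uncovered", "score")
    if (!all(need %in% colnames(object@members)))
        msg <- c(msg, paste("members must have columns:",
                            paste(need, collapse = ", ")))
    else if (!object@root %in% object@members$gene_id)
        msg <- c(msg, "root must be among members")
    if (length(msg)) msg else TRUE
})

#' PromiscuityMatrix: sparse gene-by-promiscuous-function assignments
#'
#' Each entry links a root gene to a function found in its similarity
#' tree but absent from the root's primary annotation, with provenance
#' (the highest-identity tree member carrying that function). Primary
#' annotations and gene metadata ride along so pair prediction is
#' self-contained.
#'
#' @slot entries data.frame: root_gene, function_id, evidence_gene,
#'   evidence_organism, identity, positives, coverage.
#' @slot primaries data.frame: gene_id, function_id (one row per primary
#'   function).
#' @slot geneInfo data.frame: gene_id, organism_id, is_metabolic.
#' @seealso [buildMatrix()], [predictDirectPairs()]
#' @exportClass PromiscuityMatrix
setClass("PromiscuityMatrix",
    representation(entries = "data.frame", primaries = "data.frame",
                   geneInfo = "data.frame"))

setValidity("PromiscuityMatrix", function(object) {
    msg <- character()
    e <- object@entries
    p <- object@primaries
    needE <- c("root_gene", "function_id", "evidence_gene",
               "evidence_organism", "identity", "positives", "coverage")
    if (!all(needE %in% colnames(e)))
        msg <- c(msg, paste("entries must have columns:",
                            paste(needE, collapse = ", ")))
    if (!all(c("gene_id", "function_id") %in% colnames(p)))
        msg <- c(msg, "primaries must have columns gene_id, function_id")
    if (!length(msg) && nrow(e)) {
        selfkey <- paste(p$gene_id, p$function_id)
        bad <- paste(e$root_gene, e$function_id) %in% selfkey
        if (any(bad))
            msg <- c(msg, "a gene's primary function may not appear among its promiscuous entries")
    }
    if (length(msg)) msg else TRUE
})

#' MetabolicModel: stoichiometric network with bounds, GPRs and media
#'
#' @slot mets metabolite ids.
#' @slot rxns reaction ids.
#' @slot S sparse stoichiometric matrix (metabolites x reactions).
#' @slot lb,ub flux bounds (arbitrary units).
#' @slot gpr gene-protein-reaction boolean expressions ("" when none).
#' @slot biomass id of the biomass (objective) reaction.
#' @slot media named list; each medium maps exchange reaction ids to
#'   uptake bound magnitudes (applied as negative lower bounds).
#' @seealso [loadModel()], [fba()], [applyMedium()]
#' @exportClass MetabolicModel
setClass("MetabolicModel",
    representation(mets = "character", rxns = "character", S = "Matrix",
                   lb = "numeric", ub = "numeric", gpr = "character",
                   biomass = "character", media = "list"))

setValidity("MetabolicModel", function(object) {
    msg <- character()
    n <- length(object@rxns)
    if (anyDuplicated(object@rxns)) msg <- c(msg, "duplicate reaction ids")
    if (anyDuplicated(object@mets)) msg <- c(msg, "duplicate metabolite ids")
    if (nrow(object@S) != length(object@mets) || ncol(object@S) != n)
        msg <- c(msg, "S dimensions must match metabolites x reactions")
    if (length(object@lb) != n || length(object@ub) != n ||
        length(object@gpr) != n)
        msg <- c(msg, "lb, ub, gpr must have one entry per reaction")
    else if (any(object@lb > object@ub))
        msg <- c(msg, paste0("lower_bound > upper_bound for reaction(s): ",
            paste(object@rxns[object@lb > object@ub], collapse = ", ")))
    if (!object@biomass %in% object@rxns)
        msg <- c(msg, "biomass reaction id missing from model")
    if (length(msg)) msg else TRUE
})

#' FluxSolution: result of a flux-balance optimization
#'
#' @slot status "optimal" or "infeasible".
#' @slot objective biomass flux at the optimum (NA when infeasible).
#' @slot fluxes named flux vector (empty when infeasible).
#' @seealso [fba()]
#' @exportClass FluxSolution
setClass("FluxSolution",
    representation(status = "character", objective = "numeric",
                   fluxes = "numeric"))
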