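# Flux-balance analysis: media application, biomass LP, GPR-based gene
# knockout, conditional-essentiality classification, reaction addition.

.BIG_BOUND <- 1e6          # stand-in for infinite bounds in the LP
.UNBOUNDED_AT <- 1e5       # objective beyond this signals a missing
                           # exchange constraint

#' Exchange reactions of a model
#'
#' An exchange reaction touches exactly one metabolite (the boundary
#' convention: negative flux is uptake, positive flux secretion).
#'
#' @param model a [MetabolicModel-class].
#' @return Character vector of exchange reaction ids.
#' @export
exchangeReactions <- function(model) {
    model@rxns[Matrix::colSums(model@S != 0) == 1L]
}

#' Genes referenced by a model's GPR rules
#'
#' @param model a [MetabolicModel-class].
#' @return Sorted character vector of gene ids.
#' @export
modelGenes <- function(model) {
    sort(unique(unlist(lapply(model@gpr, .gprGenes))))
}

.gprTokens <- function(gpr) {
    x <- gsub("([()])", " \\1 ", gpr)
    toks <- strsplit(trimws(x), "[[:space:]]+")[[1L]]
    toks[nzchar(toks)]
}

.gprGenes <- function(gpr) {
    if (is.na(gpr) || !nzchar(gpr)) return(character())
    toks <- .gprTokens(gpr)
    toks[!(tolower(toks) %in% c("and", "or")) & !(toks %in% c("(", ")"))]
}

# Evaluate a GPR boolean expression with the given genes knocked out.
# Grammar: gene tokens, `and`, `or`, parentheses (case-insensitive).
# Empty rule -> TRUE (reaction not gene-associated). Unknown tokens are
# genes by definition; genes not in `knocked` are present.
.evalGpr <- function(gpr, knocked) {
    if (is.na(gpr) || !nzchar(trimws(gpr))) return(TRUE)
    toks <- .gprTokens(gpr)
    mapped <- vapply(toks, function(tk) {
        lt <- tolower(tk)
        if (lt == "and") "&&"
        else if (lt == "or") "||"
        else if (tk %in% c("(", ")")) tk
        else if (grepl("^[A-Za-z0-9_.:-]+$", tk)) {
            if (tk %in% knocked) "FALSE" else "TRUE"
        } else stop("bad token in GPR rule: ", tk)
    }, "")
    expr <- paste(mapped, collapse = " ")
    ok <- tryCatch(eval(parse(text = expr), envir = baseenv()),
                   error = function(e)
                       stop("malformed GPR rule: ", gpr, call. = FALSE))
    isTRUE(ok)
}

#' Apply a growth medium to a model
#'
#' Closes the uptake direction (lower bound 0) of every exchange
#' reaction, then opens the exchanges listed in the medium with lower
#' bound \code{-uptake} (media store uptake magnitudes). Secretion
#' bounds are untouched. Idempotent.
#'
#' @param model a [MetabolicModel-class].
#' @param medium medium name, must be in \code{model@media}.
#' @return The constrained model (pure operation).
#' @export
applyMedium <- function(model, medium) {
    if (!medium %in% names(model@media))
        stop("unknown medium '", medium, "'; model defines: ",
             paste(names(model@media), collapse = ", "))
    ex <- exchangeReactions(model)
    m <- model
    i <- match(ex, m@rxns)
    m@lb[i] <- pmax(m@lb[i], 0)
    up <- model@media[[medium]]
    j <- match(names(up), m@rxns)
    if (anyNA(j))
        stop("medium '", medium, "' lists unknown exchange reaction(s): ",
             paste(names(up)[is.na(j)], collapse = ", "))
    m@lb[j] <- -abs(as.numeric(up))
    m
}

#' Flux-balance analysis (biomass maximization)
#'
#' Maximizes the biomass flux subject to steady state (S v = 0) and the
#' flux bounds, via a deterministic two-phase simplex (Bland's rule).
#' Infinite bounds are replaced by +/- 1e6 for the solve; an optimum
#' beyond 1e5 is reported as an error ("unbounded"), signalling a
#' missing exchange constraint.
#'
#' @param model a [MetabolicModel-class].
#' @return A [FluxSolution-class] with status "optimal" (objective and
#'   full flux vector) or "infeasible".
#' @export
fba <- function(model) {
    n <- length(model@rxns)
    lb <- pmax(model@lb, -.BIG_BOUND)
    ub <- pmin(model@ub, .BIG_BOUND)
    obj <- as.numeric(model@rxns == model@biomass)
    S <- as.matrix(model@S)
    # shift x = v - lb >= 0 and eliminate fixed variables (lb == ub,
    # e.g. knocked-out reactions): degenerate zero-range columns choke
    # the two-phase simplex
    free <- which(ub - lb > 0)
    b3 <- as.vector(-S %*% lb)
    A3 <- S[, free, drop = FALSE]
    # drop vacuous steady-state rows; a vacuous row with nonzero RHS
    # means infeasible outright
    vac <- apply(A3 == 0, 1L, all)
    if (any(vac & abs(b3) > 1e-9))
        return(new("FluxSolution", status = "infeasible",
                   objective = NA_real_, fluxes = numeric()))
    A3 <- A3[!vac, , drop = FALSE]
    b3 <- b3[!vac]
    neg <- b3 < 0
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
    if (!length(free))
        stop("model has no free reaction")
    sol <- .lpSolve(obj[free], A1 = diag(nrow = length(free)),
                    b1 = (ub - lb)[free], A3 = A3, b3 = b3)
    if (sol$status == "infeasible")
        return(new("FluxSolution", status = "infeasible",
                   objective = NA_real_, fluxes = numeric()))
    if (sol$status == "unbounded")
        stop("unbounded objective: model lacks an exchange constraint")
    v <- lb
    v[free] <- sol$x + lb[free]
    names(v) <- model@rxns
    objective <- v[[model@biomass]]
    if (objective > .UNBOUNDED_AT)
        stop("unbounded objective: model lacks an exchange constraint")
    new("FluxSolution", status = "optimal", objective = objective,
        fluxes = v)
}

setMethod("show", "FluxSolution", function(object) {
    if (object@status == "optimal")
        cat("FluxSolution: optimal, biomass flux =",
            format(object@objective, digits = 6), "\n")
    else cat("FluxSolution:", object@status, "\n")
})

#' Knock out genes via GPR rules
#'
#' Every reaction whose GPR evaluates to FALSE with the given genes
#' absent gets bounds [0, 0]; reactions with empty GPRs are untouched.
#' \code{knockoutGenes(model, character(0))} is the identity, and
#' knockouts compose as set union.
#'
#' @param model a [MetabolicModel-class].
#' @param genes gene ids to remove.
#' @return The constrained model (pure operation).
#' @export
knockoutGenes <- function(model, genes) {
    genes <- unique(as.character(genes))
    if (!length(genes)) return(model)
    known <- modelGenes(model)
    if (length(setdiff(genes, known)))
        warning("gene(s) absent from every GPR rule: ",
                paste(setdiff(genes, known), collapse = ", "))
    m <- model
    touch <- vapply(m@gpr, function(g) any(genes %in% .gprGenes(g)), NA)
    for (k in which(touch)) {
        if (!.evalGpr(m@gpr[k], genes)) {
            m@lb[k] <- 0
            m@ub[k] <- 0
        }
    }
    m
}

#' Classify gene essentiality across a media pair
#'
#' Growth is a biomass optimum at or above \code{growthEpsilon}
#' ("nominal production of biomass"). After knocking the gene out:
#' growth on both media = "nonessential"; growth on the rich medium
#' only = "conditionally_essential" (the multicopy-suppression
#' precondition); growth on neither = "always_essential".
#'
#' @param model a [MetabolicModel-class].
#' @param gene gene id to knock out.
#' @param media length-2 character: c(minimal, rich) medium names.
#' @param growthEpsilon growth threshold (flux units).
#' @return One of "nonessential", "conditionally_essential",
#'   "always_essential".
#' @export
essentialityClass <- function(model, gene, media = c("M9", "rich"),
                              growthEpsilon = 1e-6) {
    stopifnot(length(media) == 2L)
    wt <- fba(applyMedium(model, media[1L]))
    if (wt@status != "optimal" || wt@objective < growthEpsilon)
        stop("model infeasible baseline: wild type does not grow on ",
             media[1L])
    ko <- knockoutGenes(model, gene)
    grows <- vapply(media, function(md) {
        s <- fba(applyMedium(ko, md))
        g <- s@status == "optimal" && s@objective >= growthEpsilon
        if (s@status == "optimal" && !g &&
            s@objective >= growthEpsilon / 10)
            warning("objective for ", gene, " on ", md,
                    " falls in the ambiguity band [epsilon/10, epsilon)")
        g
    }, NA)
    if (grows[1L] && grows[2L]) "nonessential"
    else if (!grows[1L] && grows[2L]) "conditionally_essential"
    else if (!grows[1L] && !grows[2L]) "always_essential"
    else "nonessential"  # grows on minimal only: not essential anywhere
}

#' Add a reaction to a model
#'
#' Pure operation: returns a new model with the reaction appended (under
#' a fresh id when the given id collides). Metabolites not present in
#' the model are an error unless \code{allowNewMetabolites}; new ones
#' are then declared as internal species (steady state still applies to
#' them, so a dead-end addition cannot carry flux).
#'
#' @param model a [MetabolicModel-class].
#' @param rxn reaction definition list (\code{id},
#'   \code{stoichiometry}, \code{lower_bound}, \code{upper_bound},
#'   optional \code{gpr}).
#' @param allowNewMetabolites declare unknown metabolites instead of
#'   erroring.
#' @return The extended model.
#' @export
addReaction <- function(model, rxn, allowNewMetabolites = FALSE) {
    st <- unlist(rxn$stoichiometry)
    if (!length(st)) stop("empty stoichiometry")
    if (rxn$lower_bound > rxn$upper_bound)
        stop("lower_bound > upper_bound for reaction ", rxn$id)
    newMets <- setdiff(names(st), model@mets)
    if (length(newMets) && !allowNewMetabolites)
        stop("reaction ", rxn$id, " references metabolite(s) absent from ",
             "the model: ", paste(newMets, collapse = ", "))
    id <- rxn$id
    while (id %in% model@rxns) id <- paste0(id, "_added")
    m <- model
    mets <- c(m@mets, newMets)
    S <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(length(mets), length(m@rxns) + 1L),
                              dimnames = list(mets, c(m@rxns, id)))
    S[m@mets, m@rxns] <- m@S
    S[names(st), id] <- st
    m@mets <- mets
    m@rxns <- c(m@rxns, id)
    m@S <- S
    m@lb <- c(m@lb, as.numeric(rxn$lower_bound))
    m@ub <- c(m@ub, as.numeric(rxn$upper_bound))
    m@gpr <- c(m@gpr, .gprField(rxn))
    validObject(m)
    m
}
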