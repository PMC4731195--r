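# Indirect target-replacer prediction: add candidate promiscuous
# reactions to the model after target knockout and test flux-balance
# growth rescue on minimal medium.

# Same stoichiometry up to a positive scale factor?
.sameStoich <- function(a, b) {
    if (!setequal(names(a), names(b))) return(FALSE)
    b <- b[names(a)]
    nz <- which(b != 0)
    if (!length(nz) || any((a != 0) != (b != 0))) return(FALSE)
    ratio <- a[nz] / b[nz]
    all(ratio > 0) && max(ratio) - min(ratio) < 1e-9
}

#' Candidate promiscuous functions for reaction addition
#'
#' Matrix entries eligible for the indirect (bypass) test: the function
#' must be non-native (not among any scope gene's primary annotations),
#' must map to at least one catalog reaction, and at least one of those
#' reactions must not already be carried (same stoichiometry up to
#' scaling) by a gene-associated reaction of the model. Excluded
#' candidates are reported via messages.
#'
#' @param pm a [PromiscuityMatrix-class].
#' @param model a [MetabolicModel-class].
#' @param catalog reaction catalog ([loadReactionCatalog()]).
#' @param scope gene ids defining "native" primaries; defaults to all
#'   metabolic genes known to the matrix.
#' @return data.frame: gene, function_id, reaction_ids
#'   (semicolon-joined), plus provenance columns from the matrix.
#' @export
candidateFunctions <- function(pm, model, catalog, scope = NULL) {
    stopifnot(is(pm, "PromiscuityMatrix"), is(model, "MetabolicModel"))
    gi <- pm@geneInfo
    if (is.null(scope)) scope <- gi$gene_id[gi$is_metabolic %in% TRUE]
    native <- unique(pm@primaries$function_id[
        pm@primaries$gene_id %in% scope])
    e <- pm@entries
    empty <- data.frame(gene = character(), function_id = character(),
                        reaction_ids = character(),
                        evidence_gene = character(),
                        evidence_organism = character(),
                        identity = numeric(), stringsAsFactors = FALSE)
    if (!nrow(e)) return(empty)
    carried <- lapply(which(nzchar(model@gpr)), function(k) {
        col <- model@S[, k]
        col[col != 0]
    })
    rows <- lapply(seq_len(nrow(e)), function(i) {
        fn <- e$function_id[i]
        if (fn %in% native) return(NULL)          # native primary function
        rxns <- catalog[[fn]]
        if (is.null(rxns) || !length(rxns)) {
            message("candidate function ", fn,
                    " skipped: no catalog reaction")
            return(NULL)
        }
        novel <- vapply(rxns, function(r) {
            st <- unlist(r$stoichiometry)
            !any(vapply(carried, .sameStoich, NA, b = st))
        }, NA)
        if (!any(novel)) {
            message("candidate function ", fn, " skipped: all reactions ",
                    "already carried by the model")
            return(NULL)
        }
        data.frame(gene = e$root_gene[i], function_id = fn,
                   reaction_ids = paste(vapply(rxns, function(r) r$id, ""),
                                        collapse = ";"),
                   evidence_gene = e$evidence_gene[i],
                   evidence_organism = e$evidence_organism[i],
                   identity = e$identity[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(empty)
    out <- out[order(out$gene, out$function_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.emptyRescues <- function() {
    data.frame(target_gene = character(), replacer_gene = character(),
               function_id = character(), reaction_ids = character(),
               growth_before = numeric(), growth_after = numeric(),
               rescued = logical(), stringsAsFactors = FALSE)
}

#' Predict indirect target-replacer pairs by growth rescue
#'
#' For each target that is conditionally essential in silico (lethal on
#' the minimal medium after knockout, viable on the rich medium;
#' others are skipped with a message), each candidate function's
#' catalog reactions are added to the knocked-out model on the minimal
#' medium and biomass is re-optimized. A pair is emitted when the
#' addition rescues growth (objective below \code{growthEpsilon}
#' before, at or above it after). By default all reactions of a
#' function are added together (a function is a capability, possibly
#' multi-reaction); \code{perReaction} tests them one at a time.
#' Added reactions keep their catalog bounds. A reaction introducing
#' metabolites unknown to the model is added (new internal species,
#' still mass-balanced) only when it also touches at least one existing
#' metabolite; candidates entirely over unknown metabolites are skipped.
#'
#' @param model a [MetabolicModel-class] (wild type).
#' @param pm a [PromiscuityMatrix-class].
#' @param catalog reaction catalog ([loadReactionCatalog()]).
#' @param targets target gene ids to test.
#' @param scope gene ids whose primary annotations define "native"
#'   functions (passed to [candidateFunctions()]); typically the
#'   in-scope organism's genes.
#' @param media c(minimal, rich) medium names.
#' @param growthEpsilon growth threshold (flux units).
#' @param perReaction add each catalog reaction individually instead of
#'   per function.
#' @return list with \code{pairs} (pair data.frame, mode "indirect",
#'   \code{rescued_growth} = objective after addition) and
#'   \code{rescues} (one row per tested (target, candidate), rescued or
#'   not).
#' @export
predictIndirectPairs <- function(model, pm, catalog, targets,
                                 scope = NULL, media = c("M9", "rich"),
                                 growthEpsilon = 1e-6,
                                 perReaction = FALSE) {
    wt <- fba(applyMedium(model, media[1L]))
    if (wt@status != "optimal" || wt@objective < growthEpsilon)
        stop("model infeasible baseline: wild type does not grow on ",
             media[1L])
    cand <- candidateFunctions(pm, model, catalog, scope = scope)
    pairRows <- list()
    resRows <- list()
    for (tg in sort(unique(targets))) {
        cls <- essentialityClass(model, tg, media = media,
                                 growthEpsilon = growthEpsilon)
        if (cls != "conditionally_essential") {
            message("target ", tg, " skipped: ", cls,
                    " (multicopy suppression needs conditional",
                    " essentiality)")
            next
        }
        koM9 <- applyMedium(knockoutGenes(model, tg), media[1L])
        before <- fba(koM9)
        gBefore <- if (before@status == "optimal") before@objective else 0
        cc <- cand[cand$gene != tg, , drop = FALSE]
        for (i in seq_len(nrow(cc))) {
            fn <- cc$function_id[i]
            rxns <- catalog[[fn]]
            groups <- if (perReaction) lapply(rxns, list) else list(rxns)
            for (grp in groups) {
                m2 <- koM9
                ok <- TRUE
                for (r in grp) {
                    st <- unlist(r$stoichiometry)
                    if (!any(names(st) %in% m2@mets)) {
                        message("reaction ", r$id, " of ", fn, " skipped: ",
                                "no metabolite in common with the model")
                        ok <- FALSE
                        break
                    }
                    m2 <- addReaction(m2, r, allowNewMetabolites = TRUE)
                }
                if (!ok) next
                after <- fba(m2)
                gAfter <- if (after@status == "optimal") after@objective
                          else 0
                rescued <- gBefore < growthEpsilon &&
                           gAfter >= growthEpsilon
                rid <- paste(vapply(grp, function(r) r$id, ""),
                             collapse = ";")
                resRows[[length(resRows) + 1L]] <- data.frame(
                    target_gene = tg, replacer_gene = cc$gene[i],
                    function_id = fn, reaction_ids = rid,
                    growth_before = gBefore, growth_after = gAfter,
                    rescued = rescued, stringsAsFactors = FALSE)
                if (rescued)
                    pairRows[[length(pairRows) + 1L]] <- data.frame(
                        target_gene = tg, replacer_gene = cc$gene[i],
                        mode = "indirect", promiscuous_function = fn,
                        evidence_gene = cc$evidence_gene[i],
                        evidence_organism = cc$evidence_organism[i],
                        identity = cc$identity[i], positives = NA_real_,
                        coverage = NA_real_, rescued_growth = gAfter,
                        isozyme_by_annotation = NA,
                        stringsAsFactors = FALSE)
            }
        }
    }
    pairs <- do.call(rbind, pairRows)
    if (is.null(pairs)) pairs <- emptyPairs()
    key <- paste(pairs$target_gene, pairs$replacer_gene,
                 pairs$promiscuous_function)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    pairs <- pairs[order(pairs$target_gene, pairs$replacer_gene,
                         pairs$promiscuous_function), , drop = FALSE]
    rownames(pairs) <- NULL
    rescues <- do.call(rbind, resRows)
    if (is.null(rescues)) rescues <- .emptyRescues()
    rownames(rescues) <- NULL
    list(pairs = pairs, rescues = rescues)
}
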