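# From gene trees to the gene-by-promiscuous-function matrix, with the
# enzyme-complex expansion rule.

.emptyFunctionEntries <- function() {
    data.frame(function_id = character(), evidence_gene = character(),
               evidence_organism = character(), identity = numeric(),
               positives = numeric(), coverage = numeric(),
               stringsAsFactors = FALSE)
}

#' Collect candidate promiscuous functions from one gene tree
#'
#' Every function annotated on any tree member is a potential
#' promiscuous function of the root, except the root's own primary
#' functions. When several members carry the same function, the
#' provenance records the highest-identity member (ties broken by
#' lexicographic gene id). Members without annotation rows contribute
#' nothing.
#'
#' @param tree a [GeneTree-class].
#' @param proteome a [ProteomeSet-class] supplying annotations.
#' @return data.frame: function_id, evidence_gene, evidence_organism,
#'   identity, positives, coverage.
#' @export
collectTreeFunctions <- function(tree, proteome) {
    stopifnot(is(tree, "GeneTree"), is(proteome, "ProteomeSet"))
    rootFns <- primaryFunctions(proteome, tree@root)
    m <- tree@members[tree@members$gene_id != tree@root, , drop = FALSE]
    if (!nrow(m)) return(.emptyFunctionEntries())
    rows <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
        fns <- setdiff(primaryFunctions(proteome, m$gene_id[i]), rootFns)
        if (!length(fns)) return(NULL)
        data.frame(function_id = fns, evidence_gene = m$gene_id[i],
                   evidence_organism = m$organism_id[i],
                   identity = m$identity[i], positives = m$positives[i],
                   coverage = m$coverage[i], stringsAsFactors = FALSE)
    }))
    if (is.null(rows)) return(.emptyFunctionEntries())
    rows <- rows[order(rows$function_id, -rows$identity,
                       rows$evidence_gene), , drop = FALSE]
    rows <- rows[!duplicated(rows$function_id), , drop = FALSE]
    rownames(rows) <- NULL
    rows
}

#' Expand single-subunit complex hits to the whole-complex function
#'
#' When a promiscuous entry matches a subunit role of an enzyme
#' complex, the complex's full function is predicted for the root as
#' well: an entry for the whole-complex function is added with the same
#' provenance (existing whole-complex entries are left untouched; the
#' highest-identity subunit evidence wins when several roles are hit).
#' Entries not matching any subunit role pass through unchanged; the
#' operation is idempotent.
#'
#' @param fns function-entry data.frame from [collectTreeFunctions()].
#' @param complexes named list from [loadComplexes()] (complex function
#'   id -> subunit role ids); NULL disables expansion.
#' @return The augmented function-entry data.frame.
#' @export
expandComplexes <- function(fns, complexes = NULL) {
    if (is.null(complexes) || !length(complexes) || !nrow(fns)) return(fns)
    add <- list()
    for (cfn in names(complexes)) {
        hit <- fns[fns$function_id %in% complexes[[cfn]], , drop = FALSE]
        if (!nrow(hit) || cfn %in% fns$function_id) next
        hit <- hit[order(-hit$identity, hit$evidence_gene), , drop = FALSE]
        row <- hit[1L, , drop = FALSE]
        row$function_id <- cfn
        add[[cfn]] <- row
    }
    out <- rbind(fns, do.call(rbind, add))
    out <- out[order(out$function_id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Build the promiscuity matrix from gene trees
#'
#' Union over trees of the complex-expanded tree functions; entries
#' whose function is a primary function of the root are excluded (the
#' matrix predicts secondary capabilities only). The matrix is a pure,
#' deterministic function of (trees, annotations, complexes).
#'
#' @param trees list of [GeneTree-class] objects, one per root gene.
#' @param proteome a [ProteomeSet-class] supplying annotations.
#' @param complexes optional complex definitions ([loadComplexes()]).
#' @return A [PromiscuityMatrix-class].
#' @export
buildMatrix <- function(trees, proteome, complexes = NULL) {
    roots <- vapply(trees, function(t) t@root, "")
    if (anyDuplicated(roots))
        stop("duplicate root gene(s) across trees: ",
             paste(unique(roots[duplicated(roots)]), collapse = ", "))
    ann <- annotations(proteome)
    entries <- do.call(rbind, lapply(trees, function(t) {
        fns <- expandComplexes(collectTreeFunctions(t, proteome), complexes)
        fns <- fns[!fns$function_id %in%
                   primaryFunctions(proteome, t@root), , drop = FALSE]
        if (!nrow(fns)) return(NULL)
        cbind(data.frame(root_gene = t@root, stringsAsFactors = FALSE), fns)
    }))
    if (is.null(entries))
        entries <- cbind(data.frame(root_gene = character(),
                                    stringsAsFactors = FALSE),
                         .emptyFunctionEntries())
    entries <- entries[order(entries$root_gene, entries$function_id), ,
                       drop = FALSE]
    rownames(entries) <- NULL
    primaries <- do.call(rbind, lapply(seq_len(nrow(ann)), function(i) {
        fns <- ann$functions[[i]]
        if (!length(fns)) return(NULL)
        data.frame(gene_id = ann$gene_id[i], function_id = fns,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(primaries))
        primaries <- data.frame(gene_id = character(),
                                function_id = character())
    geneInfo <- ann[, c("gene_id", "organism_id", "is_metabolic")]
    rownames(geneInfo) <- NULL
    new("PromiscuityMatrix", entries = entries, primaries = primaries,
        geneInfo = geneInfo)
}

setMethod("show", "PromiscuityMatrix", function(object) {
    cat("PromiscuityMatrix:", nrow(object@entries),
        "promiscuous entr(y/ies) across",
        length(unique(object@entries$root_gene)), "root gene(s);",
        nrow(object@primaries), "primary annotation(s)\n")
})

#' Promiscuous entries of a matrix
#' @param object a [PromiscuityMatrix-class].
#' @return The entry data.frame.
#' @export
setGeneric("matrixEntries",
           function(object) standardGeneric("matrixEntries"))

#' @rdname matrixEntries
#' @export
setMethod("matrixEntries", "PromiscuityMatrix",
          function(object) object@entries)
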