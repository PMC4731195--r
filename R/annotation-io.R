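# Readers and writers for the on-disk artifacts: FASTA proteomes,
# annotation tables, complex definitions, reaction catalogs, metabolic
# model JSON, prediction tables and gene-tree serializations.

.PAIR_COLS <- c("target_gene", "replacer_gene", "mode",
                "promiscuous_function", "evidence_gene",
                "evidence_organism", "identity", "positives", "coverage",
                "rescued_growth", "isozyme_by_annotation")

#' Construct a ProteomeSet in code
#'
#' @param sequences named character vector or AAStringSet of protein
#'   sequences (names are gene ids).
#' @param annotations data.frame with columns \code{gene_id},
#'   \code{organism_id}, \code{functions} (list column) and
#'   \code{is_metabolic}. Missing genes get empty annotations.
#' @return A [ProteomeSet-class].
#' @export
#' @examples
#' ps <- ProteomeSet(c(g1 = "MKV", g2 = "MKL"),
#'     data.frame(gene_id = c("g1", "g2"), organism_id = "eco",
#'                functions = I(list("fnA", "fnB")),
#'                is_metabolic = TRUE))
#' length(ps)
ProteomeSet <- function(sequences, annotations = NULL) {
    if (!is(sequences, "AAStringSet"))
        sequences <- Biostrings::AAStringSet(toupper(sequences))
    if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
        stop("sequences must be uniquely named by gene id")
    ids <- names(sequences)
    if (is.null(annotations))
        annotations <- data.frame(gene_id = character(),
                                  organism_id = character(),
                                  functions = I(list()),
                                  is_metabolic = logical())
    miss <- setdiff(ids, annotations$gene_id)
    if (length(miss)) {
        annotations <- rbind(annotations, data.frame(
            gene_id = miss, organism_id = NA_character_,
            functions = I(rep(list(character()), length(miss))),
            is_metabolic = FALSE))
    }
    rownames(annotations) <- annotations$gene_id
    new("ProteomeSet", sequences = sequences, annotations = annotations)
}

#' @describeIn ProteomeSet-class Number of sequence records.
#' @param x a ProteomeSet.
#' @export
setMethod("length", "ProteomeSet", function(x) length(x@sequences))

#' @describeIn ProteomeSet-class Gene ids of the sequence records.
#' @param object a ProteomeSet.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname ProteomeSet-class
#' @export
setMethod("geneIds", "ProteomeSet", function(object) names(object@sequences))

#' Sequences of a ProteomeSet
#' @param object a [ProteomeSet-class].
#' @return An AAStringSet.
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' @rdname sequences
#' @export
setMethod("sequences", "ProteomeSet", function(object) object@sequences)

#' Annotation table of a ProteomeSet
#' @param object a [ProteomeSet-class].
#' @return The per-gene annotation data.frame (including genes that have
#'   annotation rows but no sequence record).
#' @export
setGeneric("annotations", function(object) standardGeneric("annotations"))

#' @rdname annotations
#' @export
setMethod("annotations", "ProteomeSet", function(object) object@annotations)

#' Primary function ids of one gene
#' @param object a [ProteomeSet-class].
#' @param gene gene id.
#' @return Character vector of primary function ids (empty when the
#'   gene is unannotated).
#' @export
setGeneric("primaryFunctions",
           function(object, gene) standardGeneric("primaryFunctions"))

#' @rdname primaryFunctions
#' @export
setMethod("primaryFunctions", "ProteomeSet", function(object, gene) {
    i <- match(gene, object@annotations$gene_id)
    if (is.na(i)) return(character())
    object@annotations$functions[[i]]
})

#' Metabolic genes of a ProteomeSet
#' @param object a [ProteomeSet-class].
#' @return Gene ids annotated with at least one reaction-linked function.
#' @export
setGeneric("metabolicGenes",
           function(object) standardGeneric("metabolicGenes"))

#' @rdname metabolicGenes
#' @export
setMethod("metabolicGenes", "ProteomeSet", function(object) {
    a <- object@annotations
    a$gene_id[a$is_metabolic]
})

setMethod("show", "ProteomeSet", function(object) {
    orgs <- unique(object@annotations$organism_id)
    cat("ProteomeSet with", length(object@sequences), "sequence(s) from",
        sum(!is.na(orgs)), "organism(s);",
        nrow(object@annotations), "annotated gene(s),",
        sum(object@annotations$is_metabolic), "metabolic\n")
})

#' @describeIn ProteomeSet-class Subset by gene id or index.
#' @param i gene ids (character) or indices.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "ProteomeSet", function(x, i, j, ..., drop = FALSE) {
    seqs <- x@sequences[i]
    ann <- x@annotations[x@annotations$gene_id %in% names(seqs), ,
                         drop = FALSE]
    new("ProteomeSet", sequences = seqs, annotations = ann)
})

#' Load a proteome from FASTA plus an annotation table
#'
#' FASTA headers are either \code{gene_id|organism_id} or a plain gene
#' id resolvable through the annotation table (the first
#' \code{|}-separated token is always the gene id). The annotation TSV
#' has one row per (gene, function) with columns \code{gene_id},
#' \code{organism_id}, \code{function_id}, \code{function_name},
#' \code{reaction_ids} (semicolon-joined, possibly empty).
#'
#' A gene is metabolic when at least one of its functions maps to a
#' reaction: through \code{catalog} when supplied, otherwise through a
#' non-empty \code{reaction_ids} field.
#'
#' @param fasta path to the protein FASTA file.
#' @param annotationFile path to the annotation TSV.
#' @param catalog optional reaction catalog (see
#'   [loadReactionCatalog()]) used to decide \code{is_metabolic}.
#' @return A [ProteomeSet-class]. Sequences without annotation rows get
#'   an empty function set; annotation rows without sequences are kept
#'   (with a warning) for matrix use.
#' @export
loadProteome <- function(fasta, annotationFile, catalog = NULL) {
    seqs <- Biostrings::readAAStringSet(fasta)
    hdr <- strsplit(names(seqs), "|", fixed = TRUE)
    ids <- vapply(hdr, `[`, "", 1L)
    hdrOrg <- vapply(hdr, function(h) if (length(h) > 1L) h[2L] else
                     NA_character_, "")
    if (anyDuplicated(ids))
        stop("duplicate gene_id in FASTA: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(seqs) <- ids
    .validateSequences(seqs)

    tab <- read.delim(annotationFile, stringsAsFactors = FALSE,
                      colClasses = "character")
    need <- c("gene_id", "organism_id", "function_id", "reaction_ids")
    if (!all(need %in% colnames(tab)))
        stop("annotation table must have columns: ",
             paste(need, collapse = ", "))
    orphan <- setdiff(tab$gene_id, ids)
    if (length(orphan))
        warning(length(orphan),
                " annotated gene(s) lack a FASTA record (kept for matrix",
                " use): ", paste(utils::head(orphan, 5L), collapse = ", "))

    split_rows <- split(tab, tab$gene_id)
    ann <- data.frame(
        gene_id = names(split_rows),
        organism_id = vapply(split_rows, function(d) d$organism_id[1L], ""),
        stringsAsFactors = FALSE)
    ann$functions <- I(lapply(split_rows, function(d)
        unique(d$function_id[nzchar(d$function_id)])))
    if (is.null(catalog)) {
        ann$is_metabolic <- vapply(split_rows, function(d)
            any(nzchar(d$reaction_ids)), NA)
    } else {
        ann$is_metabolic <- vapply(ann$functions, function(f)
            any(f %in% names(catalog)), NA)
    }
    # FASTA records without annotation rows
    ps <- ProteomeSet(seqs, ann)
    # fill organisms from headers where the table had none
    a <- ps@annotations
    i <- match(names(seqs), a$gene_id)
    fill <- is.na(a$organism_id[i]) & !is.na(hdrOrg)
    a$organism_id[i[fill]] <- hdrOrg[fill]
    ps@annotations <- a
    validObject(ps)
    ps
}

#' Write a ProteomeSet to FASTA + annotation TSV
#'
#' Inverse of [loadProteome()]; headers are \code{gene_id|organism_id}.
#'
#' @param object a [ProteomeSet-class].
#' @param fasta,annotationFile output paths.
#' @param reactionIds optional named list mapping function_id to
#'   reaction-id character vectors (fills the \code{reaction_ids}
#'   column; defaults to "rxn_<function>" for metabolic genes).
#' @return Invisibly, the two paths.
#' @export
writeProteome <- function(object, fasta, annotationFile,
                          reactionIds = NULL) {
    a <- object@annotations
    seqs <- object@sequences
    org <- a$organism_id[match(names(seqs), a$gene_id)]
    out <- seqs
    names(out) <- ifelse(is.na(org), names(seqs),
                         paste(names(seqs), org, sep = "|"))
    Biostrings::writeXStringSet(out, fasta, width = 80L)
    rows <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
        fns <- a$functions[[i]]
        if (!length(fns)) return(NULL)
        rid <- vapply(fns, function(f) {
            if (!is.null(reactionIds) && !is.null(reactionIds[[f]]))
                paste(reactionIds[[f]], collapse = ";")
            else if (a$is_metabolic[i]) paste0("rxn_", f)
            else ""
        }, "")
        data.frame(gene_id = a$gene_id[i], organism_id = a$organism_id[i],
                   function_id = fns, function_name = fns,
                   reaction_ids = rid, stringsAsFactors = FALSE)
    }))
    if (is.null(rows))
        rows <- data.frame(gene_id = character(), organism_id = character(),
                           function_id = character(),
                           function_name = character(),
                           reaction_ids = character())
    rows <- rows[order(rows$gene_id, rows$function_id), , drop = FALSE]
    .writeTsv(rows, annotationFile)
    invisible(c(fasta, annotationFile))
}

#' Load enzyme-complex definitions
#'
#' TSV with columns \code{function_id} (the whole-complex function) and
#' \code{subunit_role_id}; a complex needs at least two subunit roles.
#'
#' @param path TSV path.
#' @return Named list mapping complex function id to its subunit role
#'   ids.
#' @export
loadComplexes <- function(path) {
    tab <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = "character")
    if (!all(c("function_id", "subunit_role_id") %in% colnames(tab)))
        stop("complex table must have columns function_id, subunit_role_id")
    cx <- lapply(split(tab$subunit_role_id, tab$function_id), unique)
    bad <- names(cx)[lengths(cx) < 2L]
    if (length(bad))
        stop("complex(es) with fewer than 2 subunit roles: ",
             paste(bad, collapse = ", "))
    cx
}

#' Load a reaction catalog
#'
#' JSON object mapping function ids to arrays of reaction definitions
#' (\code{id}, \code{stoichiometry} object of metabolite:coefficient,
#' \code{lower_bound}, \code{upper_bound}, optional \code{gpr}).
#'
#' @param path JSON path.
#' @return Named list: function_id -> list of reaction definition lists.
#' @export
loadReactionCatalog <- function(path) {
    cat <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    for (fn in names(cat)) {
        for (r in cat[[fn]]) {
            if (!length(r$stoichiometry))
                stop("empty stoichiometry in catalog reaction ", r$id)
            if (r$lower_bound > r$upper_bound)
                stop("lower_bound > upper_bound in catalog reaction ", r$id)
        }
    }
    cat
}

#' Construct a MetabolicModel in code
#'
#' @param reactions list of reaction definitions, each a list with
#'   \code{id}, \code{stoichiometry} (named numeric), \code{lower_bound},
#'   \code{upper_bound} and optional \code{gpr}.
#' @param biomass id of the biomass reaction.
#' @param media named list of media; each medium is a named numeric
#'   vector of uptake bound magnitudes keyed by exchange reaction id.
#' @param metabolites optional character vector of metabolite ids; when
#'   supplied, stoichiometries referencing undeclared metabolites are an
#'   error, otherwise the metabolite set is inferred.
#' @return A [MetabolicModel-class].
#' @export
makeModel <- function(reactions, biomass, media, metabolites = NULL) {
    ids <- vapply(reactions, function(r) r$id, "")
    if (anyDuplicated(ids))
        stop("duplicate reaction ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    usedMets <- unique(unlist(lapply(reactions,
                                     function(r) names(r$stoichiometry))))
    if (is.null(metabolites)) {
        metabolites <- sort(usedMets)
    } else {
        extra <- setdiff(usedMets, metabolites)
        if (length(extra))
            stop("stoichiometry references undeclared metabolite(s): ",
                 paste(extra, collapse = ", "))
    }
    S <- Matrix::sparseMatrix(
        i = integer(), j = integer(), x = numeric(),
        dims = c(length(metabolites), length(ids)),
        dimnames = list(metabolites, ids))
    for (k in seq_along(reactions)) {
        st <- unlist(reactions[[k]]$stoichiometry)
        S[names(st), k] <- st
    }
    gpr <- vapply(reactions, .gprField, "")
    m <- new("MetabolicModel", mets = metabolites, rxns = ids,
             S = S,
             lb = vapply(reactions, function(r) as.numeric(r$lower_bound), 0),
             ub = vapply(reactions, function(r) as.numeric(r$upper_bound), 0),
             gpr = gpr, biomass = biomass,
             media = lapply(media, unlist))
    validObject(m)
    # dead ends: metabolite touched by a single reaction only
    touch <- Matrix::rowSums(S != 0)
    if (any(touch == 1L))
        warning("metabolite(s) touched by a single reaction (dead end): ",
                paste(metabolites[touch == 1L], collapse = ", "))
    m
}

#' Load a metabolic model from JSON
#'
#' Schema: \code{{"metabolites": [{"id": ...}], "reactions": [{"id",
#' "stoichiometry": {met: coef}, "lower_bound", "upper_bound", "gpr"}],
#' "biomass_reaction": id, "media": {"M9": {exchange_id: uptake}, ...}}}.
#'
#' @param path JSON path.
#' @return A [MetabolicModel-class].
#' @export
loadModel <- function(path) {
    js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (is.null(js$biomass_reaction))
        stop("model JSON lacks 'biomass_reaction'")
    if (is.null(js$media) || !length(js$media))
        stop("model JSON lacks a 'media' block; media such as \"M9\" and ",
             "\"rich\" are required for essentiality classification")
    mets <- vapply(js$metabolites, function(m) m$id, "")
    makeModel(js$reactions, biomass = js$biomass_reaction,
              media = js$media, metabolites = mets)
}

#' Write a metabolic model to JSON
#'
#' Deterministic inverse of [loadModel()].
#' @param model a [MetabolicModel-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeModel <- function(model, path) {
    rxns <- lapply(seq_along(model@rxns), function(k) {
        col <- model@S[, k]
        st <- col[col != 0]
        r <- list(id = model@rxns[k],
                  stoichiometry = as.list(st),
                  lower_bound = model@lb[k], upper_bound = model@ub[k])
        if (nzchar(model@gpr[k])) r$gpr <- model@gpr[k]
        r
    })
    js <- list(metabolites = lapply(model@mets, function(m) list(id = m)),
               reactions = rxns,
               biomass_reaction = model@biomass,
               media = lapply(model@media, as.list))
    writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE), path)
    invisible(path)
}

setMethod("show", "MetabolicModel", function(object) {
    cat("MetabolicModel:", length(object@rxns), "reactions,",
        length(object@mets), "metabolites,",
        length(modelGenes(object)), "genes; biomass =", object@biomass,
        "; media:", paste(names(object@media), collapse = ", "), "\n")
})

#' Empty target-replacer pair table
#'
#' @return Zero-row data.frame with the canonical pair columns.
#' @export
emptyPairs <- function() {
    data.frame(target_gene = character(), replacer_gene = character(),
               mode = character(), promiscuous_function = character(),
               evidence_gene = character(), evidence_organism = character(),
               identity = numeric(), positives = numeric(),
               coverage = numeric(), rescued_growth = numeric(),
               isozyme_by_annotation = logical())
}

#' Write target-replacer pairs to TSV
#'
#' Rows are ordered lexicographically by (target_gene, replacer_gene,
#' promiscuous_function); an empty input yields a header-only file.
#'
#' @param pairs data.frame of pairs (see [emptyPairs()] for columns).
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePairs <- function(pairs, path) {
    if (is.null(pairs) || !nrow(pairs)) pairs <- emptyPairs()
    for (cc in setdiff(.PAIR_COLS, colnames(pairs)))
        pairs[[cc]] <- if (cc %in% c("identity", "positives", "coverage",
                                     "rescued_growth")) NA_real_
                       else if (cc == "isozyme_by_annotation") NA
                       else NA_character_
    pairs <- pairs[, .PAIR_COLS, drop = FALSE]
    pairs <- pairs[order(pairs$target_gene, pairs$replacer_gene,
                         pairs$promiscuous_function), , drop = FALSE]
    .writeTsv(pairs, path)
}

#' Read target-replacer pairs from TSV
#'
#' @param path TSV path written by [writePairs()].
#' @return data.frame of pairs.
#' @export
readPairs <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    for (cc in c("identity", "positives", "coverage", "rescued_growth"))
        df[[cc]] <- as.numeric(df[[cc]])
    df$isozyme_by_annotation <- as.logical(df$isozyme_by_annotation)
    df
}

#' Serialize gene trees to JSON (plus optional Newick sidecars)
#'
#' @param trees list of [GeneTree-class] objects.
#' @param path output JSON path.
#' @param newickPath optional path for a Newick file (one tree per
#'   line, ordered by root gene).
#' @return Invisibly, \code{path}.
#' @export
writeGeneTrees <- function(trees, path, newickPath = NULL) {
    trees <- trees[order(vapply(trees, function(t) t@root, ""))]
    js <- lapply(trees, function(t) {
        m <- t@members[order(t@members$gene_id), , drop = FALSE]
        list(root = t@root,
             members = lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])))
    })
    writeLines(jsonlite::toJSON(js, auto_unbox = TRUE, digits = 10,
                                pretty = TRUE), path)
    if (!is.null(newickPath))
        writeLines(vapply(trees, function(t) t@newick, ""), newickPath)
    invisible(path)
}

#' Write a promiscuity matrix to TSV
#'
#' One row per (root gene, promiscuous function) with provenance.
#' @param pm a [PromiscuityMatrix-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePromiscuityMatrix <- function(pm, path) {
    e <- pm@entries
    e <- e[order(e$root_gene, e$function_id), , drop = FALSE]
    .writeTsv(e, path)
}
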