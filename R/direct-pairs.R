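# Direct target-replacer prediction from the promiscuity matrix,
# descriptive statistics (replacers per target, reciprocity), and the
# single-round BLAST-style control baseline.

#' Predict direct target-replacer pairs
#'
#' A pair (target, replacer) is emitted whenever a replacer gene's
#' promiscuously assigned function equals a primary annotated function
#' of a different target gene. Both genes must be in scope and
#' metabolic (the search is restricted to genes whose primary functions
#' are metabolic); self-pairs are excluded and pairs are deduplicated
#' per (target, replacer, function). Pairs whose two genes also share a
#' primary function (isozymes by annotation) are retained and flagged
#' in \code{isozyme_by_annotation}.
#'
#' @param pm a [PromiscuityMatrix-class].
#' @param scope gene ids to consider; defaults to all metabolic genes
#'   known to the matrix.
#' @return Pair data.frame (see [emptyPairs()] for columns), ordered by
#'   (target, replacer, function); \code{mode} is "direct" and
#'   \code{rescued_growth} is NA.
#' @export
predictDirectPairs <- function(pm, scope = NULL) {
    stopifnot(is(pm, "PromiscuityMatrix"))
    gi <- pm@geneInfo
    metabolic <- gi$gene_id[gi$is_metabolic %in% TRUE]
    if (is.null(scope)) scope <- metabolic
    scope <- intersect(scope, metabolic)
    e <- pm@entries[pm@entries$root_gene %in% scope, , drop = FALSE]
    p <- pm@primaries[pm@primaries$gene_id %in% scope, , drop = FALSE]
    if (!nrow(e) || !nrow(p)) return(emptyPairs())
    hit <- merge(e, p, by = "function_id")
    hit <- hit[hit$gene_id != hit$root_gene, , drop = FALSE]
    if (!nrow(hit)) return(emptyPairs())
    primOf <- split(pm@primaries$function_id, pm@primaries$gene_id)
    iso <- vapply(seq_len(nrow(hit)), function(i)
        length(intersect(primOf[[hit$gene_id[i]]],
                         primOf[[hit$root_gene[i]]])) > 0L, NA)
    pairs <- data.frame(
        target_gene = hit$gene_id, replacer_gene = hit$root_gene,
        mode = "direct", promiscuous_function = hit$function_id,
        evidence_gene = hit$evidence_gene,
        evidence_organism = hit$evidence_organism,
        identity = hit$identity, positives = hit$positives,
        coverage = hit$coverage, rescued_growth = NA_real_,
        isozyme_by_annotation = iso, stringsAsFactors = FALSE)
    key <- paste(pairs$target_gene, pairs$replacer_gene,
                 pairs$promiscuous_function)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    pairs <- pairs[order(pairs$target_gene, pairs$replacer_gene,
                         pairs$promiscuous_function), , drop = FALSE]
    rownames(pairs) <- NULL
    pairs
}

#' Distinct replacers per target, with histogram
#'
#' @param pairs pair data.frame.
#' @return list with \code{counts} (named integer vector, targets with
#'   at least one replacer) and \code{histogram} (data.frame
#'   n_replacers / n_targets, for plotting the replacer-per-target
#'   distribution).
#' @export
replacersPerTarget <- function(pairs) {
    if (!nrow(pairs))
        return(list(counts = integer(0),
                    histogram = data.frame(n_replacers = integer(),
                                           n_targets = integer())))
    counts <- vapply(split(pairs$replacer_gene, pairs$target_gene),
                     function(r) length(unique(r)), 0L)
    tb <- table(counts)
    list(counts = counts,
         histogram = data.frame(n_replacers = as.integer(names(tb)),
                                n_targets = as.integer(tb)))
}

#' Reciprocal target-replacer pairs
#'
#' An unordered gene pair \{a, b\} is reciprocal when both (a, b) and
#' (b, a) occur as (target, replacer), i.e. either gene can play either
#' role.
#'
#' @param pairs pair data.frame.
#' @return data.frame with columns gene_a, gene_b (gene_a < gene_b),
#'   one row per reciprocal unordered pair.
#' @export
findReciprocal <- function(pairs) {
    empty <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
    if (!nrow(pairs)) return(empty)
    fwd <- unique(paste(pairs$target_gene, pairs$replacer_gene, sep = "\r"))
    parts <- strsplit(fwd, "\r", fixed = TRUE)
    t <- vapply(parts, `[`, "", 1L)
    r <- vapply(parts, `[`, "", 2L)
    rev <- paste(r, t, sep = "\r")
    both <- fwd %in% rev & t < r
    if (!any(both)) return(empty)
    out <- data.frame(gene_a = t[both], gene_b = r[both],
                      stringsAsFactors = FALSE)
    out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Enumerate unordered within-set gene pairs
#'
#' Utility for isozyme-set comparisons: all unordered pairs of genes
#' drawn from within the same set, across a list of sets.
#'
#' @param sets list of character vectors (gene sets).
#' @return data.frame gene_a / gene_b, one row per unordered pair.
#' @export
#' @examples
#' nrow(withinSetPairs(list(c("aspC", "tyrB"),
#'                          c("argD", "astC", "gabT", "puuE"),
#'                          c("gltA", "prpC"))))   # 8
withinSetPairs <- function(sets) {
    rows <- lapply(sets, function(s) {
        s <- sort(unique(s))
        if (length(s) < 2L) return(NULL)
        cp <- t(combn(s, 2L))
        data.frame(gene_a = cp[, 1L], gene_b = cp[, 2L],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(gene_a = character(), gene_b = character())
    out
}

#' Single-round BLAST-style control pairs
#'
#' The comparison baseline: each target sequence is searched, as a
#' plain single-sequence query (no clustering, trimming or iteration),
#' against the metabolic genes of the proteome, and subjects passing a
#' conventional stringent cutoff become control "replacers". Used to
#' quantify the added value of the iterative profile search.
#'
#' @param proteome a [ProteomeSet-class].
#' @param targets gene ids to use as queries.
#' @param criteria stringent single-round cutoffs. The default
#'   (identity >= 0.35, positives >= 0.50, coverage >= 0.75, uncovered
#'   <= 50) represents annotation-transfer-grade confidence: matches a
#'   conventional search would call homologs outright, above the
#'   twilight zone that the iterative profile search is built to reach.
#' @param scoreFloor,gapOpening,gapExtension passed to [searchProfile()].
#' @return Pair data.frame with \code{mode} "blast_control".
#' @export
blastControlPairs <- function(proteome, targets,
                              criteria = filterCriteria(50, 0.75, 0.35,
                                                        0.50),
                              scoreFloor = 0, gapOpening = 11,
                              gapExtension = 1) {
    stopifnot(is(proteome, "ProteomeSet"))
    if (!length(targets)) return(emptyPairs())
    db <- proteome[intersect(metabolicGenes(proteome), geneIds(proteome))]
    ann <- annotations(proteome)
    rows <- lapply(sort(targets), function(tg) {
        prof <- buildProfile(sequences(proteome)[tg])
        hits <- searchProfile(prof, db, scoreFloor = scoreFloor,
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
        hits <- filterHits(hits, criteria)
        hits <- hits[hits$subject_gene_id != tg, , drop = FALSE]
        if (!nrow(hits)) return(NULL)
        data.frame(
            target_gene = tg, replacer_gene = hits$subject_gene_id,
            mode = "blast_control", promiscuous_function = NA_character_,
            evidence_gene = hits$subject_gene_id,
            evidence_organism = ann$organism_id[
                match(hits$subject_gene_id, ann$gene_id)],
            identity = hits$identity, positives = hits$positives,
            coverage = hits$coverage, rescued_growth = NA_real_,
            isozyme_by_annotation = NA, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) return(emptyPairs())
    out <- out[order(out$target_gene, out$replacer_gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
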