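# The profile-vs-proteome search, the four-cutoff hit filter and the
# iterative (multi-round) homolog recruitment loop.

.emptyHits <- function() {
    data.frame(subject_gene_id = character(), score = numeric(),
               identity = numeric(), positives = numeric(),
               coverage = numeric(), uncovered = integer(),
               q_start = integer(), q_end = integer(),
               s_start = integer(), s_end = integer(),
               n_aligned = integer(), stringsAsFactors = FALSE)
}

#' Search a profile against a proteome
#'
#' One best gapped local alignment (affine gaps) of the profile columns
#' against every database sequence; hits with raw score above
#' \code{scoreFloor} are returned. Per hit: \code{identity} = fraction
#' of aligned pairs whose subject residue equals the column consensus;
#' \code{positives} = fraction of aligned pairs whose
#' (consensus, subject) BLOSUM62 score is positive (identical pairs are
#' always positive, so identity <= positives); \code{coverage} =
#' aligned profile columns / profile length; \code{uncovered} = profile
#' length - aligned columns. Intervals are 0-based half-open.
#'
#' @param profile a [SearchProfile-class].
#' @param db a [ProteomeSet-class] or AAStringSet to search.
#' @param scoreFloor raw-score floor; only hits scoring strictly above
#'   it are reported.
#' @param gapOpening,gapExtension affine gap penalties (a gap of length
#'   k costs opening + k * extension).
#' @return Hit data.frame ordered by decreasing score (ties by gene
#'   id); empty for an empty database.
#' @export
searchProfile <- function(profile, db, scoreFloor = 0,
                          gapOpening = 11, gapExtension = 1) {
    stopifnot(is(profile, "SearchProfile"))
    if (is(db, "ProteomeSet")) db <- sequences(db)
    if (!length(db)) return(.emptyHits())
    L <- profileLength(profile)
    b62 <- .blosum62()
    # transposed for the C++ kernel (alphabet x columns); 21st alphabet
    # row: X scores 0 in every profile column
    prof <- t(cbind(profile@scores, 0))
    alpha <- c(.AA20, "X")
    consIdx <- match(profile@consensus, alpha)
    posMat <- b62 > 0

    out <- vector("list", length(db))
    for (k in seq_along(db)) {
        s <- strsplit(as.character(db[[k]]), "")[[1L]]
        si <- match(s, alpha)
        if (anyNA(si))
            stop("non-amino-acid characters in record ", names(db)[k])
        al <- .profileLocalAlign(prof, si - 1L, gapOpening, gapExtension)
        na <- length(al$q_cols)
        if (al$score <= scoreFloor || na == 0L) next
        qc <- al$q_cols + 1L
        sp <- al$s_pos + 1L
        ident <- mean(alpha[consIdx[qc]] == s[sp])
        pos <- mean(posMat[cbind(consIdx[qc], si[sp])])
        out[[k]] <- data.frame(
            subject_gene_id = names(db)[k], score = al$score,
            identity = ident, positives = pos,
            coverage = na / L, uncovered = L - na,
            q_start = al$q_start, q_end = al$q_end,
            s_start = al$s_start, s_end = al$s_end,
            n_aligned = na, stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, out[!vapply(out, is.null, NA)])
    if (is.null(hits)) return(.emptyHits())
    hits[order(-hits$score, hits$subject_gene_id), , drop = FALSE]
}

#' Filter hits by the four retention cutoffs
#'
#' A hit is kept iff \code{uncovered <= maxUncovered},
#' \code{coverage >= minCoverage}, \code{identity >= minIdentity} and
#' \code{positives >= minPositives}; all boundaries inclusive.
#' Relaxing any cutoff can only grow the kept set (monotonicity).
#'
#' @param hits hit data.frame from [searchProfile()].
#' @param criteria a [FilterCriteria-class].
#' @return The subset of hits passing all four cutoffs.
#' @export
filterHits <- function(hits, criteria = filterCriteria()) {
    stopifnot(is(criteria, "FilterCriteria"))
    if (!nrow(hits)) return(hits)
    keep <- hits$uncovered <= criteria@maxUncovered &
            hits$coverage >= criteria@minCoverage &
            hits$identity >= criteria@minIdentity &
            hits$positives >= criteria@minPositives
    hits[keep, , drop = FALSE]
}

.checkMonotoneRounds <- function(rounds) {
    for (k in seq_along(rounds)[-1L]) {
        a <- rounds[[k - 1L]]@criteria
        b <- rounds[[k]]@criteria
        if (b@minIdentity > a@minIdentity ||
            b@minPositives > a@minPositives ||
            b@minCoverage > a@minCoverage ||
            b@maxUncovered < a@maxUncovered)
            stop("round ", k, " criteria are stricter than round ", k - 1L,
                 "; rounds must relax monotonically")
    }
    invisible(TRUE)
}

.njNewick <- function(aln) {
    n <- length(aln)
    ids <- names(aln)
    if (n == 1L) return(paste0("(", ids, ");"))
    m <- .alnMatrix(aln)
    D <- matrix(0, n, n, dimnames = list(ids, ids))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        d <- 1 - .pairIdentity(m[i, ], m[j, ])
        D[i, j] <- D[j, i] <- d
    }
    if (n == 2L)
        return(sprintf("(%s:%.6f,%s:%.6f);", ids[1L], D[1, 2] / 2,
                       ids[2L], D[1, 2] / 2))
    tr <- ape::nj(as.dist(D))
    ape::write.tree(tr)
}

#' Iterative profile search around a root gene
#'
#' Each round aligns the current members, collapses redundant rows,
#' trims non-conserved ends, builds a position-specific profile,
#' searches the whole database and keeps hits passing the round's
#' cutoffs; accepted subjects join the member set for the next round.
#' Cutoffs must relax monotonically across rounds, so a member accepted
#' in an early round also satisfies the final round's cutoffs. The root
#' always carries its perfect self-hit. When a round leaves the member
#' set unchanged, the next round reuses the previous search (the
#' profile would be identical) and merely re-filters it.
#'
#' @param root gene id of the root (must be in \code{db}).
#' @param db a [ProteomeSet-class] to recruit from.
#' @param rounds list of [RoundConfig-class]; see [defaultRounds()].
#' @param scoreFloor,gapOpening,gapExtension passed to [searchProfile()].
#' @param newick build the decorative neighbor-joining topology
#'   (pairwise-identity distances) for the final member set.
#' @return A [GeneTree-class].
#' @export
iterateSearch <- function(root, db, rounds = defaultRounds(),
                          scoreFloor = 0, gapOpening = 11,
                          gapExtension = 1, newick = TRUE) {
    stopifnot(is(db, "ProteomeSet"), length(rounds) >= 1L)
    if (!root %in% geneIds(db))
        stop("root gene ", root, " not in database")
    .checkMonotoneRounds(rounds)
    ann <- annotations(db)
    orgOf <- function(g) ann$organism_id[match(g, ann$gene_id)]

    members <- root
    # root: perfect self-recovery entry, never overwritten
    stats <- list()
    stats[[root]] <- data.frame(
        gene_id = root, organism_id = orgOf(root), identity = 1,
        positives = 1, coverage = 1, uncovered = 0L, score = NA_real_,
        stringsAsFactors = FALSE)

    prevMembers <- character(0)
    hits <- NULL
    for (k in seq_along(rounds)) {
        rc <- rounds[[k]]
        if (!identical(sort(members), sort(prevMembers)) || is.null(hits)) {
            aln <- alignSequences(sequences(db)[members],
                                  gapOpening = gapOpening,
                                  gapExtension = gapExtension)
            aln <- clusterRepresentatives(aln, rc@clusterIdentity)
            aln <- trimAlignment(aln, rc@trimOccupancy)
            prof <- buildProfile(aln)
            hits <- searchProfile(prof, db, scoreFloor = scoreFloor,
                                  gapOpening = gapOpening,
                                  gapExtension = gapExtension)
        }
        prevMembers <- members
        kept <- filterHits(hits, rc@criteria)
        if (nrow(kept)) {
            for (i in seq_len(nrow(kept))) {
                g <- kept$subject_gene_id[i]
                if (g == root) next
                stats[[g]] <- data.frame(
                    gene_id = g, organism_id = orgOf(g),
                    identity = kept$identity[i],
                    positives = kept$positives[i],
                    coverage = kept$coverage[i],
                    uncovered = kept$uncovered[i],
                    score = kept$score[i], stringsAsFactors = FALSE)
            }
            members <- union(members, setdiff(kept$subject_gene_id, members))
        }
    }
    members <- c(root, sort(setdiff(members, root)))
    mdf <- do.call(rbind, stats[members])
    rownames(mdf) <- NULL
    nwk <- NA_character_
    if (newick) {
        fin <- alignSequences(sequences(db)[members],
                              gapOpening = gapOpening,
                              gapExtension = gapExtension)
        nwk <- .njNewick(fin)
    }
    new("GeneTree", root = root, members = mdf, newick = nwk)
}

setMethod("show", "GeneTree", function(object) {
    cat("GeneTree rooted at", object@root, "with",
        nrow(object@members), "member(s)\n")
})

#' Gene-tree member ids
#' @param object a [GeneTree-class].
#' @return Character vector of member gene ids (root first).
#' @export
setGeneric("treeMembers", function(object) standardGeneric("treeMembers"))

#' @rdname treeMembers
#' @export
setMethod("treeMembers", "GeneTree", function(object)
    object@members$gene_id)
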