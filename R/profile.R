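# Position-specific scoring profiles from trimmed alignments.

#' Build a position-specific scoring profile from an alignment
#'
#' Per-column log-odds scores with data-dependent substitution-matrix
#' pseudocounts. With observed residue counts \eqn{n_{cr}} in column c
#' (gaps and X ignored, \eqn{N_c = \sum_r n_{cr}}, frequencies
#' \eqn{f_{cr} = n_{cr}/N_c}), background \eqn{p_r = 1/20} and the
#' BLOSUM62 score s(a, r), the pseudocount distribution is
#' \deqn{g_{cr} = \sum_a f_{ca} \; Q(r \mid a), \quad
#'       Q(r \mid a) = p_r 2^{\lambda s(a,r)} / \sum_b p_b 2^{\lambda s(a,b)}}
#' and, with observation weight \eqn{m_c = N_c - 1} (independent
#' observations beyond the first), the estimated column distribution
#' and score (in bits) are
#' \deqn{q_{cr} = \frac{m_c f_{cr} + \beta\, g_{cr}}{m_c + \beta},
#'       \qquad S_{cr} = \log_2(q_{cr} / p_r).}
#' A single-sequence profile therefore reduces to the (scaled)
#' substitution matrix itself, and deep ungapped columns converge to
#' the observed frequencies - the behaviour of PSI-BLAST-style
#' position-specific matrices. A column containing only residue r
#' scores r strictly highest; columns with no observed residues score 0
#' everywhere.
#'
#' The per-column consensus (majority residue, alphabetical tie-break)
#' is stored for identity/positives bookkeeping during the search.
#'
#' The default \eqn{\lambda} = 0.35 softens the substitution matrix so
#' that, under the conservative substitutions of genuine homologs, the
#' expected score per aligned column stays positive down to roughly 20
#' percent identity - the twilight-zone regime the search targets, where
#' a harder scale makes optimal local alignments fragment and fail the
#' coverage cutoff - while the expectation for unrelated sequences
#' remains clearly negative, keeping random local islands short.
#'
#' @param aln gapped AAStringSet (typically clustered and trimmed).
#' @param pseudocount pseudocount mass \eqn{\beta}.
#' @param lambda substitution-matrix scale \eqn{\lambda} (bits).
#' @return A [SearchProfile-class].
#' @export
buildProfile <- function(aln, pseudocount = 1, lambda = 0.35) {
    stopifnot(is(aln, "AAStringSet"), length(aln) >= 1L)
    m <- .alnMatrix(aln)
    L <- ncol(m)
    if (L < 1L) stop("empty alignment")
    b62 <- .blosum62()[.AA20, .AA20]
    p <- rep(1 / 20, 20)
    # Q[a, r] = p_r 2^(lambda * s(a, r)) / Z_a
    Q <- sweep(2 ^ (lambda * b62), 2L, p, `*`)
    Q <- Q / rowSums(Q)

    counts <- matrix(0, nrow = L, ncol = 20,
                     dimnames = list(NULL, .AA20))
    for (r in .AA20) counts[, r] <- colSums(m == r)
    Nc <- rowSums(counts)
    freq <- counts / ifelse(Nc > 0, Nc, 1)
    g <- freq %*% Q                      # L x 20 pseudocount distribution
    mObs <- pmax(Nc - 1, 0)              # observation weight
    q <- (mObs * freq + pseudocount * g) / (mObs + pseudocount)
    scores <- log2(q / matrix(p, L, 20, byrow = TRUE))
    scores[Nc == 0, ] <- 0
    cons <- vapply(seq_len(L), function(c) {
        if (Nc[c] == 0) return("X")
        .AA20[which.max(counts[c, ])]    # which.max: first = alphabetical
    }, "")
    new("SearchProfile", scores = unname(scores), consensus = cons,
        sourceGenes = rownames(m))
}

setMethod("show", "SearchProfile", function(object) {
    cat("SearchProfile:", nrow(object@scores), "columns from",
        length(object@sourceGenes), "sequence(s); consensus",
        paste0(substr(paste0(object@consensus, collapse = ""), 1, 40),
               if (nrow(object@scores) > 40) "..." else ""), "\n")
})

#' @describeIn buildProfile Number of profile columns.
#' @param profile a [SearchProfile-class].
#' @export
profileLength <- function(profile) nrow(profile@scores)
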