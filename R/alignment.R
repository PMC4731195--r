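# Multiple alignment, redundancy clustering and end trimming: the
# preparation steps of each search round. Alignments are represented as
# named, equal-width, gapped AAStringSet objects; ungapping a row always
# reproduces the member's sequence exactly.

#' Align protein sequences (deterministic progressive aligner)
#'
#' Center-star progressive alignment: the center is the sequence with
#' the highest total pairwise global-alignment score (ties broken by
#' lexicographic gene id); every other sequence is aligned to the center
#' by Needleman-Wunsch (BLOSUM62, affine gap open 11 / extend 1) and the
#' pairwise alignments are merged under the "once a gap, always a gap"
#' rule. Deterministic given the input set.
#'
#' @param records an AAStringSet (named by gene id) or a
#'   [ProteomeSet-class] whose sequences are aligned.
#' @param gapOpening,gapExtension affine gap penalties.
#' @return A gapped AAStringSet with equal-width rows, one per input
#'   record, in input order.
#' @export
#' @examples
#' aln <- alignSequences(Biostrings::AAStringSet(
#'     c(a = "ACDEF", b = "ACEF")))
#' Biostrings::width(aln)   # 5, one gap in row b
alignSequences <- function(records, gapOpening = 11, gapExtension = 1) {
    if (is(records, "ProteomeSet")) records <- sequences(records)
    stopifnot(is(records, "AAStringSet"), length(records) >= 1L)
    .validateSequences(records)
    n <- length(records)
    if (n == 1L) return(records)

    b62 <- .blosum62()
    chars <- as.character(records)
    if (n == 2L) {
        center <- 1L
    } else {
        tot <- numeric(n)
        for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
            sc <- Biostrings::pairwiseAlignment(
                records[[i]], records[[j]], substitutionMatrix = b62,
                gapOpening = gapOpening, gapExtension = gapExtension,
                type = "global", scoreOnly = TRUE)
            tot[i] <- tot[i] + sc
            tot[j] <- tot[j] + sc
        }
        ord <- order(-tot, names(records))
        center <- ord[1L]
    }

    cseq <- chars[center]
    Lc <- nchar(cseq)
    others <- setdiff(seq_len(n), center)
    # per-row insertion counts before center residue k (k = 1..Lc+1,
    # slot Lc+1 = after the last residue) and row chunks
    ins <- matrix(0L, nrow = n, ncol = Lc + 1L)
    chunks <- vector("list", n)   # per row: list of (Lc+1 insert strings,
    resAt <- matrix("-", nrow = n, ncol = Lc)  # residue aligned to center k
    resAt[center, ] <- strsplit(cseq, "")[[1L]]
    chunks[[center]] <- rep(list(character()), Lc + 1L)
    for (i in others) {
        pa <- Biostrings::pairwiseAlignment(
            records[[center]], records[[i]], substitutionMatrix = b62,
            gapOpening = gapOpening, gapExtension = gapExtension,
            type = "global")
        cg <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
        sg <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
        slot <- 1L
        inschars <- rep(list(character()), Lc + 1L)
        for (p in seq_along(cg)) {
            if (cg[p] == "-") {
                inschars[[slot]] <- c(inschars[[slot]], sg[p])
            } else {
                resAt[i, slot] <- sg[p]
                slot <- slot + 1L
            }
        }
        ins[i, ] <- lengths(inschars)
        chunks[[i]] <- inschars
    }
    master <- apply(ins, 2L, max)

    rows <- vapply(seq_len(n), function(i) {
        parts <- character(0)
        for (k in seq_len(Lc + 1L)) {
            ik <- if (is.null(chunks[[i]])) character() else chunks[[i]][[k]]
            pad <- master[k] - length(ik)
            parts <- c(parts, ik, rep("-", pad),
                       if (k <= Lc) resAt[i, k])
        }
        paste0(parts, collapse = "")
    }, "")
    out <- Biostrings::AAStringSet(rows)
    names(out) <- names(records)
    out
}

#' Keep cluster representatives of an alignment
#'
#' Greedy incremental clustering on pairwise ungapped identity
#' (identical residues over columns where both rows are non-gap). Rows
#' are visited by decreasing ungapped length (ties by lexicographic
#' gene id); a row joins an existing representative when its identity to
#' it is at or above \code{identityThreshold}, otherwise it becomes a
#' new representative. Retained representatives are therefore mutually
#' below the threshold, which makes the operation idempotent.
#' Columns left entirely gapped by the removal are dropped.
#'
#' @param aln gapped AAStringSet.
#' @param identityThreshold fraction in (0, 1].
#' @return The alignment restricted to representative rows.
#' @export
clusterRepresentatives <- function(aln, identityThreshold = 0.90) {
    stopifnot(is(aln, "AAStringSet"))
    if (length(aln) <= 1L) return(aln)
    m <- .alnMatrix(aln)
    ulen <- rowSums(m != "-")
    ord <- order(-ulen, rownames(m))
    reps <- integer(0)
    for (i in ord) {
        dup <- FALSE
        for (r in reps) {
            if (.pairIdentity(m[i, ], m[r, ]) >= identityThreshold) {
                dup <- TRUE
                break
            }
        }
        if (!dup) reps <- c(reps, i)
    }
    keep <- sort(reps)             # preserve input row order
    m <- m[keep, , drop = FALSE]
    occ <- colSums(m != "-") > 0L
    .matrixAln(m[, occ, drop = FALSE])
}

#' Trim non-conserved alignment ends
#'
#' Retains the single contiguous column interval starting at the first
#' and ending at the last column whose non-gap occupancy is at least
#' \code{minOccupancy}; interior columns are untouched.
#'
#' @param aln gapped AAStringSet.
#' @param minOccupancy fraction of non-gap rows a terminal column needs
#'   to survive.
#' @return The column-trimmed alignment.
#' @export
#' @examples
#' aln <- Biostrings::AAStringSet(c(a = "ACDEF", b = "-CDE-"))
#' trimAlignment(aln, 1.0)   # columns 2..4
trimAlignment <- function(aln, minOccupancy = 0.50) {
    stopifnot(is(aln, "AAStringSet"))
    m <- .alnMatrix(aln)
    occ <- colSums(m != "-") / nrow(m)
    ok <- which(occ >= minOccupancy)
    if (!length(ok))
        stop("empty profile: no column reaches occupancy ", minOccupancy)
    .matrixAln(m[, ok[1L]:ok[length(ok)], drop = FALSE])
}
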