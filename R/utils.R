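# Internal helpers shared across modules.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.pkgCache <- new.env(parent = emptyenv())

# BLOSUM62 restricted to the 20 canonical residues plus X.
.blosum62 <- function() {
    if (is.null(.pkgCache$b62)) {
        e <- new.env()
        data("BLOSUM62", package = "Biostrings", envir = e)
        .pkgCache$b62 <- e$BLOSUM62[c(.AA20, "X"), c(.AA20, "X")]
    }
    .pkgCache$b62
}

# Run code under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
    force(code)
}

# Gapped AAStringSet -> character matrix (rows = sequences).
.alnMatrix <- function(aln) {
    stopifnot(is(aln, "AAStringSet"))
    w <- unique(Biostrings::width(aln))
    if (length(w) > 1L)
        stop("alignment rows must all have equal gapped length")
    m <- matrix(unlist(strsplit(as.character(aln), "", fixed = TRUE)),
                nrow = length(aln), byrow = TRUE)
    rownames(m) <- names(aln)
    m
}

.matrixAln <- function(m) {
    x <- Biostrings::AAStringSet(apply(m, 1L, paste0, collapse = ""))
    names(x) <- rownames(m)
    x
}

.ungap <- function(x) gsub("-", "", x, fixed = TRUE)

# Pairwise ungapped identity of two gapped rows: identical residues over
# columns where both rows are non-gap; 0 when they never overlap.
.pairIdentity <- function(a, b) {
    both <- a != "-" & b != "-"
    if (!any(both)) return(0)
    mean(a[both] == b[both])
}

.validateSequences <- function(seqs) {
    bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", as.character(seqs))
    if (any(bad))
        stop("non-amino-acid characters in record(s): ",
             paste(names(seqs)[bad], collapse = ", "))
    invisible(seqs)
}

# GPR field of a reaction definition list, "" when absent/empty (JSON
# round-trips can turn a missing gpr into an empty list).
.gprField <- function(rxn) {
    g <- rxn$gpr
    if (is.null(g) || !length(g) || !nzchar(as.character(g)[1L])) ""
    else as.character(g)[1L]
}

# Deterministic TSV writer (no quoting surprises, fixed NA string).
.writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    invisible(path)
}
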