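# Independent oracles and small in-code fixtures shared across tests.

b62_tbl <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Optimal global (Needleman-Wunsch) alignment score with affine gaps
# costing open + k * extend, written as a plain three-matrix DP --
# independent of both Biostrings and the package's aligner.
nw_score <- function(a, b, open = 11, extend = 1) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    NEG <- -1e9
    M <- matrix(NEG, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)  # gap in b (a consumed)
    Y <- matrix(NEG, n + 1, m + 1)  # gap in a (b consumed)
    M[1, 1] <- 0
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * extend)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * extend)
    for (i in seq_len(n)) for (j in seq_len(m)) {
        s <- b62_tbl[a[i], b[j]]
        M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
        X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                               X[i, j + 1] - extend)
        Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                               Y[i + 1, j] - extend)
    }
    max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Score a gapped pair of alignment rows under the same affine scheme.
score_aligned_pair <- function(ga, gb, open = 11, extend = 1) {
    ga <- strsplit(ga, "")[[1]]
    gb <- strsplit(gb, "")[[1]]
    keep <- !(ga == "-" & gb == "-")
    ga <- ga[keep]; gb <- gb[keep]
    total <- 0
    runA <- 0; runB <- 0
    for (k in seq_along(ga)) {
        if (ga[k] == "-") {
            runA <- runA + 1
            if (runB > 0) { total <- total - open - extend * runB; runB <- 0 }
        } else if (gb[k] == "-") {
            runB <- runB + 1
            if (runA > 0) { total <- total - open - extend * runA; runA <- 0 }
        } else {
            if (runA > 0) { total <- total - open - extend * runA; runA <- 0 }
            if (runB > 0) { total <- total - open - extend * runB; runB <- 0 }
            total <- total + b62_tbl[ga[k], gb[k]]
        }
    }
    if (runA > 0) total <- total - open - extend * runA
    if (runB > 0) total <- total - open - extend * runB
    total
}

# Exhaustive hypergeometric upper tail by enumerating every n-subset of
# a population of size N holding K positives (feasible for N <= 12).
hyper_enum_pvalue <- function(N, K, n, k) {
    if (k == 0) return(1)
    draws <- utils::combn(N, n)
    mean(colSums(draws <= K) >= k)
}

# Minimal linear-chain model builder for FBA oracle tests.
chain_model <- function(uptake = 10, cap = Inf) {
    makeModel(list(
        list(id = "EX_A", stoichiometry = list(A = -1),
             lower_bound = -uptake, upper_bound = 0),
        list(id = "R1", stoichiometry = list(A = -1, B = 1),
             lower_bound = 0, upper_bound = min(cap, 1000)),
        list(id = "R2", stoichiometry = list(B = -1, BM = 1),
             lower_bound = 0, upper_bound = 1000, gpr = "g2"),
        list(id = "EX_BM", stoichiometry = list(BM = -1),
             lower_bound = 0, upper_bound = 1000)),
        biomass = "R2",
        media = list(M9 = c(EX_A = uptake), rich = c(EX_A = uptake)))
}

# Random uniform protein sequence (caller manages the RNG seed).
random_seq <- function(n) paste0(sample(AA20, n, replace = TRUE),
                                 collapse = "")

# Small proteome: a root, a homolog mutated to `identity`, and
# unrelated background genes, each annotated with its own function.
mini_proteome <- function(identity = 0.4, n_background = 5, len = 150,
                          seed = 42) {
    set.seed(seed)
    root <- random_seq(len)
    hom <- mutateSequence(root, identity, seed = seed + 1)
    bg <- replicate(n_background, random_seq(len))
    seqs <- c(root = root, hom = hom,
              setNames(bg, paste0("bg", seq_len(n_background))))
    ann <- data.frame(gene_id = names(seqs),
                      organism_id = c("orgA", "orgB",
                                      rep("orgA", n_background)),
                      stringsAsFactors = FALSE)
    ann$functions <- I(as.list(paste0("fn_", names(seqs))))
    ann$is_metabolic <- TRUE
    ProteomeSet(seqs, ann)
}
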