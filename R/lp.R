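# Dense two-phase simplex with Bland's anti-cycling rule. Problem
# sizes here are tiny (toy genome-scale models), so a transparent,
# deterministic tableau implementation is preferable to heuristics.
#
#   maximize  obj' x
#   s.t.      A1 x <= b1   (b1 >= 0)
#             A3 x  = b3   (b3 >= 0)
#             x >= 0
#
# Returns list(status = "optimal"|"infeasible", x, value).

.lpSolve <- function(obj, A1, b1, A3, b3, tol = 1e-9) {
    n <- length(obj)
    m1 <- nrow(A1)
    m3 <- nrow(A3)
    m <- m1 + m3
    # columns: x (n) | slacks (m1) | artificials (m3)
    A <- cbind(rbind(A1, A3),
               rbind(diag(nrow = m1), matrix(0, m3, m1)),
               rbind(matrix(0, m1, m3), diag(nrow = m3)))
    b <- c(b1, b3)
    stopifnot(all(b >= -tol))
    b[b < 0] <- 0
    nTot <- n + m1 + m3
    basis <- c(n + seq_len(m1), n + m1 + seq_len(m3))
    art <- n + m1 + seq_len(m3)

    pivot <- function(T, basis, pr, pc) {
        T[pr, ] <- T[pr, ] / T[pr, pc]
        for (r in seq_len(nrow(T))) {
            if (r != pr && abs(T[r, pc]) > 0)
                T[r, ] <- T[r, ] - T[r, pc] * T[pr, ]
        }
        basis[pr] <- pc
        list(T = T, basis = basis)
    }

    run <- function(T, basis, allowed, maxIter) {
        it <- 0L
        repeat {
            it <- it + 1L
            if (it > maxIter) stop("LP did not converge")
            red <- T[m + 1L, seq_len(nTot)]
            cand <- allowed[red[allowed] < -tol]
            if (!length(cand)) break
            pc <- cand[1L]                      # Bland: smallest index
            ratios <- ifelse(T[seq_len(m), pc] > tol,
                             T[seq_len(m), nTot + 1L] /
                                 T[seq_len(m), pc], Inf)
            if (all(!is.finite(ratios)))
                return(list(T = T, basis = basis, unbounded = TRUE))
            pr <- which(ratios == min(ratios))
            pr <- pr[order(basis[pr])][1L]      # Bland on leaving var
            pv <- pivot(T, basis, pr, pc)
            T <- pv$T
            basis <- pv$basis
        }
        list(T = T, basis = basis, unbounded = FALSE)
    }

    maxIter <- 500L + 50L * nTot
    # phase 1: minimize sum of artificials
    T <- rbind(cbind(A, b), 0)
    for (r in which(basis %in% art))
        T[m + 1L, ] <- T[m + 1L, ] - T[r, ]
    res <- run(T, basis, seq_len(n + m1), maxIter)
    if (res$unbounded) stop("phase-1 LP unbounded (internal error)")
    if (-res$T[m + 1L, nTot + 1L] > 1e-7)
        return(list(status = "infeasible", x = NULL, value = NA_real_))
    T <- res$T
    basis <- res$basis
    # drive leftover artificials out of the basis (degenerate pivots);
    # rows where no original column can enter are redundant -> drop
    drop <- integer(0)
    for (r in which(basis %in% art)) {
        pc <- which(abs(T[r, seq_len(n + m1)]) > tol)
        if (length(pc)) {
            pv <- pivot(T, basis, r, pc[1L])
            T <- pv$T
            basis <- pv$basis
        } else {
            drop <- c(drop, r)
        }
    }
    if (length(drop)) {
        T <- T[-drop, , drop = FALSE]
        basis <- basis[-drop]
        m <- m - length(drop)
    }
    # phase 2: original objective (maximize -> minimize -obj)
    T[m + 1L, ] <- 0
    T[m + 1L, seq_len(n)] <- -obj
    for (r in seq_len(m)) {
        if (abs(T[m + 1L, basis[r]]) > 0)
            T[m + 1L, ] <- T[m + 1L, ] - T[m + 1L, basis[r]] * T[r, ]
    }
    res <- run(T, basis, seq_len(n + m1), maxIter)
    if (res$unbounded)
        return(list(status = "unbounded", x = NULL, value = Inf))
    T <- res$T
    basis <- res$basis
    x <- numeric(nTot)
    x[basis] <- T[seq_len(m), nTot + 1L]
    list(status = "optimal", x = x[seq_len(n)],
         value = sum(obj * x[seq_len(n)]))
}
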