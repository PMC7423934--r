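## Independent brute-force oracles and tiny fixture builders used across
## the suite. Oracles deliberately avoid the package's own code paths.

## G statistic and Williams divisor evaluated directly from the formulas
oracle_g <- function(tab) {
    R <- rowSums(tab); C <- colSums(tab); N <- sum(tab)
    E <- outer(R, C) / N
    G <- 2 * sum(ifelse(tab > 0, tab * log(tab / E), 0))
    q <- 1 + (N / R[1] + N / R[2] - 1) * (N / C[1] + N / C[2] - 1) / (6 * N)
    list(G = G, q = q, G_adj = G / q,
         p = pchisq(G / q, 1, lower.tail = FALSE))
}

## step-up BH written out longhand
oracle_bh <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- p[o] * n / seq_len(n)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(n)
    out[o] <- q
    out
}

## maximal cliques and MCC by exhaustive subset search on an adjacency
## matrix (feasible to ~12 nodes)
oracle_mcc <- function(adj) {
    n <- nrow(adj)
    nodes <- rownames(adj)
    mcc <- structure(numeric(n), names = nodes)
    for (code in seq_len(2^n) - 1L) {
        S <- which(bitwAnd(code, 2^(seq_len(n) - 1L)) > 0)
        if (!length(S)) next
        sub <- adj[S, S, drop = FALSE]
        if (any(sub[upper.tri(sub)] == 0)) next        # not a clique
        out <- setdiff(seq_len(n), S)
        if (length(out) && any(colSums(adj[S, out, drop = FALSE]) ==
                               length(S))) next        # extendable
        mcc[S] <- mcc[S] + factorial(length(S) - 1L)
    }
    mcc
}

## exact two-sided Mann-Whitney p by enumerating rank-sum assignments
oracle_mw <- function(a, b) {
    z <- c(a, b); nA <- length(a)
    rk <- rank(z)
    obs <- sum(rk[seq_len(nA)])
    sums <- combn(length(z), nA, function(ix) sum(rk[ix]))
    min(1, 2 * min(mean(sums <= obs), mean(sums >= obs)))
}

## random simple graph as igraph + adjacency matrix
random_graph <- function(n, p, seed) {
    set.seed(seed)
    adj <- matrix(0L, n, n, dimnames = list(sprintf("n%02d", 1:n),
                                            sprintf("n%02d", 1:n)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n)
        if (runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    list(g = g, adj = adj)
}

## tiny 3 x 2 count TSV on disk
write_tiny_counts <- function(path = tempfile(fileext = ".tsv"),
                              header = "protein\tS1\tS2",
                              rows = c("P1\t3\t0", "P2\t5\t2",
                                       "P3\t0\t7")) {
    writeLines(c(header, rows), path)
    path
}

write_meta <- function(samples, groups,
                       path = tempfile(fileext = ".tsv")) {
    writeLines(c("sample_id\tgroup", paste(samples, groups, sep = "\t")),
               path)
    path
}

## block-structured dissimilarity: tight blocks (within ~0.05) separated
## at ~0.95, with optional loose noise leaves
block_diss <- function(sizes, n_noise = 0, seed = 1) {
    set.seed(seed)
    n <- sum(sizes) + n_noise
    d <- matrix(0.95 + runif(n * n, 0, 0.04), n, n)
    d <- (d + t(d)) / 2
    at <- 1L
    for (s in sizes) {
        ix <- seq.int(at, at + s - 1L)
        d[ix, ix] <- 0.02 + (d[ix, ix] %% 0.03)
        at <- at + s
    }
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(sprintf("P%03d", 1:n), sprintf("P%03d", 1:n))
    d
}
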