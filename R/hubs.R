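## Maximal clique centrality (MCC) hub ranking on PPI networks.

#' Enumerate all maximal cliques of a graph
#'
#' Exact enumeration via the pivoted Bron-Kerbosch algorithm (igraph's C
#' implementation). Isolated nodes count as singleton maximal cliques, so
#' every node belongs to at least one clique.
#'
#' @param g an undirected simple \code{igraph} graph.
#' @param maxNodes,maxEdges refuse graphs above these bounds (clique
#'   enumeration is exponential in the worst case); extract a subnetwork
#'   first for larger inputs.
#' @return list of character vectors of node names.
#' @export
maximalCliques <- function(g, maxNodes = 5000, maxEdges = 200000) {
    stopifnot(igraph::is_igraph(g))
    if (igraph::is_directed(g)) stop("graph must be undirected")
    if (igraph::vcount(g) > maxNodes || igraph::ecount(g) > maxEdges)
        stop("graph exceeds ", maxNodes, " nodes / ", maxEdges,
             " edges; extract a subnetwork before clique enumeration")
    if (igraph::any_loop(g) || igraph::any_multiple(g))
        stop("graph must be simple (no loops or multi-edges)")
    cl <- igraph::max_cliques(g, min = 1)
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
    lapply(cl, function(v) nm[as.integer(v)])
}

#' Maximal clique centrality scores
#'
#' MCC(v) = sum over maximal cliques C containing v of (|C| - 1)!. An
#' isolated node sits in one singleton clique and scores 0! = 1, so every
#' score is >= 1. Ranks are descending by MCC with deterministic ties
#' broken by higher degree then lexicographic node id.
#'
#' @param g an undirected simple \code{igraph} graph.
#' @return data.frame with columns \code{node}, \code{mcc},
#'   \code{degree}, \code{rank}, ordered by rank.
#' @examples
#' g <- igraph::make_graph(~ a - b, b - c)   # path: centre scores 1! + 1!
#' mccScores(g)
#' @export
mccScores <- function(g) {
    if (igraph::vcount(g) == 0)
        return(data.frame(node = character(), mcc = numeric(),
                          degree = integer(), rank = integer()))
    cl <- maximalCliques(g)
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
    mcc <- structure(numeric(length(nm)), names = nm)
    for (C in cl) mcc[C] <- mcc[C] + factorial(length(C) - 1L)
    deg <- structure(igraph::degree(g), names = nm)
    ord <- order(-mcc, -deg, nm)
    out <- data.frame(node = nm[ord], mcc = unname(mcc[ord]),
                      degree = unname(deg[ord]),
                      rank = seq_along(nm), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Top-k hub nodes by MCC rank
#'
#' @param scores data.frame from [mccScores()].
#' @param k number of hubs to return (>= 1); fewer if the graph is
#'   smaller.
#' @return character vector of node ids in rank order.
#' @export
topHubs <- function(scores, k) {
    stopifnot(k >= 1)
    utils::head(scores$node[order(scores$rank)], k)
}
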