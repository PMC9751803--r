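# Independent brute-force oracles and toy-network builders used across
# the suite. These deliberately avoid the package's own code paths (and
# igraph where feasible) so they can certify them.

# Build a CoNetwork from a two-column edge matrix of vertex names.
mkNet <- function(edges, threshold = 0.5, weights = NULL, phylum = NULL) {
    g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
    if (is.null(weights)) weights <- rep(1, igraph::ecount(g))
    igraph::E(g)$weight <- weights
    igraph::E(g)$sign <- ifelse(weights >= 0, 1L, -1L)
    if (is.null(phylum)) phylum <- rep("Firmicutes", igraph::vcount(g))
    igraph::V(g)$phylum <- phylum
    methods::new("CoNetwork", graph = g, threshold = threshold, group = "")
}

completeGraphNet <- function(n) {
    v <- paste0("v", seq_len(n))
    mkNet(t(utils::combn(v, 2)))
}

starNet <- function(n_leaves) {
    mkNet(cbind("hub", paste0("leaf", seq_len(n_leaves))))
}

# adjacency matrix (named) from a CoNetwork
netAdjacency <- function(net) {
    g <- networkGraph(net)
    a <- matrix(0L, igraph::vcount(g), igraph::vcount(g),
                dimnames = list(igraph::V(g)$name, igraph::V(g)$name))
    el <- igraph::as_edgelist(g)
    for (i in seq_len(nrow(el))) a[el[i, 1], el[i, 2]] <- a[el[i, 2], el[i, 1]] <- 1L
    a
}

# All-pairs shortest paths by repeated matrix "min-plus" (Floyd-Warshall);
# mean over connected pairs only.
bruteGD <- function(net) {
    a <- netAdjacency(net)
    n <- nrow(a)
    d <- matrix(Inf, n, n); d[a == 1] <- 1; diag(d) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    vals <- d[upper.tri(d)]
    mean(vals[is.finite(vals)])
}

# Average local clustering: closed triples around each node / possible
# pairs of neighbours; degree < 2 contributes 0.
bruteAvgCC <- function(net) {
    a <- netAdjacency(net)
    cc <- vapply(seq_len(nrow(a)), function(i) {
        nb <- which(a[i, ] == 1)
        if (length(nb) < 2) return(0)
        links <- sum(a[nb, nb]) / 2
        links / choose(length(nb), 2)
    }, numeric(1))
    mean(cc)
}

# Newman modularity directly from the formula, for a given partition.
bruteQ <- function(net, membership) {
    a <- netAdjacency(net)
    membership <- membership[rownames(a)]
    l <- sum(a) / 2
    q <- 0
    for (m in unique(membership)) {
        idx <- membership == m
        lm <- sum(a[idx, idx]) / 2
        dm <- sum(a[idx, ])
        q <- q + lm / l - (dm / (2 * l))^2
    }
    q
}

# Maximum modularity over all partitions (set-partition enumeration);
# feasible for <= 8 nodes.
bruteMaxQ <- function(net) {
    nodes <- rownames(netAdjacency(net))
    n <- length(nodes)
    best <- -Inf
    assign_next <- function(labels, i, k) {
        if (i > n) {
            mem <- structure(labels, names = nodes)
            best <<- max(best, bruteQ(net, mem))
            return(invisible())
        }
        for (lab in seq_len(k + 1))
            assign_next(c(labels, lab), i + 1, max(k, lab))
    }
    assign_next(integer(0), 1, 0)
    best
}

# small fixture set of connected graphs with <= 8 nodes
fixtureGraphs <- function() {
    list(
        triangle = completeGraphNet(3),
        path4 = mkNet(cbind(paste0("p", 1:3), paste0("p", 2:4))),
        star5 = starNet(5),
        k4 = completeGraphNet(4),
        two_triangles_bridged = mkNet(rbind(
            c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
            c("b1", "b2"), c("b2", "b3"), c("b1", "b3"),
            c("a1", "b1"))),
        cycle6 = mkNet(cbind(paste0("c", 1:6), paste0("c", c(2:6, 1)))),
        barbell = mkNet(rbind(
            c("x1", "x2"), c("x2", "x3"), c("x1", "x3"),
            c("x3", "x4"), c("x4", "x5"),
            c("x5", "x6"), c("x6", "x7"), c("x5", "x7"))),
        wheel = mkNet(rbind(cbind("hub", paste0("r", 1:5)),
                            cbind(paste0("r", 1:5), paste0("r", c(2:5, 1)))))
    )
}

# two disjoint triangles (disconnected; used for GD-over-connected-pairs
# and the hand modularity value)
twoTrianglesNet <- function() {
    mkNet(rbind(c("a1", "a2"), c("a2", "a3"), c("a1", "a3"),
                c("b1", "b2"), c("b2", "b3"), c("b1", "b3")))
}

# default test community spec, small enough to keep the suite fast
testSpec <- function(...) {
    communitySpec(...)
}
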