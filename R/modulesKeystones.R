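#' Detect network modules by greedy modularity maximisation
#'
#' Agglomerative greedy optimisation of Newman modularity
#' Q = sum_m (l_m / L - (d_m / 2L)^2) on the unweighted, unsigned graph
#' (signs are analysed separately). The greedy algorithm is deterministic;
#' `seed` is accepted for interface symmetry with stochastic alternatives.
#'
#' @param net a [CoNetwork-class].
#' @param method "greedy" (default), "eigenvector" or "walktrap".
#' @param seed optional RNG seed (used by "walktrap" only).
#' @return list with `membership` (named integer vector, node -> module),
#'   `sizes` (module sizes), `Q` (modularity of the partition).
#' @export
detectModules <- function(net, method = c("greedy", "eigenvector", "walktrap"),
                          seed = NULL) {
    method <- match.arg(method)
    g <- networkGraph(net)
    if (igraph::vcount(g) == 0) stop("empty network")
    gu <- igraph::simplify(g)
    igraph::E(gu)$weight <- 1
    if (!is.null(seed)) set.seed(seed)
    comm <- switch(method,
        greedy = igraph::cluster_fast_greedy(gu),
        eigenvector = igraph::cluster_leading_eigen(gu),
        walktrap = igraph::cluster_walktrap(gu))
    mem <- igraph::membership(comm)
    list(membership = structure(as.integer(mem), names = names(mem)),
         sizes = as.integer(table(mem)),
         Q = networkModularity(net, mem))
}

#' Newman modularity of a supplied partition
#'
#' Q = sum over modules of (within-module edge fraction) minus (expected
#' fraction from the module's degree share); edges unweighted and unsigned.
#'
#' @param net a [CoNetwork-class].
#' @param membership module assignment per node (vector aligned with the
#'   network's vertices, or named by OTU id).
#' @return Q.
#' @export
networkModularity <- function(net, membership) {
    g <- igraph::simplify(networkGraph(net))
    if (!is.null(names(membership)))
        membership <- membership[igraph::V(g)$name]
    igraph::modularity(g, as.integer(factor(membership)),
                       weights = rep(1, igraph::ecount(g)))
}

#' Guimera-Amaral node roles: within-module degree and participation
#'
#' For node i in module s_i with k_is links into module s:
#' Zi = (k_i,si - mean k_j,sj over j in s_i) / sd(k_j,sj) (population sd;
#' Zi = 0 when the sd is 0), and Pi = 1 - sum_s (k_is / k_i)^2. Default
#' role thresholds follow the Guimera-Amaral convention: module hub
#' (Zi >= 2.5, Pi < 0.62), connector (Pi >= 0.62, Zi < 2.5), network hub
#' (both), peripheral (neither). All non-peripheral nodes are flagged as
#' potential keystones.
#'
#' @param net a [CoNetwork-class].
#' @param membership module assignment covering every network node.
#' @param zi_threshold,pi_threshold role cutoffs, defaults 2.5 and 0.62.
#' @return data.frame: node, module, degree, Zi, Pi, role, keystone.
#' @export
nodeRoles <- function(net, membership, zi_threshold = 2.5,
                      pi_threshold = 0.62) {
    g <- igraph::simplify(networkGraph(net))
    nodes <- igraph::V(g)$name
    if (!is.null(names(membership))) membership <- membership[nodes]
    if (anyNA(membership) || length(membership) != length(nodes))
        stop("membership must cover every network node")
    if (any(igraph::degree(g) == 0))
        stop("isolated node present; networks must drop isolates at construction")
    mem <- as.integer(factor(membership))
    el <- igraph::as_edgelist(g, names = FALSE)
    k <- igraph::degree(g)
    nmod <- max(mem)
    ## k_is: links of node i into module s
    kis <- matrix(0L, nrow = length(nodes), ncol = nmod)
    for (e in seq_len(nrow(el))) {
        a <- el[e, 1]; b <- el[e, 2]
        kis[a, mem[b]] <- kis[a, mem[b]] + 1L
        kis[b, mem[a]] <- kis[b, mem[a]] + 1L
    }
    kin <- kis[cbind(seq_along(nodes), mem)]
    zi <- numeric(length(nodes))
    for (s in seq_len(nmod)) {
        idx <- mem == s
        mu <- mean(kin[idx])
        sdev <- sqrt(mean((kin[idx] - mu)^2))   # population sd
        zi[idx] <- if (sdev > 0) (kin[idx] - mu) / sdev else 0
    }
    pi_ <- 1 - rowSums((kis / k)^2)
    role <- rep("peripheral", length(nodes))
    role[zi >= zi_threshold & pi_ < pi_threshold] <- "module hub"
    role[pi_ >= pi_threshold & zi < zi_threshold] <- "connector"
    role[zi >= zi_threshold & pi_ >= pi_threshold] <- "network hub"
    data.frame(node = nodes, module = membership, degree = k, Zi = zi,
               Pi = pi_, role = role, keystone = role != "peripheral",
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Phylum composition of large modules
#'
#' Summarises only modules with at least `min_size` nodes; proportions are
#' over the module's node count and sum to 1 per module.
#'
#' @param membership module assignment named by OTU id.
#' @param taxonomy data.frame with a `phylum` column, rownames = OTU ids.
#' @param min_size smallest module summarised, default 5.
#' @return data.frame: module, size, phylum, proportion, dominant.
#' @export
moduleComposition <- function(membership, taxonomy, min_size = 5) {
    stopifnot(!is.null(names(membership)))
    phy <- taxonomy[names(membership), "phylum"]
    out <- list()
    for (m in sort(unique(membership))) {
        idx <- membership == m
        if (sum(idx) < min_size) next
        tab <- sort(table(phy[idx]), decreasing = TRUE)
        out[[length(out) + 1L]] <- data.frame(
            module = m, size = sum(idx), phylum = names(tab),
            proportion = as.vector(tab) / sum(idx),
            dominant = names(tab) == names(tab)[1],
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(module = integer(), size = integer(),
                          phylum = character(), proportion = numeric(),
                          dominant = logical()))
    do.call(rbind, out)
}
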