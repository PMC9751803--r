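#' Global topological properties of a co-occurrence network
#'
#' Computes the standard whole-network summary: total nodes N, total links
#' L, average degree avgK = 2L/N, average clustering coefficient avgCC
#' (local clustering; nodes of degree < 2 contribute 0 and are included in
#' the average), average path distance GD (mean shortest-path length over
#' *connected* node pairs only, so disconnected components do not inflate
#' it), modularity Q of the greedily detected partition, and the R-squared
#' of the log-log degree-frequency power-law fit.
#'
#' @param net a [CoNetwork-class].
#' @param include_low_degree include degree-<2 nodes (as 0) in avgCC,
#'   default TRUE.
#' @return data.frame with one row: N, L, avgK, avgCC, GD, Q, R2_powerlaw.
#' @export
globalProperties <- function(net, include_low_degree = TRUE) {
    g <- networkGraph(net)
    n <- igraph::vcount(g)
    l <- igraph::ecount(g)
    cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
    cc[is.nan(cc)] <- 0
    avg_cc <- if (include_low_degree) mean(cc) else
        mean(cc[igraph::degree(g) >= 2])
    gd <- igraph::mean_distance(g, weights = NA, unconnected = TRUE)
    q <- detectModules(net)$Q
    data.frame(N = n, L = l, avgK = 2 * l / n, avgCC = avg_cc, GD = gd,
               Q = q, R2_powerlaw = powerlawR2(igraph::degree(g)))
}

#' R-squared of the power-law degree-distribution fit
#'
#' Ordinary least squares of log10(frequency of degree k) on log10(k) over
#' observed degrees k >= 1 (raw frequencies, not the complementary CDF).
#'
#' @param degrees integer degree sequence.
#' @return R-squared in [0, 1]; `NaN` (with a warning) when all nodes share
#'   one degree, a warning when fewer than 3 distinct degrees support the
#'   fit.
#' @export
powerlawR2 <- function(degrees) {
    tab <- table(degrees[degrees >= 1])
    k <- as.numeric(names(tab))
    if (length(k) < 2) {
        warning("degree distribution degenerate; power-law R2 undefined")
        return(NaN)
    }
    if (length(k) < 3)
        warning("fewer than 3 distinct degrees; power-law fit unreliable")
    fit <- stats::lm(log10(as.vector(tab)) ~ log10(k))
    summary(fit)$r.squared
}

#' Degree-preserving rewiring (Maslov-Sneppen null model)
#'
#' Randomises the network by double-edge swaps that reject self-loops and
#' multi-edges, preserving every node's degree exactly. Topology only is
#' rewired; edge signs are reassigned by permuting the original sign
#' multiset (the positive:negative ratio is preserved), and weights take
#' the sign's unit value.
#'
#' @param net a [CoNetwork-class].
#' @param n_swaps number of swap attempts, default 10 x edge count.
#' @param seed optional RNG seed.
#' @return a rewired [CoNetwork-class].
#' @export
rewireDegreePreserving <- function(net, n_swaps = NULL, seed = NULL) {
    g <- networkGraph(net)
    l <- igraph::ecount(g)
    if (l < 2) {
        warning("fewer than 2 edges; no swap possible, returning a copy")
        return(net)
    }
    if (is.null(n_swaps)) n_swaps <- 10L * l
    if (!is.null(seed)) set.seed(seed)
    rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = n_swaps))
    sgn <- sample(igraph::E(g)$sign)
    igraph::E(rg)$sign <- sgn
    igraph::E(rg)$weight <- sgn * net@threshold
    methods::new("CoNetwork", graph = rg, threshold = net@threshold,
                 group = net@group)
}

#' Topology of an ensemble of degree-preserving random networks
#'
#' Builds `n` rewired replicates of the empirical network, computes avgCC,
#' GD and Q for each, and reports the ensemble mean, standard deviation and
#' the z-score of the empirical network, z = (observed - mean) / sd. avgK
#' is invariant under degree-preserving rewiring so its z is undefined by
#' construction (reported NA), as is any property with ensemble sd 0.
#'
#' @param net a [CoNetwork-class].
#' @param n ensemble size, default 100.
#' @param seed RNG seed for the ensemble.
#' @return data.frame with one row per property: observed, null_mean,
#'   null_sd, z.
#' @export
randomEnsemble <- function(net, n = 100, seed = NULL) {
    stopifnot(n >= 2)
    if (!is.null(seed)) set.seed(seed)
    obs <- globalProperties(net)
    props <- c("avgK", "avgCC", "GD", "Q")
    sims <- vapply(seq_len(n), function(i) {
        rnet <- rewireDegreePreserving(net)
        g <- networkGraph(rnet)
        cc <- igraph::transitivity(g, type = "local", isolates = "NaN")
        cc[is.nan(cc)] <- 0
        c(avgK = 2 * igraph::ecount(g) / igraph::vcount(g),
          avgCC = mean(cc),
          GD = igraph::mean_distance(g, weights = NA, unconnected = TRUE),
          Q = detectModules(rnet)$Q)
    }, numeric(4))
    mu <- rowMeans(sims)
    sdev <- apply(sims, 1, stats::sd)
    z <- ifelse(sdev > 0, (unlist(obs[props]) - mu) / sdev, NA_real_)
    data.frame(property = props, observed = unlist(obs[props]),
               null_mean = mu, null_sd = sdev, z = z, n = n,
               row.names = NULL)
}
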