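#' Pairwise Pearson similarity of OTU log-abundance profiles
#'
#' @param abund an [AbundanceMatrix-class] (rows = OTUs, columns = samples).
#' @param method "pearson" (default) or "spearman".
#' @return a [SimilarityMatrix-class]. OTU rows with zero variance get
#'   r = 0 off-diagonal, with a warning. Under the "na" zero strategy,
#'   correlations use pairwise-complete observations.
#' @export
pearsonSimilarity <- function(abund, method = c("pearson", "spearman")) {
    method <- match.arg(method)
    v <- abundanceValues(abund)
    if (ncol(v) < 3) stop("at least 3 samples are required for correlation")
    use <- if (anyNA(v)) "pairwise.complete.obs" else "everything"
    suppressWarnings(r <- stats::cor(t(v), use = use, method = method))
    novar <- apply(v, 1, function(x) stats::sd(x, na.rm = TRUE)) == 0
    if (any(novar, na.rm = TRUE))
        warning(sum(novar, na.rm = TRUE), " zero-variance OTU profile(s); r set to 0")
    r[is.na(r)] <- 0
    diag(r) <- 1
    r <- (r + t(r)) / 2
    methods::new("SimilarityMatrix", r = r, nSamples = ncol(v), method = method)
}

#' Unfold an eigenvalue spectrum to unit mean spacing
#'
#' Degenerate eigenvalues (within `tol`) are collapsed, a cubic smoothing
#' spline is fitted to the empirical cumulative spectral function, and the
#' unfolded levels e_i = N * F(lambda_i) are differenced into
#' nearest-neighbour spacings with mean 1. A smooth (low-df) fit is
#' essential: following every step of the empirical staircase would force
#' all spacings to 1 and destroy the fluctuation statistics the spacings
#' are meant to capture.
#'
#' @param eigenvalues numeric vector (any order).
#' @param tol degeneracy tolerance, default 1e-8.
#' @param df spline degrees of freedom, default 10.
#' @param min_eigenvalues minimum number of distinct eigenvalues, default
#'   50; fewer returns `NULL` (the scan point is flagged unusable rather
#'   than an error thrown).
#' @return numeric vector of non-negative spacings with mean 1, or `NULL`.
#' @export
unfoldSpectrum <- function(eigenvalues, tol = 1e-8, df = 10,
                           min_eigenvalues = 50) {
    lam <- sort(eigenvalues)
    keep <- c(TRUE, diff(lam) > tol)
    lam <- lam[keep]
    n <- length(lam)
    if (n < min_eigenvalues) return(NULL)
    cdf <- (seq_len(n) - 0.5) / n
    fit <- stats::smooth.spline(lam, cdf, df = min(df, n - 1))
    e <- n * stats::predict(fit, lam)$y
    d <- pmax(diff(e), 0)
    if (mean(d) <= 0) return(NULL)
    d / mean(d)
}

#' Chi-square goodness of fit of spacings to an RMT law
#'
#' Spacings are histogrammed in equal-width bins of 0.1 up to d = 3 with a
#' single open tail bin; expected counts come from the Poisson law
#' P(d) = exp(-d) or the GOE Wigner surmise
#' P(d) = (pi d / 2) exp(-pi d^2 / 4). Adjacent bins are merged left to
#' right until every expected count is at least 5; the statistic is Pearson
#' chi-square with (bins - 1) degrees of freedom.
#'
#' @param d numeric vector of unfolded spacings (>= 30).
#' @param law "poisson" or "goe".
#' @param bin_width histogram bin width, default 0.1.
#' @param d_max start of the open tail bin, default 3.
#' @return list with `statistic`, `df`, `p.value`, `law`.
#' @export
nnsdChi2 <- function(d, law = c("poisson", "goe"), bin_width = 0.1, d_max = 3) {
    law <- match.arg(law)
    if (length(d) < 30) stop("at least 30 spacings are required")
    breaks <- c(seq(0, d_max, by = bin_width), Inf)
    obs <- as.vector(table(cut(d, breaks, right = FALSE)))
    cdf <- switch(law,
        poisson = function(x) 1 - exp(-x),
        goe = function(x) 1 - exp(-pi * x^2 / 4))
    pr <- diff(cdf(breaks))
    exp_ct <- length(d) * pr
    ## greedy left-to-right merge so each pooled bin has expected >= 5
    o <- e <- numeric(0); co <- ce <- 0
    for (i in seq_along(obs)) {
        co <- co + obs[i]; ce <- ce + exp_ct[i]
        if (ce >= 5) { o <- c(o, co); e <- c(e, ce); co <- ce <- 0 }
    }
    if (ce > 0 && length(e)) { o[length(o)] <- o[length(o)] + co
                               e[length(e)] <- e[length(e)] + ce }
    if (length(e) < 2)
        return(list(statistic = Inf, df = 1L, p.value = 0, law = law))
    stat <- sum((o - e)^2 / e)
    dfree <- length(e) - 1L
    list(statistic = stat, df = dfree,
         p.value = stats::pchisq(stat, dfree, lower.tail = FALSE), law = law)
}

#' Scan candidate similarity thresholds for the RMT transition
#'
#' For each candidate threshold s_t the similarity matrix is hard-
#' thresholded (|r| < s_t zeroed, diagonal kept), rows/columns with no
#' remaining off-diagonal entry are dropped, the spectrum is
#' eigendecomposed and unfolded, and the nearest-neighbour spacing
#' distribution is tested against both the Poisson law (modular /
#' system-specific structure) and the GOE Wigner surmise (random-matrix
#' behaviour). Scan points with too few distinct eigenvalues or spacings
#' are flagged unusable, not errors.
#'
#' @param S a [SimilarityMatrix-class].
#' @param s_min,s_max,step scan grid, default 0.30 to 0.99 by 0.01.
#' @param unfold_df spline df passed to [unfoldSpectrum()].
#' @return a [ThresholdScan-class].
#' @export
scanThresholds <- function(S, s_min = 0.30, s_max = 0.99, step = 0.01,
                           unfold_df = 10) {
    r <- similarityValues(S)
    if (nrow(r) < 60)
        warning("fewer than 60 OTUs; RMT spacing statistics will be weak")
    thresholds <- seq(s_min, s_max, by = step)
    rows <- lapply(thresholds, function(st) {
        a <- r
        a[abs(a) < st] <- 0
        diag(a) <- 1
        keep <- rowSums(abs(a) > 0) > 1          # an off-diagonal survivor
        n_nodes <- sum(keep)
        out <- data.frame(threshold = st, n_nodes = n_nodes,
                          n_spacings = 0L, chi2_poisson = NA_real_,
                          p_poisson = NA_real_, chi2_goe = NA_real_,
                          usable = FALSE)
        if (n_nodes < 3) return(out)
        lam <- eigen(a[keep, keep, drop = FALSE], symmetric = TRUE,
                     only.values = TRUE)$values
        d <- unfoldSpectrum(lam, df = unfold_df)
        if (is.null(d) || length(d) < 30) return(out)
        po <- nnsdChi2(d, "poisson")
        go <- nnsdChi2(d, "goe")
        out$n_spacings <- length(d)
        out$chi2_poisson <- po$statistic
        out$p_poisson <- po$p.value
        out$chi2_goe <- go$statistic
        out$usable <- is.finite(po$statistic) && is.finite(go$statistic)
        out
    })
    methods::new("ThresholdScan", scan = do.call(rbind, rows),
                 selected = NA_real_)
}

#' Select the RMT similarity threshold from a scan
#'
#' Returns the smallest threshold whose spacing distribution is consistent
#' with the Poisson law (goodness-of-fit p > `alpha`) and fits Poisson
#' better than GOE (chi2_poisson < chi2_goe) — the point where the spectrum
#' has crossed from random-matrix to modular statistics. If no scan point
#' qualifies, the usable threshold minimising chi2_poisson is returned with
#' a prominent warning.
#'
#' @param scan a [ThresholdScan-class].
#' @param alpha Poisson goodness-of-fit level, default 0.05.
#' @return the selected threshold (also recorded in the returned scan when
#'   assigned back); a bare numeric.
#' @export
selectThreshold <- function(scan, alpha = 0.05) {
    sc <- scanTable(scan)
    ok <- sc$usable
    if (!any(ok)) stop("no usable scan points; matrix too small or too sparse")
    qual <- ok & sc$p_poisson > alpha & sc$chi2_poisson < sc$chi2_goe
    if (any(qual)) return(sc$threshold[which(qual)[1]])
    warning("no Poisson-consistent threshold found; ",
            "returning the threshold minimising the Poisson chi-square. ",
            "Inspect the scan before trusting this network.")
    sc$threshold[ok][which.min(sc$chi2_poisson[ok])]
}

#' Build the signed co-occurrence network at a threshold
#'
#' An edge joins every OTU pair with |r| >= s_t; edge weight is the signed
#' correlation and edge sign its sign. Nodes left without any edge are
#' removed. Node phylum annotation is attached when taxonomy is supplied.
#'
#' @param S a [SimilarityMatrix-class].
#' @param s_t similarity threshold in (0, 1).
#' @param taxonomy optional data.frame with a `phylum` column, rownames =
#'   OTU ids (as from [taxonomyTable()]).
#' @param group optional group label stored on the network.
#' @return a [CoNetwork-class].
#' @export
buildNetwork <- function(S, s_t, taxonomy = NULL, group = "") {
    stopifnot(s_t > 0, s_t < 1)
    r <- similarityValues(S)
    a <- abs(r) >= s_t
    diag(a) <- FALSE
    if (!any(a)) stop("empty network: no |r| >= ", s_t)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    igraph::E(g)$weight <- r[igraph::as_edgelist(g, names = FALSE)]
    igraph::E(g)$sign <- ifelse(igraph::E(g)$weight >= 0, 1L, -1L)
    g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
    phy <- rep(NA_character_, igraph::vcount(g))
    if (!is.null(taxonomy)) {
        idx <- match(igraph::V(g)$name, rownames(taxonomy))
        phy <- as.character(taxonomy$phylum[idx])
    }
    igraph::V(g)$phylum <- phy
    methods::new("CoNetwork", graph = g, threshold = s_t, group = group)
}

#' Positive and negative edge proportions
#'
#' The share of network edges whose underlying correlation is positive
#' (co-occurrence) versus negative (mutual exclusion), as percentages
#' summing to 100.
#'
#' @param net a [CoNetwork-class].
#' @return named numeric vector `c(positive =, negative =)`.
#' @export
edgeSignProportions <- function(net) {
    sgn <- igraph::E(networkGraph(net))$sign
    if (!length(sgn)) stop("network has no edges")
    c(positive = 100 * mean(sgn > 0), negative = 100 * mean(sgn < 0))
}
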