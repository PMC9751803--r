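#' Secondary extinction after node removal
#'
#' Deletes the removed nodes and then iteratively deletes any node whose
#' remaining degree is zero (a taxon with no remaining partners is treated
#' as extinct). Returns the surviving node names.
#'
#' @param net a [CoNetwork-class].
#' @param removed character vector of node names to delete (subset of the
#'   network's nodes).
#' @return character vector of survivors (possibly empty).
#' @export
secondaryExtinction <- function(net, removed) {
    g <- networkGraph(net)
    stopifnot(all(removed %in% igraph::V(g)$name))
    g <- igraph::delete_vertices(g, removed)
    repeat {
        iso <- igraph::V(g)$name[igraph::degree(g) == 0]
        if (!length(iso)) break
        g <- igraph::delete_vertices(g, iso)
    }
    igraph::V(g)$name
}

#' Network robustness under random or keystone-targeted removal
#'
#' Each repetition removes a set of nodes, applies the secondary-extinction
#' cascade, and records the fraction of the *original* node count that
#' survives. Under `random_nodes`, floor(fraction x N) nodes are sampled
#' uniformly; under `targeted_keystones`, ceiling(fraction x |keystones|)
#' keystones are removed (a random subset when the keystone set is larger),
#' so removing "50% of one keystone" removes it.
#'
#' @param net a [CoNetwork-class].
#' @param scheme "random_nodes" or "targeted_keystones".
#' @param fraction fraction removed, in (0, 1); default 0.5.
#' @param repetitions default 100.
#' @param keystones character vector of keystone node names (required for
#'   the targeted scheme).
#' @param seed optional RNG seed.
#' @return a [RobustnessResult-class].
#' @export
networkRobustness <- function(net, scheme = c("random_nodes",
                                              "targeted_keystones"),
                              fraction = 0.5, repetitions = 100,
                              keystones = NULL, seed = NULL) {
    scheme <- match.arg(scheme)
    stopifnot(fraction > 0, fraction < 1, repetitions >= 1)
    g <- networkGraph(net)
    nodes <- igraph::V(g)$name
    n <- length(nodes)
    if (scheme == "targeted_keystones") {
        if (is.null(keystones) || !length(keystones))
            stop("no keystones supplied; use scheme = 'random_nodes' instead")
        stopifnot(all(keystones %in% nodes))
        n_rm <- ceiling(fraction * length(keystones))
        pool <- keystones
    } else {
        n_rm <- floor(fraction * n)
        pool <- nodes
    }
    if (!is.null(seed)) set.seed(seed)
    vals <- vapply(seq_len(repetitions), function(i) {
        rm <- if (n_rm >= length(pool)) pool else sample(pool, n_rm)
        length(secondaryExtinction(net, rm)) / n
    }, numeric(1))
    methods::new("RobustnessResult", values = vals, scheme = scheme,
                 fraction = fraction, repetitions = as.integer(repetitions))
}

#' Compare robustness distributions across groups
#'
#' One-way ANOVA on the per-repetition robustness values, with a Tukey HSD
#' compact letter display for more than two groups (groups sharing a
#' letter are not significantly different at `alpha`).
#'
#' @param results named list of [RobustnessResult-class], one per group.
#' @param alpha significance level for the letter display, default 0.05.
#' @return list with `F`, `p`, `df`, `means`, `sds`, and `letters` (named
#'   character vector).
#' @export
compareRobustness <- function(results, alpha = 0.05) {
    stopifnot(is.list(results), length(results) >= 2,
              !is.null(names(results)))
    if (any(vapply(results, function(r) length(robustnessValues(r)),
                   integer(1)) < 2))
        stop("every group needs at least 2 repetitions")
    values <- unlist(lapply(results, robustnessValues), use.names = FALSE)
    group <- factor(rep(names(results),
                        vapply(results, function(r)
                            length(robustnessValues(r)), integer(1))),
                    levels = names(results))
    if (stats::var(values) == 0) {
        fstat <- 0; pval <- 1
        dfree <- c(nlevels(group) - 1, length(values) - nlevels(group))
        letters <- structure(rep("a", nlevels(group)), names = levels(group))
    } else {
        fit <- stats::aov(values ~ group)
        av <- summary(fit)[[1]]
        fstat <- av$`F value`[1]
        pval <- av$`Pr(>F)`[1]
        dfree <- av$Df
        tk <- stats::TukeyHSD(fit)$group
        p_adj <- structure(tk[, "p adj"], names = rownames(tk))
        letters <- compactLetters(levels(group), p_adj, alpha)
    }
    list(F = fstat, p = pval, df = dfree,
         means = tapply(values, group, mean),
         sds = tapply(values, group, stats::sd),
         letters = letters)
}

## Insert-and-absorb compact letter display from pairwise adjusted
## p-values named "A-B" (TukeyHSD convention).
#' @keywords internal
compactLetters <- function(groups, p_adj, alpha = 0.05) {
    k <- length(groups)
    same <- matrix(TRUE, k, k, dimnames = list(groups, groups))
    if (length(p_adj)) {
        pairs <- strsplit(names(p_adj), "-", fixed = TRUE)
        for (i in seq_along(p_adj)) {
            a <- pairs[[i]][1]; b <- pairs[[i]][2]
            same[a, b] <- same[b, a] <- p_adj[i] >= alpha
        }
    }
    ## greedy clique cover over the "not significantly different" graph
    sets <- list()
    for (g in groups) {
        placed <- FALSE
        for (j in seq_along(sets)) {
            if (all(same[g, sets[[j]]])) {
                sets[[j]] <- c(sets[[j]], g); placed <- TRUE
            }
        }
        if (!placed) sets[[length(sets) + 1L]] <- g
    }
    lab <- structure(rep("", k), names = groups)
    for (j in seq_along(sets))
        for (g in sets[[j]]) lab[g] <- paste0(lab[g], letters[j])
    lab
}
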