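mkAbund <- function(v) {
    methods::new("AbundanceMatrix", values = v, zeroStrategy = "pseudo",
                 pseudoAbundance = NA_real_)
}

test_that("Pearson similarity matches the textbook sum formula", {
    set.seed(1)
    v <- matrix(rnorm(12), nrow = 3,
                dimnames = list(paste0("o", 1:3), paste0("s", 1:4)))
    sim <- pearsonSimilarity(mkAbund(v))
    r <- similarityValues(sim)
    ## independent sum-formula computation
    for (i in 1:3) for (j in 1:3) {
        x <- v[i, ]; y <- v[j, ]; n <- length(x)
        rij <- (n * sum(x * y) - sum(x) * sum(y)) /
            sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
        expect_equal(r[i, j], rij, tolerance = 1e-12)
    }
    ## identical and negated profiles
    v2 <- rbind(a = v[1, ], b = v[1, ], c = -v[1, ])
    r2 <- similarityValues(pearsonSimilarity(mkAbund(v2)))
    expect_equal(r2["a", "b"], 1)
    expect_equal(r2["a", "c"], -1)
    ## zero-variance row flagged and zeroed
    v3 <- rbind(a = v[1, ], flat = rep(2, 4))
    expect_warning(s3 <- pearsonSimilarity(mkAbund(v3)), "zero-variance")
    expect_equal(similarityValues(s3)["a", "flat"], 0)
    expect_equal(diag(similarityValues(s3)), c(a = 1, flat = 1))
    ## < 3 samples rejected
    expect_error(pearsonSimilarity(mkAbund(v[, 1:2])), "3 samples")
})

test_that("unfolding yields unit-mean spacings and handles degeneracy", {
    d <- unfoldSpectrum(1:100)
    expect_equal(mean(d), 1)
    expect_true(all(abs(d - 1) < 0.05))      # uniform spectrum
    expect_true(all(d >= 0))
    ## duplicates are collapsed; too few distinct values -> NULL flag
    expect_null(unfoldSpectrum(rep(1:10, 10)))
    expect_null(unfoldSpectrum(1:30))
    ## GOE spacings have unit mean too
    lam <- eigen(generateGoeMatrix(300, seed = 4), symmetric = TRUE,
                 only.values = TRUE)$values
    dg <- unfoldSpectrum(lam)
    expect_equal(mean(dg), 1, tolerance = 0.05)
})

test_that("NNSD chi-square separates Wigner from Poisson statistics", {
    ## GOE sample: closer to the Wigner surmise
    lam <- eigen(generateGoeMatrix(500, seed = 1), symmetric = TRUE,
                 only.values = TRUE)$values
    d <- unfoldSpectrum(lam)
    expect_lt(nnsdChi2(d, "goe")$statistic, nnsdChi2(d, "poisson")$statistic)
    ## independent blocks: closer to Poisson
    bm <- matrix(0, 500, 500)
    set.seed(2)
    for (b in 0:9) { idx <- b * 50 + 1:50
                     bm[idx, idx] <- generateGoeMatrix(50) }
    db <- unfoldSpectrum(eigen(bm, symmetric = TRUE, only.values = TRUE)$values)
    expect_lt(nnsdChi2(db, "poisson")$statistic, nnsdChi2(db, "goe")$statistic)
    ## exponential spacings: Poisson calibrated, GOE strongly rejected
    set.seed(3)
    reps <- replicate(60, {
        dd <- rexp(500)
        c(p_po = nnsdChi2(dd, "poisson")$p.value,
          p_go = nnsdChi2(dd, "goe")$p.value)
    })
    expect_lt(mean(reps["p_po", ] < 0.05), 0.15)   # near-nominal rejection
    expect_gte(mean(reps["p_go", ] < 0.001), 0.99) # GOE law rejected
    ## degenerate input stays finite
    out <- nnsdChi2(rep(1, 50), "poisson")
    expect_true(is.finite(out$statistic) || out$statistic == Inf)
    expect_error(nnsdChi2(rexp(10), "poisson"), "30 spacings")
})

test_that("threshold scan records the RMT transition on planted blocks", {
    set.seed(9)
    gc <- generateCommunity(testSpec(n_samples = 50, seed = 9))
    tab <- prevalenceFilter(gc$table)
    sim <- pearsonSimilarity(logRelativeAbundance(tab))
    scan <- scanThresholds(sim, s_min = 0.30, s_max = 0.95, step = 0.05)
    sc <- scanTable(scan)
    expect_true(is.unsorted(sc$threshold) == FALSE)
    expect_true(any(sc$usable))
    ## scan with a coarser grid is a subset of the finer grid
    scan2 <- scanThresholds(sim, s_min = 0.30, s_max = 0.95, step = 0.1)
    shared <- merge(scanTable(scan2), sc, by = "threshold")
    expect_equal(shared$chi2_poisson.x, shared$chi2_poisson.y)
    ## selection: smallest Poisson-consistent point
    st <- selectThreshold(scan)
    qual <- sc$usable & sc$p_poisson > 0.05 & sc$chi2_poisson < sc$chi2_goe
    if (any(qual)) expect_equal(st, sc$threshold[which(qual)[1]])
    ## unusable-only scan errors
    empty <- methods::new("ThresholdScan",
        scan = data.frame(threshold = 0.5, n_nodes = 2L, n_spacings = 0L,
                          chi2_poisson = NA_real_, p_poisson = NA_real_,
                          chi2_goe = NA_real_, usable = FALSE),
        selected = NA_real_)
    expect_error(selectThreshold(empty), "no usable")
    ## fallback path warns when nothing is Poisson-consistent
    fake <- methods::new("ThresholdScan",
        scan = data.frame(threshold = c(0.5, 0.6), n_nodes = c(100L, 90L),
                          n_spacings = c(99L, 89L),
                          chi2_poisson = c(40, 20), p_poisson = c(0.001, 0.002),
                          chi2_goe = c(50, 60), usable = TRUE),
        selected = NA_real_)
    expect_warning(st2 <- selectThreshold(fake), "no Poisson-consistent")
    expect_equal(st2, 0.6)
})

test_that("network construction applies the |r| >= s_t rule with signs", {
    r <- diag(3)
    dimnames(r) <- list(c("A", "B", "C"), c("A", "B", "C"))
    r["A", "B"] <- r["B", "A"] <- 0.9
    r["A", "C"] <- r["C", "A"] <- 0.2
    r["B", "C"] <- r["C", "B"] <- -0.95
    sim <- methods::new("SimilarityMatrix", r = r, nSamples = 10L,
                        method = "pearson")
    net <- buildNetwork(sim, 0.86)
    g <- networkGraph(net)
    expect_equal(igraph::vcount(g), 3)
    expect_equal(igraph::ecount(g), 2)
    expect_setequal(igraph::E(g)$sign, c(1L, -1L))
    expect_equal(sort(igraph::E(g)$weight), c(-0.95, 0.9))
    expect_equal(unname(edgeSignProportions(net)), c(50, 50))
    ## too-high threshold -> empty-network error
    expect_error(buildNetwork(sim, 0.99), "empty network")
    ## lowering s_t never removes an edge
    net2 <- buildNetwork(sim, 0.15)
    expect_gte(igraph::ecount(networkGraph(net2)), igraph::ecount(g))
    ## isolated nodes are dropped
    r2 <- diag(4); dimnames(r2) <- list(letters[1:4], letters[1:4])
    r2["a", "b"] <- r2["b", "a"] <- 0.9
    sim2 <- methods::new("SimilarityMatrix", r = r2, nSamples = 10L,
                         method = "pearson")
    expect_equal(igraph::vcount(networkGraph(buildNetwork(sim2, 0.5))), 2)
})

test_that("edge sign proportions sum to 100 and match simple cases", {
    net <- mkNet(rbind(c("a", "b"), c("b", "c"), c("c", "a")),
                 weights = c(0.9, 0.8, -0.7))
    p <- edgeSignProportions(net)
    expect_equal(unname(p["positive"]), 200 / 3, tolerance = 1e-10)
    expect_equal(sum(p), 100)
    allpos <- mkNet(rbind(c("a", "b"), c("b", "c")))
    expect_equal(unname(edgeSignProportions(allpos)), c(100, 0))
})

test_that("the similarity -> network chain is permutation-equivariant", {
    set.seed(5)
    gc <- generateCommunity(testSpec(n_otus = 60, n_modules = 2,
                                     module_size = 15, n_samples = 20,
                                     seed = 5))
    ab <- logRelativeAbundance(gc$table)
    sim <- pearsonSimilarity(ab)
    net <- buildNetwork(sim, 0.6)
    perm <- sample(nrow(abundanceValues(ab)))
    v2 <- abundanceValues(ab)[perm, ]
    sim2 <- pearsonSimilarity(methods::new("AbundanceMatrix", values = v2,
        zeroStrategy = "pseudo", pseudoAbundance = NA_real_))
    net2 <- buildNetwork(sim2, 0.6)
    e1 <- apply(igraph::as_edgelist(networkGraph(net)), 1,
                function(x) paste(sort(x), collapse = "|"))
    e2 <- apply(igraph::as_edgelist(networkGraph(net2)), 1,
                function(x) paste(sort(x), collapse = "|"))
    expect_setequal(e1, e2)
})
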