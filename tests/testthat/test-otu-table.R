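test_that("OTU tables round-trip through TSV with both lineage styles", {
    counts <- matrix(c(10L, 0L, 5L, 90L, 4L, 0L), nrow = 3,
                     dimnames = list(c("OTU_1", "OTU_2", "OTU_3"),
                                     c("S1", "S2")))
    tsv <- tempfile(fileext = ".tsv")
    md <- tempfile(fileext = ".tsv")
    writeLines(c(
        "# Constructed from biom file",
        "#OTU ID\tS1\tS2\ttaxonomy",
        "OTU_1\t10\t90\tk__Bacteria; p__Firmicutes; c__Clostridia; o__; f__; g__Blautia",
        "OTU_2\t0\t4\tD_0__Bacteria;D_1__Proteobacteria;D_2__Gammaproteobacteria",
        "OTU_3\t5\t0\tgibberish lineage"), tsv)
    writeLines(c("sample_id\tgroup\ttimepoint", "S1\tctrl\tT1", "S2\tctrl\tT2"), md)
    expect_warning(tab <- readOtuTable(tsv, md), "Unclassified")
    expect_s4_class(tab, "OtuTable")
    expect_identical(dim(tab), c(3L, 2L))
    tax <- taxonomyTable(tab)
    expect_identical(tax$phylum, c("Firmicutes", "Proteobacteria", "Unclassified"))
    expect_identical(tax$genus[1], "Blautia")
    expect_identical(tax$class[2], "Gammaproteobacteria")
    expect_identical(otuCounts(tab)["OTU_1", "S2"], 90L)

    ## writeOtuTable -> readOtuTable round trip
    spec <- testSpec(n_otus = 20, n_samples = 5, n_modules = 2,
                     module_size = 5, seed = 7)
    tab2 <- generateCommunity(spec)$table
    f1 <- tempfile(); f2 <- tempfile()
    writeOtuTable(tab2, f1, f2)
    back <- readOtuTable(f1, f2)
    expect_identical(otuCounts(back), otuCounts(tab2))
    expect_identical(taxonomyTable(back)$phylum, taxonomyTable(tab2)$phylum)
})

test_that("malformed tables are rejected", {
    tsv <- tempfile(); md <- tempfile()
    writeLines(c("otu\tS1\tS1\ttaxonomy", "A\t1\t2\tk__Bacteria"), tsv)
    writeLines(c("sample_id\tgroup", "S1\tg"), md)
    expect_error(readOtuTable(tsv, md), "duplicate sample")
    writeLines(c("otu\tS1\ttaxonomy", "A\t1\tk__B", "A\t2\tk__B"), tsv)
    expect_error(readOtuTable(tsv, md), "duplicate OTU")
    writeLines(c("otu\tS1\ttaxonomy", "A\t-4\tk__B"), tsv)
    expect_error(readOtuTable(tsv, md), "non-negative")
    writeLines(c("otu\tS1\tS2\ttaxonomy", "A\t1\t2\tk__B"), tsv)
    writeLines(c("sample_id\tgroup", "S1\tg"), md)
    expect_error(readOtuTable(tsv, md), "without metadata")
})

test_that("prevalence filter keeps the boundary and behaves monotonically", {
    counts <- rbind(p44 = c(1L, 2L, 3L, 4L), p34 = c(0L, 2L, 3L, 4L),
                    p24 = c(0L, 0L, 3L, 4L), p14 = c(0L, 0L, 0L, 4L),
                    p04 = c(0L, 0L, 0L, 0L))
    colnames(counts) <- paste0("S", 1:4)
    tab <- MicEcoNet:::makeOtuTable(counts, parseLineages(rep("k__B", 5)),
                                    group = rep("g", 4))
    kept <- prevalenceFilter(tab, 0.5)
    expect_identical(rownames(kept), c("p44", "p34", "p24"))   # 2/4 kept
    expect_identical(ncol(kept), 4L)
    ## idempotent
    expect_identical(rownames(prevalenceFilter(kept, 0.5)), rownames(kept))
    ## monotone shrinkage in min_prevalence
    sizes <- vapply(c(0.25, 0.5, 0.75, 1), function(p)
        nrow(prevalenceFilter(tab, p)), integer(1))
    expect_true(all(diff(sizes) <= 0))
    expect_identical(rownames(prevalenceFilter(tab, 1)), "p44")
    ## the all-zero OTU never survives
    expect_false("p04" %in% rownames(prevalenceFilter(tab, 0.01)))
    ## empty result errors
    tab0 <- tab[5, ]
    expect_error(prevalenceFilter(tab0, 0.5), "no OTUs survive")
})

test_that("log relative abundance applies the stated zero rule", {
    counts <- rbind(a = c(10L, 30L), b = c(90L, 0L), c = c(0L, 70L))
    colnames(counts) <- c("S1", "S2")
    tab <- MicEcoNet:::makeOtuTable(counts, parseLineages(rep("k__B", 3)),
                                    group = c("g", "g"))
    ab <- logRelativeAbundance(tab)
    v <- abundanceValues(ab)
    expect_equal(v["a", "S1"], -1)                      # p = 0.1
    expect_equal(v["b", "S1"], log10(0.9))
    ## min nonzero p is 0.1 -> zeros replaced by 1e-3
    expect_equal(ab@pseudoAbundance, 0.001)
    expect_equal(v["c", "S1"], -3)
    ## strictly positive table: strategy irrelevant
    cts2 <- rbind(a = c(10L, 30L), b = c(90L, 70L))
    colnames(cts2) <- c("S1", "S2")
    tab2 <- MicEcoNet:::makeOtuTable(cts2, parseLineages(rep("k__B", 2)),
                                     group = c("g", "g"))
    expect_identical(abundanceValues(logRelativeAbundance(tab2, "pseudo")),
                     abundanceValues(logRelativeAbundance(tab2, "na")))
    ## zero-total sample errors by name
    cts3 <- rbind(a = c(10L, 0L)); colnames(cts3) <- c("S1", "Sbad")
    tab3 <- MicEcoNet:::makeOtuTable(cts3, parseLineages("k__B"),
                                     group = c("g", "g"))
    expect_error(logRelativeAbundance(tab3), "Sbad")
    ## sample-order equivariance
    perm <- c("S2", "S1")
    expect_identical(abundanceValues(logRelativeAbundance(tab))[, perm],
                     abundanceValues(logRelativeAbundance(tab[, perm])))
})

test_that("alpha diversity matches closed forms and attains its bounds", {
    expect_equal(shannonIndex(rep(1, 4)), 2)
    expect_equal(shannonIndex(c(5, 0, 0)), 0)
    expect_equal(shannonIndex(c(0.5, 0.25, 0.25)), 1.5)
    expect_equal(shannonIndex(rep(1, 8), base = exp(1)), log(8))
    expect_equal(simpsonIndex(rep(1, 4)), 0.75)
    expect_equal(simpsonIndex(c(3, 0)), 0)
    expect_equal(simpsonIndex(c(0.5, 0.5)), 0.5)
    expect_error(shannonIndex(c(0, 0)), "zero")
    expect_error(simpsonIndex(c(0, 0)), "zero")
    ## H is maximal exactly at the uniform vector (grid search, S <= 10)
    for (S in 2:10) {
        hmax <- shannonIndex(rep(1, S))
        expect_equal(hmax, log2(S))
        set.seed(S)
        for (i in 1:50) {
            p <- stats::runif(S)
            expect_lte(shannonIndex(p), hmax + 1e-12)
        }
    }
    ## simpson invariant to taxon order
    p <- c(0.4, 0.3, 0.2, 0.1)
    expect_equal(simpsonIndex(p), simpsonIndex(rev(p)))
})

test_that("compareAlpha is one-way ANOVA with the F = t^2 property", {
    v <- c(1, 2, 3, 1, 2, 3)
    g <- rep(c("a", "b"), each = 3)
    res <- compareAlpha(v, g)
    expect_equal(res$F, 0)
    expect_equal(res$p, 1)
    set.seed(42)
    v2 <- c(rnorm(6), rnorm(7, 1))
    g2 <- rep(c("a", "b"), c(6, 7))
    res2 <- compareAlpha(v2, g2)
    tt <- t.test(v2 ~ g2, var.equal = TRUE)
    expect_equal(res2$F, unname(tt$statistic)^2)
    expect_equal(res2$p, tt$p.value)
    expect_error(compareAlpha(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("ANOVA type-I error is calibrated at the nominal level", {
    set.seed(11)
    rej <- mean(replicate(400, {
        v <- rnorm(15)
        compareAlpha(v, rep(c("a", "b", "c"), each = 5))$p < 0.05
    }))
    expect_gt(rej, 0.02)
    expect_lt(rej, 0.09)
})
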