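#' Specification of a synthetic microbial community
#'
#' Collects and validates the parameters of the synthetic-community
#' generator. Defaults emulate a gut-microbiome 16S study arm: a few
#' hundred OTUs, about a dozen samples, compositional counts at a fixed
#' sequencing depth with zero inflation, planted correlation modules with
#' a tunable negative-association fraction, and one high-connectivity hub
#' per module.
#'
#' @param n_otus number of OTUs, default 200.
#' @param n_samples samples in the group, default 12.
#' @param n_modules planted modules, default 4.
#' @param module_size OTUs per planted module, default 25; the remaining
#'   n_otus - n_modules x module_size OTUs form unstructured background
#'   (no planted associations), as in real communities where only part of
#'   the assemblage is tightly covarying. Background biomass also damps
#'   the spurious positive shift that compositional closure would
#'   otherwise impose on every correlation.
#' @param rho_pos peak within-module latent correlation, in (0, 1);
#'   default 0.8. Member loadings are spread below this peak
#'   (`loading_spread`), giving heterogeneous within-module correlations
#'   and a right-skewed degree distribution.
#' @param f_neg fraction of within-module pairs planted with a negative
#'   association, in [0, 0.5]; default 0.2. Implemented by per-OTU sign
#'   flips (positive semi-definite by construction), which caps the
#'   representable fraction at 0.5.
#' @param hubs_per_module planted hubs per module, default 1; hubs get a
#'   loading boost (`hub_boost`) so they carry the strongest correlations
#'   of their block.
#' @param loading_spread spread of member squared loadings below
#'   `rho_pos`, default 0.2.
#' @param hub_boost increment of hub squared loading over `rho_pos`
#'   (capped at 0.97), default 0.15.
#' @param depth sequencing depth (reads per sample), default 50000.
#' @param zero_inflation post-sampling dropout: a count c is zeroed with
#'   probability `zero_inflation * exp(-c / dropout_tau)`, so dropout
#'   concentrates on low-abundance entries as in real 16S libraries;
#'   default 0.05.
#' @param dropout_tau abundance scale of the dropout kernel (counts),
#'   default 25.
#' @param mu_sd standard deviation of per-OTU log mean abundances,
#'   default 1.5 (natural-log scale).
#' @param group_label group label written to the sample metadata.
#' @param seed RNG seed.
#' @return validated list of class "CommunitySpec".
#' @export
communitySpec <- function(n_otus = 200, n_samples = 12, n_modules = 4,
                          module_size = 25, rho_pos = 0.8, f_neg = 0.2,
                          hubs_per_module = 1, loading_spread = 0.2,
                          hub_boost = 0.15, depth = 50000,
                          zero_inflation = 0.05, dropout_tau = 25,
                          mu_sd = 1.5, group_label = "G1", seed = 1) {
    stopifnot(rho_pos > 0, rho_pos < 1, f_neg >= 0, depth > 0,
              n_modules <= n_otus, n_samples >= 3, zero_inflation >= 0,
              zero_inflation < 1, loading_spread >= 0, loading_spread < rho_pos,
              n_modules * module_size <= n_otus, dropout_tau > 0)
    if (f_neg > 0.5)
        stop("f_neg > 0.5 is not representable by the sign-flip model; ",
             "gut co-occurrence networks are predominantly positive")
    structure(as.list(environment()), class = "CommunitySpec")
}

PHYLA <- c("Firmicutes", "Proteobacteria", "Actinobacteria",
           "Bacteroidetes", "Verrucomicrobia", "Fusobacteria",
           "Tenericutes", "Cyanobacteria")

#' Generate a synthetic OTU table with known network ground truth
#'
#' Latent log-abundances follow a per-module single-factor model:
#' z_i = e_i (a_i F_m(i) + sqrt(1 - a_i^2) eps_i) with standard-normal
#' factors and noise, sign e_i in {-1, +1}, so the planted correlation of
#' OTUs i, j in the same module is e_i e_j a_i a_j and 0 across modules —
#' positive semi-definite by construction. The fraction of flipped signs
#' per module is solved from `f_neg` (negative pair fraction = 2q(1-q)).
#' Latents are exponentiated to log-normal abundances around per-OTU means,
#' scaled to compositions, counts drawn multinomially at `depth`, and zeros
#' injected by Bernoulli dropout whose rate decays with the count
#' (abundance-dependent, as sequencing dropout is). OTUs beyond the
#' planted blocks are unstructured background. Taxonomy is assigned so
#' each module is dominated (80%) by one phylum.
#'
#' @param spec a [communitySpec()].
#' @param mu optional per-OTU log mean abundances (recycled across groups
#'   to build matched-marginal scenarios); drawn from N(0, mu_sd^2) when
#'   absent.
#' @param sample_prefix prefix for sample ids, default the group label.
#' @return list with `table` (an [OtuTable-class]) and `truth` (list:
#'   `module` named assignment, `hubs`, `signs` per-OTU, `sigma` planted
#'   correlation matrix, `sign_matrix`, `mu`).
#' @export
generateCommunity <- function(spec, mu = NULL, sample_prefix = NULL) {
    stopifnot(inherits(spec, "CommunitySpec"))
    set.seed(spec$seed)
    n <- spec$n_otus; ns <- spec$n_samples; m <- spec$n_modules
    otu_ids <- sprintf("OTU_%04d", seq_len(n))
    if (is.null(sample_prefix)) sample_prefix <- spec$group_label
    sample_ids <- sprintf("%s_S%02d", sample_prefix, seq_len(ns))

    ## module 0 = unstructured background
    module <- rep(0L, n)
    module[seq_len(m * spec$module_size)] <- rep(seq_len(m),
                                                 each = spec$module_size)
    hubs <- unlist(lapply(seq_len(m), function(s)
        which(module == s)[seq_len(min(spec$hubs_per_module,
                                       sum(module == s)))]))
    ## sign flips: per-module flipped fraction q gives 2q(1-q) negative pairs
    q <- (1 - sqrt(1 - 2 * spec$f_neg)) / 2
    signs <- rep(1L, n)
    for (s in seq_len(m)) {
        idx <- setdiff(which(module == s), hubs)
        nflip <- round(q * sum(module == s))
        if (nflip > 0) signs[sample(idx, min(nflip, length(idx)))] <- -1L
    }
    ## factor loadings: members spread below rho_pos, hubs boosted above,
    ## background unloaded
    a2 <- stats::runif(n, spec$rho_pos - spec$loading_spread, spec$rho_pos)
    a2[hubs] <- min(0.97, spec$rho_pos + spec$hub_boost)
    a2[module == 0L] <- 0
    a <- sqrt(a2)

    sigma <- diag(n)
    for (s in seq_len(m)) {
        idx <- which(module == s)
        sigma[idx, idx] <- outer(a[idx], a[idx])
    }
    diag(sigma) <- 1
    sigma <- sigma * outer(signs, signs)
    ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min < -1e-8) {
        warning("planted correlation matrix not PSD; applying nearest-PSD repair")
        sigma <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    }
    dimnames(sigma) <- list(otu_ids, otu_ids)

    f <- matrix(stats::rnorm(ns * m), ns, m)
    e <- matrix(stats::rnorm(ns * n), ns, n)
    zf <- t(sweep(f[, pmax(module, 1L), drop = FALSE], 2, a, "*"))
    ze <- t(sweep(e, 2, sqrt(1 - a2), "*"))
    z <- signs * (zf + ze)                       # OTU x sample
    if (is.null(mu)) mu <- stats::rnorm(n, 0, spec$mu_sd)
    w <- exp(mu + z)
    counts <- vapply(seq_len(ns), function(s)
        stats::rmultinom(1, spec$depth, w[, s])[, 1], integer(n))
    if (spec$zero_inflation > 0) {
        p_drop <- spec$zero_inflation * exp(-counts / spec$dropout_tau)
        mask <- matrix(stats::runif(n * ns) < p_drop, n, ns)
        counts[mask] <- 0L
    }
    dimnames(counts) <- list(otu_ids, sample_ids)

    phylum <- character(n)
    structured <- module > 0L
    phylum[structured] <- PHYLA[((module[structured] - 1) %% length(PHYLA)) + 1]
    swap <- structured & stats::runif(n) > 0.8
    phylum[swap] <- sample(PHYLA, sum(swap), replace = TRUE)
    phylum[!structured] <- sample(PHYLA, sum(!structured), replace = TRUE)
    taxonomy <- data.frame(kingdom = "Bacteria", phylum = phylum,
                           class = "Unclassified", order = "Unclassified",
                           family = "Unclassified",
                           genus = sprintf("Genus_%04d", seq_len(n)),
                           stringsAsFactors = FALSE)
    tab <- makeOtuTable(counts, taxonomy,
                        group = rep(spec$group_label, ns))
    names(module) <- names(signs) <- otu_ids
    list(table = tab,
         truth = list(module = module, hubs = otu_ids[hubs], signs = signs,
                      sigma = sigma,
                      sign_matrix = sign(sigma) * (abs(sigma) > 1e-12),
                      mu = mu, latent = z))
}

#' Sample a Gaussian Orthogonal Ensemble matrix
#'
#' Symmetric matrix with independent N(0, 1) off-diagonal entries and
#' N(0, 2) diagonal entries; its unfolded nearest-neighbour spacings
#' follow the Wigner surmise. Used as the positive control for the RMT
#' threshold machinery (a block-diagonal composite of independent GOE
#' blocks is the matching Poisson control).
#'
#' @param n matrix size.
#' @param seed optional RNG seed.
#' @return n x n symmetric numeric matrix.
#' @export
generateGoeMatrix <- function(n, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    b <- matrix(stats::rnorm(n * n), n, n)
    (b + t(b)) / sqrt(2)
}

#' Generate a two-group scenario with planted connectivity ordering
#'
#' Group B is generated with denser latent structure than group A (by
#' default a higher within-module correlation peak), while both groups
#' share the same per-OTU mean log abundances so their composition
#' margins — hence alpha diversity — are matched. Ground truth records the
#' planted ordering for trend tests.
#'
#' @param spec_A a [communitySpec()] for group A.
#' @param spec_B optional spec for group B; by default spec_A with
#'   `rho_pos` raised to 0.85 (A defaults to 0.60 when left at the
#'   `communitySpec` default 0.8 peak this function overrides — pass
#'   explicit specs to control both), `group_label` "B" and an offset seed.
#' @return list with `table` (combined [OtuTable-class], groups A and B),
#'   `truth_A`, `truth_B`, and `ordering` ("denser_B").
#' @export
generateTwoGroupScenario <- function(spec_A = NULL, spec_B = NULL) {
    if (is.null(spec_A))
        spec_A <- communitySpec(rho_pos = 0.60, group_label = "A", seed = 1)
    if (is.null(spec_B)) {
        spec_B <- spec_A
        spec_B$rho_pos <- 0.85
        spec_B$group_label <- "B"
        spec_B$seed <- spec_A$seed + 1000L
    }
    stopifnot(spec_A$n_otus == spec_B$n_otus)
    if (identical(spec_A$group_label, spec_B$group_label))
        stop("the two groups need distinct group labels")
    set.seed(spec_A$seed + 5000L)
    mu <- stats::rnorm(spec_A$n_otus, 0, spec_A$mu_sd)
    gA <- generateCommunity(spec_A, mu = mu)
    gB <- generateCommunity(spec_B, mu = mu)
    counts <- cbind(otuCounts(gA$table), otuCounts(gB$table))
    tax <- taxonomyTable(gA$table)
    tab <- makeOtuTable(counts, tax,
                        group = c(sampleGroups(gA$table),
                                  sampleGroups(gB$table)))
    list(table = tab, truth_A = gA$truth, truth_B = gB$truth,
         ordering = "denser_B")
}

#' Write an OTU table (counts + taxonomy + metadata) to TSV files
#'
#' The counts file has OTU ids in the first column, one column per sample,
#' and a `taxonomy` lineage column last (Greengenes-style prefixes); the
#' metadata file has columns sample_id, group, timepoint. The pair
#' round-trips through [readOtuTable()].
#'
#' @param table an [OtuTable-class].
#' @param counts_path,metadata_path output TSV paths.
#' @export
writeOtuTable <- function(table, counts_path, metadata_path) {
    cts <- otuCounts(table)
    tax <- taxonomyTable(table)
    lineage <- sprintf("k__%s; p__%s; c__%s; o__%s; f__%s; g__%s",
                       tax$kingdom, tax$phylum, tax$class, tax$order,
                       tax$family, tax$genus)
    df <- data.frame(`#OTU ID` = rownames(cts), cts,
                     taxonomy = lineage, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- SummarizedExperiment::colData(table)
    md <- data.frame(sample_id = rownames(cd), group = cd$group,
                     timepoint = cd$timepoint, stringsAsFactors = FALSE)
    utils::write.table(md, metadata_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(counts_path, metadata_path))
}
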