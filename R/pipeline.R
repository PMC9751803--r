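#' Pipeline configuration
#'
#' Resolves user settings against documented defaults; accepts a list or a
#' path to a JSON file with the same fields.
#'
#' @param config list or JSON path. Recognised fields: `otu_table`,
#'   `metadata` (input TSV paths; alternatively pass an [OtuTable-class]
#'   as `table`), `min_prevalence` (0.5), `prevalence_scope` ("per_group"
#'   or "global"), `zero_strategy` ("pseudo"), `threshold_mode` ("auto":
#'   RMT selection per group; "shared_auto": RMT selection per group, then
#'   the smallest selected value applied to every group, mirroring how a
#'   single similarity threshold is used when comparing networks across
#'   groups; "fixed"), `threshold_value` (required when fixed, in (0, 1)),
#'   `s_min`/`s_max`/`step` (0.30/0.99/0.01), `ensemble_n` (100),
#'   `removal_fraction` (0.5), `repetitions` (100), `shannon_base` (2),
#'   `seed` (1), `out_dir`.
#' @return resolved config list.
#' @export
pipelineConfig <- function(config = list()) {
    if (is.character(config)) config <- jsonlite::read_json(config,
                                                            simplifyVector = TRUE)
    defaults <- list(otu_table = NULL, metadata = NULL, table = NULL,
                     min_prevalence = 0.5, prevalence_scope = "per_group",
                     zero_strategy = "pseudo", threshold_mode = "auto",
                     threshold_value = NA_real_, s_min = 0.30, s_max = 0.99,
                     step = 0.01, ensemble_n = 100, removal_fraction = 0.5,
                     repetitions = 100, shannon_base = 2, seed = 1,
                     out_dir = NULL)
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)
    stopifnot(cfg$min_prevalence > 0, cfg$min_prevalence <= 1,
              cfg$removal_fraction > 0, cfg$removal_fraction < 1,
              cfg$repetitions >= 1, cfg$ensemble_n >= 2,
              cfg$prevalence_scope %in% c("per_group", "global"),
              cfg$threshold_mode %in% c("auto", "shared_auto", "fixed"))
    if (cfg$threshold_mode == "fixed" &&
        !(is.finite(cfg$threshold_value) && cfg$threshold_value > 0 &&
          cfg$threshold_value < 1))
        stop("fixed threshold mode requires threshold_value in (0, 1)")
    cfg
}

#' Run the full per-group network pipeline
#'
#' For every level of the sample `group` column: prevalence filtering, log
#' relative abundance, Pearson similarity, RMT threshold (scanned per
#' group, or one shared fixed value), network construction, topology with
#' a degree-preserving null ensemble, module detection, Zi/Pi node roles
#' and keystones, module phylum composition, and robustness under random
#' and keystone-targeted removal. Cross-group tables (edge-sign
#' proportions, topology summary, robustness ANOVA, alpha diversity) and a
#' machine-readable manifest are produced at the end. With `out_dir` set,
#' every table is written as TSV (networks additionally as GraphML); reruns
#' with the same config and seed are byte-identical.
#'
#' @param config a [pipelineConfig()] list (or raw list / JSON path).
#' @return invisible list: per-group results (`groups`), cross-group tables
#'   (`sign_table`, `topology_table`, `robustness_anova`, `alpha`,
#'   `alpha_anova`), and `manifest`.
#' @export
runPipeline <- function(config) {
    cfg <- pipelineConfig(config)
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    }
    tab <- stage("input", {
        if (!is.null(cfg$table)) cfg$table
        else readOtuTable(cfg$otu_table, cfg$metadata)
    })
    out <- cfg$out_dir
    if (!is.null(out) && !dir.exists(out))
        dir.create(out, recursive = TRUE)
    wtsv <- function(df, file) {
        if (!is.null(out))
            utils::write.table(df, file.path(out, file), sep = "\t",
                               quote = FALSE, row.names = FALSE)
    }
    if (cfg$prevalence_scope == "global")
        tab <- stage("prevalence_filter",
                     prevalenceFilter(tab, cfg$min_prevalence))
    groups <- unique(sampleGroups(tab))
    ## first pass: per-group filtering, similarity and threshold evidence
    prep <- list()
    for (gi in seq_along(groups)) {
        g <- groups[gi]
        sub <- tab[, sampleGroups(tab) == g]
        if (cfg$prevalence_scope == "per_group")
            sub <- stage(paste0(g, ":prevalence_filter"),
                         prevalenceFilter(sub, cfg$min_prevalence))
        abund <- stage(paste0(g, ":log_abundance"),
                       logRelativeAbundance(sub, cfg$zero_strategy))
        sim <- stage(paste0(g, ":similarity"), pearsonSimilarity(abund))
        scan <- NULL
        sel <- NA_real_
        if (cfg$threshold_mode != "fixed") {
            scan <- stage(paste0(g, ":threshold_scan"),
                          scanThresholds(sim, cfg$s_min, cfg$s_max, cfg$step))
            sel <- stage(paste0(g, ":threshold_select"), selectThreshold(scan))
        }
        prep[[g]] <- list(sub = sub, sim = sim, scan = scan, sel = sel)
    }
    shared <- if (cfg$threshold_mode == "shared_auto")
        min(vapply(prep, `[[`, numeric(1), "sel")) else NA_real_
    res <- list()
    for (gi in seq_along(groups)) {
        g <- groups[gi]
        sub <- prep[[g]]$sub
        sim <- prep[[g]]$sim
        scan <- prep[[g]]$scan
        s_t <- switch(cfg$threshold_mode,
                      fixed = cfg$threshold_value,
                      shared_auto = shared,
                      auto = prep[[g]]$sel)
        net <- stage(paste0(g, ":network"),
                     buildNetwork(sim, s_t, taxonomyTable(sub), group = g))
        topo <- stage(paste0(g, ":topology"), globalProperties(net))
        ens <- stage(paste0(g, ":null_ensemble"),
                     randomEnsemble(net, n = cfg$ensemble_n,
                                    seed = deriveSeed(cfg$seed, gi, 1)))
        mod <- stage(paste0(g, ":modules"), detectModules(net))
        roles <- stage(paste0(g, ":node_roles"),
                       nodeRoles(net, mod$membership))
        comp <- stage(paste0(g, ":module_composition"),
                      moduleComposition(mod$membership, taxonomyTable(sub)))
        keys <- roles$node[roles$keystone]
        rob_rand <- stage(paste0(g, ":robustness_random"),
                          networkRobustness(net, "random_nodes",
                              fraction = cfg$removal_fraction,
                              repetitions = cfg$repetitions,
                              seed = deriveSeed(cfg$seed, gi, 2)))
        rob_targ <- if (length(keys))
            stage(paste0(g, ":robustness_targeted"),
                  networkRobustness(net, "targeted_keystones",
                      fraction = cfg$removal_fraction,
                      repetitions = cfg$repetitions, keystones = keys,
                      seed = deriveSeed(cfg$seed, gi, 3)))
        else NULL
        signs <- edgeSignProportions(net)
        res[[g]] <- list(network = net, scan = scan, threshold = s_t,
                         topology = topo, ensemble = ens, modules = mod,
                         roles = roles, composition = comp,
                         keystones = keys, robustness_random = rob_rand,
                         robustness_targeted = rob_targ, signs = signs)
        ## per-group artifacts
        cts <- otuCounts(sub)
        wtsv(data.frame(otu_id = rownames(cts), cts, check.names = FALSE),
             paste0(g, "_filtered_counts.tsv"))
        r <- similarityValues(sim)
        wtsv(data.frame(otu_id = rownames(r), r, check.names = FALSE),
             paste0(g, "_similarity.tsv"))
        if (!is.null(scan)) wtsv(scanTable(scan), paste0(g, "_threshold_scan.tsv"))
        wtsv(roles, paste0(g, "_node_roles.tsv"))
        wtsv(comp, paste0(g, "_module_composition.tsv"))
        rob_df <- data.frame(group = g, scheme = "random_nodes",
                             repetition = seq_along(robustnessValues(rob_rand)),
                             robustness = robustnessValues(rob_rand))
        if (!is.null(rob_targ))
            rob_df <- rbind(rob_df, data.frame(group = g,
                scheme = "targeted_keystones",
                repetition = seq_along(robustnessValues(rob_targ)),
                robustness = robustnessValues(rob_targ)))
        wtsv(rob_df, paste0(g, "_robustness.tsv"))
        if (!is.null(out))
            writeNetworkFiles(net, file.path(out, g))
    }
    ## cross-group tables
    sign_table <- do.call(rbind, lapply(groups, function(g)
        data.frame(group = g, positive_pct = res[[g]]$signs["positive"],
                   negative_pct = res[[g]]$signs["negative"],
                   n_edges = igraph::ecount(networkGraph(res[[g]]$network)),
                   row.names = NULL)))
    topology_table <- do.call(rbind, lapply(groups, function(g) {
        ens <- res[[g]]$ensemble
        cbind(data.frame(group = g, threshold = res[[g]]$threshold),
              res[[g]]$topology,
              data.frame(null_avgCC = ens$null_mean[ens$property == "avgCC"],
                         null_GD = ens$null_mean[ens$property == "GD"],
                         null_Q = ens$null_mean[ens$property == "Q"],
                         z_avgCC = ens$z[ens$property == "avgCC"],
                         z_Q = ens$z[ens$property == "Q"]))
    }))
    rob_anova <- if (length(groups) >= 2)
        compareRobustness(lapply(res, `[[`, "robustness_random")) else NULL
    alpha <- alphaDiversity(tab, base = cfg$shannon_base)
    alpha_anova <- if (length(groups) >= 2 && all(table(alpha$group) >= 2))
        list(shannon = compareAlpha(alpha$shannon, alpha$group),
             simpson = compareAlpha(alpha$simpson, alpha$group)) else NULL
    manifest <- list(package = "MicEcoNet",
                     version = as.character(utils::packageVersion("MicEcoNet")),
                     config = cfg[setdiff(names(cfg), c("table", "out_dir"))],
                     groups = groups,
                     thresholds = vapply(res, `[[`, numeric(1), "threshold"),
                     seeds = vapply(seq_along(groups), function(gi)
                         deriveSeed(cfg$seed, gi, 1), integer(1)))
    wtsv(sign_table, "edge_sign_proportions.tsv")
    wtsv(topology_table, "topology_summary.tsv")
    wtsv(alpha, "alpha_diversity.tsv")
    if (!is.null(rob_anova))
        wtsv(data.frame(group = names(rob_anova$means),
                        mean = as.vector(rob_anova$means),
                        sd = as.vector(rob_anova$sds),
                        letter = rob_anova$letters[names(rob_anova$means)],
                        F = rob_anova$F, p = rob_anova$p),
             "robustness_comparison.tsv")
    if (!is.null(out))
        jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(groups = res, sign_table = sign_table,
                   topology_table = topology_table,
                   robustness_anova = rob_anova, alpha = alpha,
                   alpha_anova = alpha_anova, manifest = manifest))
}

#' Export a network as GraphML and Gephi/Cytoscape-ready TSVs
#'
#' Writes `<prefix>_network.graphml`, `<prefix>_nodes.tsv` (node, phylum,
#' degree) and `<prefix>_edges.tsv` (source, target, weight, sign).
#'
#' @param net a [CoNetwork-class].
#' @param prefix output path prefix.
#' @export
writeNetworkFiles <- function(net, prefix) {
    g <- networkGraph(net)
    igraph::write_graph(g, paste0(prefix, "_network.graphml"),
                        format = "graphml")
    utils::write.table(
        data.frame(node = igraph::V(g)$name, phylum = igraph::V(g)$phylum,
                   degree = igraph::degree(g)),
        paste0(prefix, "_nodes.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    el <- igraph::as_edgelist(g)
    utils::write.table(
        data.frame(source = el[, 1], target = el[, 2],
                   weight = igraph::E(g)$weight, sign = igraph::E(g)$sign),
        paste0(prefix, "_edges.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(prefix)
}

#' Compare pipeline results between groups
#'
#' Side-by-side deltas (b minus a) of the topological properties and the
#' positive-edge percentage for each requested contrast.
#'
#' @param result a [runPipeline()] result.
#' @param contrasts data.frame with columns `a` and `b` naming group
#'   levels present in the result; defaults to consecutive pairs in group
#'   order (later minus earlier).
#' @return data.frame, one row per contrast and property.
#' @export
compareGroups <- function(result, contrasts = NULL) {
    tt <- result$topology_table
    st <- result$sign_table
    if (is.null(contrasts)) {
        gs <- tt$group
        if (length(gs) < 2) stop("need at least two groups to compare")
        contrasts <- data.frame(a = gs[-length(gs)], b = gs[-1])
    }
    bad <- setdiff(unique(c(contrasts$a, contrasts$b)), tt$group)
    if (length(bad))
        stop("contrast group(s) not in results: ", paste(bad, collapse = ", "))
    props <- c("N", "L", "avgK", "avgCC", "GD", "Q")
    out <- lapply(seq_len(nrow(contrasts)), function(i) {
        a <- contrasts$a[i]; b <- contrasts$b[i]
        ra <- tt[tt$group == a, ]; rb <- tt[tt$group == b, ]
        rbind(data.frame(contrast = paste(b, "-", a), property = props,
                         value_a = unlist(ra[props]),
                         value_b = unlist(rb[props]),
                         delta = unlist(rb[props]) - unlist(ra[props])),
              data.frame(contrast = paste(b, "-", a),
                         property = "positive_pct",
                         value_a = st$positive_pct[st$group == a],
                         value_b = st$positive_pct[st$group == b],
                         delta = st$positive_pct[st$group == b] -
                             st$positive_pct[st$group == a]))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
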