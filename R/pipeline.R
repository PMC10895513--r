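# Configuration-driven three-step analysis pipeline: parent symptom
# network, cross-parent bridge symptoms, and re-estimation with the child
# emotional-difficulties factor node. Artifacts are plain CSV/JSON, each
# stamped with the seed and a configuration hash.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    # redundancy screen
    corr_min = 0.50, prop_threshold = 0.25, redundancy_alpha = 0.05,
    redundancy_method = "hittner", run_redundancy = TRUE,
    drop_items = character(0),      # human-review outcome: items removed
    # model selection
    corr_method = "auto", start = "sig", sig_alpha = 0.01, max_sweeps = 500L,
    # centrality
    top_prop = 0.30,
    # stability
    run_stability = FALSE, boot_edges_B = 1000L, casedrop_B = 500L,
    drop_proportions = seq(0.05, 0.75, by = 0.10),
    # comparison
    n_perm = 1000L,
    # child factor
    factor_scores = "regression", factor_node_name = "child_emotional",
    covariate_columns = character(0))
}

#' Pipeline configuration
#'
#' Flat configuration for the three-step analysis. Unknown keys are
#' errors, not warnings. The seed is mandatory and drives every stochastic
#' stage.
#'
#' @param ... Named overrides of the defaults: `seed`, `outdir`,
#'   `corr_min`, `prop_threshold`, `redundancy_alpha`, `redundancy_method`,
#'   `run_redundancy`, `drop_items`, `corr_method` (`"auto"`, `"spearman"`
#'   or `"pearson"`; auto uses Spearman unless every column is continuous),
#'   `start`, `sig_alpha`, `max_sweeps`,
#'   `top_prop`, `run_stability`, `boot_edges_B`, `casedrop_B`,
#'   `drop_proportions`, `n_perm`, `factor_scores`, `factor_node_name`,
#'   `covariate_columns`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("pipeline_config: all arguments must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("pipeline_config: unknown key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (is.null(cfg$seed) || is.na(cfg$seed))
    stop("pipeline_config: seed is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a flat key = value file
#'
#' One `key = value` pair per line; `#` starts a comment; vector values are
#' comma-separated. Unknown keys are errors.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad))
    stop("read_pipeline_config: malformed line(s): ",
         paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 1))
  vals <- trimws(vapply(kv, `[`, character(1), 2))
  defaults <- pipeline_defaults()
  parsed <- lapply(seq_along(keys), function(i) {
    k <- keys[i]
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    v <- trimws(v)
    proto <- defaults[[k]]
    if (is.logical(proto)) as.logical(v)
    else if (is.numeric(proto) || is.integer(proto)) as.numeric(v)
    else v
  })
  names(parsed) <- keys
  do.call(pipeline_config, parsed)
}

# Polynomial rolling hash (mod 2^31) over the deparsed configuration;
# stamped into every output file so artifacts can be traced to the exact
# settings that produced them.
config_hash <- function(config) {
  cfg <- config[setdiff(names(config), "outdir")]  # location-independent
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

stamp_line <- function(config) {
  sprintf("# famnet seed=%d config=%s", config$seed, config_hash(config))
}

write_stamped_csv <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(stamp_line(config), con)
  write.table(df, con, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

write_stamped_json <- function(obj, path, config) {
  obj[["_seed"]] <- config$seed
  obj[["_config"]] <- config_hash(config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Serialize a network to JSON
#' @param net A `ggm_network`.
#' @param path Output path.
#' @param config A `pipeline_config` (for the seed/hash stamp).
#' @export
write_network_json <- function(net, path, config = pipeline_config()) {
  stopifnot(inherits(net, "ggm_network"))
  write_stamped_json(list(labels = net$labels,
                          communities = as.list(net$communities[net$labels]),
                          edges = network_edges(net),
                          n = net$n, loglik = net$loglik, bic = net$bic,
                          n_edges = net$n_edges),
                     path, config)
}

parent_nodes <- function(table) {
  table$node_labels[table$communities %in% c("mother", "father")]
}

#' Step 1: estimate the parent symptom network
#'
#' Redundancy screen on the parent communities, removal of the configured
#' items (the human-review outcome), Spearman correlations on complete
#' rows, stepwise BIC network selection, centrality with bridge flags, and
#' (optionally) edge-bootstrap and case-dropping stability. All artifacts
#' are written under `config$outdir` when it is set.
#'
#' @param table A `symptom_table` containing mother and father columns.
#' @param config A [pipeline_config()].
#' @return List: `network`, `centrality`, `redundancy`, `corr`, `layout`,
#'   plus `edge_boot` and `casedrop` when `config$run_stability` is TRUE.
#' @export
run_step1_parent_network <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "symptom_table"),
            inherits(config, "pipeline_config"))
  nodes <- parent_nodes(table)
  if (length(nodes) < 6)
    stop("run_step1_parent_network: need at least 3 nodes per parent")
  ptab <- subset_symptoms(table, nodes)
  redundancy <- if (config$run_redundancy)
    find_redundant_pairs(ptab, corr_min = config$corr_min,
                         prop_threshold = config$prop_threshold,
                         alpha = config$redundancy_alpha,
                         method = config$redundancy_method)
  else NULL
  keep <- setdiff(nodes, config$drop_items)
  ptab <- subset_symptoms(table, keep)
  cm <- corr_matrix_of(ptab, resolve_corr_method(config, ptab))
  net <- select_ggm(cm, start = config$start, sig_alpha = config$sig_alpha,
                    max_sweeps = config$max_sweeps,
                    communities = ptab$communities)
  cent <- centrality_table(net, top_prop = config$top_prop)
  coords <- layout_coordinates(net, seed = config$seed)
  out <- list(network = net, centrality = cent, redundancy = redundancy,
              corr = cm, layout = coords)
  if (config$run_stability) {
    out$edge_boot <- bootstrap_edges(ptab, config, B = config$boot_edges_B,
                                     seed = config$seed + 10L)
    out$casedrop <- casedrop_bootstrap(
      ptab, config, drop_proportions = config$drop_proportions,
      B = config$casedrop_B, seed = config$seed + 20L)
  }
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$outdir, f)
    write_stamped_csv(network_edges(net), fp("edges.csv"), config)
    write_network_json(net, fp("network.json"), config)
    write_stamped_csv(cent, fp("centrality.csv"), config)
    write_stamped_json(
      list(candidate_pairs = if (is.null(redundancy)) list()
           else redundancy$candidate_pairs,
           thresholds = if (is.null(redundancy)) list()
           else redundancy$threshold_config,
           dropped = config$drop_items),
      fp("redundancy.json"), config)
    write_stamped_csv(coords, fp("layout.csv"), config)
    if (config$run_stability) {
      write_stamped_csv(out$edge_boot$edges, fp("bootstrap_edges.csv"), config)
      cd <- data.frame(drop_proportion = rep(out$casedrop$drop_proportions,
                                             each = nrow(out$casedrop$correlations)),
                       correlation = as.vector(out$casedrop$correlations))
      write_stamped_csv(cd, fp("casedrop.csv"), config)
    }
  }
  out
}

#' Step 2: flag bridge symptoms between the parent communities
#'
#' Bridge strength over the mother/father communities with top-proportion
#' flagging. When the network has no negative edges, bridge expected
#' influence coincides with bridge strength and the signed variant is
#' omitted (noted in the result); with negative edges present both are
#' reported.
#'
#' @param step1 Result of [run_step1_parent_network()].
#' @param config A [pipeline_config()].
#' @return List: `centrality` (flagged table), `bridges` (flagged node
#'   labels), `all_positive`, `note`.
#' @export
run_step2_bridges <- function(step1, config = pipeline_config()) {
  if (is.null(step1$network))
    stop("run_step2_bridges: step-1 artifacts are missing")
  net <- step1$network
  cent <- centrality_table(net, top_prop = config$top_prop)
  all_positive <- all(net$weights >= 0)
  note <- if (all_positive)
    "no negative edges: bridge expected influence equals bridge strength; signed variant omitted"
  else
    "negative edges present: bridge expected influence reported alongside bridge strength"
  if (all_positive)
    cent$bridge_expected_influence <- NULL
  out <- list(centrality = cent,
              bridges = cent$node[cent$is_bridge],
              all_positive = all_positive, note = note)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_stamped_csv(cent, file.path(config$outdir, "bridge_centrality.csv"),
                      config)
  }
  out
}

#' Step 3: re-estimate the network with the child factor node
#'
#' Fits the one-factor model to the three child wave columns, appends the
#' factor score as a continuous node, and re-estimates the network over
#' the (screened) parent symptoms, the child node and any configured
#' covariate columns.
#'
#' @param table A `symptom_table` with parent columns and exactly three
#'   child wave columns (community `"child"`).
#' @param config A [pipeline_config()].
#' @return List: `network`, `centrality`, `factor`, `child_edges` (edges
#'   between parent symptoms and the child node).
#' @export
run_step3_child_network <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "symptom_table"),
            inherits(config, "pipeline_config"))
  wave_cols <- table$node_labels[table$communities == "child"]
  if (length(wave_cols) < 3)
    stop("run_step3_child_network: need 3 child wave columns, found ",
         length(wave_cols))
  keep_rows <- complete.cases(table$values)
  fac <- fit_one_factor(table$values[keep_rows, wave_cols, drop = FALSE],
                        scores = config$factor_scores)
  node <- config$factor_node_name
  parents <- setdiff(parent_nodes(table), config$drop_items)
  covars <- config$covariate_columns
  if (length(covars) && !all(covars %in% table$node_labels))
    stop("run_step3_child_network: unknown covariate column(s)")
  values <- table$values[keep_rows, c(parents, covars), drop = FALSE]
  values[[node]] <- fac$scores
  labels <- c(parents, covars, node)
  comms <- c(table$communities[parents],
             setNames(rep("covariate", length(covars)), covars),
             setNames("child", node))
  scl <- c(table$scale[parents],
           setNames(rep("continuous", length(covars)), covars),
           setNames("continuous", node))
  tab3 <- new_symptom_table(values[, labels, drop = FALSE], labels, comms,
                            scl, seed = table$seed)
  cm <- corr_matrix_of(tab3, resolve_corr_method(config, tab3))
  net <- select_ggm(cm, start = config$start, sig_alpha = config$sig_alpha,
                    max_sweeps = config$max_sweeps, communities = comms)
  cent <- centrality_table(net, top_prop = config$top_prop)
  edges <- network_edges(net)
  child_edges <- edges[edges$node1 == node | edges$node2 == node, ,
                       drop = FALSE]
  out <- list(network = net, centrality = cent, factor = fac,
              child_edges = child_edges)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$outdir, f)
    write_stamped_csv(edges, fp("edges2.csv"), config)
    write_network_json(net, fp("network2.json"), config)
    write_stamped_csv(cent, fp("centrality2.csv"), config)
    write_stamped_json(list(loadings = as.list(fac$loadings),
                            uniquenesses = as.list(fac$uniquenesses),
                            kmo = fac$kmo, alpha = fac$alpha,
                            wave_correlations = fac$wave_correlations,
                            n_used = fac$n_used),
                       fp("factor.json"), config)
    scores_df <- data.frame(family = which(keep_rows), score = fac$scores)
    names(scores_df)[2] <- node
    write_stamped_csv(scores_df, fp("factor_scores.csv"), config)
  }
  out
}

#' Force-directed layout coordinates
#'
#' Fruchterman-Reingold coordinates with attraction proportional to the
#' absolute edge weight, so the strongest connections sit together;
#' deterministic given the seed and normalized to the unit bounding box.
#' An empty network falls back to evenly spaced points on a circle.
#'
#' @param net A `ggm_network`.
#' @param iterations Layout iterations. Default 500.
#' @param seed Integer seed.
#' @return data.frame: node, x, y.
#' @export
layout_coordinates <- function(net, iterations = 500L, seed = 42L) {
  stopifnot(inherits(net, "ggm_network"))
  p <- length(net$labels)
  if (net$n_edges == 0) {
    theta <- 2 * pi * (seq_len(p) - 1) / p
    xy <- cbind(cos(theta), sin(theta))
  } else {
    g <- igraph::graph_from_adjacency_matrix(abs(net$weights),
                                             mode = "undirected",
                                             weighted = TRUE)
    set.seed(as.integer(seed))
    xy <- igraph::layout_with_fr(g, niter = as.integer(iterations),
                                 weights = igraph::E(g)$weight)
  }
  norm01 <- function(v) {
    rng <- range(v)
    if (diff(rng) < 1e-12) rep(0.5, length(v)) else (v - rng[1]) / diff(rng)
  }
  data.frame(node = net$labels, x = norm01(xy[, 1]), y = norm01(xy[, 2]),
             stringsAsFactors = FALSE)
}
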