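# Thresholded Spearman co-occurrence networks over taxon abundances and their
# topology metrics (node/edge counts, positive-edge ratio, degree, density,
# clustering, modularity, diameter, path length, components).

#' Configuration for co-occurrence network construction
#'
#' Defaults follow common practice for genus-level co-occurrence analysis:
#' taxa with relative abundance above 0.01% (`1e-4` as a fraction), edges for
#' pairs with `|r| > 0.7` and `p < 0.05`. No multiple-testing correction is
#' applied by default; Benjamini-Hochberg is available by flag.
#'
#' @param min_abundance abundance filter cutoff as a fraction (default
#'   `1e-4`, i.e. 0.01%); taxa must exceed it strictly.
#' @param r_threshold absolute Spearman correlation threshold (edges require
#'   `|r| >` this value).
#' @param p_threshold significance threshold (edges require `p <` this value).
#' @param p_adjust `"none"` or `"BH"`.
#' @param filter_stat statistic compared against `min_abundance`: `"mean"`
#'   (default) or `"max"` relative abundance across samples.
#' @return Object of class `"network_config"`.
#' @export
network_config <- function(min_abundance = 1e-4, r_threshold = 0.7,
                           p_threshold = 0.05, p_adjust = c("none", "BH"),
                           filter_stat = c("mean", "max")) {
  stopifnot(min_abundance >= 0, r_threshold >= 0, r_threshold <= 1,
            p_threshold > 0, p_threshold <= 1)
  structure(list(min_abundance = min_abundance, r_threshold = r_threshold,
                 p_threshold = p_threshold, p_adjust = match.arg(p_adjust),
                 filter_stat = match.arg(filter_stat)),
            class = "network_config")
}

as_abundance_matrix <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("abundance table must be numeric", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- sprintf("taxon_%02d", seq_len(ncol(m)))
  m
}

#' Filter taxa by relative abundance
#'
#' Retains taxa whose filter statistic (mean or max relative abundance across
#' samples) strictly exceeds the cutoff.
#'
#' @param x samples x taxa abundance matrix or data frame.
#' @param config a [network_config()].
#' @return The filtered matrix; zero columns (with a warning) if every taxon
#'   falls below the cutoff.
#' @export
filter_taxa <- function(x, config = network_config()) {
  m <- as_abundance_matrix(x)
  if (!nrow(m) || !ncol(m)) stop("empty abundance table", call. = FALSE)
  stat <- switch(config$filter_stat,
                 mean = colMeans(m),
                 max = apply(m, 2, max))
  keep <- stat > config$min_abundance
  if (!any(keep)) {
    warning("all taxa fall below the abundance cutoff; empty result")
  }
  m[, keep, drop = FALSE]
}

# Two-sided Spearman p-value: exact permutation enumeration for n <= 10,
# t approximation for larger n. Midranks handle ties.
spearman_pvalue <- function(xr, yr, r) {
  n <- length(xr)
  if (n <= 10) {
    exact_spearman_pvalue(xr, yr)
  } else {
    r <- min(max(r, -1), 1)
    if (abs(r) >= 1) return(0)
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
}

#' Significant Spearman correlation edges between taxa
#'
#' Computes midrank Spearman correlations for every taxon pair of the
#' (already filtered) table and keeps pairs with `|r|` above and p below the
#' configured thresholds. P-values come from exhaustive permutation
#' enumeration for 10 or fewer samples and from the t approximation
#' otherwise; constant taxa are skipped with a warning since their
#' correlation is undefined.
#'
#' @param x samples x taxa abundance matrix (at least 4 samples).
#' @param config a [network_config()].
#' @return Data frame with columns `taxon_a`, `taxon_b`, `r`, `p`,
#'   `p_adjusted` (equal to `p` when no correction is configured) and `sign`.
#' @export
spearman_edges <- function(x, config = network_config()) {
  m <- as_abundance_matrix(x)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 samples for correlation edges", call. = FALSE)
  p_tax <- ncol(m)
  if (p_tax < 2) {
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      r = numeric(0), p = numeric(0), p_adjusted = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE))
  }
  ranks <- apply(m, 2, rank)
  constant <- apply(m, 2, function(v) length(unique(v)) == 1L)
  if (any(constant)) {
    warning(sprintf("skipping constant taxa: %s",
                    paste(colnames(m)[constant], collapse = ", ")))
  }
  rmat <- suppressWarnings(stats::cor(ranks))
  pairs <- which(upper.tri(rmat), arr.ind = TRUE)
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (constant[i] || constant[j]) return(NULL)
    r <- rmat[i, j]
    data.frame(taxon_a = colnames(m)[i], taxon_b = colnames(m)[j], r = r,
               p = spearman_pvalue(ranks[, i], ranks[, j], r),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      r = numeric(0), p = numeric(0), p_adjusted = numeric(0),
                      sign = character(0), stringsAsFactors = FALSE))
  }
  df$p_adjusted <- if (config$p_adjust == "BH") {
    stats::p.adjust(df$p, method = "BH")
  } else df$p
  df <- df[abs(df$r) > config$r_threshold & df$p_adjusted < config$p_threshold, ,
           drop = FALSE]
  df$sign <- ifelse(df$r >= 0, "positive", "negative")
  rownames(df) <- NULL
  df
}

#' Build a thresholded Spearman co-occurrence network
#'
#' Applies the abundance filter, computes significant correlation edges, and
#' assembles the graph. Nodes are the taxa incident to at least one retained
#' edge (the convention of edge-list network tools).
#'
#' @param x samples x taxa abundance matrix.
#' @param config a [network_config()].
#' @return Object of class `"cooccurrence_network"`: list with `graph`
#'   (igraph, edge attributes `r`, `p`, `sign`), `edges`, `taxa` (taxa that
#'   passed the filter) and `config`.
#' @export
build_cooccurrence <- function(x, config = network_config()) {
  m <- filter_taxa(x, config)
  edges <- if (ncol(m) >= 2 && nrow(m) >= 4) spearman_edges(m, config) else
    data.frame(taxon_a = character(0), taxon_b = character(0), r = numeric(0),
               p = numeric(0), p_adjusted = numeric(0), sign = character(0),
               stringsAsFactors = FALSE)
  g <- if (nrow(edges)) {
    igraph::graph_from_data_frame(
      edges[, c("taxon_a", "taxon_b")], directed = FALSE)
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }
  if (nrow(edges)) {
    igraph::E(g)$r <- edges$r
    igraph::E(g)$p <- edges$p
    igraph::E(g)$sign <- edges$sign
  }
  structure(list(graph = g, edges = edges, taxa = colnames(m),
                 config = config),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("<cooccurrence_network> %d nodes, %d edges (|r| > %g, p < %g)\n",
              igraph::vcount(x$graph), nrow(x$edges),
              x$config$r_threshold, x$config$p_threshold))
  invisible(x)
}

#' Topology metrics of a co-occurrence network
#'
#' The metric set reported for microbial co-occurrence networks: node and
#' edge counts, positive-edge ratio, average degree, density, average local
#' clustering coefficient (degree-one nodes count as zero), modularity from
#' deterministic greedy community optimization, number of connected
#' components, and diameter / average path length computed on the largest
#' connected component. An empty network yields zeros with `empty = TRUE`.
#'
#' @param net a `"cooccurrence_network"` (or bare igraph).
#' @return Named list of metrics.
#' @export
topology <- function(net) {
  g <- if (inherits(net, "cooccurrence_network")) net$graph else net
  n <- igraph::vcount(g)
  e <- igraph::ecount(g)
  if (n == 0 || e == 0) {
    return(list(nodes = n, edges = e, positive_edge_ratio = NA_real_,
                average_degree = 0, density = 0,
                clustering_coefficient = 0, modularity = NA_real_,
                components = if (n == 0) 0L else
                  igraph::components(g)$no,
                diameter = 0, average_path_length = 0, empty = TRUE))
  }
  pos_ratio <- if (!is.null(igraph::E(g)$sign)) {
    mean(igraph::E(g)$sign == "positive")
  } else NA_real_
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  comm <- igraph::cluster_fast_greedy(g, weights = NULL)
  list(
    nodes = n,
    edges = e,
    positive_edge_ratio = pos_ratio,
    average_degree = 2 * e / n,
    density = igraph::edge_density(g),
    clustering_coefficient = mean(
      igraph::transitivity(g, type = "localundirected", isolates = "zero")),
    modularity = igraph::modularity(comm),
    components = comp$no,
    diameter = igraph::diameter(giant, weights = NA),
    average_path_length = igraph::mean_distance(giant, weights = NA),
    empty = FALSE
  )
}

#' Export a co-occurrence network
#'
#' @param net a `"cooccurrence_network"`.
#' @param csv,graphml,metrics_json optional output paths for the edge list,
#'   the GraphML graph, and the topology metrics.
#' @return Invisibly, the topology metric list.
#' @export
export_cooccurrence <- function(net, csv = NULL, graphml = NULL,
                                metrics_json = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (!is.null(csv)) utils::write.csv(net$edges, csv, row.names = FALSE)
  if (!is.null(graphml)) igraph::write_graph(net$graph, graphml,
                                             format = "graphml")
  top <- topology(net)
  if (!is.null(metrics_json)) {
    jsonlite::write_json(top, metrics_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(top)
}
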