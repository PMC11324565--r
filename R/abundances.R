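# Synthetic compositional taxon-abundance tables: a log-normal generator with
# planted rank-correlated blocks (Gaussian copula) and multiplicative group
# effects, standing in for 16S-derived genus tables.

#' Specification for a synthetic abundance table
#'
#' Samples are generated per group from taxon-wise log-normal abundances
#' driven by a Gaussian copula: taxa inside a planted block share a latent
#' factor whose loading is chosen so the population Spearman correlation of
#' each within-block pair equals the block's `rho` (the rank correlation of a
#' bivariate normal with Pearson correlation `a` is `6/pi * asin(a/2)`, so
#' `a = 2 sin(pi * rho / 6)`); the log-normal transform is monotone, hence
#' rank-preserving. A block with `sign = -1` splits its taxa into two halves
#' with opposite loadings, realizing negative cross-half correlations.
#'
#' @param n_per_group samples per group.
#' @param groups character vector of group labels (the study layout is four
#'   treatments, e.g. `c("Bla", "HM", "HA", "AQDS")`).
#' @param n_taxa number of taxa; names are `taxon_01`, ... The default (50)
#'   mirrors the scale of a filtered genus table; with far fewer taxa, or a
#'   much larger `log_mean_sd`, compositional closure itself induces rank
#'   correlation between otherwise independent taxa (the classic
#'   relative-abundance artifact), and the generator no longer approximates
#'   an independence null.
#' @param log_mean_sd sd of taxon log-mean abundances (between-taxon spread).
#' @param log_sigma within-taxon log-normal sd.
#' @param blocks list of planted blocks, each
#'   `list(taxa = <names or indices>, rho = <Spearman in (0,1)>, sign = 1 or -1)`.
#' @param group_effects optional data frame `taxon`, `group`, `multiplier`
#'   of multiplicative abundance shifts.
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @return Object of class `"abundance_spec"`.
#' @export
abundance_spec <- function(n_per_group = 3, groups = c("Bla", "HM", "HA", "AQDS"),
                           n_taxa = 50, log_mean_sd = 1, log_sigma = 1,
                           blocks = list(), group_effects = NULL, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_per_group >= 1, n_taxa >= 2, log_sigma > 0)
  taxa <- sprintf("taxon_%02d", seq_len(n_taxa))
  blocks <- lapply(blocks, function(b) {
    if (is.numeric(b$taxa)) {
      if (any(b$taxa < 1 | b$taxa > n_taxa)) {
        stop("block references unknown taxon index", call. = FALSE)
      }
      b$taxa <- taxa[b$taxa]
    }
    if (!all(b$taxa %in% taxa)) {
      stop("block references unknown taxon", call. = FALSE)
    }
    if (is.null(b$sign)) b$sign <- 1
    if (abs(b$rho) >= 1 || b$rho <= 0) {
      stop("block strength rho must lie in (0, 1)", call. = FALSE)
    }
    b
  })
  all_block_taxa <- unlist(lapply(blocks, `[[`, "taxa"))
  if (anyDuplicated(all_block_taxa)) {
    stop("a taxon may belong to at most one block", call. = FALSE)
  }
  if (!is.null(group_effects)) {
    stopifnot(all(c("taxon", "group", "multiplier") %in% names(group_effects)))
    if (!all(group_effects$group %in% groups) ||
        !all(group_effects$taxon %in% taxa)) {
      stop("group effect references unknown taxon or group", call. = FALSE)
    }
  }
  structure(list(n_per_group = n_per_group, groups = groups, n_taxa = n_taxa,
                 taxa = taxa, log_mean_sd = log_mean_sd,
                 log_sigma = log_sigma, blocks = blocks,
                 group_effects = group_effects, seed = as.integer(seed)),
            class = "abundance_spec")
}

#' Simulate a relative-abundance table
#'
#' @param spec an [abundance_spec()].
#' @return A samples x taxa matrix of relative abundances (rows sum to 1),
#'   with sample names `<group>_<replicate>` and attributes `groups` (sample
#'   group labels) and `spec`.
#' @examples
#' sp <- abundance_spec(n_per_group = 6, groups = c("A", "B"), n_taxa = 10,
#'                      blocks = list(list(taxa = 1:3, rho = 0.9)), seed = 1)
#' tab <- simulate_abundances(sp)
#' rowSums(tab)
#' @export
simulate_abundances <- function(spec) {
  stopifnot(inherits(spec, "abundance_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_group * length(spec$groups)
  p <- spec$n_taxa
  mu <- stats::rnorm(p, 0, spec$log_mean_sd)
  z <- matrix(stats::rnorm(n * p), n, p)
  colnames(z) <- spec$taxa
  for (b in spec$blocks) {
    a <- 2 * sin(pi * b$rho / 6)
    f <- stats::rnorm(n)
    k <- length(b$taxa)
    sgn <- if (b$sign < 0) rep(c(1, -1), c(ceiling(k / 2), floor(k / 2))) else
      rep(1, k)
    for (i in seq_len(k)) {
      tx <- b$taxa[i]
      z[, tx] <- sgn[i] * sqrt(a) * f + sqrt(1 - a) * z[, tx]
    }
  }
  ab <- exp(sweep(z * spec$log_sigma, 2, mu, "+"))
  grp <- rep(spec$groups, each = spec$n_per_group)
  if (!is.null(spec$group_effects)) {
    for (i in seq_len(nrow(spec$group_effects))) {
      ge <- spec$group_effects[i, ]
      ab[grp == ge$group, ge$taxon] <- ab[grp == ge$group, ge$taxon] * ge$multiplier
    }
  }
  ab <- ab / rowSums(ab)
  rownames(ab) <- paste0(grp, "_", sequence(rep(spec$n_per_group,
                                                length(spec$groups))))
  attr(ab, "groups") <- grp
  attr(ab, "spec") <- spec
  ab
}

#' Write an abundance table as samples x taxa CSV
#'
#' @param table matrix from [simulate_abundances()] (or compatible).
#' @param path output CSV path.
#' @export
write_abundance_csv <- function(table, path) {
  df <- data.frame(sample = rownames(table), as.data.frame(unclass(table)[, ,
                   drop = FALSE]), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Read a samples x taxa abundance CSV
#'
#' @param path CSV with a `sample` column followed by taxon columns.
#' @return Numeric matrix with sample rownames.
#' @export
read_abundance_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, setdiff(names(df), "sample"), drop = FALSE])
  rownames(m) <- df$sample
  m
}
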