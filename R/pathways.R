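# Single-chlorine-removal reaction network over the 209 congeners:
# parent -> product edges annotated with position class, flanking context and
# the attacked ring's chlorophenyl group; reachability and rule-based
# dechlorination-process (N, H/H') classification.

POSITION_CLASSES <- c("ortho", "meta", "para")

position_class <- function(pos) {
  ifelse(pos == 4L, "para", ifelse(pos %in% c(3L, 5L), "meta", "ortho"))
}

# Flanking context of a chlorine: neighbors are ring-adjacent positions along
# the path 2-3-4-5-6; the ring-bond position 1 never flanks.
flanking_context <- function(ring, pos) {
  nb <- intersect(c(pos - 1L, pos + 1L), 2:6)
  n <- sum(nb %in% ring)
  c("unflanked", "singly-flanked", "doubly-flanked")[n + 1L]
}

# Chlorophenyl group of the attacked ring in canonical orientation (the flip
# with the lexicographically smaller digit string), together with the removed
# position mapped through the same flip.
ring_group <- function(ring, pos) {
  s1 <- ring_string(sort(ring))
  s2 <- ring_string(flip_ring(ring))
  if (s2 < s1) {
    list(group = s2, position = 8L - pos)
  } else if (s1 < s2) {
    list(group = s1, position = pos)
  } else {
    list(group = s1, position = min(pos, 8L - pos))
  }
}

#' All single-chlorine-removal reactions of a congener
#'
#' Removes each chlorine in turn, canonicalizes the product, and aggregates
#' symmetry-equivalent removals: one row per distinct (product, position
#' class) pair with its `multiplicity` (number of equivalent removable
#' chlorines). Each row carries the removed position class, the flanking
#' context of the removed chlorine, and the attacked ring's chlorophenyl
#' group rendered as ascending digits (e.g. `"2345"`).
#'
#' @param x a congener identifier (see [parse_congener()]) or `"congener"`.
#' @return Data frame with columns `parent_bz`, `product_bz` (0 = biphenyl),
#'   `position`, `group`, `group_position`, `flanking`, `multiplicity`.
#' @examples
#' single_dechlor_products("PCB180")
#' @export
single_dechlor_products <- function(x) {
  cg <- as_congener(x)
  parent_bz <- if (cg$n_cl == 0L) 0L else
    unname(congener_env()$key2bz[[congener_key(cg)]])
  if (cg$n_cl == 0L) {
    return(data.frame(parent_bz = integer(0), product_bz = integer(0),
                      position = character(0), group = character(0),
                      group_position = integer(0), flanking = character(0),
                      multiplicity = integer(0), stringsAsFactors = FALSE))
  }
  rows <- list()
  for (ring_id in c("A", "B")) {
    ring <- if (ring_id == "A") cg$ringA else cg$ringB
    other <- if (ring_id == "A") cg$ringB else cg$ringA
    for (pos in ring) {
      prod <- canonicalize(setdiff(ring, pos), other)
      grp <- ring_group(ring, pos)
      rows[[length(rows) + 1L]] <- data.frame(
        parent_bz = parent_bz,
        product_bz = if (prod$n_cl == 0L) 0L else
          unname(congener_env()$key2bz[[congener_key(prod)]]),
        position = position_class(pos),
        group = grp$group,
        group_position = grp$position,
        flanking = flanking_context(ring, pos),
        multiplicity = 1L, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(multiplicity ~ parent_bz + product_bz + position +
                            group + group_position + flanking,
                          data = df, FUN = sum)
  agg <- agg[order(agg$product_bz, agg$position), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("parent_bz", "product_bz", "position", "group", "group_position",
          "flanking", "multiplicity")]
}

#' Default dechlorination-process rule table
#'
#' Rule-based classification of reactions into named microbial dechlorination
#' processes, each defined by (chlorophenyl group, attacked position) pairs:
#' process N removes flanked meta chlorines from the groups 236, 245, 2345
#' and 2356; process H/H' removes para chlorines from 234, 245 and 2345.
#' The table is plain data and fully overridable (e.g. via a YAML rule file)
#' because group-to-position tables are configuration, not constants.
#'
#' @return Data frame with columns `process`, `group`, `position`.
#' @export
default_process_rules <- function() {
  data.frame(
    process = c(rep("N", 6), rep("H/H'", 3)),
    group = c("236", "245", "2345", "2345", "2356", "2356",
              "234", "245", "2345"),
    position = c(3L, 5L, 3L, 5L, 3L, 5L, 4L, 4L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Read a process-rule table from a YAML file
#'
#' Expected schema: a mapping from process name to a list of
#' `{group: "245", position: 5}` entries.
#'
#' @param path YAML file path.
#' @return Data frame in the format of [default_process_rules()].
#' @export
read_process_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(names(raw), function(pn) {
    do.call(rbind, lapply(raw[[pn]], function(e) {
      data.frame(process = pn, group = as.character(e$group),
                 position = as.integer(e$position), stringsAsFactors = FALSE)
    }))
  })
  validate_process_rules(do.call(rbind, rows))
}

validate_process_rules <- function(rules) {
  need <- c("process", "group", "position")
  if (!is.data.frame(rules) || !all(need %in% names(rules))) {
    stop("process rules need columns process, group, position", call. = FALSE)
  }
  ok <- mapply(function(g, p) {
    grepl("^[2-6]+$", g) && p %in% as.integer(strsplit(g, "")[[1]])
  }, rules$group, rules$position)
  if (!all(ok)) {
    stop("malformed process rule: attacked position must be substituted in the group",
         call. = FALSE)
  }
  rules
}

#' Classify a dechlorination reaction against process rules
#'
#' A reaction matches a rule when its attacked ring's chlorophenyl group and
#' removed position (both in the canonical orientation used by
#' [single_dechlor_products()]) equal the rule's pair.
#'
#' @param group chlorophenyl group string of the attacked ring (e.g. `"245"`).
#' @param position removed position (2-6) in the group's orientation.
#' @param rules rule table as from [default_process_rules()].
#' @return Character vector of matching process names (empty = unclassified).
#' @examples
#' classify_process("245", 5)  # flanked meta removal -> "N"
#' classify_process("234", 4)  # para removal -> "H/H'"
#' @export
classify_process <- function(group, position, rules = default_process_rules()) {
  rules <- validate_process_rules(rules)
  unique(rules$process[rules$group == group & rules$position == position])
}

#' Build the single-removal dechlorination reaction network
#'
#' Directed edges between congeners for every single-chlorine removal whose
#' position class is allowed. The network is a DAG (every edge drops the
#' chlorine count by exactly one) with deterministic node and edge order;
#' biphenyl (node `"0"`) has out-degree zero.
#'
#' @param allowed character subset of `c("ortho", "meta", "para")`.
#' @param rules process-rule table used to annotate edges; `NULL` to skip.
#' @return Object of class `"dechlor_network"`: list with `graph` (igraph),
#'   `edges` (data frame as in [single_dechlor_products()] plus `processes`),
#'   and `allowed`.
#' @export
build_network <- function(allowed = c("ortho", "meta", "para"),
                          rules = default_process_rules()) {
  allowed <- match.arg(allowed, POSITION_CLASSES, several.ok = TRUE)
  env <- congener_env()
  if (is.null(env$all_reactions)) {
    env$all_reactions <- do.call(rbind, lapply(1:209, single_dechlor_products))
  }
  edges <- env$all_reactions[env$all_reactions$position %in% allowed, ,
                             drop = FALSE]
  rownames(edges) <- NULL
  if (!is.null(rules)) {
    edges$processes <- vapply(seq_len(nrow(edges)), function(i) {
      paste(classify_process(edges$group[i], edges$group_position[i], rules),
            collapse = ";")
    }, character(1))
  } else {
    edges$processes <- ""
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$parent_bz),
               to = as.character(edges$product_bz),
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = as.character(0:209), stringsAsFactors = FALSE))
  structure(list(graph = g, edges = edges, allowed = allowed),
            class = "dechlor_network")
}

#' @export
print.dechlor_network <- function(x, ...) {
  cat(sprintf("<dechlor_network> positions {%s}: %d reactions over 209 congeners\n",
              paste(x$allowed, collapse = ", "), nrow(x$edges)))
  invisible(x)
}

#' Reachability of target congeners from a parent
#'
#' Breadth-first search over the allowed single-removal edges; reports, per
#' target, whether it is reachable and the shortest witness path.
#'
#' @param parent congener identifier.
#' @param targets vector of congener identifiers.
#' @param network a `"dechlor_network"`, or `NULL` to build one from
#'   `allowed`.
#' @param allowed position classes used when `network` is `NULL`.
#' @return Data frame with columns `parent`, `target`, `reachable`,
#'   `path_length` (number of removal steps, `NA` if unreachable) and `path`
#'   (BZ numbers joined by `" -> "`).
#' @examples
#' reachable("PCB153", "PCB47", allowed = "meta")
#' @export
reachable <- function(parent, targets, network = NULL,
                      allowed = c("meta", "para")) {
  if (is.null(network)) network <- build_network(allowed)
  stopifnot(inherits(network, "dechlor_network"))
  p <- as.character(parse_congener(parent))
  t_bz <- parse_congener(targets)
  sp <- suppressWarnings(
    igraph::shortest_paths(network$graph, from = p,
                           to = as.character(t_bz), mode = "out"))
  rows <- lapply(seq_along(t_bz), function(i) {
    path <- as.integer(names(sp$vpath[[i]]))
    ok <- length(path) > 0
    data.frame(parent = as.integer(p), target = t_bz[i], reachable = ok,
               path_length = if (ok) length(path) - 1L else NA_integer_,
               path = if (ok) paste(path, collapse = " -> ") else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a reaction network
#'
#' Writes an edge-list CSV (`parent_bz`, `product_bz`, `position`, `group`,
#' `processes`, ...) and optionally GraphML.
#'
#' @param network a `"dechlor_network"`.
#' @param csv,graphml output paths (`NULL` to skip either).
#' @return Invisibly, the edge data frame.
#' @export
export_network <- function(network, csv = NULL, graphml = NULL) {
  stopifnot(inherits(network, "dechlor_network"))
  if (!is.null(csv)) utils::write.csv(network$edges, csv, row.names = FALSE)
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(network$edges$parent_bz),
                 to = as.character(network$edges$product_bz)),
      directed = TRUE)
    igraph::E(g)$position <- network$edges$position
    igraph::E(g)$group <- network$edges$group
    igraph::E(g)$processes <- network$edges$processes
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(network$edges)
}
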