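# Independent oracles used across the suite. They share no code with the
# package internals: substitution patterns are 10-bit vectors and symmetry
# images are computed by explicit index permutations.

# Bit layout: positions 2..6 of ring 1 then 2'..6' of ring 2.
oracle_symmetry_images <- function(bits) {
  flip <- function(v) v[c(5, 4, 3, 2, 1)]          # 2<->6, 3<->5 within a ring
  r1 <- bits[1:5]; r2 <- bits[6:10]
  imgs <- list()
  for (a in list(r1, flip(r1))) {
    for (b in list(r2, flip(r2))) {
      imgs[[length(imgs) + 1]] <- c(a, b)
      imgs[[length(imgs) + 1]] <- c(b, a)
    }
  }
  imgs
}

oracle_canonical_pattern <- function(bits) {
  keys <- vapply(oracle_symmetry_images(bits),
                 function(v) paste(v, collapse = ""), character(1))
  min(keys)
}

# Distinct congeners per chlorine count by brute-force orbit enumeration
# over all 2^10 substitution patterns.
oracle_homolog_counts <- function() {
  seen <- new.env(parent = emptyenv())
  counts <- integer(11)  # 0..10 chlorines
  for (m in 0:1023) {
    bits <- as.integer(intToBits(m)[1:10])
    key <- oracle_canonical_pattern(bits)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      counts[sum(bits) + 1] <- counts[sum(bits) + 1] + 1L
    }
  }
  counts
}

# Brute-force single-removal products: remove each set bit, canonicalize.
oracle_single_removals <- function(bits) {
  out <- character(0)
  for (i in which(bits == 1)) {
    child <- bits
    child[i] <- 0L
    pos <- c(2:6, 2:6)[i]
    cls <- if (pos == 4) "para" else if (pos %in% c(3, 5)) "meta" else "ortho"
    out <- c(out, paste(oracle_canonical_pattern(child), cls, sep = "/"))
  }
  unique(out)
}

oracle_pattern_of_bz <- function(bz) {
  tab <- congener_table()
  ringA <- as.integer(strsplit(tab$ringA[match(bz, tab$bz)], "")[[1]])
  ringB <- as.integer(strsplit(tab$ringB[match(bz, tab$bz)], "")[[1]])
  bits <- integer(10)
  bits[ringA - 1L] <- 1L
  bits[ringB + 4L] <- 1L
  bits
}

# Exhaustive DFS path enumeration over allowed single removals (independent
# of the package's igraph BFS): returns the shortest number of steps from
# parent to target, or NA.
oracle_shortest_steps <- function(parent_bits, target_key, allowed) {
  best <- NA_integer_
  walk <- function(bits, depth) {
    key <- oracle_canonical_pattern(bits)
    if (key == target_key) {
      if (is.na(best) || depth < best) best <<- depth
      return(invisible())
    }
    for (i in which(bits == 1)) {
      pos <- c(2:6, 2:6)[i]
      cls <- if (pos == 4) "para" else if (pos %in% c(3, 5)) "meta" else "ortho"
      if (!(cls %in% allowed)) next
      child <- bits
      child[i] <- 0L
      walk(child, depth + 1L)
    }
  }
  walk(parent_bits, 0L)
  best
}

# All permutations of a vector (for the exhaustive Spearman oracle).
oracle_permutations <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) {
      out[[length(out) + 1]] <- c(v[i], rest)
    }
  }
  out
}

# Exhaustive-permutation two-sided Spearman p-value (R implementation).
oracle_spearman_p <- function(x, y) {
  xr <- rank(x); yr <- rank(y)
  r_obs <- abs(stats::cor(xr, yr))
  rs <- vapply(oracle_permutations(yr),
               function(pp) abs(stats::cor(xr, pp)), numeric(1))
  mean(rs >= r_obs - 1e-12)
}

# Small fixed abundance fixture: 6 samples x 4 taxa with one strongly
# correlated pair, one anti-correlated pair and ties.
fixture_abundance_6x4 <- function() {
  m <- matrix(c(
    0.10, 0.30, 0.25, 0.35,
    0.20, 0.25, 0.20, 0.35,
    0.30, 0.20, 0.15, 0.35,
    0.40, 0.15, 0.15, 0.30,
    0.50, 0.10, 0.10, 0.30,
    0.60, 0.05, 0.05, 0.30), nrow = 6, byrow = TRUE)
  colnames(m) <- c("tax_a", "tax_b", "tax_c", "tax_d")
  rownames(m) <- paste0("s", 1:6)
  m
}
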