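test_that("single-removal products match the brute-force oracle for every congener", {
  for (bz in 1:209) {
    got <- single_dechlor_products(bz)
    # every edge drops the chlorine count by exactly one
    parent_ncl <- congener_table()$n_cl[bz]
    prod_ncl <- ifelse(got$product_bz == 0, 0L,
                       congener_table()$n_cl[match(got$product_bz,
                                                   congener_table()$bz)])
    expect_true(all(prod_ncl == parent_ncl - 1L))
    # distinct (product, class) pairs and total multiplicity agree with the
    # bit-level oracle
    oracle <- oracle_single_removals(oracle_pattern_of_bz(bz))
    expect_equal(nrow(got), length(oracle))
    expect_equal(sum(got$multiplicity), parent_ncl)
  }
})

test_that("worked single-removal examples hold", {
  p1 <- single_dechlor_products(1)
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$product_bz, 0L)
  expect_equal(p1$position, "ortho")
  expect_equal(nrow(single_dechlor_products(209)), 3L)
  p180 <- single_dechlor_products("PCB180")
  expect_true(any(p180$product_bz == 153 & p180$position == "meta"))
})

test_that("the reaction network is a DAG with oracle-matching edge count", {
  net <- build_network()
  expect_true(igraph::is_dag(net$graph))
  # brute-force count of distinct (parent, product, class) triples
  oracle_n <- sum(vapply(1:209, function(bz) {
    length(oracle_single_removals(oracle_pattern_of_bz(bz)))
  }, numeric(1)))
  expect_equal(nrow(net$edges), oracle_n)
  # every chlorinated congener has at least one outgoing reaction
  expect_true(all(1:209 %in% net$edges$parent_bz))
  # biphenyl is terminal
  expect_equal(sum(net$edges$parent_bz == 0), 0L)
  # meta-only restriction: PCB47 carries no meta chlorine
  net_m <- build_network("meta")
  expect_equal(sum(net_m$edges$parent_bz == 47), 0L)
  expect_error(build_network(character(0)))
})

test_that("meta-only reachability reproduces the hexa-to-tetra product routes", {
  net_m <- build_network("meta")
  r1 <- reachable("PCB153", "PCB47", net_m)
  expect_true(r1$reachable)
  expect_equal(r1$path_length, 2L)
  r2 <- reachable("PCB135", "PCB53", net_m)
  expect_true(r2$reachable)
  expect_equal(r2$path_length, 2L)
  # chlorine count only decreases: no route back up
  expect_false(reachable("PCB47", "PCB180", build_network())$reachable)
})

test_that("BFS shortest paths equal exhaustive path enumeration", {
  net_mp <- build_network(c("meta", "para"))
  targets <- c(47L, 49L, 51L, 53L)
  tab <- congener_table()
  target_keys <- vapply(targets, function(t) {
    oracle_canonical_pattern(oracle_pattern_of_bz(t))
  }, character(1))
  parents <- c(101L, 110L, 138L, 149L, 153L, 158L, 174L, 180L, 187L)
  for (p in parents) {
    got <- reachable(p, targets, net_mp)
    bits <- oracle_pattern_of_bz(p)
    for (i in seq_along(targets)) {
      steps <- oracle_shortest_steps(bits, target_keys[i], c("meta", "para"))
      expect_equal(got$reachable[i], !is.na(steps),
                   label = sprintf("parent %d target %d reachable", p, targets[i]))
      if (!is.na(steps)) {
        expect_equal(got$path_length[i], steps,
                     label = sprintf("parent %d target %d steps", p, targets[i]))
      }
    }
  }
})

test_that("meta-only terminal congeners carry no meta chlorines", {
  net_m <- build_network("meta")
  parents <- c(135L, 138L, 149L, 153L, 174L, 180L, 187L)
  tab <- congener_table()
  for (p in parents) {
    desc <- igraph::subcomponent(net_m$graph, as.character(p), mode = "out")
    desc_bz <- as.integer(names(desc))
    terminal <- desc_bz[vapply(desc_bz, function(d) {
      sum(net_m$edges$parent_bz == d) == 0L
    }, logical(1))]
    n_meta <- ifelse(terminal == 0L, 0L, tab$n_meta[match(terminal, tab$bz)])
    expect_true(all(n_meta == 0L))
    # from hexa/hepta Aroclor parents the terminal metabolites are tetra
    # congeners (ortho+para skeletons), matching the observed end products
    expect_true(all(congener_table()$n_cl[match(terminal, tab$bz)] >= 3))
  }
})

test_that("process classification follows the rule table and rejects bad rules", {
  expect_identical(classify_process("245", 5), "N")
  expect_identical(classify_process("2345", 3), "N")
  expect_identical(classify_process("234", 4), "H/H'")
  expect_identical(classify_process("245", 4), "H/H'")
  expect_length(classify_process("2", 2), 0L)         # unflanked ortho
  expect_length(classify_process("236", 2), 0L)
  expect_setequal(classify_process("2345", 4), "H/H'")
  bad <- data.frame(process = "X", group = "234", position = 5)
  expect_error(classify_process("234", 5, rules = bad), "substituted")
  # the attacked ring's group annotation on a known edge
  p153 <- single_dechlor_products("PCB153")
  meta_edge <- p153[p153$position == "meta", ]
  expect_equal(meta_edge$group, "245")
  expect_equal(meta_edge$group_position, 5L)
  net <- build_network(c("meta", "para"))
  e <- net$edges
  expect_true(any(e$parent_bz == 153 & e$processes == "N"))
  expect_true(any(e$parent_bz == 138 & e$position == "para" &
                    grepl("H/H'", e$processes, fixed = TRUE)))
})

test_that("process rules round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "N:",
    "  - {group: '245', position: 5}",
    "  - {group: '236', position: 3}",
    "Hprime:",
    "  - {group: '234', position: 4}"), path)
  rules <- read_process_rules(path)
  expect_equal(nrow(rules), 3L)
  expect_identical(classify_process("234", 4, rules), "Hprime")
})

test_that("network export writes edge CSV and GraphML", {
  net <- build_network("meta")
  csv <- withr::local_tempfile(fileext = ".csv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, csv = csv, graphml = gml)
  edges <- read.csv(csv)
  expect_true(all(c("parent_bz", "product_bz", "position", "group",
                    "processes") %in% names(edges)))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
})
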