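dys_for <- function(triplets) {
  ids <- unique(c(triplets$lncrna_id, triplets$mirna_id, triplets$mrna_id))
  data.frame(
    molecule_id = ids,
    gene_class = ifelse(grepl("^L", ids), "lncRNA",
                        ifelse(grepl("^m", ids), "miRNA", "mRNA")),
    direction = ifelse(grepl("^m", ids), "down", "up"))
}

test_that("a single triplet yields 3 nodes and 3 typed edges", {
  tri <- data.frame(lncrna_id = "L1", mirna_id = "m1", mrna_id = "G1")
  net <- build_network(tri, dys_for(tri))
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(table(net$edges$edge_type),
               table(factor(c("direct", "direct", "coexpression"))))
  # duplicated triplets leave the network unchanged
  net2 <- build_network(rbind(tri, tri), dys_for(tri))
  expect_equal(net2, net)
  expect_error(build_network(tri, dys_for(tri)[-1, ]), "absent")
})

test_that("network counts match set-based oracles on random triplet sets", {
  set.seed(12)
  for (i in 1:20) {
    tri <- unique(data.frame(
      lncrna_id = sample(sprintf("L%d", 1:3), 15, TRUE),
      mirna_id = sample(sprintf("m%d", 1:4), 15, TRUE),
      mrna_id = sample(sprintf("G%d", 1:4), 15, TRUE)))
    net <- build_network(tri, dys_for(tri))
    expect_lte(nrow(net$nodes), 3L * nrow(tri))
    expect_equal(sum(net$edges$edge_type == "coexpression"),
                 nrow(unique(tri[, c("lncrna_id", "mrna_id")])))
    expect_equal(sum(net$edges$edge_type == "direct"),
                 nrow(unique(tri[, c("mirna_id", "lncrna_id")])) +
                   nrow(unique(tri[, c("mirna_id", "mrna_id")])))
  }
})

test_that("network typing invariants are enforced", {
  nodes <- data.frame(id = c("L1", "m1", "G1"),
                      gene_class = c("lncRNA", "miRNA", "mRNA"),
                      direction = c("up", "down", "up"))
  expect_error(cerna_network(nodes, data.frame(
    source = "L1", target = "G1", edge_type = "direct")),
    "exactly one miRNA")
  expect_error(cerna_network(nodes, data.frame(
    source = "m1", target = "G1", edge_type = "coexpression")),
    "lncRNA and mRNA")
  expect_error(cerna_network(nodes, data.frame(
    source = "m1", target = "m1", edge_type = "direct")), "self-loops")
  expect_error(cerna_network(nodes, data.frame(
    source = "m1", target = "G9", edge_type = "direct")), "unknown nodes")
})

test_that("network files round-trip node and edge multisets", {
  tri <- data.frame(lncrna_id = c("L1", "L2"), mirna_id = c("m1", "m1"),
                    mrna_id = c("G1", "G1"))
  net <- build_network(tri, dys_for(tri))
  # edges are undirected: compare as unordered endpoint pairs
  ekey <- function(e) paste(pmin(e$source, e$target),
                            pmax(e$source, e$target), e$edge_type)
  for (fmt in c("graphml", "edge_tsv")) {
    f <- withr::local_tempfile()
    write_network(net, f, format = fmt)
    back <- read_network(f, format = fmt)
    expect_setequal(
      do.call(paste, back$nodes), do.call(paste, net$nodes))
    expect_setequal(ekey(back$edges), ekey(net$edges))
  }
  # SIF keeps topology and edge types only
  f <- withr::local_tempfile()
  write_network(net, f, format = "sif")
  back <- read_network(f, format = "sif")
  expect_setequal(ekey(back$edges), ekey(net$edges))

  empty <- cerna_network(
    data.frame(id = character(0), gene_class = character(0),
               direction = character(0)),
    data.frame(source = character(0), target = character(0),
               edge_type = character(0)))
  f2 <- withr::local_tempfile()
  expect_warning(write_network(empty, f2, format = "edge_tsv"),
                 "zero edges")
  expect_equal(nrow(read_network(f2, format = "edge_tsv")$edges), 0L)
})

test_that("gene-set enrichment equals the brute-force hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  ann <- list(term5 = universe[1:5], all = universe)
  query <- c(universe[1:3], universe[50:56])  # overlap 3 with term5
  res <- enrich_fisher(query, ann, universe)
  # brute-force tail: sum over overlap >= 3 of the hypergeometric pmf
  oracle <- sum(dhyper(3:5, 5, 95, 10))
  expect_equal(res$p_value[res$term == "term5"], oracle, tolerance = 1e-12)
  expect_equal(res$count[res$term == "term5"], 3L)
  expect_equal(res$gene_ratio[res$term == "term5"], 0.3)
  # a term equal to the universe is never enriched
  expect_equal(res$p_value[res$term == "all"], 1)
  # zero overlap gives p = 1
  res0 <- enrich_fisher(universe[90:99], list(t = universe[1:5]), universe)
  expect_equal(res0$p_value, 1)
  expect_error(enrich_fisher(character(0), ann, universe), "empty query")
  expect_error(enrich_fisher("outsider", ann, universe), "outside universe")
})

test_that("enrichment p decreases monotonically in overlap", {
  universe <- sprintf("g%03d", 1:100)
  ann <- list(t = universe[1:10])
  ps <- vapply(1:8, function(k) {
    q <- c(universe[seq_len(k)], universe[51:(60 - k)])
    enrich_fisher(q, ann, universe)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("GMT signatures round-trip", {
  sets <- list(stateA = c("g1", "g2", "g3"), stateB = c("g9", "g2"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
  bad <- withr::local_tempfile()
  writeLines("onlyname\tdesc", bad)
  expect_error(read_gmt(bad), "fewer than 3")
})
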