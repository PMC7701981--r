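toy_domains <- function() {
  data.frame(accession = c("Q00001", "Q00002", "Q00003", "Q00003"),
             family_id = c("FAM1", "FAM1", "FAM2", "FAM3"),
             family_name = c("fam one", "fam one", "fam two", "fam three"),
             start = c(1L, 10L, 1L, 200L),
             end = c(99L, 80L, 150L, 260L), stringsAsFactors = FALSE)
}

test_that("proteins sharing a domain family collapse to one node", {
  net <- toy_protein_network()  # H-X, H-Y with X,Y in FAM1
  dnet <- to_domain_level(net, toy_domains())
  expect_equal(dnet$granularity, "domain")
  expect_setequal(dnet$nodes$id, c("P68431", "FAM1"))
  expect_equal(nrow(dnet$edges), 1L)
  # evidence union from both protein edges
  expect_length(dnet$evidence[[1]], 2L)
  expect_equal(dnet$nodes$members[dnet$nodes$id == "FAM1"],
               "Q00001;Q00002")
  expect_equal(nrow(validate_network(dnet)), 0L)
})

test_that("unannotated partners become singleton pseudo-families", {
  net <- toy_protein_network()
  empty <- toy_domains()[0, ]
  expect_warning(dnet <- to_domain_level(net, empty), "singleton")
  # grouping is the identity: same counts as the protein network
  expect_equal(nrow(dnet$nodes), nrow(net$nodes))
  expect_equal(nrow(dnet$edges), nrow(net$edges))
  expect_setequal(dnet$nodes$id, net$nodes$id)
})

test_that("interface residues select the interacting family", {
  nodes <- data.frame(id = c("P68431", "Q00003"),
                      is_histone = c(TRUE, FALSE))
  edges <- data.frame(node_a = "P68431", node_b = "Q00003")
  edges$evidence <- I(list(list(evidence_item("structural", "S1"))))
  net <- interaction_network(nodes, edges, "protein")
  # Q00003 has FAM2 (1-150) and FAM3 (200-260); interface at 210 picks FAM3
  hint_nodes <- data.frame(id = c("P68431:5", "Q00003:210"),
                           accession = c("P68431", "Q00003"),
                           position = c(5L, 210L),
                           is_histone = c(TRUE, FALSE))
  hint <- interaction_network(hint_nodes, NULL, "residue")
  dnet <- to_domain_level(net, toy_domains(), interface_hint = hint)
  expect_true("FAM3" %in% dnet$nodes$id)
  expect_false("FAM2" %in% dnet$nodes$id)
  # without the hint, collapse mode takes the first annotated family
  dnet2 <- to_domain_level(net, toy_domains())
  expect_true("FAM2" %in% dnet2$nodes$id)
  # expand mode maps the partner to both of its families
  dnet3 <- to_domain_level(net, toy_domains(), multi_family = "expand")
  expect_setequal(setdiff(dnet3$nodes$id, "P68431"), c("FAM2", "FAM3"))
})

test_that("domain collapse never increases the edge count", {
  domains <- toy_domains()
  for (seed in 1:20) {
    net <- random_toy_network(seed, n_partners = 8)
    # annotate a random half of the partners into two families
    partners <- net$nodes$id[!net$nodes$is_histone]
    ann <- partners[seq_along(partners) %% 2 == 0]
    dom <- data.frame(accession = ann,
                      family_id = rep(c("FAMA", "FAMB"),
                                      length.out = length(ann)),
                      family_name = "fam", start = 1L, end = 100L,
                      stringsAsFactors = FALSE)
    dnet <- suppressWarnings(to_domain_level(net, dom))
    expect_lte(nrow(dnet$edges), nrow(net$edges))
    expect_equal(nrow(validate_network(dnet)), 0L)
  }
})

test_that("global expansion adds exactly the one-hop neighbour layer", {
  net <- toy_protein_network()
  # empty neighbour table -> unchanged
  expect_true(network_equal(
    net, expand_global(net, data.frame(accession_a = character(),
                                       accession_b = character()))))
  nbr <- data.frame(
    accession_a = c("Q00001", "Q00009", "P68431"),
    accession_b = c("Q00005", "Q00010", "Q00006"),
    stringsAsFactors = FALSE)
  g <- expand_global(net, nbr)
  # (Q00001,Q00005) anchors on partner X; (Q00009,Q00010) touches no core
  # node; (P68431,Q00006) anchors on a histone, not a partner -> ignored
  expect_setequal(setdiff(g$nodes$id, net$nodes$id), "Q00005")
  expect_equal(nrow(g$edges), nrow(net$edges) + 1L)
  added <- g$edges[g$edges$layer == "global", ]
  expect_equal(paste(added$node_a, added$node_b), "Q00001 Q00005")
  # core is untouched and never re-layered
  expect_true(all(net$edges$node_a %in% g$edges$node_a))
  expect_equal(sum(g$edges$layer == "core"), nrow(net$edges))
  expect_equal(nrow(validate_network(g)), 0L)
})

test_that("global expansion is monotone and single-hop on random networks", {
  for (seed in 1:20) {
    net <- random_toy_network(seed)
    partners <- net$nodes$id[!net$nodes$is_histone]
    set.seed(seed + 9000)
    nbr <- data.frame(
      accession_a = sample(partners, 4, replace = TRUE),
      accession_b = sprintf("N%05d", sample.int(99999L, 4)),
      stringsAsFactors = FALSE)
    g <- expand_global(net, nbr)
    expect_gte(nrow(g$nodes), nrow(net$nodes))
    expect_gte(nrow(g$edges), nrow(net$edges))
    # no existing element removed or re-layered
    core_key <- paste(net$edges$node_a, net$edges$node_b)
    g_core <- g$edges[g$edges$layer == "core", ]
    expect_setequal(paste(g_core$node_a, g_core$node_b), core_key)
    # one hop only: added nodes touch a partner of the core
    new_nodes <- setdiff(g$nodes$id, net$nodes$id)
    glob <- g$edges[g$edges$layer == "global", ]
    expect_true(all(glob$node_a %in% c(partners, new_nodes) &
                      glob$node_b %in% c(partners, new_nodes)))
  }
})

test_that("merge unions by accession with evidence deduplication", {
  net <- toy_protein_network()
  # identity element
  expect_true(network_equal(
    merge_networks(list(net, interaction_network(granularity = "protein"))),
    net))
  # idempotence on node/edge sets
  m2 <- merge_networks(list(net, net))
  expect_true(network_equal(m2, net))
  # hand-enumerated union of two overlapping networks
  other_nodes <- data.frame(id = c("P68431", "Q00002", "Q00099"),
                            is_histone = c(TRUE, FALSE, FALSE))
  other_edges <- data.frame(node_a = c("P68431", "P68431"),
                            node_b = c("Q00002", "Q00099"))
  other_edges$evidence <- I(list(list(evidence_item("binary",
                                                    "two-hybrid")),
                                 list(evidence_item("binary",
                                                    "two-hybrid"))))
  other <- interaction_network(other_nodes, other_edges, "protein")
  m <- merge_networks(list(net, other))
  expect_setequal(m$nodes$id, union(net$nodes$id, other$nodes$id))
  expect_equal(nrow(m$nodes), 4L)
  expect_equal(nrow(m$edges), 3L)
  # shared edge H-Y accumulates evidence from both sources
  shared <- which(m$edges$node_b == "Q00002")
  kinds <- vapply(m$evidence[[shared]], `[[`, character(1), "source_kind")
  expect_setequal(kinds, c("crosslink", "binary"))
  # granularity mixing is an error
  res <- interaction_network(data.frame(id = "P68431:1",
                                        accession = "P68431",
                                        position = 1L), NULL, "residue")
  expect_error(merge_networks(list(net, res)), "granularity mismatch")
})

test_that("merge is commutative and associative on identity sets", {
  for (seed in 1:20) {
    a <- random_toy_network(seed, source_kind = "structural")
    b <- random_toy_network(seed + 100, source_kind = "crosslink")
    c_ <- random_toy_network(seed + 200, source_kind = "binary")
    ab <- merge_networks(list(a, b))
    ba <- merge_networks(list(b, a))
    expect_true(network_equal(ab, ba, check_attributes = FALSE))
    abc1 <- merge_networks(list(merge_networks(list(a, b)), c_))
    abc2 <- merge_networks(list(a, merge_networks(list(b, c_))))
    expect_true(network_equal(abc1, abc2, check_attributes = FALSE))
    # subadditivity of node counts, equality iff disjoint accession sets
    expect_lte(nrow(ab$nodes), nrow(a$nodes) + nrow(b$nodes))
    if (length(intersect(a$nodes$id, b$nodes$id)) == 0)
      expect_equal(nrow(ab$nodes), nrow(a$nodes) + nrow(b$nodes))
  }
})

test_that("a merged edge keeps the core layer over global", {
  nodes <- data.frame(id = c("P68431", "Q1"), is_histone = c(TRUE, FALSE))
  mk <- function(layer, kind, id) {
    e <- data.frame(node_a = "P68431", node_b = "Q1", layer = layer)
    e$evidence <- I(list(list(evidence_item(kind, id))))
    interaction_network(nodes, e, "protein")
  }
  m <- merge_networks(list(mk("global", "binary", "b1"),
                           mk("core", "structural", "s1")))
  expect_equal(m$edges$layer, "core")
})

test_that("network statistics count nodes, edges, partners and families", {
  st0 <- network_stats(interaction_network(granularity = "protein"))
  expect_equal(st0$n_nodes, 0L)
  expect_equal(st0$n_edges, 0L)
  expect_equal(st0$n_unique_partners, 0L)

  net <- toy_protein_network()
  st <- network_stats(net, toy_catalog(), toy_domains())
  expect_equal(st$n_nodes, 3L)
  expect_equal(st$n_edges, 2L)
  expect_equal(st$n_unique_partners, 2L)
  expect_equal(st$n_domain_families, 1L)  # X and Y share FAM1
  expect_lte(st$n_unique_partners, st$n_nodes)
})
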