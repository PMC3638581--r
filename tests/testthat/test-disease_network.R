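test_that("seed assembly merges provenance labels", {
  s <- assemble_seeds(known = "TNF", predicted = c("TNF", "IL1B"))
  expect_equal(nrow(s), 2)
  expect_true(s$known[s$gene == "TNF"] && s$predicted[s$gene == "TNF"])
  expect_false(s$drug_target[s$gene == "TNF"])

  s2 <- assemble_seeds(c("A", "B"), c("C", "D", "E"), c("F", "G", "H", "I"))
  expect_equal(nrow(s2), 9)

  s3 <- assemble_seeds(known = "Tnf", predicted = "TNF")
  expect_equal(nrow(s3), 1)
  expect_error(assemble_seeds(), "empty")
})

test_that("one-hop expansion fishes first neighbors only", {
  # star graph, center seeded: whole star, leaves at layer 1
  star <- suppressMessages(load_network(tmp_lines(
    c("HUB\tL1", "HUB\tL2", "HUB\tL3"))))
  dn <- expand_to_disease_network(assemble_seeds(known = "HUB"), star)
  expect_setequal(igraph::V(dn$graph)$name, c("HUB", "L1", "L2", "L3"))
  expect_equal(unname(dn$layer[c("L1", "L2", "L3")]), c(1L, 1L, 1L))
  expect_equal(unname(dn$layer["HUB"]), 0L)

  # seed absent from the network is kept isolated, with a warning
  expect_warning(dn2 <- expand_to_disease_network(
    assemble_seeds(known = "GHOST"), star), "absent")
  expect_setequal(igraph::V(dn2$graph)$name, "GHOST")
  expect_equal(igraph::ecount(dn2$graph), 0)
})

test_that("expansion matches the brute-force adjacency oracle", {
  set.seed(17)
  for (rep in 1:5) {
    nodes <- paste0("N", 1:12)
    edges <- t(replicate(16, sample(nodes, 2)))
    edges <- unique(edges[edges[, 1] != edges[, 2], , drop = FALSE])
    g <- suppressMessages(load_network(tmp_lines(
      paste(edges[, 1], edges[, 2], sep = "\t"))))
    seeds_v <- sample(igraph::V(g)$name, 3)
    dn <- expand_to_disease_network(assemble_seeds(known = seeds_v), g)
    expect_setequal(igraph::V(dn$graph)$name, oracle_one_hop(seeds_v, edges))
    # induced edges: every parent edge between kept nodes, nothing else
    kept <- igraph::V(dn$graph)$name
    parent_el <- igraph::as_edgelist(g)
    expected_edges <- parent_el[parent_el[, 1] %in% kept &
                                  parent_el[, 2] %in% kept, , drop = FALSE]
    expect_equal(igraph::ecount(dn$graph), nrow(expected_edges))
  }
})

test_that("adding a seed never shrinks the disease network", {
  g <- qly_fixture()$ppi
  s1 <- assemble_seeds(known = c("TNF", "IL1B"))
  s2 <- assemble_seeds(known = c("TNF", "IL1B"), predicted = "KDR")
  n1 <- igraph::V(expand_to_disease_network(s1, g)$graph)$name
  n2 <- igraph::V(expand_to_disease_network(s2, g)$graph)$name
  expect_true(all(n1 %in% n2))
})

test_that("herb targets map into the disease network with contributors", {
  fx <- qly_fixture()
  seeds <- assemble_seeds(fx$seeds$known, fx$seeds$predicted,
                          fx$seeds$drug_target)
  dn <- suppressWarnings(expand_to_disease_network(seeds, fx$ppi))

  hb <- fx$minor_targets[fx$minor_targets$herb == "Huang-Bai", ]
  hb_profiles <- c(
    lapply(split(hb$gene, hb$ingredient), function(g)
      structure(list(ingredient_id = "x", genes = g, scores = rep(1, length(g)),
                     degenerate = rep(FALSE, length(g)), k = length(g)),
                class = "target_profile")),
    list(Berberine = structure(list(ingredient_id = "Berberine",
                                    genes = fx$major_targets$Berberine,
                                    scores = 1, degenerate = FALSE, k = 1),
                               class = "target_profile")))
  hn <- map_herb_targets(hb_profiles, dn, herb = "Huang-Bai")
  expect_true(all(c("KDR", "PTGS1") %in% hn$mapped_targets))
  expect_true("Berberine" %in% hn$contributors[["KDR"]])

  # profiles entirely outside the disease network give an empty mapping
  out_prof <- list(x = structure(list(ingredient_id = "x", genes = "NOPE",
                                      scores = 1, degenerate = FALSE, k = 1),
                                 class = "target_profile"))
  expect_warning(hn0 <- map_herb_targets(out_prof, dn, herb = "H"), "no targets")
  expect_length(hn0$mapped_targets, 0)

  # a profile covering every disease-network node reproduces it
  all_prof <- list(x = structure(list(
    ingredient_id = "x", genes = igraph::V(dn$graph)$name,
    scores = rep(1, igraph::vcount(dn$graph)),
    degenerate = rep(FALSE, igraph::vcount(dn$graph)),
    k = igraph::vcount(dn$graph)), class = "target_profile"))
  hn_all <- map_herb_targets(all_prof, dn, herb = "H")
  expect_setequal(hn_all$mapped_targets, igraph::V(dn$graph)$name)
  expect_equal(igraph::ecount(hn_all$graph), igraph::ecount(dn$graph))
})

test_that("off-target flagging reports counter-acting herbs", {
  fx <- qly_fixture()
  seeds <- assemble_seeds(fx$seeds$known, fx$seeds$predicted,
                          fx$seeds$drug_target)
  dn <- suppressWarnings(expand_to_disease_network(seeds, fx$ppi))
  mk <- function(genes, id) stats::setNames(list(structure(list(
    ingredient_id = id, genes = genes, scores = rep(1, length(genes)),
    degenerate = rep(FALSE, length(genes)), k = length(genes)),
    class = "target_profile")), id)
  ks <- map_herb_targets(mk(c("PTGS1", "IL1R1"), "Xanthohumol"), dn, "Ku-Shen")
  hb <- map_herb_targets(mk(c("PTGS1", "KDR"), "Ferulic acid"), dn, "Huang-Bai")

  ks <- flag_off_targets(ks, fx$adverse_genes, other_herb_nets = list(hb))
  expect_identical(ks$off_target_flags, "PTGS1")
  expect_identical(ks$counteracted_by[["PTGS1"]], "Huang-Bai")

  # empty adverse list: no flags
  ks0 <- flag_off_targets(ks, character(0))
  expect_length(ks0$off_target_flags, 0)

  # adverse gene outside the mapped targets is only logged
  expect_message(ks1 <- flag_off_targets(ks, c("PTGS1", "ZZZ9")), "ZZZ9")
  expect_identical(ks1$off_target_flags, "PTGS1")
})

test_that("bridging adds connectors adjacent to two or more targets", {
  g <- suppressMessages(load_network(tmp_lines(
    c("A\tX", "X\tB", "A\tB2", "X\tC"))))
  dn <- expand_to_disease_network(assemble_seeds(known = c("A", "B", "X")), g)
  prof <- list(p = structure(list(ingredient_id = "p", genes = c("A", "B"),
                                  scores = c(1, 1), degenerate = c(FALSE, FALSE),
                                  k = 2), class = "target_profile"))
  plain <- map_herb_targets(prof, dn, herb = "H")
  expect_equal(igraph::ecount(plain$graph), 0)
  bridged <- map_herb_targets(prof, dn, herb = "H", bridge = TRUE)
  expect_true("X" %in% bridged$bridge_nodes)
  expect_equal(igraph::ecount(bridged$graph), 2)
})
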