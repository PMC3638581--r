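test_that("pathway models parse edges, labels, loops and sinks", {
  p <- tmp_lines(c("A\tB\tP1", "B\tC\tP1", "C\tD\tP2"))
  m <- load_pathway_model(p)
  expect_equal(nrow(m$edges), 3)
  expect_setequal(m$labels, c("P1", "P2"))
  expect_identical(m$sinks, "D")  # default: zero out-degree

  # loop over an absent node errors naming it
  p2 <- tmp_lines(c("@loop\tA\tZMISSING", "A\tB\tP1"))
  expect_error(load_pathway_model(p2), "ZMISSING")
  # unlabeled edges are rejected
  expect_error(load_pathway_model(tmp_lines(c("A\tB"))), "exactly")

  fx <- qly_fixture()
  pm <- fx$pathway_model
  expect_setequal(pm$labels, c("IL1B", "NFKB", "TNF", "VEGFA"))
  expect_length(pm$loops, 1)
  expect_setequal(pm$loops[[1]], c("NFKB1", "NFKB2", "RELA", "RELB"))
  expect_identical(pm$sinks, "PTGS2")
})

test_that("a linear one-label pathway yields exactly one same_pathway record", {
  m <- pathway_model(data.frame(from = c("A", "B"), to = c("B", "C"),
                                pathway = "P1"))
  rec <- detect_mechanisms("A", "B", m)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$kind, "same_pathway")
  expect_equal(rec$via, "P1")
  # identical single target: no mechanism (targets must be distinct)
  expect_equal(nrow(detect_mechanisms("A", "A", m)), 0)
  # no model hit at all warns and returns no records
  expect_warning(none <- detect_mechanisms("X9", "Y9", m), "neither")
  expect_equal(nrow(none), 0)
})

test_that("mechanism detection is symmetric and monotone", {
  fx <- qly_fixture()
  pm <- fx$pathway_model
  a <- fx$major_targets$Kurarinone
  b <- fx$major_targets$Diosgenin
  r_ab <- detect_mechanisms(a, b, pm, "K", "D")
  r_ba <- detect_mechanisms(b, a, pm, "D", "K")
  expect_setequal(r_ab$kind, r_ba$kind)
  expect_equal(nrow(r_ab), nrow(r_ba))
  # roles swap exactly
  swapped <- data.frame(kind = r_ba$kind, a_target = r_ba$b_target,
                        b_target = r_ba$a_target)
  expect_setequal(paste(r_ab$kind, r_ab$a_target, r_ab$b_target),
                  paste(swapped$kind, swapped$a_target, swapped$b_target))

  # enlarging a target set never removes a detected mechanism
  r_big <- detect_mechanisms(c(a, "IL1R1"), b, pm, "K", "D")
  expect_true(all(paste(r_ab$kind, r_ab$via) %in% paste(r_big$kind, r_big$via)))
})

test_that("the worked example flags exactly the six reported pairs", {
  fx <- qly_fixture()
  expect_length(fx$major_targets, 5)
  net <- build_synergy_network(fx$major_targets, fx$pathway_model)
  expect_equal(nrow(net$edges), 6)
  pairs <- apply(net$edges[, c("a", "b")], 1, function(x)
    paste(sort(x), collapse = "--"))
  expect_setequal(pairs, c("Matrine--Sinomenine", "Kurarinone--Matrine",
                           "Berberine--Matrine", "Kurarinone--Sinomenine",
                           "Berberine--Kurarinone", "Diosgenin--Kurarinone"))
  # feedback + compensation pairs carry more weight than single-mechanism ones
  kd <- net$edges$weight[pairs == "Diosgenin--Kurarinone"]
  expect_true(all(kd > net$edges$weight[pairs != "Diosgenin--Kurarinone"]))
  expect_setequal(strsplit(net$edges$kinds[pairs == "Diosgenin--Kurarinone"],
                           ",")[[1]],
                  c("compensation", "feedback_loop"))
})

test_that("ingredients with pathway-unconnected targets form no edges", {
  m <- pathway_model(data.frame(from = c("A", "C"), to = c("B", "D"),
                                pathway = c("P1", "P2")))
  net <- build_synergy_network(list(i1 = "B", i2 = "D"), m)
  expect_equal(nrow(net$edges), 0)
  expect_error(build_synergy_network(list(i1 = "A"), m), "at least 2")
})

test_that("mechanism kinds match exhaustive triple enumeration", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(5:10, 1)
    nodes <- paste0("V", seq_len(n))
    ne <- sample(6:14, 1)
    edges <- data.frame(from = sample(nodes, ne, replace = TRUE),
                        to = sample(nodes, ne, replace = TRUE),
                        pathway = sample(c("P1", "P2", "P3"), ne, replace = TRUE),
                        stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    edges <- edges[!duplicated(edges), , drop = FALSE]
    if (nrow(edges) < 4) next
    model_nodes <- unique(c(edges$from, edges$to))
    loops <- if (length(model_nodes) >= 3 && runif(1) < 0.7)
      list(sample(model_nodes, sample(2:3, 1))) else list()
    m <- pathway_model(edges, loops = loops)
    a <- sample(model_nodes, sample(1:3, 1))
    b <- sample(model_nodes, sample(1:3, 1))
    got <- sort(unique(suppressWarnings(detect_mechanisms(a, b, m))$kind))
    want <- sort(oracle_mechanisms(a, b, edges, loops))
    expect_identical(got, want,
                     label = sprintf("rep %d kinds [%s]", rep,
                                     paste(got, collapse = ",")),
                     expected.label = paste(want, collapse = ","))
  }
})
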