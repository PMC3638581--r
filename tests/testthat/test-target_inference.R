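test_that("concordance score is the Pearson correlation with degeneracy flag", {
  sim <- c(a = 0.1, b = 0.5, c = 0.9, d = 0.3)
  expect_equal(as.numeric(concordance_score(sim, 2 * sim + 1)), 1)
  expect_equal(as.numeric(concordance_score(sim, -sim)), -1)
  clo <- c(a = 0.2, b = 0.4, c = 1.1, d = 0.2)
  expect_equal(as.numeric(concordance_score(sim, clo)),
               oracle_pearson(sim, clo), tolerance = 1e-12)
  expect_false(attr(concordance_score(sim, clo), "degenerate"))

  s <- concordance_score(sim, c(a = 1, b = 1, c = 1, d = 1))
  expect_identical(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))

  expect_error(concordance_score(sim, clo[1:3]), "mismatch")
  expect_error(concordance_score(sim[1:2], clo[1:2]), "at least 3")
  expect_error(concordance_score(sim, clo[c(2, 1, 3, 4)]), "ordering")
})

test_that("concordance is invariant to positive affine transforms", {
  set.seed(5)
  for (i in 1:20) {
    x <- runif(8)
    y <- runif(8)
    base <- as.numeric(concordance_score(x, y))
    expect_equal(as.numeric(concordance_score(2.5 * x + 3, y)), base,
                 tolerance = 1e-12)
    expect_equal(as.numeric(concordance_score(x, 0.1 * y + 7)), base,
                 tolerance = 1e-12)
  }
})

# A hand-built space where structure similarity tracks target modules:
# 5 reference drugs, two structural families (bits 1-8 vs 9-16), two
# disjoint network modules; family-1 drugs target module 1 only.
.toy_space <- function() {
  refs <- toy_compounds(list(
    dA1 = c(1, 2, 3, 4), dA2 = c(1, 2, 3, 5), dA3 = c(1, 2, 4, 5),
    dB1 = c(9, 10, 11, 12), dB2 = c(9, 10, 11, 13)))
  net <- suppressMessages(load_network(tmp_lines(c(
    "M1\tM2", "M2\tM3", "M1\tM3", "M3\tM4",
    "N1\tN2", "N2\tN3", "N1\tN3", "N3\tN4"))))
  rt <- list(dA1 = c("M1", "M2"), dA2 = c("M2", "M3"), dA3 = c("M1", "M3"),
             dB1 = c("N1", "N2"), dB2 = c("N2", "N3"))
  list(refs = refs, net = net, rt = rt)
}

test_that("a query matching a reference family recovers that family's module", {
  sp <- .toy_space()
  q <- toy_compounds(list(q = c(1, 2, 3, 4)))  # identical to dA1
  r <- rank_targets(q, sp$refs, sp$rt, sp$net)
  expect_equal(nrow(r), 8)
  top4 <- r$gene[1:4]
  expect_setequal(top4, c("M1", "M2", "M3", "M4"))
  expect_true(all(c("N1", "N2", "N3", "N4") %in% r$gene[5:8]))
})

test_that("ranking is deterministic and order-independent", {
  sp <- .toy_space()
  q <- toy_compounds(list(q = c(9, 10, 11, 12)))
  r1 <- rank_targets(q, sp$refs, sp$rt, sp$net)
  r2 <- rank_targets(q, sp$refs, sp$rt, sp$net,
                     gene_universe = rev(igraph::V(sp$net)$name))
  expect_identical(r1, r2)
  # single-gene universe
  r3 <- rank_targets(q, sp$refs, sp$rt, sp$net, gene_universe = "M1")
  expect_equal(nrow(r3), 1)
  expect_identical(r3$gene, "M1")
  # too few references
  expect_error(rank_targets(q, sp$refs[1:2], sp$rt[1:2], sp$net), "at least 3")
})

test_that("degenerate genes rank after all scored genes", {
  sp <- .toy_space()
  net2 <- suppressMessages(load_network(tmp_lines(c(
    "M1\tM2", "M2\tM3", "M1\tM3", "M3\tM4",
    "N1\tN2", "N2\tN3", "N1\tN3", "N3\tN4", "ZZ\tYY"))))
  q <- toy_compounds(list(q = c(1, 2, 3, 4)))
  r <- rank_targets(q, sp$refs, sp$rt, net2)
  # ZZ/YY are disconnected from every target: zero-variance closeness
  expect_true(all(which(r$degenerate) > max(which(!r$degenerate))))
  expect_true(all(r$score[r$degenerate] == 0))
})

test_that("top-k truncation respects k and the universe floor", {
  sp <- .toy_space()
  q <- toy_compounds(list(q = c(1, 2, 3, 4)))
  r <- rank_targets(q, sp$refs, sp$rt, sp$net)
  expect_length(top_k_profile(r, k = 3, "q")$genes, 3)
  expect_length(top_k_profile(r, k = 100, "q")$genes, 8)  # universe floor
  p1 <- top_k_profile(r, k = 1, "q")
  expect_identical(p1$genes, r$gene[1])
  expect_error(top_k_profile(r, k = 0), "positive")
})

test_that("formula profiles are shared-space consistent", {
  sp <- .toy_space()
  ing <- toy_compounds(list(i1 = c(1, 2, 3, 4), i2 = c(1, 2, 3, 4),
                            i3 = c(9, 10, 11, 12)),
                       herbs = c("H1", "H1", "H2"))
  profs <- formula_profiles(ing, sp$refs, sp$rt, sp$net, k = 4)
  expect_named(profs, c("i1", "i2", "i3"))
  # identical structures give identical profiles
  expect_identical(profs$i1$genes, profs$i2$genes)
  expect_identical(profs$i1$scores, profs$i2$scores)
  # matches the single-query path
  single <- top_k_profile(rank_targets(ing[1], sp$refs, sp$rt, sp$net),
                          k = 4, "i1")
  expect_identical(profs$i1$genes, single$genes)

  it <- integrative_targets(profs)
  expect_true(all(c("gene", "herbs", "ingredients") %in% names(it)))
  expect_true(all(it$gene[it$n_ingredients == 2] %in% profs$i1$genes))

  empty <- compound_set(character(0),
                        matrix(integer(0), 0, 16), herbs = character(0))
  expect_warning(p0 <- formula_profiles(empty, sp$refs, sp$rt, sp$net),
                 "empty ingredient")
  expect_length(p0, 0)
})

test_that("planted targets are recovered above the random baseline", {
  space <- generate_space(seed = 42)
  q <- generate_query(space, 3)
  r <- rank_targets(q$fingerprint, space$reference_drugs,
                    space$reference_targets, space$ppi)
  prof <- top_k_profile(r, k = 100, q$id)
  hits <- sum(prof$genes %in% q$planted_targets)
  baseline <- 100 * length(q$planted_targets) / igraph::vcount(space$ppi)
  expect_gt(hits, baseline)
})
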