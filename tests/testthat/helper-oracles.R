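# Independent brute-force oracles used to validate the package's
# implementations. These deliberately avoid igraph/stats shortcuts used by
# the code under test.

# Pearson correlation by the direct sum formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# All-pairs shortest paths by Floyd-Warshall on an undirected edge matrix.
oracle_apsp <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# Hypergeometric upper tail P(X >= k) by enumerating overlap values.
oracle_hyper_tail <- function(k, term_size, bg_size, query_size) {
  js <- max(0, query_size - (bg_size - term_size)):min(term_size, query_size)
  mass <- choose(term_size, js) * choose(bg_size - term_size, query_size - js) /
    choose(bg_size, query_size)
  sum(mass[js >= k])
}

# One-hop expansion as an explicit union of seed adjacency.
oracle_one_hop <- function(seeds, edges) {
  nb <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (edges[i, 1] %in% seeds) nb <- c(nb, edges[i, 2])
    if (edges[i, 2] %in% seeds) nb <- c(nb, edges[i, 1])
  }
  sort(unique(c(seeds, nb)))
}

# Label-restricted transitive closure by boolean matrix powers.
.oracle_closure <- function(nodes, edges, label) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  sel <- edges$pathway == label
  A[cbind(edges$from[sel], edges$to[sel])] <- TRUE
  R <- A
  for (step in seq_len(n)) {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Exhaustive mechanism enumeration over all (target pair, label pair,
# node) triples; mirrors the documented predicates, independent machinery.
oracle_mechanisms <- function(a_targets, b_targets, edges, loops) {
  nodes <- unique(c(edges$from, edges$to))
  labels <- unique(edges$pathway)
  Ta <- intersect(a_targets, nodes)
  Tb <- intersect(b_targets, nodes)
  member <- sapply(labels, function(L)
    sapply(nodes, function(v) any(edges$from == v & edges$pathway == L)))
  member <- matrix(member, nrow = length(nodes),
                   dimnames = list(nodes, labels))
  closures <- lapply(setNames(labels, labels), function(L)
    .oracle_closure(nodes, edges, L))
  reach <- function(v, L) setdiff(nodes[closures[[L]][v, ]], v)

  kinds <- character(0)
  same <- FALSE; cross <- FALSE; comp <- FALSE; feed <- FALSE
  comp_support <- rep(FALSE, length(loops))
  for (ta in Ta) for (tb in Tb) {
    if (ta == tb) next
    for (La in labels[member[ta, ]]) for (Lb in labels[member[tb, ]]) {
      if (La == Lb) { same <- TRUE; next }
      ra <- reach(ta, La); rb <- reach(tb, Lb)
      for (v in nodes) if (v %in% ra && v %in% rb) cross <- TRUE
      for (li in seq_along(loops)) {
        ia <- intersect(ra, loops[[li]]); ib <- intersect(rb, loops[[li]])
        if (length(ia) > 0 && length(ib) > 0 && length(union(ia, ib)) >= 2) {
          comp <- TRUE
          if (!(ta %in% loops[[li]]) && !(tb %in% loops[[li]]))
            comp_support[li] <- TRUE
        }
      }
    }
  }
  for (li in seq_along(loops)) {
    ma <- intersect(Ta, loops[[li]]); mb <- intersect(Tb, loops[[li]])
    if (length(ma) > 0 && length(mb) > 0 && length(union(ma, mb)) >= 2 &&
        comp_support[li]) feed <- TRUE
  }
  c(character(0), if (same) "same_pathway", if (cross) "crosstalk_convergence",
    if (comp) "compensation", if (feed) "feedback_loop")
}

# Random bit vector helper for property tests.
random_bits <- function(n, p = 0.3) as.integer(runif(n) < p)

# A small deterministic compound set built from synthetic bits.
toy_compounds <- function(bitsets, n_bits = 16, herbs = "reference") {
  m <- t(vapply(bitsets, function(b) {
    v <- integer(n_bits); v[b] <- 1L; v
  }, integer(n_bits)))
  compound_set(names(bitsets), m, herbs = herbs)
}

# Write a temporary whitespace-delimited file and return its path.
tmp_lines <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
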