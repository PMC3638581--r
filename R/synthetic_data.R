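#' Generate a planted-structure synthetic drug space
#'
#' Emulates the statistical structure the concordance method assumes
#' ("like attracts like"): reference drugs fall into structural families,
#' drugs of one family share a fingerprint template (perturbed by per-drug
#' bit flips), and each family's targets live inside one densely connected
#' module of a stochastic-block-model interaction network, with only sparse
#' edges between modules. Structural similarity therefore tracks
#' target-module proximity by construction, and planted targets are known
#' ground truth for recovery tests.
#'
#' All randomness flows from the single integer `seed`.
#'
#' @param n_families number of drug families / network modules.
#' @param drugs_per_family reference drugs per family.
#' @param genes_per_module genes per network module.
#' @param p_within within-module edge probability (dense).
#' @param inter_module_edges total number of random between-module edges
#'   (sparse).
#' @param targets_per_drug planted targets per reference drug, sampled from
#'   the family module.
#' @param fingerprint_bits synthetic fingerprint length.
#' @param fingerprint_noise per-bit flip rate applied to the family
#'   template for each drug, in \[0, 1).
#' @param template_density expected fraction of set bits in a family
#'   template.
#' @param seed integer seed.
#' @return an object of class `synthetic_space`: list with `ppi` (igraph),
#'   `reference_drugs` ([compound_set()]), `reference_targets` (named
#'   list), `families` (drug id -> family index), `modules` (family ->
#'   module genes), `templates` (family x bits matrix), `params`, `seed`.
#' @export
generate_space <- function(n_families = 5, drugs_per_family = 10,
                           genes_per_module = 80, p_within = 0.15,
                           inter_module_edges = 200, targets_per_drug = 10,
                           fingerprint_bits = 256, fingerprint_noise = 0.1,
                           template_density = 0.3, seed = 42) {
  .assert(n_families >= 1 && drugs_per_family >= 1 && genes_per_module >= 1 &&
            targets_per_drug >= 1 && fingerprint_bits >= 1 &&
            inter_module_edges >= 0, "all counts must be >= 1")
  .assert(fingerprint_noise >= 0 && fingerprint_noise < 1,
          "fingerprint_noise must be in [0, 1)")
  .assert(targets_per_drug <= genes_per_module,
          "targets_per_drug cannot exceed genes_per_module")
  set.seed(seed)
  n_genes <- n_families * genes_per_module
  genes <- sprintf("G%04d", seq_len(n_genes))
  module_of <- rep(seq_len(n_families), each = genes_per_module)
  modules <- split(genes, module_of)
  names(modules) <- paste0("F", seq_len(n_families))

  # within-module Bernoulli(p_within) edges
  edge_list <- list()
  for (m in seq_len(n_families)) {
    gm <- modules[[m]]
    if (length(gm) >= 2) {
      pr <- utils::combn(gm, 2)
      keep <- stats::runif(ncol(pr)) < p_within
      if (any(keep)) edge_list[[length(edge_list) + 1L]] <- t(pr[, keep, drop = FALSE])
    }
  }
  # sparse between-module edges, sampled without duplicates
  if (inter_module_edges > 0 && n_families >= 2) {
    got <- character(0)
    cross <- matrix(character(0), 0, 2)
    while (nrow(cross) < inter_module_edges) {
      a <- sample.int(n_genes, inter_module_edges)
      b <- sample.int(n_genes, inter_module_edges)
      ok <- module_of[a] != module_of[b]
      key <- paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]))
      new <- !duplicated(key) & !(key %in% got)
      got <- c(got, key[new])
      cross <- rbind(cross, cbind(genes[a[ok][new]], genes[b[ok][new]]))
    }
    edge_list[[length(edge_list) + 1L]] <- cross[seq_len(inter_module_edges), , drop = FALSE]
  }
  edges <- do.call(rbind, edge_list)
  ppi <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  missing <- setdiff(genes, igraph::V(ppi)$name)
  if (length(missing) > 0) ppi <- igraph::add_vertices(ppi, length(missing), name = missing)

  templates <- matrix(as.integer(stats::runif(n_families * fingerprint_bits) <
                                   template_density),
                      nrow = n_families)
  drug_ids <- as.vector(t(outer(seq_len(n_families), seq_len(drugs_per_family),
                                function(f, d) sprintf("D_F%d_%02d", f, d))))
  families <- stats::setNames(rep(seq_len(n_families), each = drugs_per_family),
                              drug_ids)
  fps <- matrix(0L, nrow = length(drug_ids), ncol = fingerprint_bits,
                dimnames = list(drug_ids, NULL))
  reference_targets <- vector("list", length(drug_ids))
  names(reference_targets) <- drug_ids
  for (i in seq_along(drug_ids)) {
    f <- families[[i]]
    flip <- stats::runif(fingerprint_bits) < fingerprint_noise
    fps[i, ] <- ifelse(flip, 1L - templates[f, ], templates[f, ])
    reference_targets[[i]] <- sample(modules[[f]], targets_per_drug)
  }
  structure(list(ppi = ppi,
                 reference_drugs = compound_set(drug_ids, fps, herbs = "reference"),
                 reference_targets = reference_targets,
                 families = families,
                 modules = modules,
                 templates = templates,
                 params = list(n_families = n_families,
                               drugs_per_family = drugs_per_family,
                               genes_per_module = genes_per_module,
                               p_within = p_within,
                               inter_module_edges = inter_module_edges,
                               targets_per_drug = targets_per_drug,
                               fingerprint_bits = fingerprint_bits,
                               fingerprint_noise = fingerprint_noise,
                               template_density = template_density),
                 seed = seed),
            class = "synthetic_space")
}

#' @export
print.synthetic_space <- function(x, ...) {
  cat(sprintf("<synthetic_space> seed %d: %d drugs in %d families, %d-gene network (%d edges)\n",
              x$seed, length(x$families), x$params$n_families,
              igraph::vcount(x$ppi), igraph::ecount(x$ppi)))
  invisible(x)
}

#' Generate a query ingredient with planted true targets
#'
#' The query fingerprint is the chosen family's template with bits flipped
#' at rate `noise`; its planted true targets are that family's whole module
#' gene set, giving an unambiguous ground truth for precision-at-k.
#'
#' @param space a [generate_space()] result.
#' @param family_index which family the query belongs to.
#' @param noise per-bit flip rate; default the space's fingerprint noise.
#' @param seed seed for the query draw; default derived from the space seed
#'   and family index.
#' @return list with `id`, `fingerprint`, `planted_targets`,
#'   `family_index`.
#' @export
generate_query <- function(space, family_index,
                           noise = space$params$fingerprint_noise,
                           seed = space$seed + 10000 + family_index) {
  .assert(inherits(space, "synthetic_space"), "space must be a synthetic_space")
  .assert(family_index >= 1 && family_index <= space$params$n_families,
          "no such family: ", family_index)
  .assert(noise >= 0 && noise < 1, "noise must be in [0, 1)")
  set.seed(seed)
  tmpl <- space$templates[family_index, ]
  flip <- stats::runif(length(tmpl)) < noise
  list(id = sprintf("Q_F%d", family_index),
       fingerprint = ifelse(flip, 1L - tmpl, tmpl),
       planted_targets = space$modules[[family_index]],
       family_index = family_index)
}

#' Synthetic binary profile matrices with planted ingredient groups
#'
#' Builds a block-structured binary ingredient x gene matrix: each group
#' has a dedicated gene block, and each member marks `per_profile` genes
#' drawn mostly (`1 - noise`) from its own block. Used for PCA/clustering
#' validation where ground-truth group labels are required.
#'
#' @param n_groups number of planted groups.
#' @param per_group ingredients per group.
#' @param genes_per_block genes in each group's block.
#' @param per_profile genes marked per ingredient.
#' @param noise fraction of an ingredient's genes drawn outside its block.
#' @param seed integer seed.
#' @return binary matrix with rownames `<group>_<member>` and attribute
#'   `groups` (named character vector of true labels).
#' @export
generate_profile_groups <- function(n_groups = 3, per_group = 10,
                                    genes_per_block = 40, per_profile = 20,
                                    noise = 0.1, seed = 11) {
  .assert(n_groups >= 1 && per_group >= 1 && genes_per_block >= per_profile,
          "genes_per_block must be >= per_profile")
  set.seed(seed)
  n_genes <- n_groups * genes_per_block
  genes <- sprintf("G%04d", seq_len(n_genes))
  blocks <- split(genes, rep(seq_len(n_groups), each = genes_per_block))
  rows <- list()
  labels <- character(0)
  for (g in seq_len(n_groups)) {
    for (i in seq_len(per_group)) {
      n_out <- stats::rbinom(1, per_profile, noise)
      own <- sample(blocks[[g]], per_profile - n_out)
      other <- if (n_out > 0) sample(setdiff(genes, blocks[[g]]), n_out) else character(0)
      row <- as.integer(genes %in% c(own, other))
      id <- sprintf("grp%d_%02d", g, i)
      rows[[id]] <- row
      labels[id] <- paste0("class", g)
    }
  }
  m <- do.call(rbind, rows)
  colnames(m) <- genes
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  attr(m, "groups") <- labels
  attr(m, "encoding") <- "binary"
  m
}
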