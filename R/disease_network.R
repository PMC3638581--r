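#' Assemble disease seed genes from three provenance classes
#'
#' Seeds come from known disease genes (e.g. OMIM), computationally
#' predicted disease genes, and targets of approved drugs for the disease.
#' Duplicate symbols (including case variants) are merged and keep every
#' provenance label they appear under.
#'
#' @param known,predicted,drug_targets character vectors of gene symbols
#'   (any may be empty, not all).
#' @return an object of class `seed_set`: data.frame with columns `gene`
#'   and logical `known`, `predicted`, `drug_target`.
#' @export
assemble_seeds <- function(known = character(), predicted = character(),
                           drug_targets = character()) {
  known <- unique(.norm_genes(known))
  predicted <- unique(.norm_genes(predicted))
  drug_targets <- unique(.norm_genes(drug_targets))
  genes <- sort(unique(c(known, predicted, drug_targets)))
  .assert(length(genes) > 0, "all seed lists are empty")
  out <- data.frame(gene = genes,
                    known = genes %in% known,
                    predicted = genes %in% predicted,
                    drug_target = genes %in% drug_targets,
                    stringsAsFactors = FALSE)
  class(out) <- c("seed_set", "data.frame")
  out
}

#' Expand seed genes into a disease-specific network
#'
#' One-hop expansion: the node set is the seeds plus every direct
#' interaction partner of a seed in the parent network; edges are all
#' parent-network edges induced on that node set. Seeds absent from the
#' parent network are retained as isolated layer-0 nodes (with a warning)
#' so their provenance survives into reports.
#'
#' @param seeds a [assemble_seeds()] `seed_set`.
#' @param ppi parent undirected interaction network ([load_network()]).
#' @param depth expansion depth in hops (default 1, the standard
#'   "first interaction partners" rule).
#' @return an object of class `disease_network`: list with `graph`
#'   (induced igraph, isolated absent seeds included), `layer` (named
#'   integer, 0 = seed, 1.. = expansion hop) and `seeds`.
#' @export
expand_to_disease_network <- function(seeds, ppi, depth = 1) {
  .assert(inherits(seeds, "seed_set"), "seeds must come from assemble_seeds()")
  .assert(depth >= 0, "depth must be >= 0")
  vn <- igraph::V(ppi)$name
  present <- intersect(seeds$gene, vn)
  absent <- setdiff(seeds$gene, vn)
  if (length(absent) > 0) {
    warning(sprintf("%d seed(s) absent from the interaction network kept as isolated nodes: %s",
                    length(absent), paste(utils::head(absent, 5), collapse = ", ")))
  }
  layer <- stats::setNames(rep(0L, length(seeds$gene)), seeds$gene)
  frontier <- present
  nodes <- present
  d <- 0L
  while (d < depth && length(frontier) > 0) {
    d <- d + 1L
    nb <- unique(unlist(lapply(
      igraph::adjacent_vertices(ppi, frontier),
      function(v) igraph::as_ids(v))))
    frontier <- setdiff(nb, nodes)
    if (length(frontier) > 0) {
      layer[frontier] <- d
      nodes <- c(nodes, frontier)
    }
  }
  g <- igraph::induced_subgraph(ppi, nodes)
  if (length(absent) > 0) g <- igraph::add_vertices(g, length(absent), name = absent)
  structure(list(graph = g,
                 layer = layer[igraph::V(g)$name],
                 seeds = seeds),
            class = "disease_network")
}

#' @export
print.disease_network <- function(x, ...) {
  cat(sprintf("<disease_network> %d node(s) (%d seed, %d expanded), %d edge(s)\n",
              igraph::vcount(x$graph), sum(x$layer == 0), sum(x$layer > 0),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Map a herb's predicted targets into the disease network
#'
#' The herb target network is the induced subgraph of the disease network
#' on the union of the herb's ingredient profile genes intersected with the
#' disease-network nodes. With `bridge = TRUE`, disease-network nodes
#' adjacent to two or more mapped targets are added as connectors (the
#' construction used when inter-target paths through non-target genes are
#' wanted).
#'
#' @param herb_profiles named list of [top_k_profile()] objects, all from
#'   one herb.
#' @param disease_net a [expand_to_disease_network()] result.
#' @param herb herb label for the report.
#' @param bridge add 1-hop connector nodes (default `FALSE`).
#' @return an object of class `herb_target_network`: list with `herb`,
#'   `graph`, `mapped_targets`, `contributors` (gene -> ingredient ids),
#'   `bridge_nodes`, `off_target_flags`, `counteracted_by`.
#' @export
map_herb_targets <- function(herb_profiles, disease_net, herb = "herb",
                             bridge = FALSE) {
  .assert(inherits(disease_net, "disease_network"),
          "disease_net must come from expand_to_disease_network()")
  .assert(length(herb_profiles) > 0, "no profiles supplied")
  .assert(!is.null(names(herb_profiles)), "profiles must be named by ingredient")
  dn_nodes <- igraph::V(disease_net$graph)$name
  long <- do.call(rbind, lapply(names(herb_profiles), function(id) {
    data.frame(gene = herb_profiles[[id]]$genes, ingredient = id,
               stringsAsFactors = FALSE)
  }))
  mapped <- sort(intersect(unique(long$gene), dn_nodes))
  if (length(mapped) == 0) {
    warning(sprintf("no targets of herb '%s' map into the disease network", herb))
  }
  contributors <- lapply(split(long$ingredient, long$gene)[mapped], function(x)
    sort(unique(x)))
  bridge_nodes <- character(0)
  keep <- mapped
  if (bridge && length(mapped) > 0) {
    others <- setdiff(dn_nodes, mapped)
    if (length(others) > 0) {
      deg_to_mapped <- vapply(others, function(u) {
        length(intersect(igraph::as_ids(
          igraph::neighbors(disease_net$graph, u)), mapped))
      }, 1L)
      bridge_nodes <- others[deg_to_mapped >= 2]
      keep <- c(mapped, bridge_nodes)
    }
  }
  g <- igraph::induced_subgraph(disease_net$graph, keep)
  structure(list(herb = herb,
                 graph = g,
                 mapped_targets = mapped,
                 contributors = contributors,
                 bridge_nodes = bridge_nodes,
                 off_target_flags = character(0),
                 counteracted_by = list()),
            class = "herb_target_network")
}

#' @export
print.herb_target_network <- function(x, ...) {
  cat(sprintf("<herb_target_network> %s: %d mapped target(s), %d edge(s)%s\n",
              x$herb, length(x$mapped_targets), igraph::ecount(x$graph),
              if (length(x$off_target_flags) > 0)
                paste0("; off-target: ", paste(x$off_target_flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Flag adverse-effect-relevant off-target genes in a herb network
#'
#' Marks mapped targets that appear on a user-supplied adverse-gene list.
#' When the target networks of the other herbs are supplied, herbs that
#' also hit a flagged gene are reported as potential counter-acting herbs
#' (the "reducing toxicity" reading of formula composition).
#'
#' @param herb_net a [map_herb_targets()] result.
#' @param adverse_genes character vector of adverse-effect genes (may be
#'   empty).
#' @param other_herb_nets optional list of `herb_target_network` objects
#'   for the remaining herbs.
#' @return the herb network with `off_target_flags` and `counteracted_by`
#'   filled in.
#' @export
flag_off_targets <- function(herb_net, adverse_genes,
                             other_herb_nets = NULL) {
  .assert(inherits(herb_net, "herb_target_network"),
          "herb_net must come from map_herb_targets()")
  adverse_genes <- unique(.norm_genes(adverse_genes))
  flags <- intersect(herb_net$mapped_targets, adverse_genes)
  missed <- setdiff(adverse_genes, flags)
  if (length(missed) > 0) {
    message(sprintf("flag_off_targets: %d adverse gene(s) not among mapped targets: %s",
                    length(missed), paste(missed, collapse = ", ")))
  }
  herb_net$off_target_flags <- flags
  herb_net$counteracted_by <- lapply(stats::setNames(flags, flags), function(g) {
    hits <- vapply(other_herb_nets, function(o) g %in% o$mapped_targets, TRUE)
    sort(unique(vapply(other_herb_nets[hits], `[[`, "", "herb")))
  })
  herb_net
}
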