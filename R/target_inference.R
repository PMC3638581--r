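#' Concordance score between a similarity vector and a closeness vector
#'
#' The likelihood score for one (ingredient, gene) pair: the correlation
#' (default Pearson) between the ingredient's structure-similarity vector
#' in drug space and the gene's closeness vector in target space, both over
#' the same ordered reference drugs. Genes whose closeness vector tracks
#' the query's chemical similarity pattern are likely targets ("like
#' attracts like"). If either vector has zero variance the score is exactly
#' 0 with attribute `degenerate = TRUE` (no evidence, not negative
#' evidence).
#'
#' @param sim named similarity vector from [similarity_vector()].
#' @param clo named closeness vector from [closeness_vector()], same
#'   reference order.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a number in \[-1, 1\] with logical attribute `degenerate`.
#' @export
concordance_score <- function(sim, clo, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  .assert(length(sim) == length(clo),
          "similarity/closeness length mismatch: ", length(sim), " vs ", length(clo))
  .assert(length(sim) >= 3, "need at least 3 reference drugs for a correlation")
  if (!is.null(names(sim)) && !is.null(names(clo))) {
    .assert(identical(names(sim), names(clo)),
            "reference drug ordering differs between vectors")
  }
  if (stats::sd(sim) == 0 || stats::sd(clo) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  structure(stats::cor(sim, clo, method = method), degenerate = FALSE)
}

#' Rank all candidate genes as targets of a query ingredient
#'
#' Computes the query's similarity vector against the reference drugs, the
#' closeness vector of every gene in the universe against the reference
#' drugs' target sets, and scores each gene by [concordance_score()].
#' Results are sorted by decreasing score with lexicographic gene-symbol
#' tie-breaking; degenerate (zero-variance) genes sort after all scored
#' genes. The ordering is fully deterministic.
#'
#' @param query a single-compound [compound_set()] or a fingerprint vector.
#' @param references [compound_set()] of >= 3 reference drugs.
#' @param reference_targets named list of target-gene sets, names matching
#'   `references$ids` (order is taken from `references`).
#' @param network undirected interaction network ([load_network()]).
#' @param gene_universe candidate genes; default all network nodes. Must be
#'   a subset of network nodes plus reference target genes.
#' @param kernel closeness kernel, see [closeness_matrix()].
#' @param method correlation type, see [concordance_score()].
#' @return data.frame with columns `gene`, `score`, `degenerate`, `rank`.
#' @export
rank_targets <- function(query, references, reference_targets, network,
                         gene_universe = NULL,
                         kernel = c("gaussian", "exponential"),
                         method = c("pearson", "spearman")) {
  .assert(inherits(references, "compound_set"), "references must be a compound_set")
  .assert(length(references$ids) >= 3,
          "need at least 3 reference drugs (correlation undefined otherwise)")
  .assert(all(references$ids %in% names(reference_targets)),
          "every reference drug needs a target set")
  reference_targets <- reference_targets[references$ids]
  sim <- similarity_vector(query, references)
  clo <- .universe_closeness(gene_universe, reference_targets, network, kernel)
  .score_universe(sim, clo, method)
}

# Closeness matrix for the (validated) gene universe; shared by
# rank_targets() and formula_profiles() so the expensive BFS runs once.
.universe_closeness <- function(gene_universe, reference_targets, network,
                                kernel = c("gaussian", "exponential")) {
  vn <- igraph::V(network)$name
  tg <- unique(unlist(reference_targets, use.names = FALSE))
  universe <- if (is.null(gene_universe)) vn else unique(.norm_genes(gene_universe))
  .assert(length(universe) > 0, "empty gene universe")
  stray <- setdiff(universe, union(vn, .norm_genes(tg)))
  .assert(length(stray) == 0,
          "gene_universe entries outside network and reference targets: ",
          paste(utils::head(stray, 5), collapse = ", "))
  closeness_matrix(universe, reference_targets, network, kernel)
}

# Correlate one similarity vector against every row of a closeness matrix.
.score_universe <- function(sim, clo, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scores <- suppressWarnings(as.vector(stats::cor(t(clo), sim, method = method)))
  degenerate <- is.na(scores)
  scores[degenerate] <- 0
  df <- data.frame(gene = rownames(clo), score = scores,
                   degenerate = degenerate, stringsAsFactors = FALSE)
  df <- df[order(df$degenerate, -df$score, df$gene), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}

#' Truncate ranked target scores to a top-k target profile
#'
#' The operating point used throughout the pipeline keeps the `k = 100`
#' best-scoring genes per ingredient as its target profile.
#'
#' @param scores data.frame from [rank_targets()] (already sorted).
#' @param k positive profile size; profiles are shorter only when the gene
#'   universe is smaller than `k`.
#' @param ingredient_id identifier stored in the profile.
#' @return an object of class `target_profile` with fields
#'   `ingredient_id`, `genes`, `scores`, `degenerate`, `k`.
#' @export
top_k_profile <- function(scores, k = 100, ingredient_id = "query") {
  .assert(is.numeric(k) && length(k) == 1 && k > 0, "k must be a positive integer")
  k <- as.integer(k)
  n <- min(k, nrow(scores))
  top <- scores[seq_len(n), , drop = FALSE]
  structure(list(ingredient_id = ingredient_id,
                 genes = top$gene,
                 scores = top$score,
                 degenerate = top$degenerate,
                 k = k),
            class = "target_profile")
}

#' @export
print.target_profile <- function(x, ...) {
  cat(sprintf("<target_profile> %s: %d gene(s) (k = %d), top: %s\n",
              x$ingredient_id, length(x$genes), x$k,
              paste(utils::head(x$genes, 5), collapse = ", ")))
  invisible(x)
}

#' Target profiles for every ingredient of a formula
#'
#' Runs the ranking step for each ingredient against a shared reference
#' space and network, and truncates each ranking to its top-k profile. The
#' closeness matrix is computed once and reused across ingredients.
#'
#' @param ingredients [compound_set()] of query ingredients (with herb
#'   labels).
#' @inheritParams rank_targets
#' @param k profile size, see [top_k_profile()].
#' @return named list of [top_k_profile()] objects, one per ingredient,
#'   with the ingredient herb labels attached as attribute `herbs`.
#' @export
formula_profiles <- function(ingredients, references, reference_targets,
                             network, gene_universe = NULL, k = 100,
                             kernel = c("gaussian", "exponential"),
                             method = c("pearson", "spearman")) {
  .assert(inherits(ingredients, "compound_set"), "ingredients must be a compound_set")
  if (length(ingredients$ids) == 0) {
    warning("empty ingredient collection; returning no profiles")
    return(structure(list(), herbs = character(0)))
  }
  .assert(length(references$ids) >= 3, "need at least 3 reference drugs")
  .assert(all(references$ids %in% names(reference_targets)),
          "every reference drug needs a target set")
  reference_targets <- reference_targets[references$ids]
  clo <- .universe_closeness(gene_universe, reference_targets, network, kernel)
  sims <- similarity_matrix(ingredients, references)
  profiles <- lapply(seq_along(ingredients$ids), function(i) {
    scores <- .score_universe(sims[i, ], clo, method)
    top_k_profile(scores, k = k, ingredient_id = ingredients$ids[i])
  })
  names(profiles) <- ingredients$ids
  structure(profiles, herbs = stats::setNames(ingredients$herbs, ingredients$ids))
}

#' Integrative target set of a formula with per-herb provenance
#'
#' Union of all ingredient profile genes, annotated with the herbs and
#' ingredients contributing each gene.
#'
#' @param profiles named list of [top_k_profile()] objects.
#' @param herbs named character vector mapping ingredient id to herb;
#'   defaults to the `herbs` attribute attached by [formula_profiles()].
#' @return data.frame with columns `gene`, `n_ingredients`, `ingredients`,
#'   `herbs`, sorted by decreasing `n_ingredients`.
#' @export
integrative_targets <- function(profiles, herbs = attr(profiles, "herbs")) {
  .assert(length(profiles) > 0, "no profiles supplied")
  if (is.null(herbs)) {
    herbs <- stats::setNames(rep("unknown", length(profiles)), names(profiles))
  }
  long <- do.call(rbind, lapply(names(profiles), function(id) {
    data.frame(gene = profiles[[id]]$genes, ingredient = id,
               herb = unname(herbs[id]), stringsAsFactors = FALSE)
  }))
  agg <- split(long, long$gene)
  out <- data.frame(
    gene = names(agg),
    n_ingredients = vapply(agg, function(d) length(unique(d$ingredient)), 1L),
    ingredients = vapply(agg, function(d)
      paste(sort(unique(d$ingredient)), collapse = ","), ""),
    herbs = vapply(agg, function(d)
      paste(sort(unique(d$herb)), collapse = ","), ""),
    stringsAsFactors = FALSE)
  out <- out[order(-out$n_ingredients, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
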