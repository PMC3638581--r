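#' Gene-set annotation collections
#'
#' A collection bundles named gene sets (with an optional category label
#' per term, e.g. "Angiogenesis" or "Inflammatory response") and the
#' background gene universe against which over-representation is tested.
#' Term genes outside the background are dropped; terms left empty are
#' removed with a warning.
#'
#' @param sets named list of character gene sets (term id -> genes).
#' @param background background gene universe; default the union of all
#'   term genes. In pipeline use the background is the interaction-network
#'   node set.
#' @param term_names optional named character vector of human-readable term
#'   names (defaults to the term ids).
#' @param categories optional named character vector of category labels.
#' @return an object of class `gene_set_collection`: list with `sets`,
#'   `term_names`, `categories`, `background`.
#' @export
gene_set_collection <- function(sets, background = NULL, term_names = NULL,
                                categories = NULL) {
  .assert(length(sets) > 0, "no gene sets supplied")
  .assert(!is.null(names(sets)) && all(nzchar(names(sets))),
          "gene sets must be named by term id")
  ids <- names(sets)
  sets <- lapply(sets, function(x) unique(.norm_genes(x)))
  if (is.null(background)) background <- unlist(sets, use.names = FALSE)
  background <- unique(.norm_genes(background))
  .assert(length(background) > 0, "empty background")
  sets <- lapply(sets, function(x) intersect(x, background))
  names(sets) <- ids
  empty <- vapply(sets, length, 1L) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty term(s) after background intersection: %s",
                    sum(empty), paste(ids[empty], collapse = ", ")))
    sets <- sets[!empty]
    ids <- ids[!empty]
  }
  .assert(length(sets) > 0, "no non-empty terms left")
  tn <- stats::setNames(rep(NA_character_, length(ids)), ids)
  tn[ids] <- ids
  if (!is.null(term_names)) tn[intersect(ids, names(term_names))] <-
    term_names[intersect(ids, names(term_names))]
  ct <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(categories)) ct[intersect(ids, names(categories))] <-
    categories[intersect(ids, names(categories))]
  structure(list(sets = sets, term_names = tn, categories = ct,
                 background = background),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d term(s), background of %d gene(s)\n",
              length(x$sets), length(x$background)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `term_id`, `description`,
#' then member genes. The description field may carry a category label as
#' `category|term name` (the convention used by the packaged fixture); a
#' description without `|` is used as the term name with no category.
#'
#' @param path GMT file path.
#' @param background optional background universe; default union of all
#'   term genes.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, background = NULL) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  .assert(length(lines) > 0, "empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  .assert(all(vapply(fields, length, 1L) >= 3),
          "GMT lines need term, description and at least one gene: ", path)
  ids <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) f[seq(3, length(f))])
  names(sets) <- ids
  has_cat <- grepl("|", desc, fixed = TRUE)
  categories <- ifelse(has_cat, sub("\\|.*$", "", desc), NA_character_)
  term_names <- ifelse(has_cat, sub("^[^|]*\\|", "", desc), desc)
  gene_set_collection(sets, background = background,
                      term_names = stats::setNames(term_names, ids),
                      categories = stats::setNames(categories, ids))
}

#' One-sided Fisher (hypergeometric) over-representation p-value
#'
#' Probability of observing at least the actual overlap between a query
#' gene set and an annotation term when drawing `|query|` genes from the
#' background without replacement; the DAVID-style one-sided test.
#'
#' @param query query gene set (genes outside the background are dropped
#'   with a warning).
#' @param term annotation gene set (subset of background enforced).
#' @param background background gene universe.
#' @return the upper-tail hypergeometric probability `P(X >= overlap)`.
#' @export
fisher_enrichment <- function(query, term, background) {
  background <- unique(.norm_genes(background))
  .assert(length(background) > 0, "empty background")
  query <- unique(.norm_genes(query))
  term <- unique(.norm_genes(term))
  outside <- setdiff(query, background)
  if (length(outside) > 0) {
    warning(sprintf("dropping %d query gene(s) outside the background", length(outside)))
    query <- intersect(query, background)
  }
  term <- intersect(term, background)
  k <- length(intersect(query, term))
  stats::phyper(k - 1, m = length(term), n = length(background) - length(term),
                k = length(query), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH adjusted p-values (monotone after sorting, capped at 1,
#' returned in the original input order).
#'
#' @param p_values numeric vector of raw p-values, all in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_values) {
  .assert(is.numeric(p_values) && length(p_values) > 0, "no p-values supplied")
  .assert(all(!is.na(p_values)) && all(p_values >= 0 & p_values <= 1),
          "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis of a target network
#'
#' Tests every term of a collection against a query gene set (or the
#' mapped targets of a herb target network) with the one-sided Fisher test,
#' adjusts across terms by Benjamini-Hochberg, and reports terms with
#' adjusted p below `alpha` (all terms with `all_results = TRUE`).
#'
#' @param query character gene set or a [map_herb_targets()] network.
#' @param collection a [gene_set_collection()].
#' @param alpha reporting threshold on the adjusted p-value (default 0.05).
#' @param all_results return every term regardless of significance.
#' @return data.frame with columns `term_id`, `term_name`, `category`,
#'   `overlap`, `term_size`, `query_size`, `background_size`, `p_raw`,
#'   `p_adjusted`, sorted by adjusted then raw p-value.
#' @export
enrich_network <- function(query, collection, alpha = 0.05,
                           all_results = FALSE) {
  .assert(inherits(collection, "gene_set_collection"),
          "collection must be a gene_set_collection")
  if (inherits(query, "herb_target_network")) query <- query$mapped_targets
  query <- unique(.norm_genes(query))
  q <- intersect(query, collection$background)
  .assert(length(q) > 0, "query has no genes in the enrichment background")
  if (length(q) < length(query)) {
    warning(sprintf("dropping %d query gene(s) outside the background",
                    length(query) - length(q)))
  }
  ids <- names(collection$sets)
  p_raw <- vapply(collection$sets, function(term) {
    k <- length(intersect(q, term))
    stats::phyper(k - 1, m = length(term),
                  n = length(collection$background) - length(term),
                  k = length(q), lower.tail = FALSE)
  }, 0)
  out <- data.frame(term_id = ids,
                    term_name = unname(collection$term_names[ids]),
                    category = unname(collection$categories[ids]),
                    overlap = vapply(collection$sets, function(term)
                      length(intersect(q, term)), 1L),
                    term_size = vapply(collection$sets, length, 1L),
                    query_size = length(q),
                    background_size = length(collection$background),
                    p_raw = unname(p_raw),
                    stringsAsFactors = FALSE)
  out$p_adjusted <- benjamini_hochberg(out$p_raw)
  if (!all_results) out <- out[out$p_adjusted < alpha, , drop = FALSE]
  out <- out[order(out$p_adjusted, out$p_raw, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
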