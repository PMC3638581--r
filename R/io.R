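#' Write a tab-separated table with a provenance header
#'
#' All tabular pipeline outputs share this format: a single `#` comment
#' line naming the producing module and package version, then a header row
#' and tab-separated values.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param module name of the producing module, recorded in the comment.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, module = "herbnet") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s | herbnet %s", module,
                     as.character(utils::packageVersion("herbnet"))), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export an undirected network as SIF
#'
#' One `A <TAB> pp <TAB> B` line per edge; isolated nodes are written as a
#' bare node name line is not legal SIF, so they are listed in a companion
#' node-attribute table instead (see [write_node_attributes()]).
#'
#' @param graph an [igraph::graph].
#' @param path output path.
#' @param interaction SIF interaction type string.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path, interaction = "pp") {
  el <- igraph::as_edgelist(graph)
  lines <- if (nrow(el) > 0) paste(el[, 1], interaction, el[, 2], sep = "\t") else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write a node-attribute table for a network
#'
#' @param attrs data.frame with a `gene` column plus attribute columns.
#' @param path output path.
#' @param module provenance comment, see [write_tsv()].
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(attrs, path, module = "network") {
  write_tsv(attrs, path, module = module)
}

#' Write / read target profiles as a long TSV
#'
#' Columns: `ingredient`, `herb`, `rank`, `gene`, `score`, `degenerate`,
#' `k`. The reader reconstructs the named profile list (and `herbs`
#' attribute) so the file round-trips losslessly.
#'
#' @param profiles named list of [top_k_profile()] objects (with optional
#'   `herbs` attribute).
#' @param path file path.
#' @return `path` invisibly for the writer; a named list of
#'   `target_profile` objects for the reader.
#' @export
write_profiles <- function(profiles, path) {
  herbs <- attr(profiles, "herbs")
  if (is.null(herbs)) herbs <- stats::setNames(rep("unknown", length(profiles)),
                                               names(profiles))
  long <- do.call(rbind, lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    data.frame(ingredient = id, herb = unname(herbs[id]),
               rank = seq_along(p$genes), gene = p$genes,
               score = p$scores, degenerate = p$degenerate, k = p$k,
               stringsAsFactors = FALSE)
  }))
  write_tsv(long, path, module = "target_inference")
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  long <- read_tsv(path)
  .assert(all(c("ingredient", "gene", "score", "k") %in% names(long)),
          "not a profile table: ", path)
  ids <- unique(long$ingredient)
  profiles <- lapply(ids, function(id) {
    d <- long[long$ingredient == id, , drop = FALSE]
    d <- d[order(d$rank), , drop = FALSE]
    structure(list(ingredient_id = id, genes = d$gene, scores = d$score,
                   degenerate = as.logical(d$degenerate), k = d$k[1]),
              class = "target_profile")
  })
  names(profiles) <- ids
  herbs <- if ("herb" %in% names(long)) {
    vapply(ids, function(id) long$herb[long$ingredient == id][1], "")
  } else stats::setNames(rep("unknown", length(ids)), ids)
  structure(profiles, herbs = herbs)
}

#' Write / read compound fingerprints as TSV
#'
#' Columns: `id`, `herb`, `fingerprint` (a 0/1 bitstring). This is the
#' exchange format for synthetic fingerprints that have no structure.
#'
#' @param compounds a [compound_set()].
#' @param path file path.
#' @return `path` invisibly for the writer; a [compound_set()] for the
#'   reader.
#' @export
write_fingerprints <- function(compounds, path) {
  bits <- apply(compounds$fingerprints, 1, paste, collapse = "")
  write_tsv(data.frame(id = compounds$ids, herb = compounds$herbs,
                       fingerprint = unname(bits), stringsAsFactors = FALSE),
            path, module = "chem_space")
}

#' @rdname write_fingerprints
#' @export
read_fingerprints <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  .assert(all(c("id", "fingerprint") %in% names(d)),
          "not a fingerprint table: ", path)
  m <- do.call(rbind, lapply(strsplit(as.character(d$fingerprint), ""),
                             as.integer))
  compound_set(d$id, m, herbs = if ("herb" %in% names(d)) d$herb else "reference")
}

#' Write / read drug-target interaction tables
#'
#' Long TSV with columns `drug`, `gene`; the reader returns the named list
#' of target sets used across the package.
#'
#' @param reference_targets named list drug id -> target genes.
#' @param path file path.
#' @return `path` invisibly for the writer; a named list for the reader.
#' @export
write_drug_targets <- function(reference_targets, path) {
  long <- do.call(rbind, lapply(names(reference_targets), function(id) {
    data.frame(drug = id, gene = reference_targets[[id]], stringsAsFactors = FALSE)
  }))
  write_tsv(long, path, module = "ppi_space")
}

#' @rdname write_drug_targets
#' @export
read_drug_targets <- function(path) {
  d <- read_tsv(path)
  .assert(all(c("drug", "gene") %in% names(d)), "not a drug-target table: ", path)
  lapply(split(d$gene, d$drug)[unique(d$drug)], function(x) unique(.norm_genes(x)))
}

#' Export an undirected network as a 2-column edge list TSV
#'
#' The counterpart of [load_network()]'s TSV reader.
#'
#' @param graph an [igraph::graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(a = el[, 1], b = el[, 2], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
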