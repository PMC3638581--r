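#' Load an undirected protein-interaction network
#'
#' Accepts SIF (`A pp B [C ...]`, one hub per line with one or more
#' partners) or 2-column whitespace/tab-delimited edge lists. Gene symbols
#' are uppercase-normalized; self-loops and duplicate edges are dropped
#' with logged counts. Nodes exist only through edges.
#'
#' @param path path to the edge-list file.
#' @param format `"auto"`, `"sif"` or `"tsv"`. `"auto"` treats 3+ column
#'   files as SIF and 2-column files as plain edge lists.
#' @return an undirected, simple [igraph::graph] whose vertex names are
#'   gene symbols.
#' @export
load_network <- function(path, format = c("auto", "sif", "tsv")) {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  .assert(length(lines) > 0, "empty network file: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  nf <- vapply(fields, length, 1L)
  if (format == "auto") format <- if (any(nf >= 3)) "sif" else "tsv"
  if (format == "sif") {
    .assert(all(nf >= 3), "SIF lines need at least 3 fields (A type B ...)")
    pairs <- do.call(rbind, lapply(fields, function(f) {
      cbind(f[1], f[seq(3, length(f))])
    }))
  } else {
    .assert(all(nf >= 2), "edge-list lines need 2 fields")
    pairs <- do.call(rbind, lapply(fields, function(f) cbind(f[1], f[2])))
  }
  pairs <- matrix(.norm_genes(pairs), ncol = 2)
  self <- pairs[, 1] == pairs[, 2]
  key <- apply(pairs, 1, function(p) paste(sort(p), collapse = "\r"))
  dup <- duplicated(key) & !self
  if (any(self)) message(sprintf("load_network: dropped %d self-loop(s)", sum(self)))
  if (any(dup)) message(sprintf("load_network: dropped %d duplicate edge(s)", sum(dup)))
  pairs <- pairs[!self & !dup, , drop = FALSE]
  .assert(nrow(pairs) > 0 && length(unique(c(pairs))) >= 2,
          "fewer than 2 nodes after cleaning: ", path)
  g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
  message(sprintf("load_network: %d nodes, %d edges",
                  igraph::vcount(g), igraph::ecount(g)))
  g
}

# Gaussian (exp(-d^2)) or exponential (exp(-d)) kernel of shortest-path
# distance; unreachable pairs get 0.
.kernel_fun <- function(kernel = c("gaussian", "exponential")) {
  kernel <- match.arg(kernel)
  if (kernel == "gaussian") function(d) exp(-d^2) else function(d) exp(-d)
}

#' Closeness matrix of genes to reference-drug target sets
#'
#' The target-space axis of the concordance score. For gene `g` and a drug
#' with target set `T`, closeness is `sum_{t in T} K(d(g, t))` where `d` is
#' the unweighted shortest-path distance in the interaction network and `K`
#' the distance kernel (default Gaussian, `exp(-d^2)`). Unreachable pairs
#' and genes absent from the network contribute 0, except that `d(g, g) = 0`
#' always contributes `K(0) = 1` (a gene is maximally close to itself even
#' when isolated).
#'
#' @param genes character vector of gene symbols (rows).
#' @param reference_targets named list of non-empty target-gene vectors,
#'   one per reference drug, in the fixed reference order (columns).
#' @param network undirected [igraph::graph] from [load_network()].
#' @param kernel `"gaussian"` (`exp(-d^2)`) or `"exponential"` (`exp(-d)`).
#' @return numeric matrix, gene rows x reference-drug columns, values >= 0.
#' @export
closeness_matrix <- function(genes, reference_targets, network,
                             kernel = c("gaussian", "exponential")) {
  K <- .kernel_fun(kernel)
  genes <- unique(.norm_genes(genes))
  .assert(length(genes) > 0, "no genes supplied")
  .assert(length(reference_targets) > 0, "no reference target sets supplied")
  reference_targets <- lapply(reference_targets, function(x) unique(.norm_genes(x)))
  empty <- vapply(reference_targets, length, 1L) == 0
  if (any(empty)) {
    stop("empty target set for reference drug(s): ",
         paste(names(reference_targets)[empty], collapse = ", "), call. = FALSE)
  }
  all_t <- unique(unlist(reference_targets, use.names = FALSE))
  vn <- igraph::V(network)$name
  gp <- intersect(genes, vn)
  tp <- intersect(all_t, vn)
  D <- matrix(Inf, length(genes), length(all_t), dimnames = list(genes, all_t))
  if (length(gp) > 0 && length(tp) > 0) {
    D[gp, tp] <- igraph::distances(network, v = gp, to = tp)
  }
  # self-distance is 0 even for nodes outside the network
  shared <- intersect(genes, all_t)
  for (s in shared) D[s, s] <- 0
  Kd <- K(D)
  Kd[is.infinite(D)] <- 0
  out <- vapply(reference_targets, function(ts) {
    rowSums(Kd[, ts, drop = FALSE])
  }, numeric(length(genes)))
  out <- matrix(out, nrow = length(genes),
                dimnames = list(genes, names(reference_targets)))
  out
}

#' Closeness of one gene to one target set
#'
#' @inheritParams closeness_matrix
#' @param gene a single gene symbol.
#' @param target_set non-empty character vector of target genes.
#' @return a non-negative number.
#' @export
closeness <- function(gene, target_set, network,
                      kernel = c("gaussian", "exponential")) {
  .assert(length(gene) == 1, "gene must be a single symbol")
  .assert(length(.norm_genes(target_set)) > 0, "empty target_set")
  closeness_matrix(gene, list(drug = target_set), network, kernel)[1, 1]
}

#' Closeness vector of one gene across all reference drugs
#'
#' Element `i` is [closeness()] of the gene to the target set of reference
#' drug `i`; the reference order must match the [similarity_vector()]
#' order so the two vectors can be correlated.
#'
#' @inheritParams closeness_matrix
#' @param gene a single gene symbol.
#' @return named non-negative numeric vector (names = reference drug ids).
#' @export
closeness_vector <- function(gene, reference_targets, network,
                             kernel = c("gaussian", "exponential")) {
  .assert(length(gene) == 1, "gene must be a single symbol")
  closeness_matrix(gene, reference_targets, network, kernel)[1, ]
}
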