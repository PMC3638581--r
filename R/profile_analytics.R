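#' Build an ingredient x gene profile matrix
#'
#' Rows are ingredients, columns the sorted union of all profile genes.
#' Binary encoding (default) marks top-k membership; score encoding stores
#' the concordance score (0 for genes outside a profile). Columns that are
#' zero for every ingredient are dropped before analysis.
#'
#' @param profiles named list of [top_k_profile()] objects (>= 2).
#' @param encoding `"binary"` or `"score"`.
#' @return numeric matrix with attribute `encoding`; rownames are
#'   ingredient ids, colnames gene symbols.
#' @export
build_profile_matrix <- function(profiles, encoding = c("binary", "score")) {
  encoding <- match.arg(encoding)
  .assert(length(profiles) >= 2, "need at least 2 profiles")
  genes <- sort(unique(unlist(lapply(profiles, `[[`, "genes"))))
  .assert(length(genes) > 0, "profiles contain no genes")
  m <- matrix(0, nrow = length(profiles), ncol = length(genes),
              dimnames = list(names(profiles), genes))
  for (id in names(profiles)) {
    p <- profiles[[id]]
    if (encoding == "binary") {
      m[id, p$genes] <- 1
    } else {
      m[id, p$genes] <- p$scores
    }
  }
  keep <- colSums(m != 0) > 0
  m <- m[, keep, drop = FALSE]
  attr(m, "encoding") <- encoding
  m
}

#' Principal component analysis of a profile matrix
#'
#' Column-mean-centered (no variance scaling) PCA. Components are ordered
#' by decreasing explained variance; every loading vector has unit norm and
#' distinct loadings are orthogonal. Loadings are sign-fixed so that the
#' largest-magnitude element of each component is positive, which makes
#' outputs reproducible across linear-algebra backends.
#'
#' @param x numeric matrix, ingredient rows x gene columns
#'   ([build_profile_matrix()]).
#' @param n_components number of components to keep; at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return an object of class `pca_result`: list with `loadings` (genes x
#'   components), `scores` (ingredients x components),
#'   `explained_variance_ratio`, `center` and `total_variance`.
#' @export
run_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  .assert(nrow(x) >= 2, "need at least 2 rows")
  max_comp <- min(nrow(x) - 1, ncol(x))
  .assert(n_components >= 1 && n_components <= max_comp,
          "n_components must be in [1, ", max_comp, "]")
  total_var <- sum(apply(x, 2, stats::var))
  .assert(total_var > 0, "profile matrix is constant (zero total variance)")
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  load <- p$rotation[, seq_len(n_components), drop = FALSE]
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  evr <- (p$sdev^2 / total_var)[seq_len(n_components)]
  structure(list(loadings = load,
                 scores = scores,
                 explained_variance_ratio = evr,
                 center = p$center,
                 total_variance = total_var),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d component(s); explained variance ratio: %s\n",
              ncol(x$scores),
              paste(sprintf("%.3f", x$explained_variance_ratio), collapse = ", ")))
  invisible(x)
}

#' Cluster ingredients in component space and compare to chemical classes
#'
#' k-means clustering (default k = 3, mirroring the three chemical classes
#' of the worked example: saponins, glycosides, alkaloids) on the first two
#' component scores, followed by a cluster-vs-label contingency table and
#' purity (fraction of ingredients whose cluster's majority label matches
#' their own). k-means uses the session RNG; set a seed for reproducible
#' cluster assignments.
#'
#' @param pca a `pca_result` from [run_pca()] (with >= 2 components) or a
#'   numeric score matrix.
#' @param labels named character vector mapping ingredient id to chemical
#'   class (`"unknown"` allowed); must cover all ingredients.
#' @param k number of clusters; reduced (with a warning) when the data
#'   contain fewer distinct points.
#' @param nstart k-means restarts.
#' @return list with `cluster` (named integer vector), `contingency`
#'   (cluster x label table), `purity`, and `k` actually used.
#' @export
assign_groups <- function(pca, labels, k = 3, nstart = 10) {
  scores <- if (inherits(pca, "pca_result")) pca$scores else as.matrix(pca)
  .assert(ncol(scores) >= 2, "need at least 2 component scores")
  scores <- scores[, 1:2, drop = FALSE]
  ids <- rownames(scores)
  .assert(!is.null(ids), "score matrix must have ingredient rownames")
  .assert(all(ids %in% names(labels)), "labels must cover all ingredients")
  .assert(k >= 1 && k <= nrow(scores), "k must be in [1, number of ingredients]")
  distinct <- unique(scores)
  n_distinct <- nrow(distinct)
  if (k > n_distinct) {
    warning(sprintf("only %d distinct point(s); reducing k from %d", n_distinct, k))
    k <- n_distinct
  }
  cl <- if (k == 1) {
    stats::setNames(rep(1L, nrow(scores)), ids)
  } else if (k == n_distinct) {
    # each distinct point is its own cluster: the exact k-means optimum
    key <- apply(scores, 1, paste, collapse = "\r")
    stats::setNames(match(key, unique(key)), ids)
  } else {
    stats::setNames(stats::kmeans(scores, centers = k, nstart = nstart)$cluster, ids)
  }
  lab <- labels[ids]
  tab <- table(cluster = cl, label = lab)
  purity <- sum(apply(tab, 1, max)) / length(ids)
  list(cluster = cl, contingency = tab, purity = purity, k = k)
}
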