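#' Directed, pathway-labelled signaling models
#'
#' A pathway model is a directed graph whose every edge carries at least
#' one pathway label (e.g. `"IL1B"`, `"TNF"`, `"VEGFA"`), together with
#' declared feedback loops (node sets acting as self-reinforcing complexes,
#' e.g. the NFKB1-NFKB2-RELA-RELB complex) and designated downstream
#' effector (sink) nodes. Mechanism detection for ingredient pairs runs on
#' this model.
#'
#' Two conventions matter for everything downstream:
#' * a node is a *member* of pathway `L` when it has an outgoing `L` edge
#'   (it regulates something within the pathway); nodes with only incoming
#'   `L` edges are *outputs regulated by* `L`, not members;
#' * downstream reach within a pathway follows only edges of that label, so
#'   crossing into a differently-labelled edge is what constitutes
#'   cross-talk.
#'
#' @param edges data.frame with character columns `from`, `to`, `pathway`.
#' @param loops list of character vectors, each a declared feedback
#'   loop/complex of >= 2 model nodes.
#' @param sinks designated effector nodes; default all nodes with zero
#'   out-degree.
#' @return an object of class `pathway_model`: list with `graph` (directed
#'   igraph with `pathway` edge attribute), `edges`, `loops`, `sinks`,
#'   `nodes`, `labels`.
#' @export
pathway_model <- function(edges, loops = list(), sinks = NULL) {
  .assert(is.data.frame(edges) && all(c("from", "to", "pathway") %in% names(edges)),
          "edges needs columns from, to, pathway")
  .assert(nrow(edges) > 0, "pathway model has no edges")
  edges$from <- .norm_genes(edges$from)
  edges$to <- .norm_genes(edges$to)
  edges$pathway <- trimws(as.character(edges$pathway))
  .assert(all(nzchar(edges$pathway)), "every edge must carry a pathway label")
  nodes <- unique(c(edges$from, edges$to))
  loops <- lapply(loops, function(x) unique(.norm_genes(x)))
  for (lp in loops) {
    .assert(length(lp) >= 2, "feedback loops need at least 2 members")
    dangling <- setdiff(lp, nodes)
    .assert(length(dangling) == 0,
            "feedback-loop member(s) absent from the model: ",
            paste(dangling, collapse = ", "))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  if (is.null(sinks)) {
    sinks <- igraph::V(g)$name[igraph::degree(g, mode = "out") == 0]
  } else {
    sinks <- unique(.norm_genes(sinks))
    .assert(all(sinks %in% nodes), "sink(s) absent from the model")
  }
  structure(list(graph = g, edges = edges, loops = loops, sinks = sinks,
                 nodes = nodes, labels = sort(unique(edges$pathway))),
            class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %d node(s), %d edge(s), pathways: %s; %d loop(s)\n",
              length(x$nodes), nrow(x$edges),
              paste(x$labels, collapse = ", "), length(x$loops)))
  invisible(x)
}

#' Load a pathway model from a labelled edge-list file
#'
#' The file is tab/whitespace-delimited with three columns per edge line
#' (`source`, `target`, `pathway`). Directive lines declare loops and
#' sinks: `@loop A B C D` and `@sink X`. `#` lines are comments.
#'
#' @param path model file path.
#' @return a [pathway_model()].
#' @export
load_pathway_model <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  .assert(length(lines) > 0, "empty pathway-model file: ", path)
  fields <- strsplit(lines, "[[:space:]]+")
  is_loop <- vapply(fields, function(f) f[1] == "@loop", TRUE)
  is_sink <- vapply(fields, function(f) f[1] == "@sink", TRUE)
  edge_fields <- fields[!is_loop & !is_sink]
  .assert(all(vapply(edge_fields, length, 1L) == 3),
          "edge lines must have exactly source, target and pathway label: ", path)
  edges <- data.frame(from = vapply(edge_fields, `[[`, "", 1L),
                      to = vapply(edge_fields, `[[`, "", 2L),
                      pathway = vapply(edge_fields, `[[`, "", 3L),
                      stringsAsFactors = FALSE)
  loops <- lapply(fields[is_loop], function(f) f[-1])
  sinks <- if (any(is_sink)) unlist(lapply(fields[is_sink], function(f) f[-1])) else NULL
  pathway_model(edges, loops = loops, sinks = sinks)
}

# Pathway memberships: named list node -> labels of its outgoing edges.
.memberships <- function(model) {
  out <- lapply(stats::setNames(model$nodes, model$nodes), function(n) character(0))
  sp <- split(model$edges$pathway, model$edges$from)
  for (n in names(sp)) out[[n]] <- sort(unique(sp[[n]]))
  out
}

# Downstream reach of `node` following only `label` edges, node excluded.
.label_reach <- function(model, node, label) {
  keep <- which(model$edges$pathway == label)
  sub <- igraph::subgraph_from_edges(model$graph,
                                     igraph::E(model$graph)[keep],
                                     delete.vertices = FALSE)
  setdiff(igraph::as_ids(igraph::subcomponent(sub, node, mode = "out")), node)
}

# All (target, label, reach) triples for one ingredient's valid targets.
.target_arms <- function(model, targets, membership) {
  arms <- list()
  for (t in targets) {
    for (L in membership[[t]]) {
      arms[[length(arms) + 1L]] <- list(target = t, label = L,
                                        reach = .label_reach(model, t, L))
    }
  }
  arms
}

#' Enumerate synergy mechanisms between two ingredients' target sets
#'
#' Four topological patterns are recognized, each a separate predicate over
#' the pathway model (A and B are the two target sets restricted to model
#' nodes):
#'
#' * `same_pathway` - distinct targets `ta != tb` that are members of one
#'   common pathway: two hits along one signaling route.
#' * `crosstalk_convergence` - distinct targets on differently-labelled
#'   pathways whose label-restricted downstream reaches share a node: two
#'   cross-talking routes converging on a common regulator.
#' * `compensation` - distinct targets on differently-labelled pathways
#'   that feed *distinct members* of one declared feedback loop: two
#'   compensatory arms of a self-reinforcing system are blocked.
#' * `feedback_loop` - the ingredients directly hit *distinct members* of
#'   one declared loop while a `compensation` pattern on the same loop
#'   (with non-loop targets) also holds: the complex is engaged directly on
#'   two subunits and its upstream re-supply arms are disabled, so the loop
#'   cannot regenerate.
#'
#' Records are deduplicated by (kind, evidence); detection is symmetric in
#' the two ingredients and monotone in their target sets.
#'
#' @param a_targets,b_targets character target sets of the two ingredients.
#' @param model a [pathway_model()].
#' @param a_id,b_id ingredient identifiers used in the records.
#' @return data.frame with columns `a`, `b`, `kind`, `a_target`, `b_target`,
#'   `a_pathway`, `b_pathway`, `via` (convergence node, loop members, or
#'   shared pathway), zero rows when no mechanism fires.
#' @export
detect_mechanisms <- function(a_targets, b_targets, model,
                              a_id = "A", b_id = "B") {
  .assert(inherits(model, "pathway_model"), "model must be a pathway_model")
  Ta <- intersect(unique(.norm_genes(a_targets)), model$nodes)
  Tb <- intersect(unique(.norm_genes(b_targets)), model$nodes)
  empty <- data.frame(a = character(0), b = character(0), kind = character(0),
                      a_target = character(0), b_target = character(0),
                      a_pathway = character(0), b_pathway = character(0),
                      via = character(0), stringsAsFactors = FALSE)
  if (length(Ta) == 0 || length(Tb) == 0) {
    if (length(Ta) == 0 && length(Tb) == 0) {
      warning(sprintf("neither %s nor %s hits the pathway model", a_id, b_id))
    }
    return(empty)
  }
  membership <- .memberships(model)
  arms_a <- .target_arms(model, Ta, membership)
  arms_b <- .target_arms(model, Tb, membership)
  rec <- list()
  add <- function(kind, ta, tb, la, lb, via) {
    rec[[length(rec) + 1L]] <<- data.frame(
      a = a_id, b = b_id, kind = kind, a_target = ta, b_target = tb,
      a_pathway = la, b_pathway = lb, via = via, stringsAsFactors = FALSE)
  }

  # same_pathway: distinct targets sharing a pathway membership
  for (ta in Ta) for (tb in Tb) {
    if (ta == tb) next
    for (L in intersect(membership[[ta]], membership[[tb]])) {
      add("same_pathway", ta, tb, L, L, L)
    }
  }

  # crosstalk_convergence: different labels, overlapping downstream reach
  for (aa in arms_a) for (bb in arms_b) {
    if (aa$target == bb$target || aa$label == bb$label) next
    common <- intersect(aa$reach, bb$reach)
    if (length(common) > 0) {
      add("crosstalk_convergence", aa$target, bb$target, aa$label, bb$label,
          paste(sort(common), collapse = "+"))
    }
  }

  # compensation: different labels feeding distinct members of one loop
  comp_support <- list()  # per-loop-index support outside the loop, for feedback
  for (li in seq_along(model$loops)) {
    loop <- model$loops[[li]]
    for (aa in arms_a) for (bb in arms_b) {
      if (aa$target == bb$target || aa$label == bb$label) next
      ra <- intersect(aa$reach, loop)
      rb <- intersect(bb$reach, loop)
      if (length(ra) == 0 || length(rb) == 0) next
      distinct <- length(union(ra, rb)) >= 2
      if (!distinct) next
      add("compensation", aa$target, bb$target, aa$label, bb$label,
          paste(sort(unique(c(ra, rb))), collapse = "+"))
      if (!(aa$target %in% loop) && !(bb$target %in% loop)) {
        comp_support[[as.character(li)]] <- TRUE
      }
    }
  }

  # feedback_loop: distinct loop members hit directly + upstream support
  for (li in seq_along(model$loops)) {
    loop <- model$loops[[li]]
    ma <- intersect(Ta, loop)
    mb <- intersect(Tb, loop)
    if (length(ma) == 0 || length(mb) == 0 || length(union(ma, mb)) < 2) next
    if (!isTRUE(comp_support[[as.character(li)]])) next
    add("feedback_loop",
        paste(sort(ma), collapse = "+"), paste(sort(mb), collapse = "+"),
        "loop", "loop", paste(sort(loop), collapse = "+"))
  }

  if (length(rec) == 0) return(empty)
  out <- do.call(rbind, rec)
  out <- out[!duplicated(out[, c("kind", "a_target", "b_target",
                                 "a_pathway", "b_pathway", "via")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the ingredient-ingredient synergy network
#'
#' Runs [detect_mechanisms()] for every unordered ingredient pair and keeps
#' pairs with at least one mechanism. The edge weight is the number of
#' *distinct mechanism kinds* (1-4), the quantity the line width encodes in
#' the worked example's synergy figure; raw record counts are kept
#' alongside.
#'
#' @param ingredient_targets named list mapping ingredient id to its target
#'   gene set (>= 2 ingredients).
#' @param model a [pathway_model()].
#' @return an object of class `synergy_network`: list with `nodes`
#'   (ingredient ids), `edges` (data.frame `a`, `b`, `weight`, `kinds`,
#'   `n_records`) and `records` (all mechanism records, one data.frame).
#' @export
build_synergy_network <- function(ingredient_targets, model) {
  .assert(length(ingredient_targets) >= 2, "need at least 2 ingredients")
  .assert(!is.null(names(ingredient_targets)), "ingredient targets must be named")
  ids <- names(ingredient_targets)
  pairs <- utils::combn(ids, 2)
  edges <- list()
  records <- list()
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    mech <- suppressWarnings(
      detect_mechanisms(ingredient_targets[[a]], ingredient_targets[[b]],
                        model, a_id = a, b_id = b))
    if (nrow(mech) == 0) next
    records[[length(records) + 1L]] <- mech
    kinds <- sort(unique(mech$kind))
    edges[[length(edges) + 1L]] <- data.frame(
      a = a, b = b, weight = length(kinds),
      kinds = paste(kinds, collapse = ","), n_records = nrow(mech),
      stringsAsFactors = FALSE)
  }
  edges <- if (length(edges) > 0) do.call(rbind, edges) else
    data.frame(a = character(0), b = character(0), weight = integer(0),
               kinds = character(0), n_records = integer(0),
               stringsAsFactors = FALSE)
  records <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(a = character(0), b = character(0), kind = character(0),
               a_target = character(0), b_target = character(0),
               a_pathway = character(0), b_pathway = character(0),
               via = character(0), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(nodes = ids, edges = edges, records = records),
            class = "synergy_network")
}

#' @export
print.synergy_network <- function(x, ...) {
  cat(sprintf("<synergy_network> %d ingredient(s), %d synergistic pair(s)\n",
              length(x$nodes), nrow(x$edges)))
  if (nrow(x$edges) > 0) {
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("  %s -- %s  weight %d  (%s)\n", x$edges$a[i], x$edges$b[i],
                  x$edges$weight[i], x$edges$kinds[i]))
    }
  }
  invisible(x)
}
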