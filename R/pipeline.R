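#' Default pipeline configuration
#'
#' Returns the full configuration list with the standard operating points:
#' profile size `k = 100`, enrichment threshold `alpha = 0.05`, one-hop
#' disease-network expansion, Gaussian closeness kernel, Pearson
#' concordance, 2 principal components and 3 ingredient clusters. Path
#' entries are `NULL` and must be supplied by the caller (or by
#' [write_synthetic_inputs()] for a fully synthetic run).
#'
#' @param ... named overrides of any default.
#' @return configuration list for [run_pipeline()].
#' @export
default_config <- function(...) {
  cfg <- list(
    # input paths
    ingredients = NULL,        # SMILES/SDF path, named vector (names = herbs),
                               # or fingerprint TSV (read_fingerprints format)
    references = NULL,         # reference drug structures or fingerprint TSV
    reference_targets = NULL,  # drug-target TSV (drug, gene)
    ppi = NULL,                # interaction network (SIF or TSV)
    seeds_known = NULL, seeds_predicted = NULL, seeds_drug_targets = NULL,
    gene_sets = NULL,          # GMT
    pathway_model = NULL,      # labelled edge list with @loop/@sink directives
    adverse_genes = NULL,      # optional gene list
    chemical_classes = NULL,   # optional TSV (ingredient, class) for clustering
    out_dir = "herbnet_out",
    # operating points
    k = 100, alpha = 0.05, expansion_depth = 1,
    n_components = 2, n_clusters = 3,
    fingerprint_type = "FP2",
    kernel = "gaussian", method = "pearson",
    profile_encoding = "binary",
    seed = 1)
  over <- list(...)
  .assert(all(names(over) %in% names(cfg)),
          "unknown config field(s): ",
          paste(setdiff(names(over), names(cfg)), collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Load a YAML configuration file
#'
#' Fields mirror [default_config()]; unspecified fields keep their
#' defaults. Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
read_config <- function(path) {
  .assert(file.exists(path), "config file not found: ", path)
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  base <- dirname(normalizePath(path))
  path_fields <- c("ingredients", "references", "reference_targets", "ppi",
                   "seeds_known", "seeds_predicted", "seeds_drug_targets",
                   "gene_sets", "pathway_model", "adverse_genes",
                   "chemical_classes")
  for (f in path_fields) {
    p <- cfg[[f]]
    if (!is.null(p)) {
      resolved <- ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
      cfg[[f]] <- stats::setNames(resolved, names(p))
    }
  }
  cfg
}

# Load a compound input that may be structures or a fingerprint table.
.load_compound_input <- function(spec, default_herb, fp_type) {
  .assert(!is.null(spec), "missing compound input path")
  load_one <- function(path, herb) {
    if (grepl("\\.(smi|smiles|sdf)$", path, ignore.case = TRUE)) {
      load_compounds(path, herb_label = herb, fp_type = fp_type)
    } else {
      read_fingerprints(path)
    }
  }
  if (length(spec) == 1) {
    herb <- if (!is.null(names(spec)) && nzchar(names(spec)[1])) names(spec)[1]
            else default_herb
    return(load_one(unname(spec), herb))
  }
  .assert(!is.null(names(spec)), "multiple compound files need herb names")
  sets <- lapply(seq_along(spec), function(i)
    load_one(unname(spec[i]), names(spec)[i]))
  .assert(length(unique(vapply(sets, function(s) ncol(s$fingerprints), 1L))) == 1,
          "fingerprint lengths differ between compound files")
  compound_set(unlist(lapply(sets, `[[`, "ids")),
               do.call(rbind, lapply(sets, `[[`, "fingerprints")),
               herbs = unlist(lapply(sets, `[[`, "herbs")),
               smiles = unlist(lapply(sets, `[[`, "smiles")))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full network-pharmacology pipeline
#'
#' Executes the five analysis tracks in order - target profiles, PCA
#' clustering, disease/herb network construction, gene-set enrichment and
#' synergy detection - and writes all outputs plus a run manifest (package
#' version, configuration, input checksums) to `config$out_dir`.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @return invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- do.call(default_config, config[!vapply(config, is.null, TRUE)])
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  out <- function(f) file.path(cfg$out_dir, f)

  # ---- inputs -------------------------------------------------------------
  ingredients <- .stage("inputs", .load_compound_input(
    cfg$ingredients, "formula", cfg$fingerprint_type))
  references <- .stage("inputs", .load_compound_input(
    cfg$references, "reference", cfg$fingerprint_type))
  reference_targets <- .stage("inputs", read_drug_targets(cfg$reference_targets))
  ppi <- .stage("inputs", suppressMessages(load_network(cfg$ppi)))

  # ---- stage 1: target profiles ------------------------------------------
  profiles <- .stage("profile", {
    p <- formula_profiles(ingredients, references, reference_targets, ppi,
                          k = cfg$k, kernel = cfg$kernel, method = cfg$method)
    write_profiles(p, out("profiles.tsv"))
    write_tsv(integrative_targets(p), out("integrative_targets.tsv"),
              module = "target_inference")
    sim <- similarity_matrix(ingredients, references)
    write_tsv(data.frame(ingredient = rownames(sim), sim,
                         check.names = FALSE, stringsAsFactors = FALSE),
              out("similarity.tsv"), module = "chem_space")
    p
  })

  # ---- stage 2: PCA clustering -------------------------------------------
  cluster <- .stage("cluster", {
    m <- build_profile_matrix(profiles, encoding = cfg$profile_encoding)
    pca <- run_pca(m, n_components = min(cfg$n_components,
                                         nrow(m) - 1, ncol(m)))
    labels <- if (!is.null(cfg$chemical_classes)) {
      cc <- read_tsv(cfg$chemical_classes)
      stats::setNames(cc$class, cc$ingredient)
    } else attr(profiles, "herbs")
    labels[setdiff(rownames(m), names(labels))] <- "unknown"
    grp <- assign_groups(pca, labels,
                         k = min(cfg$n_clusters, nrow(m)))
    write_tsv(data.frame(ingredient = rownames(pca$scores), pca$scores,
                         label = unname(labels[rownames(pca$scores)]),
                         cluster = unname(grp$cluster[rownames(pca$scores)]),
                         check.names = FALSE, stringsAsFactors = FALSE),
              out("pca_scores.tsv"), module = "profile_analytics")
    write_tsv(data.frame(gene = rownames(pca$loadings), pca$loadings,
                         check.names = FALSE, stringsAsFactors = FALSE),
              out("pca_loadings.tsv"), module = "profile_analytics")
    write_tsv(data.frame(component = seq_along(pca$explained_variance_ratio),
                         explained_variance_ratio = pca$explained_variance_ratio),
              out("pca_variance.tsv"), module = "profile_analytics")
    list(matrix = m, pca = pca, groups = grp)
  })

  # ---- stage 3: disease and herb target networks --------------------------
  network <- .stage("network", {
    seeds <- assemble_seeds(
      known = if (!is.null(cfg$seeds_known)) read_gene_list(cfg$seeds_known) else character(),
      predicted = if (!is.null(cfg$seeds_predicted)) read_gene_list(cfg$seeds_predicted) else character(),
      drug_targets = if (!is.null(cfg$seeds_drug_targets)) read_gene_list(cfg$seeds_drug_targets) else character())
    dn <- suppressWarnings(expand_to_disease_network(seeds, ppi,
                                                     depth = cfg$expansion_depth))
    write_sif(dn$graph, out("disease_network.sif"))
    nodes <- igraph::V(dn$graph)$name
    sd <- dn$seeds[match(nodes, dn$seeds$gene), , drop = FALSE]
    write_node_attributes(
      data.frame(gene = nodes, layer = unname(dn$layer[nodes]),
                 known = !is.na(sd$gene) & sd$known,
                 predicted = !is.na(sd$gene) & sd$predicted,
                 drug_target = !is.na(sd$gene) & sd$drug_target,
                 stringsAsFactors = FALSE),
      out("disease_network_nodes.tsv"), module = "disease_network")
    herbs <- attr(profiles, "herbs")
    adverse <- if (!is.null(cfg$adverse_genes)) read_gene_list(cfg$adverse_genes) else character()
    herb_nets <- lapply(unique(herbs), function(h) {
      suppressWarnings(map_herb_targets(profiles[names(herbs)[herbs == h]],
                                        dn, herb = h))
    })
    names(herb_nets) <- unique(herbs)
    herb_nets <- lapply(names(herb_nets), function(h) {
      flag_off_targets(herb_nets[[h]], adverse,
                       other_herb_nets = herb_nets[setdiff(names(herb_nets), h)])
    })
    names(herb_nets) <- unique(herbs)
    herb_rows <- do.call(rbind, lapply(herb_nets, function(hn) {
      if (length(hn$mapped_targets) == 0) return(NULL)
      data.frame(herb = hn$herb, gene = hn$mapped_targets,
                 ingredients = vapply(hn$contributors[hn$mapped_targets],
                                      paste, "", collapse = ","),
                 off_target = hn$mapped_targets %in% hn$off_target_flags,
                 counteracted_by = vapply(hn$mapped_targets, function(g)
                   if (g %in% names(hn$counteracted_by))
                     paste(hn$counteracted_by[[g]], collapse = ",") else "",
                   ""),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(herb_rows)) herb_rows <- data.frame(
      herb = character(0), gene = character(0), ingredients = character(0),
      off_target = logical(0), counteracted_by = character(0))
    write_tsv(herb_rows, out("herb_targets.tsv"), module = "disease_network")
    list(seeds = seeds, disease_network = dn, herb_networks = herb_nets)
  })

  # ---- stage 4: gene-set enrichment ---------------------------------------
  enrichment <- .stage("enrich", {
    collection <- read_gmt(cfg$gene_sets, background = igraph::V(ppi)$name)
    query_sets <- c(list(formula = integrative_targets(profiles)$gene),
                    lapply(network$herb_networks, `[[`, "mapped_targets"))
    res <- do.call(rbind, lapply(names(query_sets), function(nm) {
      q <- intersect(query_sets[[nm]], collection$background)
      if (length(q) == 0) return(NULL)
      r <- enrich_network(q, collection, alpha = cfg$alpha)
      if (nrow(r) == 0) return(NULL)
      cbind(query = nm, r, stringsAsFactors = FALSE)
    }))
    if (is.null(res)) res <- data.frame(query = character(0))
    write_tsv(res, out("enrichment.tsv"), module = "enrichment")
    res
  })

  # ---- stage 5: synergy ----------------------------------------------------
  synergy <- .stage("synergy", {
    model <- load_pathway_model(cfg$pathway_model)
    targets <- lapply(profiles, function(p) intersect(p$genes, model$nodes))
    net <- build_synergy_network(targets, model)
    write_tsv(net$edges, out("synergy.tsv"), module = "synergy")
    write_tsv(net$records, out("synergy_records.tsv"), module = "synergy")
    net
  })

  # ---- manifest ------------------------------------------------------------
  manifest <- .stage("manifest", {
    inputs <- Filter(Negate(is.null), cfg[c(
      "ingredients", "references", "reference_targets", "ppi", "seeds_known",
      "seeds_predicted", "seeds_drug_targets", "gene_sets", "pathway_model",
      "adverse_genes", "chemical_classes")])
    checksums <- lapply(inputs, function(p)
      unname(tools::md5sum(normalizePath(unname(p)))))
    outputs <- list.files(cfg$out_dir, pattern = "\\.(tsv|sif)$")
    man <- list(package = "herbnet",
                version = as.character(utils::packageVersion("herbnet")),
                config = cfg[setdiff(names(cfg), "out_dir")],
                config_hash = .config_hash(cfg),
                input_checksums = checksums,
                outputs = sort(outputs))
    jsonlite::write_json(man, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
    man
  })
  invisible(list(profiles = profiles, cluster = cluster, network = network,
                 enrichment = enrichment, synergy = synergy,
                 manifest = manifest, config = cfg))
}

.config_hash <- function(cfg) {
  flat <- cfg[setdiff(names(cfg), "out_dir")]
  s <- jsonlite::toJSON(flat[order(names(flat))], auto_unbox = TRUE, null = "null")
  # small rolling hash; avoids a digest dependency for a provenance tag
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Validate a pipeline output manifest
#'
#' Checks that the manifest parses, that every listed output file exists in
#' the directory, and that recorded input checksums still match the inputs
#' (when they are still present).
#'
#' @param out_dir pipeline output directory.
#' @return `TRUE` (invisibly) if valid; otherwise an error.
#' @export
validate_manifest <- function(out_dir) {
  path <- file.path(out_dir, "manifest.json")
  .assert(file.exists(path), "no manifest.json in ", out_dir)
  man <- jsonlite::read_json(path)
  .assert(identical(man$package, "herbnet"), "manifest not produced by herbnet")
  missing <- setdiff(unlist(man$outputs), list.files(out_dir))
  .assert(length(missing) == 0, "missing output file(s): ",
          paste(missing, collapse = ", "))
  for (nm in names(man$input_checksums)) {
    p <- man$config[[nm]]
    if (is.character(p) && length(p) == 1 && file.exists(p)) {
      .assert(identical(unname(tools::md5sum(normalizePath(p)))[[1]],
                        man$input_checksums[[nm]]),
              "checksum mismatch for input: ", nm)
    }
  }
  invisible(TRUE)
}

#' Write a complete synthetic input bundle for the pipeline
#'
#' Materializes a [generate_space()] world as pipeline input files:
#' interaction network, reference fingerprints and drug-target table, one
#' query ingredient per family (fingerprint TSV with the family as herb
#' label), planted-truth table, seed lists, a module-based GMT collection
#' and a small labelled pathway model with one declared feedback loop.
#' Together with the returned config the bundle drives a fully synthetic
#' end-to-end [run_pipeline()] run.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed passed to [generate_space()].
#' @param ... further arguments to [generate_space()].
#' @return configuration list (paths filled in), invisibly.
#' @export
write_synthetic_inputs <- function(dir, seed = 42, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  space <- generate_space(seed = seed, ...)
  nf <- space$params$n_families
  write_edgelist(space$ppi, file.path(dir, "ppi.tsv"))
  write_fingerprints(space$reference_drugs, file.path(dir, "ref_fingerprints.tsv"))
  write_drug_targets(space$reference_targets, file.path(dir, "ref_targets.tsv"))
  queries <- lapply(seq_len(nf), function(f) generate_query(space, f))
  qset <- compound_set(vapply(queries, `[[`, "", "id"),
                       do.call(rbind, lapply(queries, `[[`, "fingerprint")),
                       herbs = sprintf("herb%d", seq_len(nf)))
  write_fingerprints(qset, file.path(dir, "ingredient_fingerprints.tsv"))
  write_tsv(do.call(rbind, lapply(queries, function(q)
    data.frame(ingredient = q$id, gene = q$planted_targets,
               stringsAsFactors = FALSE))),
    file.path(dir, "truth.tsv"), module = "synthetic_data")
  m1 <- space$modules[[1]]
  m2 <- space$modules[[min(2, nf)]]
  writeLines(c("# synthetic seeds", utils::head(m1, 5)),
             file.path(dir, "seeds_known.txt"))
  writeLines(m1[6:min(10, length(m1))], file.path(dir, "seeds_predicted.txt"))
  writeLines(utils::head(m2, 5), file.path(dir, "seeds_drug_targets.txt"))
  gmt <- vapply(seq_len(nf), function(f)
    paste(c(sprintf("MODULE%d", f), sprintf("Module|family %d module genes", f),
            space$modules[[f]]), collapse = "\t"), "")
  writeLines(gmt, file.path(dir, "gene_sets.gmt"))
  model_lines <- if (nf >= 2) sprintf("@loop\t%s\t%s", m1[4], m2[4]) else character(0)
  for (f in seq_len(nf)) {
    g <- utils::head(space$modules[[f]], 4)
    model_lines <- c(model_lines,
                     sprintf("%s\t%s\tP%d", g[1:3], g[2:4], f))
  }
  writeLines(model_lines, file.path(dir, "pathway_model.tsv"))
  n_genes <- nf * space$params$genes_per_module
  cfg <- default_config(
    # keep profiles below the universe size so they stay discriminative
    k = min(100L, max(2L, n_genes %/% 4L)),
    ingredients = file.path(dir, "ingredient_fingerprints.tsv"),
    references = file.path(dir, "ref_fingerprints.tsv"),
    reference_targets = file.path(dir, "ref_targets.tsv"),
    ppi = file.path(dir, "ppi.tsv"),
    seeds_known = file.path(dir, "seeds_known.txt"),
    seeds_predicted = file.path(dir, "seeds_predicted.txt"),
    seeds_drug_targets = file.path(dir, "seeds_drug_targets.txt"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    pathway_model = file.path(dir, "pathway_model.tsv"),
    out_dir = file.path(dir, "out"),
    seed = seed)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, TRUE)],
                   file.path(dir, "config.yaml"))
  invisible(cfg)
}
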