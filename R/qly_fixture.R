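#' The packaged Qing-Luo-Yin worked-example fixture
#'
#' A small, versioned transcription of the published rheumatoid-arthritis
#' worked example for the four-herb formula Qing-Luo-Yin (QLY): the five
#' major ingredients with their reported protein targets, the manually
#' curated RA signaling model (TNF-, IL1B- and VEGFA-induced routes
#' converging on the NF-kB system, with the NFKB1-NFKB2-RELA-RELB complex
#' declared as a feedback loop), a matching miniature undirected
#' interaction network, RA seed-gene lists in three provenance classes, a
#' small annotation collection themed on the reported enriched functions,
#' the adverse-effect gene list (PTGS1), and additional minor ingredients
#' used in the off-target/counteraction example. The interaction network,
#' seed lists and gene sets are synthetic stand-ins shaped around the
#' published gene names (the original databases are not redistributable);
#' the ingredient targets and pathway model are transcribed from the
#' published figure and text.
#'
#' Major ingredients and herbs: Matrine and Kurarinone (Ku-Shen),
#' Sinomenine (Qing-Feng-Teng), Berberine (Huang-Bai), Diosgenin (Bi-Xie).
#'
#' @return list with elements `major_targets` (named list ingredient ->
#'   target genes), `herbs` (ingredient -> herb), `pathway_model`
#'   ([pathway_model()]), `ppi` (igraph), `seeds` (list `known`,
#'   `predicted`, `drug_target`), `gene_sets` ([gene_set_collection()] with
#'   the mini-network nodes as background), `adverse_genes`,
#'   `minor_targets` (data.frame ingredient/herb/gene).
#' @export
qly_fixture <- function() {
  dir <- system.file("extdata", "qly_fig3", package = "herbnet")
  .assert(nzchar(dir), "packaged qly_fig3 fixture not found")
  tg <- utils::read.delim(file.path(dir, "ingredient_targets.tsv"),
                          comment.char = "#", stringsAsFactors = FALSE)
  major_targets <- lapply(split(tg$gene, tg$ingredient), unique)
  herbs <- vapply(split(tg$herb, tg$ingredient), `[[`, "", 1L)
  # preserve the canonical ingredient order of the worked example
  ord <- unique(tg$ingredient)
  major_targets <- major_targets[ord]
  herbs <- herbs[ord]
  minor <- utils::read.delim(file.path(dir, "minor_ingredient_targets.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
  ppi <- suppressMessages(load_network(file.path(dir, "ppi_mini.tsv")))
  seeds <- list(
    known = .read_gene_list(file.path(dir, "seeds_known.txt")),
    predicted = .read_gene_list(file.path(dir, "seeds_predicted.txt")),
    drug_target = .read_gene_list(file.path(dir, "seeds_drug_targets.txt")))
  list(major_targets = major_targets,
       herbs = herbs,
       pathway_model = load_pathway_model(file.path(dir, "pathway_model.tsv")),
       ppi = ppi,
       seeds = seeds,
       gene_sets = read_gmt(file.path(dir, "gene_sets.gmt"),
                            background = igraph::V(ppi)$name),
       adverse_genes = .read_gene_list(file.path(dir, "adverse_genes.txt")),
       minor_targets = minor)
}

#' Read a one-gene-per-line list file
#'
#' Blank lines and `#` comments are skipped; symbols are
#' uppercase-normalized.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) .read_gene_list(path)

.read_gene_list <- function(path) {
  .assert(file.exists(path), "file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  unique(.norm_genes(lines[nzchar(lines) & !startsWith(lines, "#")]))
}
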