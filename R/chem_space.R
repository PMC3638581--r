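#' Compound collections
#'
#' A `compound_set` holds the ingredients (or reference drugs) of one
#' analysis: identifiers, herb-of-origin labels, structures (canonical
#' SMILES where available) and a fixed-length binary fingerprint per
#' compound. All fingerprints in one set have identical length, so a set
#' can be used directly as one axis of the drug space.
#'
#' @param ids character vector of unique compound identifiers.
#' @param fingerprints numeric/logical 0-1 matrix, one row per compound.
#' @param herbs herb-of-origin label(s), recycled to `length(ids)`.
#' @param smiles optional canonical SMILES strings (NA for synthetic
#'   fingerprints that have no structure).
#' @return an object of class `compound_set`.
#' @export
compound_set <- function(ids, fingerprints, herbs = "reference", smiles = NA_character_) {
  ids <- as.character(ids)
  fingerprints <- as.matrix(fingerprints)
  storage.mode(fingerprints) <- "integer"
  .assert(length(ids) == nrow(fingerprints),
          "number of ids must match fingerprint rows")
  .assert(all(fingerprints %in% c(0L, 1L)), "fingerprints must be binary")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("duplicate compound id(s) %s: last-loaded record wins",
                    paste(dup, collapse = ", ")))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]
    fingerprints <- fingerprints[keep, , drop = FALSE]
    herbs <- rep_len(herbs, length(keep))[keep]
    smiles <- rep_len(smiles, length(keep))[keep]
  }
  rownames(fingerprints) <- ids
  structure(list(ids = ids,
                 herbs = rep_len(as.character(herbs), length(ids)),
                 smiles = rep_len(as.character(smiles), length(ids)),
                 fingerprints = fingerprints),
            class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat(sprintf("<compound_set> %d compound(s), %d-bit fingerprints, herbs: %s\n",
              length(x$ids), ncol(x$fingerprints),
              paste(unique(x$herbs), collapse = ", ")))
  invisible(x)
}

#' @export
length.compound_set <- function(x) length(x$ids)

#' Subset a compound set
#' @param x a `compound_set`.
#' @param i index or id vector.
#' @param ... unused.
#' @export
`[.compound_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$ids)
  compound_set(x$ids[i], x$fingerprints[i, , drop = FALSE],
               x$herbs[i], x$smiles[i])
}

#' Load compounds from a SMILES or SDF file
#'
#' SMILES files are two-column whitespace-delimited (`id`, `smiles`), one
#' record per line; lines starting with `#` are skipped. SDF files are read
#' with ChemmineR. Records whose structure does not parse to a valid
#' molecule are skipped with a logged count; fingerprints are computed with
#' OpenBabel for every retained compound.
#'
#' @param path path to the structure file.
#' @param herb_label herb-of-origin label attached to every compound.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @param fp_type OpenBabel fingerprint name; the default `"FP2"` is a
#'   hashed linear-fragment (path) fingerprint of 1024 bits.
#' @return a [compound_set()].
#' @export
load_compounds <- function(path, herb_label = "reference",
                           format = c("auto", "smiles", "sdf"),
                           fp_type = "FP2") {
  format <- match.arg(format)
  .assert(file.exists(path), "file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"
  }
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    .assert(length(lines) > 0, "empty structure file: ", path)
    fields <- strsplit(lines, "[[:space:]]+")
    bad <- vapply(fields, length, 1L) < 2L
    ids <- vapply(fields[!bad], `[[`, "", 1L)
    smi <- vapply(fields[!bad], `[[`, "", 2L)
    ok <- vapply(seq_along(smi), function(i) {
      tryCatch({
        sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi[i], ids[i])))
        sum(ChemmineR::atomcount(sdf)[[1]]) >= 1
      }, error = function(e) FALSE)
    }, TRUE)
    n_skipped <- sum(bad) + sum(!ok)
    if (n_skipped > 0) {
      message(sprintf("load_compounds: skipped %d unparseable record(s) in %s",
                      n_skipped, path))
    }
    .assert(any(ok), "no parseable structure records in file: ", path)
    ids <- ids[ok]
    smi <- smi[ok]
    sdfset <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi, ids)))
  } else {
    sdfset <- ChemmineR::read.SDFset(path)
    valid <- ChemmineR::validSDF(sdfset)
    if (sum(!valid) > 0) {
      message(sprintf("load_compounds: skipped %d invalid SDF record(s) in %s",
                      sum(!valid), path))
    }
    .assert(sum(valid) > 0, "no parseable structure records in file: ", path)
    sdfset <- sdfset[valid]
    ids <- ChemmineR::sdfid(sdfset)
    smi <- tryCatch(ChemmineR::sdf2smiles(sdfset),
                    error = function(e) rep(NA_character_, length(ids)))
    smi <- as.character(smi)
  }
  # duplicate ids are legal here (compound_set resolves them with its own
  # warning), so silence ChemmineR's non-unique-id advisory
  fp <- suppressWarnings(ChemmineR::fingerprintOB(sdfset, fp_type))
  m <- methods::slot(fp, "fpma")  # FPset bit matrix, rows in input order
  compound_set(ids, m, herbs = herb_label, smiles = smi)
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' `|a AND b| / |a OR b|`. By convention two all-zero (featureless)
#' fingerprints have similarity 1, with a warning, so that degenerate
#' inputs stay visible rather than producing 0/0.
#'
#' @param a,b equal-length binary (0/1 or logical) vectors.
#' @return a number in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  .assert(length(a) == length(b), "fingerprint length mismatch: ",
          length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0) {
    warning("both fingerprints are all-zero; returning similarity 1 by convention")
    return(1)
  }
  sum(a & b) / u
}

#' Structure-similarity vector of a query against a reference drug set
#'
#' The drug-space axis: element `i` is the Tanimoto similarity between the
#' query fingerprint and reference drug `i`, in the fixed reference order.
#'
#' @param query a binary fingerprint vector, or a single-compound
#'   [compound_set()].
#' @param references a [compound_set()] of at least 2 reference drugs.
#' @return named numeric vector (names = reference ids), values in \[0,1\].
#' @export
similarity_vector <- function(query, references) {
  qfp <- if (inherits(query, "compound_set")) {
    .assert(length(query$ids) == 1, "query must be a single compound")
    query$fingerprints[1, ]
  } else as.integer(as.logical(query))
  .assert(inherits(references, "compound_set"), "references must be a compound_set")
  .assert(length(references$ids) >= 2, "need at least 2 reference drugs")
  vapply(seq_along(references$ids), function(i) {
    tanimoto(qfp, references$fingerprints[i, ])
  }, 0, USE.NAMES = FALSE) -> v
  stats::setNames(v, references$ids)
}

#' Pairwise similarity matrix between two compound sets
#'
#' @param queries,references [compound_set()] objects with equal
#'   fingerprint lengths.
#' @return matrix of Tanimoto similarities, query rows x reference columns.
#' @export
similarity_matrix <- function(queries, references) {
  .assert(ncol(queries$fingerprints) == ncol(references$fingerprints),
          "fingerprint length mismatch between sets")
  A <- queries$fingerprints
  B <- references$fingerprints
  inter <- A %*% t(B)
  na <- rowSums(A)
  nb <- rowSums(B)
  un <- outer(na, nb, `+`) - inter
  s <- ifelse(un == 0, 1, inter / un)
  if (any(un == 0)) {
    warning("all-zero fingerprint pair(s); similarity 1 by convention")
  }
  dimnames(s) <- list(queries$ids, references$ids)
  s
}
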