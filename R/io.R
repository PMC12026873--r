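# Plain-text readers and writers for the pipeline's interchange formats:
# GMT annotation collections, STRING-style edge tables, SMILES lists,
# bit-string fingerprint tables and ligand (target) databases. Fixed column
# orders; everything round-trips through the matching reader.

#' Write an annotation collection as GMT
#'
#' One term per line: term_id, description, then tab-separated genes.
#'
#' @param collection List of `GeneSet`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection, function(ts) {
    paste(c(ts$term_id, ts$term_name, ts$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT annotation collection
#'
#' @param path GMT file.
#' @param namespace Namespace label attached to every term.
#' @return List of `GeneSet`s.
#' @export
read_gmt <- function(path, namespace = "pathway") {
  if (!file.exists(path)) np_stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) np_stop("GMT line with fewer than 3 fields: ", ln)
    structure(list(term_id = f[1], term_name = f[2],
                   genes = normalize_symbols(f[-(1:2)]),
                   namespace = namespace),
              class = "GeneSet")
  })
}

#' Write a STRING-style edge table
#'
#' @param edges data.frame: node1, node2, combined_score.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(edges, path) {
  write_tsv(edges[, c("node1", "node2", "combined_score")], path)
}

#' Write compounds as a SMILES file (smiles TAB id)
#'
#' @param compounds data.frame with columns `smiles` and `id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(compounds, path) {
  writeLines(paste(compounds$smiles, compounds$id, sep = "\t"), path)
  invisible(path)
}

#' Write a fingerprint matrix as a bit-string TSV
#'
#' Columns: id, fingerprint (a 0/1 character string, one char per bit).
#'
#' @param fingerprints 0/1 matrix with ids as row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fingerprints, path) {
  write_tsv(data.frame(
    id = rownames(fingerprints),
    fingerprint = apply(fingerprints, 1, paste, collapse = ""),
    stringsAsFactors = FALSE), path)
}

#' Read a bit-string fingerprint TSV
#'
#' @param path TSV written by [write_fingerprints()].
#' @return 0/1 integer matrix with ids as row names.
#' @export
read_fingerprints <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  bits <- strsplit(df$fingerprint, "", fixed = TRUE)
  len <- unique(lengths(bits))
  if (length(len) != 1) np_stop("inconsistent fingerprint lengths in ", path)
  m <- matrix(as.integer(unlist(bits)), nrow = nrow(df), byrow = TRUE,
              dimnames = list(df$id, NULL))
  if (any(is.na(m)) || any(!m %in% c(0L, 1L))) {
    np_stop("fingerprint strings must contain only 0 and 1 in ", path)
  }
  m
}

#' Write a ligand universe as a target-database TSV
#'
#' Columns: target_id, gene_symbol, ligand_id, fingerprint (bit string).
#'
#' @param universe_out Output of [generate_ligand_universe()] or a list of
#'   `TargetSet`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_db <- function(universe_out, path) {
  universe <- if (!is.null(universe_out$universe)) universe_out$universe
              else universe_out
  rows <- do.call(rbind, lapply(universe, function(ts) {
    data.frame(target_id = ts$target_id, gene_symbol = ts$gene_symbol,
               ligand_id = rownames(ts$ligands),
               fingerprint = apply(ts$ligands, 1, paste, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(target_id = character(0), gene_symbol = character(0),
                       ligand_id = character(0), fingerprint = character(0))
  }
  write_tsv(rows, path)
}

#' Read a target-database TSV into a ligand universe
#'
#' @param path TSV written by [write_target_db()].
#' @return List of `TargetSet`s.
#' @export
read_target_db <- function(path) {
  df <- read_tsv(path, colClasses = "character")
  need <- c("target_id", "gene_symbol", "ligand_id", "fingerprint")
  if (!all(need %in% names(df))) {
    np_stop("target DB must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$target_id), function(g) {
    bits <- strsplit(g$fingerprint, "", fixed = TRUE)
    m <- matrix(as.integer(unlist(bits)), nrow = nrow(g), byrow = TRUE,
                dimnames = list(g$ligand_id, NULL))
    structure(list(target_id = g$target_id[1],
                   gene_symbol = g$gene_symbol[1], ligands = m),
              class = "TargetSet")
  })
  out[order(names(out))]
}
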