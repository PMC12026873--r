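# Optional chemistry route: hashed circular fingerprints from SMILES.
#
# The pipeline's statistics operate on plain bit vectors; this module maps
# real structures onto the same representation. Structures are parsed and
# canonicalized with Open Babel (via ChemmineOB), then fingerprinted with a
# Morgan-style circular hash over the heavy-atom graph: each atom's
# neighborhood identifier at radii 0..radius sets one bit. All hashing uses
# order-invariant atom invariants, so any SMILES of one molecule yields the
# same fingerprint.

# Deterministic 31-bit integer hash of an integer vector (exact in doubles).
hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% 2147483647) + 1) %% 2147483647
  h
}

# Parse the atom and bond blocks of a V2000 molfile text.
parse_v2000 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  n_atoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  n_bonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n_atoms) || n_atoms < 1) return(NULL)
  atom_lines <- lines[4 + seq_len(n_atoms)]
  elements <- trimws(substr(atom_lines, 32, 34))
  charges <- integer(n_atoms)
  bonds <- if (n_bonds > 0) {
    bl <- lines[4 + n_atoms + seq_len(n_bonds)]
    cbind(a = as.integer(substr(bl, 1, 3)),
          b = as.integer(substr(bl, 4, 6)),
          order = as.integer(substr(bl, 7, 9)))
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("a", "b", "order")))
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    n <- f[1]
    for (k in seq_len(n)) charges[f[2 * k]] <- f[2 * k + 1]
  }
  list(elements = elements, charges = charges, bonds = bonds)
}

#' Hashed circular fingerprint from a SMILES string
#'
#' Canonicalizes the SMILES with Open Babel, then hashes each heavy atom's
#' circular neighborhood at radii 0..`radius` into an `nbits`-long 0/1
#' vector. Atom invariants are (element, heavy degree, total bond order,
#' formal charge); neighbor contributions are sorted before hashing, so the
#' result does not depend on atom numbering or SMILES writing order.
#'
#' @param smiles A single SMILES string.
#' @param nbits Fingerprint length in bits (default 2048).
#' @param radius Circular neighborhood radius (default 2).
#' @return 0/1 integer vector of length `nbits`.
#' @export
fingerprint_from_smiles <- function(smiles, nbits = 2048, radius = 2) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    np_stop("fingerprint_from_smiles requires the ChemmineOB package")
  }
  nbits <- check_count(nbits, "nbits", positive = TRUE)
  radius <- check_count(radius, "radius")
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles))) {
    np_stop("smiles must be a single non-empty string")
  }
  can <- tryCatch(
    trimws(sub("\t.*", "", ChemmineOB::convertFormat(
      "SMI", "CAN", source = paste0(smiles, " m\n")))),
    error = function(e) "")
  if (!nzchar(can)) np_stop("unparseable SMILES: '", smiles, "'")
  sdf <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", source = paste0(can, " m\n")),
    error = function(e) "")
  mol <- parse_v2000(sdf)
  if (is.null(mol)) np_stop("unparseable SMILES: '", smiles, "'")

  n <- length(mol$elements)
  elem_code <- as.integer(factor(mol$elements,
    levels = c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
               sort(setdiff(unique(mol$elements),
                            c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                              "Cl", "Br", "I"))))))
  nbr <- vector("list", n)
  deg <- integer(n)
  bsum <- integer(n)
  if (nrow(mol$bonds) > 0) {
    for (i in seq_len(nrow(mol$bonds))) {
      a <- mol$bonds[i, "a"]; b <- mol$bonds[i, "b"]
      o <- mol$bonds[i, "order"]
      nbr[[a]] <- rbind(nbr[[a]], c(b, o))
      nbr[[b]] <- rbind(nbr[[b]], c(a, o))
      deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
      bsum[a] <- bsum[a] + o; bsum[b] <- bsum[b] + o
    }
  }
  ids <- vapply(seq_len(n), function(i) {
    hash_ints(c(elem_code[i], deg[i], bsum[i], mol$charges[i] + 8L))
  }, 0)
  fp <- integer(nbits)
  fp[(ids %% nbits) + 1] <- 1L
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        if (is.null(nbr[[i]])) return(hash_ints(c(r, ids[i])))
        contrib <- cbind(nbr[[i]][, 2], ids[nbr[[i]][, 1]])
        contrib <- contrib[order(contrib[, 1], contrib[, 2]), , drop = FALSE]
        hash_ints(c(r, ids[i], as.vector(t(contrib))))
      }, 0)
      ids <- new_ids
      fp[(ids %% nbits) + 1] <- 1L
    }
  }
  fp
}
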