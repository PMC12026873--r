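# Synthetic-data generators: every pipeline input with known ground truth,
# so each downstream stage has a recovery test without any database download.
# Fingerprints are plain fixed-length bit vectors generated directly; the
# statistical structure (within-target ligand similarity, planted expression
# shifts, planted enrichment, random PPI edges) is what matters here, not
# real chemistry or biology.

#' Construct an (initially empty) ground-truth record
#'
#' A `SyntheticTruth` collects everything the generators planted: the
#' differentially expressed genes and their log2 effects, the truly
#' associated (compound, target) pairs, and the enriched annotation terms.
#' Recovery tests compare pipeline output against this record.
#'
#' @param seed Integer seed the generating call used.
#' @return An object of class `SyntheticTruth`: a list with elements
#'   `planted_deg_genes` (character), `planted_effect` (named numeric,
#'   log2 units), `active_pairs` (data.frame with columns `compound_id`,
#'   `target_id`), `enriched_terms` (character), `seed`.
#' @export
synthetic_truth <- function(seed = NA_integer_) {
  structure(list(
    planted_deg_genes = character(0),
    planted_effect = numeric(0),
    active_pairs = data.frame(compound_id = character(0),
                              target_id = character(0),
                              stringsAsFactors = FALSE),
    enriched_terms = character(0),
    seed = seed
  ), class = "SyntheticTruth")
}

# Flip probability giving expected pairwise Tanimoto `s` between two ligands
# independently mutated from a common seed vector of bit density `p`.
# E[Tc] ~ P(both bits 1) / P(either bit 1), solved numerically; for s at or
# below the unrelated-vector baseline (1/3) full randomization is enough.
flip_prob_for_similarity <- function(s, p) {
  tc_of <- function(f) {
    a11 <- p * (1 - f)^2 + (1 - p) * f^2
    aor <- p * (1 - f^2) + (1 - p) * (2 * f - f^2)
    a11 / aor
  }
  if (s >= 1) return(0)
  if (s <= tc_of(0.5)) return(0.5)
  stats::uniroot(function(f) tc_of(f) - s, c(1e-9, 0.5), tol = 1e-9)$root
}

random_bits <- function(n, density) {
  as.integer(stats::runif(n) < density)
}

#' Generate a ligand universe of mutually similar target sets
#'
#' Each target receives `ligands_per_target` random bit-vector fingerprints
#' perturbed from a per-target seed vector, so that the expected pairwise
#' Tanimoto coefficient within a set is at least `within_set_similarity`;
#' ligands of different targets are independent draws. This emulates the
#' structure a ligand-based target-prediction database assumes: a target's
#' known ligands resemble each other.
#'
#' @param n_targets Number of targets (may be 0).
#' @param ligands_per_target Ligands per target set, at least 2.
#' @param fp_length Fingerprint length in bits.
#' @param within_set_similarity Desired expected within-set Tanimoto, in (0, 1).
#' @param seed Integer seed; identical seeds give bit-identical universes.
#' @param density Expected fraction of set bits in a seed vector.
#' @param gene_symbols Optional character vector of gene symbols to assign
#'   to the targets (recycled from its head); defaults to synthetic symbols.
#' @return A list with `universe` (list of `TargetSet`: `target_id`,
#'   `gene_symbol`, `ligands` as a ligands-by-bits 0/1 matrix) and `truth`
#'   (a [synthetic_truth()] record).
#' @export
generate_ligand_universe <- function(n_targets, ligands_per_target,
                                     fp_length = 512,
                                     within_set_similarity = 0.65,
                                     seed = 1, density = 0.3,
                                     gene_symbols = NULL) {
  n_targets <- check_count(n_targets, "n_targets")
  fp_length <- check_count(fp_length, "fp_length", positive = TRUE)
  check_fraction(within_set_similarity, "within_set_similarity", open = TRUE)
  check_fraction(density, "density", open = TRUE)
  if (n_targets > 0) {
    ligands_per_target <- check_count(ligands_per_target, "ligands_per_target",
                                      positive = TRUE)
    if (ligands_per_target < 2) {
      np_stop("ligands_per_target must be at least 2")
    }
  }
  truth <- synthetic_truth(seed)
  if (n_targets == 0L) {
    return(list(universe = list(), truth = truth))
  }
  if (is.null(gene_symbols)) {
    gene_symbols <- sprintf("GENT%03d", seq_len(n_targets))
  } else {
    gene_symbols <- rep_len(normalize_symbols(gene_symbols), n_targets)
  }
  set.seed(seed)
  f <- flip_prob_for_similarity(within_set_similarity, density)
  universe <- vector("list", n_targets)
  for (i in seq_len(n_targets)) {
    base <- random_bits(fp_length, density)
    lig <- matrix(0L, nrow = ligands_per_target, ncol = fp_length)
    for (j in seq_len(ligands_per_target)) {
      flip <- stats::runif(fp_length) < f
      lig[j, ] <- ifelse(flip, 1L - base, base)
    }
    rownames(lig) <- sprintf("TGT%03d_L%02d", i, seq_len(ligands_per_target))
    universe[[i]] <- structure(list(
      target_id = sprintf("TGT%03d", i),
      gene_symbol = gene_symbols[i],
      ligands = lig
    ), class = "TargetSet")
  }
  names(universe) <- vapply(universe, `[[`, "", "target_id")
  list(universe = universe, truth = truth)
}

# Synthetic physicochemical profiles for the ADME stage: magnitudes typical
# of small natural products (polyphenol-heavy mixtures).
random_physchem <- function(n) {
  data.frame(
    mw = round(exp(stats::rnorm(n, log(350), 0.4)), 1),
    tpsa = round(stats::rgamma(n, shape = 4, scale = 25), 1),
    logp = round(stats::rnorm(n, 2, 1.5), 2),
    hbd = stats::rpois(n, 2),
    hba = stats::rpois(n, 5),
    anionic = stats::runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
}

#' Generate query compounds with known target associations
#'
#' Actives are copies of randomly chosen target ligands with `perturb_bits`
#' random bit flips (each recorded in `truth$active_pairs`); decoys are
#' independent random bit vectors. Every compound carries a synthetic
#' physicochemical profile so the ADME screening stage has input.
#'
#' @param universe_out Output of [generate_ligand_universe()] (or its
#'   `universe` element).
#' @param n_actives Number of active compounds (at most the total ligand count).
#' @param n_decoys Number of decoy compounds.
#' @param perturb_bits Bits to flip in each active; must be below fp length.
#' @param seed Integer seed.
#' @return A list with `compounds` (data.frame: id, name, cas, cls, and
#'   physicochemical columns), `fingerprints` (compounds-by-bits 0/1 matrix,
#'   row names = compound ids) and `truth`.
#' @export
generate_query_compounds <- function(universe_out, n_actives, n_decoys,
                                     perturb_bits = 8, seed = 1) {
  universe <- if (!is.null(universe_out$universe)) universe_out$universe
              else universe_out
  n_actives <- check_count(n_actives, "n_actives")
  n_decoys <- check_count(n_decoys, "n_decoys")
  perturb_bits <- check_count(perturb_bits, "perturb_bits")
  slots <- do.call(rbind, lapply(universe, function(ts) {
    data.frame(target_id = ts$target_id,
               ligand = seq_len(nrow(ts$ligands)),
               stringsAsFactors = FALSE)
  }))
  n_slots <- if (is.null(slots)) 0L else nrow(slots)
  if (n_actives > n_slots) {
    np_stop("n_actives (", n_actives, ") exceeds total ligand count (",
            n_slots, ")")
  }
  fp_length <- if (n_slots > 0) ncol(universe[[1]]$ligands) else 512L
  if (perturb_bits >= fp_length) {
    np_stop("perturb_bits must be smaller than the fingerprint length")
  }
  set.seed(seed)
  n <- n_actives + n_decoys
  truth <- synthetic_truth(seed)
  fps <- matrix(0L, nrow = n, ncol = fp_length)
  ids <- sprintf("CMP%03d", seq_len(n))
  rownames(fps) <- ids
  if (n_actives > 0) {
    pick <- slots[sample.int(n_slots, n_actives), , drop = FALSE]
    for (i in seq_len(n_actives)) {
      fp <- universe[[pick$target_id[i]]]$ligands[pick$ligand[i], ]
      if (perturb_bits > 0) {
        flip <- sample.int(fp_length, perturb_bits)
        fp[flip] <- 1L - fp[flip]
      }
      fps[i, ] <- fp
    }
    truth$active_pairs <- data.frame(compound_id = ids[seq_len(n_actives)],
                                     target_id = pick$target_id,
                                     stringsAsFactors = FALSE)
  }
  if (n_decoys > 0) {
    density <- if (n_slots > 0) {
      mean(vapply(universe, function(ts) mean(ts$ligands), 0))
    } else 0.3
    for (i in n_actives + seq_len(n_decoys)) {
      fps[i, ] <- random_bits(fp_length, density)
    }
  }
  compounds <- cbind(
    data.frame(id = ids, name = ids,
               cas = sprintf("%06d-%02d-%d", seq_len(n), seq_len(n) %% 100,
                             seq_len(n) %% 10),
               cls = sample(c("Polyphenols", "Alkaloids", "Triterpenoids",
                              "Furfurals"), n, replace = TRUE,
                            prob = c(0.6, 0.2, 0.15, 0.05)),
               stringsAsFactors = FALSE),
    random_physchem(n)
  )
  list(compounds = compounds, fingerprints = fps, truth = truth)
}

#' Generate paired case/control expression chips with planted effects
#'
#' Emulates two independent microarray series on a shared platform:
#' log2-scale values are a gene-specific baseline (Normal(8, 2), mimicking
#' log2 series-matrix intensities) plus Normal(0, sigma) noise; planted
#' genes receive +effect or -effect (alternating, so both volcano branches
#' are exercised) in case samples only. Probe ids map many-to-one onto gene
#' symbols to exercise probe collapsing. The two chips share the planted
#' gene set but have independent noise.
#'
#' @param n_genes Number of genes.
#' @param n_case,n_control Samples per group on each chip (each at least 2).
#' @param n_planted Number of planted differentially expressed genes.
#' @param effect Planted shift in log2 units (non-negative).
#' @param sigma Standard deviation of the log2 noise.
#' @param seed Integer seed.
#' @param gene_symbols Optional gene symbols (length `n_genes`).
#' @param second_probe_frac Fraction of genes carrying a second probe.
#' @param planted_genes Optional character vector naming the genes to plant
#'   (must be a subset of `gene_symbols`); overrides random selection and
#'   `n_planted`.
#' @return A list with `chips` (list of two `ExpressionMatrix` objects),
#'   `probe_gene_map` (data.frame: probe_id, gene_symbol) and `truth`.
#' @export
generate_expression_chips <- function(n_genes, n_case, n_control,
                                      n_planted, effect = 2, sigma = 0.5,
                                      seed = 1, gene_symbols = NULL,
                                      second_probe_frac = 0.3,
                                      planted_genes = NULL) {
  n_genes <- check_count(n_genes, "n_genes", positive = TRUE)
  n_case <- check_count(n_case, "n_case")
  n_control <- check_count(n_control, "n_control")
  n_planted <- check_count(n_planted, "n_planted")
  if (n_case < 2 || n_control < 2) {
    np_stop("n_case and n_control must both be at least 2 ",
            "(within-group variance undefined otherwise)")
  }
  if (n_planted > n_genes) np_stop("n_planted exceeds n_genes")
  if (!is.numeric(effect) || effect < 0) np_stop("effect must be >= 0")
  if (is.null(gene_symbols)) {
    gene_symbols <- sprintf("GENE%05d", seq_len(n_genes))
  } else {
    gene_symbols <- toupper(as.character(gene_symbols))
    if (length(gene_symbols) != n_genes) {
      np_stop("gene_symbols must have length n_genes")
    }
  }
  set.seed(seed)
  truth <- synthetic_truth(seed)
  if (!is.null(planted_genes)) {
    planted_idx <- match(toupper(planted_genes), gene_symbols)
    if (any(is.na(planted_idx))) {
      np_stop("planted_genes must be a subset of gene_symbols")
    }
    planted_idx <- sort(planted_idx)
    n_planted <- length(planted_idx)
  } else {
    planted_idx <- if (n_planted > 0) sort(sample.int(n_genes, n_planted))
                   else integer(0)
  }
  signs <- rep_len(c(1, -1), n_planted)
  truth$planted_deg_genes <- gene_symbols[planted_idx]
  truth$planted_effect <- stats::setNames(signs * effect,
                                          gene_symbols[planted_idx])

  # probe layout shared by both chips: every gene has one probe, a fraction
  # gets a second one (exercises many-to-one probe -> gene collapapsing)
  second <- which(stats::runif(n_genes) < second_probe_frac)
  probe_gene <- c(seq_len(n_genes), second)
  probe_ids <- c(sprintf("%05d_at", seq_len(n_genes)),
                 sprintf("%05d_s_at", second))
  probe_gene_map <- data.frame(probe_id = probe_ids,
                               gene_symbol = gene_symbols[probe_gene],
                               stringsAsFactors = FALSE)
  baseline <- stats::rnorm(n_genes, 8, 2)
  shift <- numeric(n_genes)
  shift[planted_idx] <- signs * effect

  make_chip <- function(chip_no) {
    n_s <- n_case + n_control
    sample_ids <- c(sprintf("C%d_IBS%02d", chip_no, seq_len(n_case)),
                    sprintf("C%d_HC%02d", chip_no, seq_len(n_control)))
    groups <- stats::setNames(rep(c("case", "control"), c(n_case, n_control)),
                              sample_ids)
    vals <- matrix(stats::rnorm(length(probe_ids) * n_s,
                                mean = baseline[probe_gene], sd = sigma),
                   nrow = length(probe_ids), ncol = n_s)
    vals[, seq_len(n_case)] <- vals[, seq_len(n_case)] + shift[probe_gene]
    dimnames(vals) <- list(probe_ids, sample_ids)
    expression_matrix(vals, groups, platform = "SYNGPL")
  }
  chips <- list(make_chip(1L), make_chip(2L))
  list(chips = chips, probe_gene_map = probe_gene_map, truth = truth)
}

#' Generate a random annotation collection with one planted term
#'
#' Produces `n_terms` gene sets over `genes`: random sets with sizes uniform
#' in `term_size_range`, plus (when `planted_term_genes` is nonempty) a first
#' term exactly equal to the planted set, recorded as enriched truth. The
#' collection serializes to GMT via [write_gmt()].
#'
#' @param genes Character vector, the gene universe.
#' @param n_terms Total number of terms, including the planted one.
#' @param term_size_range Length-2 integer range of random term sizes.
#' @param planted_term_genes Character vector (subset of `genes`), or empty.
#' @param seed Integer seed.
#' @param namespace Namespace label attached to every term.
#' @return A list with `collection` (list of `GeneSet`: term_id, term_name,
#'   genes, namespace) and `truth`.
#' @export
generate_annotations <- function(genes, n_terms, term_size_range = c(10, 60),
                                 planted_term_genes = character(0), seed = 1,
                                 namespace = "pathway") {
  n_terms <- check_count(n_terms, "n_terms", positive = TRUE)
  genes <- normalize_symbols(genes)
  planted_term_genes <- normalize_symbols(planted_term_genes)
  if (length(planted_term_genes) && !all(planted_term_genes %in% genes)) {
    np_stop("planted_term_genes must be a subset of genes")
  }
  if (max(term_size_range) > length(genes)) {
    np_stop("term sizes cannot exceed the number of genes")
  }
  set.seed(seed)
  truth <- synthetic_truth(seed)
  collection <- vector("list", n_terms)
  start <- 1L
  if (length(planted_term_genes)) {
    collection[[1]] <- structure(list(
      term_id = "TERM0000", term_name = "planted_term",
      genes = planted_term_genes, namespace = namespace
    ), class = "GeneSet")
    truth$enriched_terms <- "TERM0000"
    start <- 2L
  }
  sizes <- sample(seq(term_size_range[1], term_size_range[2]),
                  n_terms, replace = TRUE)
  for (i in seq_len(n_terms)[-seq_len(start - 1L)]) {
    collection[[i]] <- structure(list(
      term_id = sprintf("TERM%04d", i - 1L),
      term_name = sprintf("random_term_%04d", i - 1L),
      genes = sort(sample(genes, sizes[i])),
      namespace = namespace
    ), class = "GeneSet")
  }
  collection <- collection[!vapply(collection, is.null, TRUE)]
  list(collection = collection, truth = truth)
}

#' Generate random protein-protein interaction edges
#'
#' Erdos-Renyi edges among `nodes` with uniform combined scores in
#' `score_range`, in the column layout of a STRING interaction export
#' (node1, node2, combined_score on the 0-1000 scale).
#'
#' @param nodes Character vector of node (gene) symbols.
#' @param edge_prob Probability of each undirected edge.
#' @param score_range Length-2 numeric range for combined scores.
#' @param seed Integer seed.
#' @return A data.frame with columns node1, node2, combined_score.
#' @export
generate_ppi_edges <- function(nodes, edge_prob, score_range = c(150, 999),
                               seed = 1) {
  check_fraction(edge_prob, "edge_prob")
  nodes <- normalize_symbols(nodes)
  empty <- data.frame(node1 = character(0), node2 = character(0),
                      combined_score = integer(0), stringsAsFactors = FALSE)
  if (length(nodes) < 2 || edge_prob == 0) return(empty)
  set.seed(seed)
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < edge_prob
  if (!any(keep)) return(empty)
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(node1 = pairs[, 1], node2 = pairs[, 2],
             combined_score = as.integer(round(
               stats::runif(nrow(pairs), score_range[1], score_range[2]))),
             stringsAsFactors = FALSE)
}
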