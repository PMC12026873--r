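# Ligand-similarity (similarity-ensemble) target prediction.
#
# A query compound is scored against each target by summing the Tanimoto
# coefficients to the target's known ligands that exceed a similarity
# threshold (default Tc > 0.45). Raw scores are normalized by the target's
# ligand count and standardized against a random background model:
#
#   Z = (raw - mu * N) / (sigma * N^lambda),   lambda = 0.335
#
# where N is the ligand count, mu the expected raw score per random
# query-ligand pair, and sigma the coefficient of the empirical power law
# SD(raw) ~ sigma * N^lambda describing how background noise grows with
# set size. Higher Z means the similarity to the target's ligand set is
# less likely under chance resemblance alone.

#' Tanimoto coefficient of two bit-vector fingerprints
#'
#' |a AND b| / |a OR b|; defined as 0 when both vectors are all-zero.
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) {
    np_stop("fingerprint length mismatch (", length(a), " vs ", length(b), ")")
  }
  both <- sum(a & b)
  either <- sum(a | b)
  if (either == 0) return(0)
  both / either
}

# Tanimoto of one query against every row of a ligand matrix (vectorized).
tanimoto_rows <- function(query, mat) {
  if (ncol(mat) != length(query)) {
    np_stop("fingerprint length mismatch (", length(query), " vs ",
            ncol(mat), ")")
  }
  both <- as.vector(mat %*% query)
  either <- rowSums(mat) + sum(query) - both
  ifelse(either == 0, 0, both / either)
}

#' Thresholded similarity-ensemble raw score of a query against a target set
#'
#' Sum of the Tanimoto coefficients between the query and the target's
#' ligands that are strictly greater than `tc_threshold`.
#'
#' @param query 0/1 fingerprint vector.
#' @param target A `TargetSet` (list with a `ligands` 0/1 matrix) or a bare
#'   ligand matrix.
#' @param tc_threshold Similarity threshold (default 0.45).
#' @return A list with `raw` (the thresholded sum) and `n_pairs` (the
#'   ligand count N used for normalization and the Z-score).
#' @export
raw_score <- function(query, target, tc_threshold = 0.45) {
  check_fraction(tc_threshold, "tc_threshold", open = TRUE)
  lig <- if (is.matrix(target)) target else target$ligands
  if (is.null(lig) || nrow(lig) == 0) np_stop("target has no ligands")
  tc <- tanimoto_rows(query, lig)
  list(raw = sum(tc[tc > tc_threshold]), n_pairs = nrow(lig))
}

#' Calibrate the random-background model for Z-scores
#'
#' Draws `n_samples` random (query, ligand-set) pairs and records their raw
#' scores: the query is a ligand drawn at random from the pooled universe,
#' the set is a random subset (excluding the query itself) of each size in
#' `set_sizes`, so mu and sigma measure the chance-resemblance noise of the
#' database itself. `mu` is the least-squares slope through the origin of
#' mean raw score against set size N; `sigma` is fitted in log-log space
#' from SD(raw) ~ sigma * N^lambda with `lambda` held fixed, over sizes
#' with nonzero SD (a single size gives the one-point fit).
#'
#' @param universe_out Output of [generate_ligand_universe()] or a list of
#'   `TargetSet`s.
#' @param set_sizes Integer vector of background set sizes to sample.
#' @param n_samples Total background draws (at least 100).
#' @param tc_threshold Similarity threshold used for raw scores.
#' @param seed Integer seed; the model is deterministic given the seed.
#' @param lam Fixed power-law exponent (default 0.335).
#' @return A `BackgroundModel`: list(mu, sigma, lam, tc_threshold, fit_n).
#' @export
calibrate_background <- function(universe_out, set_sizes = c(2, 5, 10, 20),
                                 n_samples = 1000, tc_threshold = 0.45,
                                 seed = 1, lam = 0.335) {
  universe <- if (!is.null(universe_out$universe)) universe_out$universe
              else universe_out
  if (length(universe) == 0) np_stop("universe is empty")
  n_samples <- check_count(n_samples, "n_samples", positive = TRUE)
  if (n_samples < 100) np_stop("n_samples must be at least 100")
  set_sizes <- sort(unique(vapply(set_sizes, check_count, 0L,
                                  name = "set_sizes", positive = TRUE)))
  pool <- do.call(rbind, lapply(universe, `[[`, "ligands"))
  if (nrow(pool) < 2) np_stop("universe must pool at least 2 ligands")
  set.seed(seed)
  per_size <- ceiling(n_samples / length(set_sizes))
  sizes <- rep(set_sizes, each = per_size)
  raws <- vapply(sizes, function(n) {
    qi <- sample.int(nrow(pool), 1)
    rest <- seq_len(nrow(pool))[-qi]
    idx <- sample(rest, n, replace = n > length(rest))
    raw_score(pool[qi, ], pool[idx, , drop = FALSE], tc_threshold)$raw
  }, 0)
  if (all(raws == 0)) {
    np_stop("background degenerate; lower tc_threshold or enlarge samples")
  }
  mean_by <- tapply(raws, sizes, mean)
  sd_by <- tapply(raws, sizes, stats::sd)
  ns <- as.numeric(names(mean_by))
  mu <- sum(ns * mean_by) / sum(ns^2)
  pos <- which(sd_by > 0)
  sigma <- if (length(pos)) {
    exp(mean(log(sd_by[pos]) - lam * log(ns[pos])))
  } else {
    np_stop("background degenerate; lower tc_threshold or enlarge samples")
  }
  structure(list(mu = mu, sigma = sigma, lam = lam,
                 tc_threshold = tc_threshold, fit_n = length(raws)),
            class = "BackgroundModel")
}

#' @export
print.BackgroundModel <- function(x, ...) {
  cat(sprintf(
    "BackgroundModel: mu = %.4g, sigma = %.4g, lambda = %.3f, Tc > %.2f (fit on %d draws)\n",
    x$mu, x$sigma, x$lam, x$tc_threshold, x$fit_n))
  invisible(x)
}

#' Standardized similarity-ensemble Z-score
#'
#' Z = (raw - mu * n_pairs) / (sigma * n_pairs^lambda).
#'
#' @param raw Thresholded raw score.
#' @param n_pairs Ligand count of the target set (>= 1).
#' @param model A `BackgroundModel` from [calibrate_background()].
#' @return Unitless Z-score.
#' @export
z_score <- function(raw, n_pairs, model) {
  if (any(n_pairs < 1)) np_stop("n_pairs must be at least 1")
  (raw - model$mu * n_pairs) / (model$sigma * n_pairs^model$lam)
}

#' Predict targets for a query compound
#'
#' Scores the query against every target set, keeps targets with a
#' positive raw score and Z >= `z_min`, and returns them sorted by Z
#' descending (ties broken by normalized score, then target id).
#'
#' @param query 0/1 fingerprint vector (or a list with element `fp`).
#' @param db List of `TargetSet`s (or a [generate_ligand_universe()] output).
#' @param model A `BackgroundModel`.
#' @param z_min Minimum Z to retain (default 3.0; use `-Inf` for all).
#' @param compound_id Identifier recorded in the output.
#' @return data.frame: compound_id, target_id, gene_symbol, raw, n_pairs,
#'   normalized, z — one row per retained target.
#' @export
predict_targets <- function(query, db, model, z_min = 3.0,
                            compound_id = "query") {
  db <- if (is.list(db) && !is.null(db$universe)) db$universe else db
  if (is.list(query) && !is.null(query$fp)) query <- query$fp
  empty <- data.frame(compound_id = character(0), target_id = character(0),
                      gene_symbol = character(0), raw = numeric(0),
                      n_pairs = integer(0), normalized = numeric(0),
                      z = numeric(0), stringsAsFactors = FALSE)
  if (length(db) == 0) return(empty)
  rows <- lapply(db, function(ts) {
    rs <- raw_score(query, ts, model$tc_threshold)
    if (rs$raw <= 0) return(NULL)
    data.frame(compound_id = compound_id, target_id = ts$target_id,
               gene_symbol = ts$gene_symbol, raw = rs$raw,
               n_pairs = rs$n_pairs, normalized = rs$raw / rs$n_pairs,
               z = z_score(rs$raw, rs$n_pairs, model),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[out$z >= z_min, , drop = FALSE]
  out <- out[order(-out$z, -out$normalized, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict targets for a set of compounds
#'
#' Applies [predict_targets()] to each row of a fingerprint matrix.
#'
#' @param fingerprints Compounds-by-bits 0/1 matrix with compound ids as
#'   row names.
#' @param db List of `TargetSet`s.
#' @param model A `BackgroundModel`.
#' @param z_min Minimum Z to retain.
#' @return Row-bound prediction data.frame.
#' @export
predict_targets_all <- function(fingerprints, db, model, z_min = 3.0) {
  out <- do.call(rbind, lapply(rownames(fingerprints), function(id) {
    predict_targets(fingerprints[id, ], db, model, z_min, compound_id = id)
  }))
  if (is.null(out)) {
    out <- predict_targets(integer(0), list(), model)
  }
  rownames(out) <- NULL
  out
}
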