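# Over-representation analysis: hypergeometric upper-tail p-values per
# annotation term, Benjamini-Hochberg adjustment across the tested terms,
# and the significance cutoff on the adjusted p (default <= 0.01).

#' Hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` annotated genes when `n` genes are drawn without replacement
#' from a universe of `N` genes of which `K` carry the annotation.
#' Evaluated on the log scale internally for numerical stability.
#'
#' @param k Observed overlap.
#' @param K Term size in the universe.
#' @param n Query size in the universe.
#' @param N Universe size.
#' @return Tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  k <- check_count(k, "k"); K <- check_count(K, "K")
  n <- check_count(n, "n"); N <- check_count(N, "N")
  if (k > min(K, n) || K > N || n > N) {
    np_stop("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' p_adj(i) = min over j with p(j) >= p(i) (by rank) of p(j) * m / rank(j),
#' capped at 1; the input order is preserved in the output.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    np_stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Over-representation analysis of a query gene set
#'
#' Tests every term with at least one query gene against the hypergeometric
#' null, adjusts across the tested terms with Benjamini-Hochberg, and flags
#' rows with adjusted p at (or below/under, see `strict`) `p_adj_max`.
#' Query genes outside the universe are dropped with a warning. The
#' universe defaults to all genes appearing in the collection.
#'
#' @param query Character vector of gene symbols.
#' @param collection List of `GeneSet`s (see [generate_annotations()] /
#'   [read_gmt()]).
#' @param universe Optional character vector; default: union of the
#'   collection's genes.
#' @param p_adj_max Significance cutoff on the adjusted p (default 0.01).
#' @param strict Use `<` instead of `<=` for the cutoff.
#' @return data.frame: term_id, term_name, namespace, k, K, n, N, p, p_adj,
#'   significant, genes (semicolon-joined overlap), sorted by p_adj then p
#'   then term_id.
#' @export
enrich <- function(query, collection, universe = NULL, p_adj_max = 0.01,
                   strict = FALSE) {
  query <- normalize_symbols(query)
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(collection, `[[`, "genes")))
  }
  universe <- normalize_symbols(universe)
  if (length(universe) == 0) np_stop("universe is empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  empty <- data.frame(term_id = character(0), term_name = character(0),
                      namespace = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0),
                      genes = character(0), stringsAsFactors = FALSE)
  if (length(query) == 0 || length(collection) == 0) return(empty)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(collection, function(ts) {
    tg <- intersect(normalize_symbols(ts$genes), universe)
    ov <- intersect(tg, query)
    if (length(ov) == 0) return(NULL)
    data.frame(term_id = ts$term_id, term_name = ts$term_name,
               namespace = if (is.null(ts$namespace)) NA_character_
                           else ts$namespace,
               k = length(ov), K = length(tg), n = n, N = N,
               p = hypergeom_tail(length(ov), length(tg), n, N),
               genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- if (strict) out$p_adj < p_adj_max
                     else out$p_adj <= p_adj_max
  out <- out[order(out$p_adj, out$p, out$term_id),
             c("term_id", "term_name", "namespace", "k", "K", "n", "N",
               "p", "p_adj", "significant", "genes")]
  rownames(out) <- NULL
  out
}

#' Top significant enrichment rows
#'
#' First `k` significant rows of a sorted enrichment table (a prefix of the
#' input ordering).
#'
#' @param rows Output of [enrich()].
#' @param k Maximum rows (default 20).
#' @return data.frame subset.
#' @export
top_terms <- function(rows, k = 20) {
  k <- check_count(k, "k")
  out <- utils::head(rows[rows$significant, , drop = FALSE], k)
  rownames(out) <- NULL
  out
}
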