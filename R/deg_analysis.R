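# Two-group differential expression on log2 microarray intensities:
# per-probe fold change and p-value, the |logFC| >= 0.5 & p <= 0.05
# screening filter, probe -> gene collapsing, cross-chip union and union
# with disease-gene lists.

#' Construct an ExpressionMatrix
#'
#' @param values Numeric probes-by-samples matrix of log2 intensities, with
#'   probe ids as row names and sample ids as column names.
#' @param groups Named character vector mapping every sample id to
#'   `"case"` or `"control"`.
#' @param platform Platform label.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, groups, platform = "unknown") {
  if (!is.matrix(values) || !is.numeric(values)) {
    np_stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    np_stop("values must have probe row names and sample column names")
  }
  if (any(!is.finite(values))) np_stop("values must be finite")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    np_stop("samples without group labels: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("case", "control"))) {
    np_stop("group labels must be 'case' or 'control'")
  }
  if (min(table(factor(groups, c("case", "control")))) < 2) {
    np_stop("each group needs at least 2 samples")
  }
  structure(list(values = values,
                 probe_ids = rownames(values),
                 sample_ids = colnames(values),
                 groups = groups,
                 platform = platform),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%d case / %d control), platform %s\n",
              nrow(x$values), ncol(x$values), sum(x$groups == "case"),
              sum(x$groups == "control"), x$platform))
  invisible(x)
}

#' Write an ExpressionMatrix in series-matrix layout
#'
#' The expression table is delimited by `!series_matrix_table_begin` /
#' `!series_matrix_table_end` marker lines with an `ID_REF` header row of
#' sample ids, as in a GEO series matrix; group labels go to a two-column
#' sidecar TSV (sample_id, group).
#'
#' @param m An `ExpressionMatrix`.
#' @param path Output path for the matrix file.
#' @param groups_path Output path for the group sidecar TSV.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(m, path, groups_path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("!Series_platform_id\t", m$platform),
               "!series_matrix_table_begin"), con)
  writeLines(paste(c("ID_REF", m$sample_ids), collapse = "\t"), con)
  writeLines(paste(m$probe_ids,
                   apply(format(m$values, trim = TRUE, digits = 15), 1,
                         paste, collapse = "\t"),
                   sep = "\t"), con)
  writeLines("!series_matrix_table_end", con)
  write_tsv(data.frame(sample_id = m$sample_ids,
                       group = unname(m$groups[m$sample_ids]),
                       stringsAsFactors = FALSE), groups_path)
  invisible(path)
}

#' Read a series-matrix expression file
#'
#' Parses the table between the standard begin/end markers; sample ids come
#' from the header row, group labels from the sidecar TSV. Values are
#' assumed to be on the log2 scale already; if the maximum exceeds 50 the
#' matrix is log2(x + 1)-transformed with a warning.
#'
#' @param path Series-matrix file.
#' @param groups_path Sidecar TSV with columns sample_id, group.
#' @return An `ExpressionMatrix`.
#' @export
read_series_matrix <- function(path, groups_path) {
  if (!file.exists(path)) np_stop("series-matrix file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1 || length(end) != 1 || end <= beg + 1) {
    np_stop("missing or malformed series-matrix table markers in ", path)
  }
  platform <- sub("^!Series_platform_id\t", "",
                  grep("^!Series_platform_id\t", lines, value = TRUE)[1])
  if (is.na(platform)) platform <- "unknown"
  header <- strsplit(lines[beg + 1], "\t", fixed = TRUE)[[1]]
  sample_ids <- gsub('^"|"$', "", header[-1])
  body <- lines[(beg + 2):(end - 1)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(parts)
  bad <- which(widths != length(header))
  if (length(bad)) {
    np_stop("ragged row at line ", beg + 1 + bad[1], " in ", path,
            " (", widths[bad[1]], " fields, expected ", length(header), ")")
  }
  probe_ids <- gsub('^"|"$', "", vapply(parts, `[`, "", 1))
  vals <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(parts, `[`, -1)))),
    nrow = length(parts), byrow = TRUE,
    dimnames = list(probe_ids, sample_ids))
  if (any(is.na(vals))) {
    np_stop("non-numeric expression value in ", path)
  }
  if (max(vals) > 50) {
    warning("expression values look unlogged (max ", round(max(vals), 1),
            "); applying log2(x + 1)", call. = FALSE)
    vals <- log2(vals + 1)
  }
  gr <- read_tsv(groups_path)
  if (!all(c("sample_id", "group") %in% names(gr))) {
    np_stop("group sidecar must have columns sample_id, group")
  }
  missing <- setdiff(sample_ids, gr$sample_id)
  if (length(missing)) {
    np_stop("samples in table absent from group sidecar: ",
            paste(missing, collapse = ", "))
  }
  expression_matrix(vals, stats::setNames(gr$group, gr$sample_id), platform)
}

# Inverse of trigamma by Newton iteration on 1/trigamma (close to linear),
# used for the moment-matching prior df estimate.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Moment-matching estimate of the variance prior (d0, s0^2): the log sample
# variances z = log(s^2) follow z ~ const + log-F noise under the hierarchical
# model; matching the mean and variance of e = z - digamma(d/2) + log(d/2)
# gives d0 via the trigamma inverse and s0^2 from the mean.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0
  if (sum(ok) < 2) return(list(d0 = 0, s0sq = mean(s2)))
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread: variances essentially shared -> infinite prior df
    return(list(d0 = Inf, s0sq = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

#' Per-probe two-group differential expression
#'
#' Log fold change is mean(case) - mean(control) in log2 units, so
#' up-regulation in cases is positive. Two tests are available:
#' \describe{
#'   \item{welch}{Welch two-sample t-test with Satterthwaite degrees of
#'     freedom. Probes with zero variance in both groups get the degenerate
#'     limit (p = 0 if the means differ, p = 1 otherwise) and are flagged.}
#'   \item{moderated}{Empirical-Bayes moderated t: the pooled variance of
#'     each probe is shrunk toward a prior, s2_post = (d0 s0^2 + d s^2) /
#'     (d0 + d), with (d0, s0^2) estimated by moment matching on the log
#'     sample variances across probes; t = logFC / (s_post sqrt(1/n1 +
#'     1/n2)) with d0 + d degrees of freedom.}
#' }
#'
#' @param m An `ExpressionMatrix`.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param probe_gene_map Optional data.frame (probe_id, gene_symbol) used to
#'   attach gene symbols.
#' @param d0_override Optional fixed prior df for the moderated test
#'   (`0` disables shrinkage, recovering the ordinary pooled t).
#' @return data.frame: probe_id, gene_symbol, logfc, t, p, direction,
#'   degenerate.
#' @export
differential_expression <- function(m, method = c("moderated", "welch"),
                                    probe_gene_map = NULL,
                                    d0_override = NULL) {
  method <- match.arg(method)
  case <- m$values[, m$groups == "case", drop = FALSE]
  ctrl <- m$values[, m$groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) np_stop("each group needs at least 2 samples")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var); v2 <- apply(ctrl, 1, stats::var)
  logfc <- m1 - m2
  degenerate <- rep(FALSE, length(logfc))
  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    tstat <- logfc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
    zero <- se2 == 0
    if (any(zero)) {
      degenerate[zero] <- TRUE
      p[zero] <- ifelse(logfc[zero] != 0, 0, 1)
      tstat[zero] <- ifelse(logfc[zero] != 0, Inf * sign(logfc[zero]), 0)
    }
  } else {
    d <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
    if (is.null(d0_override)) {
      prior <- fit_variance_prior(s2, d)
    } else {
      prior <- list(d0 = d0_override,
                    s0sq = if (d0_override > 0) fit_variance_prior(s2, d)$s0sq
                           else 0)
    }
    s2_post <- if (is.infinite(prior$d0)) rep(prior$s0sq, length(s2))
               else (prior$d0 * prior$s0sq + d * s2) / (prior$d0 + d)
    tstat <- logfc / sqrt(s2_post * (1 / n1 + 1 / n2))
    df_total <- min(prior$d0 + d, .Machine$double.xmax)
    p <- 2 * stats::pt(-abs(tstat), df_total)
    zero <- s2_post == 0
    if (any(zero)) {
      degenerate[zero] <- TRUE
      p[zero] <- ifelse(logfc[zero] != 0, 0, 1)
      tstat[zero] <- ifelse(logfc[zero] != 0, Inf * sign(logfc[zero]), 0)
    }
  }
  out <- data.frame(probe_id = m$probe_ids,
                    gene_symbol = NA_character_,
                    logfc = unname(logfc), t = unname(tstat), p = unname(p),
                    direction = ifelse(logfc >= 0, "up", "down"),
                    degenerate = degenerate,
                    stringsAsFactors = FALSE)
  if (!is.null(probe_gene_map)) {
    out$gene_symbol <- toupper(
      probe_gene_map$gene_symbol[match(out$probe_id, probe_gene_map$probe_id)])
  }
  rownames(out) <- NULL
  out
}

#' Apply the fold-change and p-value screening filter
#'
#' Keeps exactly the records with |logFC| >= `lfc_min` and p <= `p_max`;
#' both comparisons are inclusive. Idempotent.
#'
#' @param records Output of [differential_expression()].
#' @param lfc_min Minimum absolute log2 fold change (default 0.5).
#' @param p_max Maximum p-value (default 0.05).
#' @return The passing records, with a `passed` column (all `TRUE`).
#' @export
filter_degs <- function(records, lfc_min = 0.5, p_max = 0.05) {
  if (nrow(records) == 0) {
    records$passed <- logical(0)
    return(records)
  }
  passed <- abs(records$logfc) >= lfc_min & records$p <= p_max
  out <- records[passed, , drop = FALSE]
  out$passed <- TRUE
  rownames(out) <- NULL
  out
}

#' Collapse probe-level records to gene level
#'
#' Per gene, keeps the probe with the largest |logFC| (default) or averages
#' the probes (`how = "mean"`, p combined as the minimum). Probes without a
#' gene mapping are dropped; their count is reported in the `n_unmapped`
#' attribute.
#'
#' @param records Probe-level data.frame with `gene_symbol` filled (or a
#'   `probe_gene_map` to fill it).
#' @param probe_gene_map Optional data.frame (probe_id, gene_symbol).
#' @param how `"max_abs_lfc"` (default) or `"mean"`.
#' @return Gene-level data.frame keyed by unique `gene_symbol`.
#' @export
collapse_probes <- function(records, probe_gene_map = NULL,
                            how = c("max_abs_lfc", "mean")) {
  how <- match.arg(how)
  if (!is.null(probe_gene_map)) {
    records$gene_symbol <- toupper(
      probe_gene_map$gene_symbol[match(records$probe_id,
                                       probe_gene_map$probe_id)])
  }
  unmapped <- is.na(records$gene_symbol) | !nzchar(records$gene_symbol)
  n_unmapped <- sum(unmapped)
  records <- records[!unmapped, , drop = FALSE]
  if (nrow(records) == 0) {
    attr(records, "n_unmapped") <- n_unmapped
    return(records)
  }
  if (how == "max_abs_lfc") {
    ord <- order(records$gene_symbol, -abs(records$logfc), records$probe_id)
    records <- records[ord, , drop = FALSE]
    out <- records[!duplicated(records$gene_symbol), , drop = FALSE]
  } else {
    sp <- split(records, records$gene_symbol)
    out <- do.call(rbind, lapply(sp, function(g) {
      r <- g[1, , drop = FALSE]
      r$logfc <- mean(g$logfc)
      r$p <- min(g$p)
      r$direction <- if (r$logfc >= 0) "up" else "down"
      r$probe_id <- paste(g$probe_id, collapse = ";")
      r
    }))
  }
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Union of per-chip gene sets, duplicates removed
#'
#' @param per_chip_gene_sets List of character vectors.
#' @return Sorted unique union (upper-cased symbols).
#' @export
union_deg_sets <- function(per_chip_gene_sets) {
  if (length(per_chip_gene_sets) == 0) return(character(0))
  sort(normalize_symbols(unlist(per_chip_gene_sets, use.names = FALSE)))
}

#' Merge the DEG union with disease-gene database lists
#'
#' Symbols are case-normalized and de-duplicated; with no database lists
#' the disease set equals the DEG union.
#'
#' @param deg_union Character vector of gene symbols.
#' @param database_lists Character vector of file paths (one symbol per
#'   line) and/or in-memory character vectors.
#' @return Sorted unique union.
#' @export
build_disease_targets <- function(deg_union, database_lists = list()) {
  sets <- list(normalize_symbols(deg_union))
  for (x in database_lists) {
    sets <- c(sets, list(
      if (is.character(x) && length(x) == 1 && file.exists(x)) {
        read_symbol_list(x)
      } else {
        normalize_symbols(x)
      }))
  }
  sort(unique(unlist(sets)))
}
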