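make_matrix <- function(case, ctrl, probe_ids = NULL) {
  vals <- cbind(case, ctrl)
  if (is.null(probe_ids)) probe_ids <- sprintf("p%03d", seq_len(nrow(vals)))
  colnames(vals) <- c(sprintf("S_case%d", seq_len(ncol(case))),
                      sprintf("S_ctrl%d", seq_len(ncol(ctrl))))
  rownames(vals) <- probe_ids
  groups <- stats::setNames(rep(c("case", "control"),
                                c(ncol(case), ncol(ctrl))), colnames(vals))
  expression_matrix(vals, groups)
}

test_that("Welch test matches an independent hand computation", {
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  m <- make_matrix(matrix(x, 1), matrix(y, 1))
  de <- differential_expression(m, method = "welch")
  # hand Welch: t = (mx - my) / sqrt(vx/3 + vy/3), Satterthwaite df
  mx <- mean(x); my <- mean(y); vx <- var(x); vy <- var(y)
  se2 <- vx / 3 + vy / 3
  t_hand <- (mx - my) / sqrt(se2)
  df_hand <- se2^2 / ((vx / 3)^2 / 2 + (vy / 3)^2 / 2)
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(de$t, t_hand, tolerance = 1e-12)
  expect_equal(de$p, p_hand, tolerance = 1e-12)
  expect_equal(de$logfc, mx - my)
  # cross-check against stats::t.test
  tt <- t.test(x, y)
  expect_equal(de$p, tt$p.value, tolerance = 1e-12)
})

test_that("identical groups give logFC 0 and p 1; zero variance is flagged", {
  v <- matrix(rep(c(5, 6, 7), 2), 1)
  m <- make_matrix(v[, 1:3, drop = FALSE], v[, 4:6, drop = FALSE])
  de <- differential_expression(m, method = "welch")
  expect_equal(de$logfc, 0)
  expect_equal(de$p, 1)

  m2 <- make_matrix(matrix(c(3, 3, 3), 1), matrix(c(1, 1, 1), 1))
  de2 <- differential_expression(m2, method = "welch")
  expect_true(de2$degenerate)
  expect_equal(de2$p, 0)
  m3 <- make_matrix(matrix(c(3, 3, 3), 1), matrix(c(3, 3, 3), 1))
  de3 <- differential_expression(m3, method = "welch")
  expect_equal(de3$p, 1)
})

test_that("moderated t with zero prior df equals the ordinary pooled t", {
  set.seed(5)
  m <- make_matrix(matrix(rnorm(50 * 4, 8), 50), matrix(rnorm(50 * 5, 8), 50))
  de <- differential_expression(m, method = "moderated", d0_override = 0)
  pooled <- apply(m$values, 1, function(r) {
    t.test(r[m$groups == "case"], r[m$groups == "control"],
           var.equal = TRUE)$p.value
  })
  expect_equal(de$p, unname(pooled), tolerance = 1e-6)
})

test_that("moderated t agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  set.seed(8)
  # heterogeneous true variances so shrinkage actually acts
  n <- 200
  sds <- sqrt(1 / rgamma(n, shape = 3, rate = 3))
  case <- matrix(rnorm(n * 5, 8, sds), n)
  ctrl <- matrix(rnorm(n * 5, 8, sds), n)
  m <- make_matrix(case, ctrl)
  de <- differential_expression(m, method = "moderated")
  design <- cbind(1, m$groups == "case")
  fit <- limma::eBayes(limma::lmFit(m$values, design))
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
  expect_equal(de$logfc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
})

test_that("planted probes outrank null probes by |t|", {
  wins <- 0
  for (s in 1:5) {
    g <- generate_expression_chips(400, 10, 10, n_planted = 20, effect = 2,
                                   sigma = 0.5, seed = s)
    de <- differential_expression(g$chips[[1]], method = "moderated",
                                  probe_gene_map = g$probe_gene_map)
    planted <- de$gene_symbol %in% g$truth$planted_deg_genes
    # every planted probe above the null median, almost all above 99th pct
    thresh <- quantile(abs(de$t[!planted]), 0.99)
    wins <- wins + mean(abs(de$t[planted]) > thresh)
  }
  expect_gte(wins / 5, 0.99)
})

test_that("DEG filter is inclusive at both boundaries and idempotent", {
  rec <- data.frame(probe_id = c("a", "b", "c", "d"),
                    gene_symbol = c("A", "B", "C", "D"),
                    logfc = c(0.5, 0.49, -0.8, 2),
                    t = 1, p = c(0.05, 0.001, 0.04, 0.2),
                    direction = c("up", "down", "down", "up"),
                    degenerate = FALSE)
  f <- filter_degs(rec)
  expect_equal(f$probe_id, c("a", "c"))   # boundary row kept, 0.49 and p=0.2 out
  expect_identical(filter_degs(f), f[, ])
  expect_equal(nrow(filter_degs(rec[0, , drop = FALSE])), 0)
})

test_that("probe collapsing keeps the extreme probe and counts unmapped", {
  rec <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                    gene_symbol = c("G1", "G1", "G2", NA),
                    logfc = c(0.6, -1.2, 0.3, 5),
                    t = 1, p = c(0.01, 0.02, 0.2, 0.001),
                    direction = c("up", "down", "up", "up"),
                    degenerate = FALSE)
  out <- collapse_probes(rec)
  expect_equal(nrow(out), 2)
  expect_equal(out$logfc[out$gene_symbol == "G1"], -1.2)
  expect_equal(attr(out, "n_unmapped"), 1)

  # one probe per gene -> identity of rows
  one <- collapse_probes(rec[c(1, 3), ])
  expect_equal(one$probe_id, c("p1", "p3"))

  # mean collapsing alternative
  avg <- collapse_probes(rec[1:3, ], how = "mean")
  expect_equal(avg$logfc[avg$gene_symbol == "G1"], mean(c(0.6, -1.2)))
})

test_that("set unions reproduce printed-count arithmetic", {
  expect_setequal(union_deg_sets(list(c("A", "B"), c("B", "C"))),
                  c("A", "B", "C"))
  s1 <- sprintf("X%03d", 1:152)
  s2 <- sprintf("Y%03d", 1:202)
  expect_length(union_deg_sets(list(s1, s2)), 354)
  s2[1] <- s1[1]   # one shared gene
  expect_length(union_deg_sets(list(s1, s2)), 353)
  expect_length(union_deg_sets(list()), 0)

  # disease union case-folds and falls back to the DEG union alone
  td <- withr::local_tempdir()
  writeLines(c("a", "B "), file.path(td, "db.txt"))
  expect_setequal(build_disease_targets(c("a"), list(file.path(td, "db.txt"))),
                  c("A", "B"))
  expect_setequal(build_disease_targets(c("x", "y")), c("X", "Y"))
})

test_that("series-matrix reader validates and auto-logs unlogged values", {
  td <- withr::local_tempdir()
  g <- generate_expression_chips(30, 3, 3, 5, seed = 1)
  chip <- file.path(td, "c.tsv"); grp <- file.path(td, "g.tsv")
  write_series_matrix(g$chips[[1]], chip, grp)

  # unlogged intensities: values in the thousands trigger the transform
  m <- g$chips[[1]]
  m$values <- 2^m$values
  write_series_matrix(m, chip, grp)
  expect_warning(back <- read_series_matrix(chip, grp), "unlogged")
  expect_lt(max(back$values), 50)

  # missing group for a sample
  write_series_matrix(g$chips[[1]], chip, grp)
  bad <- utils::read.delim(grp)[-1, ]
  utils::write.table(bad, grp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_series_matrix(chip, grp), "absent from group sidecar")

  # missing markers / ragged rows
  writeLines(c("a\tb", "1\t2"), chip)
  expect_error(read_series_matrix(chip, grp), "markers")
  writeLines(c("!series_matrix_table_begin", "ID_REF\tS1\tS2",
               "p1\t1.0", "!series_matrix_table_end"), chip)
  expect_error(read_series_matrix(chip, grp), "ragged row at line 3")
})

test_that("type-I error is nominal under the null for both methods", {
  g <- generate_expression_chips(5000, 20, 20, n_planted = 0, effect = 0,
                                 sigma = 0.5, seed = 99, second_probe_frac = 0)
  for (method in c("welch", "moderated")) {
    de <- differential_expression(g$chips[[1]], method = method)
    rate <- mean(de$p <= 0.05)
    expect_gte(rate, 0.04)
    expect_lte(rate, 0.06)
  }
})
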