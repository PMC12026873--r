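test_that("ligand universes have the designed within-set similarity", {
  hits <- 0
  for (s in 1:100) {
    u <- generate_ligand_universe(1, 2, fp_length = 256,
                                  within_set_similarity = 0.99, seed = s)
    lig <- u$universe[[1]]$ligands
    if (tanimoto(lig[1, ], lig[2, ]) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 95)

  # looser similarity: mean pairwise Tc near the requested level
  u <- generate_ligand_universe(20, 6, fp_length = 512,
                                within_set_similarity = 0.6, seed = 11)
  within <- unlist(lapply(u$universe, function(ts) {
    idx <- utils::combn(nrow(ts$ligands), 2)
    apply(idx, 2, function(ij) tanimoto(ts$ligands[ij[1], ],
                                        ts$ligands[ij[2], ]))
  }))
  expect_gt(mean(within), 0.55)
})

test_that("universe generation: empty case, determinism, validation", {
  u0 <- generate_ligand_universe(0, 5, seed = 1)
  expect_identical(u0$universe, list())
  expect_identical(u0$truth$active_pairs$compound_id, character(0))

  u1 <- generate_ligand_universe(5, 3, fp_length = 128, seed = 42)
  u2 <- generate_ligand_universe(5, 3, fp_length = 128, seed = 42)
  expect_identical(u1, u2)

  expect_error(generate_ligand_universe(3, 1, seed = 1), "at least 2")
  expect_error(generate_ligand_universe(-1, 2, seed = 1), "non-negative")
  expect_error(generate_ligand_universe(3, 2, within_set_similarity = 1.2,
                                        seed = 1), "must be a number")
})

test_that("query compounds: actives trace to sources, decoys do not", {
  u <- generate_ligand_universe(10, 4, fp_length = 256, seed = 3)

  # perturb_bits = 0: exact copies of a source ligand
  q0 <- generate_query_compounds(u, n_actives = 8, n_decoys = 0,
                                 perturb_bits = 0, seed = 5)
  for (i in seq_len(8)) {
    src <- u$universe[[q0$truth$active_pairs$target_id[i]]]$ligands
    tcs <- apply(src, 1, tanimoto, b = q0$fingerprints[i, ])
    expect_equal(max(tcs), 1.0)
  }

  qe <- generate_query_compounds(u, n_actives = 0, n_decoys = 5,
                                 perturb_bits = 2, seed = 5)
  expect_equal(nrow(qe$truth$active_pairs), 0)
  expect_equal(nrow(qe$compounds), 5)

  expect_error(generate_query_compounds(u, n_actives = 1000, n_decoys = 0,
                                        perturb_bits = 0, seed = 1),
               "exceeds total ligand count")
  expect_error(generate_query_compounds(u, n_actives = 1, n_decoys = 0,
                                        perturb_bits = 256, seed = 1),
               "smaller than the fingerprint length")
})

test_that("lightly perturbed actives stay similar to their source set", {
  # perturbation ~5% of expected set bits
  hits <- 0; total <- 0
  for (s in 1:10) {
    u <- generate_ligand_universe(8, 4, fp_length = 256, seed = s)
    q <- generate_query_compounds(u, n_actives = 10, n_decoys = 0,
                                  perturb_bits = 4, seed = s + 100)
    for (i in seq_len(10)) {
      src <- u$universe[[q$truth$active_pairs$target_id[i]]]$ligands
      tcs <- apply(src, 1, tanimoto, b = q$fingerprints[i, ])
      total <- total + 1
      if (max(tcs) > 0.45) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("expression chips carry the planted structure", {
  g <- generate_expression_chips(500, 5, 5, n_planted = 20, effect = 1.5,
                                 sigma = 0.5, seed = 9)
  expect_length(g$chips, 2)
  expect_equal(length(g$truth$planted_deg_genes), 20)
  # planted genes are genes of the matrix
  expect_true(all(g$truth$planted_deg_genes %in% g$probe_gene_map$gene_symbol))
  # alternating signs
  expect_setequal(unique(sign(g$truth$planted_effect)), c(1, -1))
  # probe ids map many-to-one
  expect_gt(nrow(g$probe_gene_map),
            length(unique(g$probe_gene_map$gene_symbol)))

  g0 <- generate_expression_chips(100, 3, 3, n_planted = 0, seed = 2)
  expect_length(g0$truth$planted_deg_genes, 0)

  expect_error(generate_expression_chips(100, 1, 5, 0, seed = 1),
               "at least 2")
  expect_error(generate_expression_chips(10, 3, 3, 11, seed = 1),
               "exceeds n_genes")
  # determinism
  expect_identical(generate_expression_chips(50, 3, 3, 5, seed = 4),
                   generate_expression_chips(50, 3, 3, 5, seed = 4))
})

test_that("annotation generator plants one exact term and serializes", {
  genes <- sprintf("G%03d", 1:200)
  planted <- genes[1:10]
  a <- generate_annotations(genes, 30, c(5, 40), planted, seed = 6)
  expect_length(a$collection, 30)
  expect_identical(a$collection[[1]]$genes, planted)
  expect_identical(a$truth$enriched_terms, a$collection[[1]]$term_id)

  # single-term collection -> single GMT line; identical seed -> same bytes
  one <- generate_annotations(genes, 1, c(5, 40), planted, seed = 6)
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(one$collection, f1)
  write_gmt(generate_annotations(genes, 1, c(5, 40), planted,
                                 seed = 6)$collection, f2)
  expect_length(readLines(f1), 1)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(generate_annotations(genes, 5, c(5, 40), c("NOT_A_GENE"),
                                    seed = 1), "subset of genes")
  expect_error(generate_annotations(genes[1:10], 5, c(5, 40), seed = 1),
               "cannot exceed")
})

test_that("PPI edge generator matches the Erdos-Renyi expectation", {
  nodes <- sprintf("N%02d", 1:5)
  expect_equal(nrow(generate_ppi_edges(nodes, 0, seed = 1)), 0)
  full <- generate_ppi_edges(nodes, 1, seed = 1)
  expect_equal(nrow(full), 10)
  expect_true(all(full$combined_score >= 150 & full$combined_score <= 999))

  n <- 40; p <- 0.2
  m <- n * (n - 1) / 2
  counts <- vapply(1:20, function(s) {
    nrow(generate_ppi_edges(sprintf("N%02d", 1:n), p, seed = s))
  }, 0)
  # mean count within 3 SD of the binomial expectation
  expect_lt(abs(mean(counts) - p * m), 3 * sqrt(m * p * (1 - p) / 20))
})

test_that("generated files round-trip through the readers", {
  td <- withr::local_tempdir()
  u <- generate_ligand_universe(6, 3, fp_length = 64, seed = 1)
  write_target_db(u, file.path(td, "db.tsv"))
  back <- read_target_db(file.path(td, "db.tsv"))
  expect_equal(length(back), 6)
  expect_identical(unname(back[["TGT003"]]$ligands),
                   unname(u$universe[["TGT003"]]$ligands))

  q <- generate_query_compounds(u, 4, 2, perturb_bits = 2, seed = 2)
  write_fingerprints(q$fingerprints, file.path(td, "fps.tsv"))
  expect_identical(read_fingerprints(file.path(td, "fps.tsv")),
                   q$fingerprints)

  g <- generate_expression_chips(40, 3, 3, 5, seed = 3)
  write_series_matrix(g$chips[[1]], file.path(td, "chip.tsv"),
                      file.path(td, "groups.tsv"))
  m <- read_series_matrix(file.path(td, "chip.tsv"),
                          file.path(td, "groups.tsv"))
  expect_equal(m$values, g$chips[[1]]$values, tolerance = 1e-12)
  expect_identical(m$groups, g$chips[[1]]$groups)

  ann <- generate_annotations(sprintf("G%02d", 1:50), 8, c(3, 10),
                              sprintf("G%02d", 1:5), seed = 4)
  write_gmt(ann$collection, file.path(td, "c.gmt"))
  back2 <- read_gmt(file.path(td, "c.gmt"))
  expect_equal(lapply(back2, `[[`, "genes"),
               lapply(ann$collection, function(x) sort(x$genes)))
})
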