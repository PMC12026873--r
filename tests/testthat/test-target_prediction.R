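test_that("tanimoto matches hand enumeration and has metric properties", {
  a <- fp_from_bits(c(1, 3, 5, 7), 16)
  b <- fp_from_bits(c(3, 5, 9), 16)
  expect_equal(tanimoto(a, b), 2 / 5)   # |{3,5}| / |{1,3,5,7,9}|

  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(fp_from_bits(1:4, 16), fp_from_bits(5:8, 16)), 0)
  expect_equal(tanimoto(integer(16), integer(16)), 0)
  expect_error(tanimoto(integer(8), integer(16)), "length mismatch")

  set.seed(20)
  for (i in 1:50) {
    x <- as.integer(runif(32) < 0.4)
    y <- as.integer(runif(32) < 0.4)
    tc <- tanimoto(x, y)
    expect_equal(tc, oracle_tanimoto(x, y))
    expect_equal(tc, tanimoto(y, x))
    expect_gte(tc, 0); expect_lte(tc, 1)
  }
})

test_that("raw score sums exactly the similarities strictly above threshold", {
  # ligands constructed to give Tc 0.50, 0.30, 0.46 against the query
  query <- fp_from_bits(1:50, 100)
  ligands <- rbind(fp_from_bits(1:25, 100),   # 25/50 = 0.50
                   fp_from_bits(1:15, 100),   # 15/50 = 0.30
                   fp_from_bits(1:23, 100))   # 23/50 = 0.46
  rs <- raw_score(query, ligands, tc_threshold = 0.45)
  expect_equal(rs$raw, 0.96)
  expect_equal(rs$n_pairs, 3)

  # nothing above threshold -> 0; identical ligands -> N_A
  expect_equal(raw_score(query, rbind(fp_from_bits(1:15, 100)), 0.45)$raw, 0)
  expect_equal(raw_score(query, rbind(query, query, query), 0.45)$raw, 3.0)
  expect_error(raw_score(query, matrix(0L, 0, 100)), "no ligands")

  # oracle equivalence on random instances
  set.seed(7)
  for (i in 1:20) {
    q <- as.integer(runif(64) < 0.5)
    L <- matrix(as.integer(runif(64 * 5) < 0.5), nrow = 5)
    thr <- runif(1, 0.2, 0.7)
    expect_equal(raw_score(q, L, thr)$raw, oracle_raw_score(q, L, thr))
  }
})

test_that("z-score follows the power-law standardization", {
  model <- structure(list(mu = 0.01, sigma = 0.02, lam = 0.335,
                          tc_threshold = 0.45, fit_n = 1000),
                     class = "BackgroundModel")
  # centered case
  expect_equal(z_score(0.01 * 50, 50, model), 0)
  # direct evaluation: Z = 1 / (0.02 * 100^0.335), 100^0.335 via exp/log
  expect_equal(z_score(2.0, 100, model),
               1.0 / (0.02 * exp(0.335 * log(100))))
  # doubling sigma halves Z
  model2 <- model; model2$sigma <- 0.04
  expect_equal(z_score(2.0, 100, model2), z_score(2.0, 100, model) / 2)
  # strictly increasing in raw
  zs <- z_score(seq(0.5, 3, by = 0.5), 10, model)
  expect_true(all(diff(zs) > 0))
  expect_error(z_score(1, 0, model), "n_pairs")
})

test_that("background calibration is deterministic and sane", {
  u <- generate_ligand_universe(12, 6, fp_length = 256,
                                within_set_similarity = 0.7, seed = 5)
  m1 <- calibrate_background(u, set_sizes = c(3, 6, 12), n_samples = 600,
                             seed = 9)
  m2 <- calibrate_background(u, set_sizes = c(3, 6, 12), n_samples = 600,
                             seed = 9)
  expect_identical(m1, m2)
  expect_gt(m1$mu, 0)
  expect_gt(m1$sigma, 0)
  expect_equal(m1$lam, 0.335)

  # single set size: fit still defined
  m3 <- calibrate_background(u, set_sizes = 6, n_samples = 300, seed = 2)
  expect_true(is.finite(m3$mu) && is.finite(m3$sigma))

  expect_error(calibrate_background(list(), n_samples = 200, seed = 1),
               "empty")
  expect_error(calibrate_background(u, n_samples = 50, seed = 1),
               "at least 100")
})

test_that("background mean recovers the database's true per-pair score", {
  u <- generate_ligand_universe(15, 8, fp_length = 128,
                                within_set_similarity = 0.7, seed = 21)
  pool <- do.call(rbind, lapply(u$universe, `[[`, "ligands"))
  # brute-force truth: mean thresholded Tc over all ordered distinct pairs
  inter <- pool %*% t(pool)
  pops <- rowSums(pool)
  uni <- outer(pops, pops, "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  diag(tc) <- NA
  mu_true <- mean(ifelse(!is.na(tc) & tc > 0.45, tc, 0), na.rm = TRUE)
  model <- calibrate_background(u, set_sizes = c(2, 5, 10, 20),
                                n_samples = 5000, seed = 13)
  expect_lt(abs(model$mu - mu_true) / mu_true, 0.2)
})

test_that("prediction ranks the true source target first", {
  u <- generate_ligand_universe(15, 5, fp_length = 256,
                                within_set_similarity = 0.7, seed = 31)
  q <- generate_query_compounds(u, n_actives = 12, n_decoys = 0,
                                perturb_bits = 4, seed = 32)
  model <- calibrate_background(u, n_samples = 800, seed = 33)
  top1 <- 0
  for (i in seq_len(12)) {
    pred <- predict_targets(q$fingerprints[i, ], u, model, z_min = -Inf,
                            compound_id = rownames(q$fingerprints)[i])
    expect_true(all(diff(pred$z) <= 1e-12))           # sorted by z
    expect_true(all(pred$raw > 0))
    expect_true(all(pred$normalized >= 0 & pred$normalized <= 1))
    if (nrow(pred) > 0 &&
        pred$target_id[1] == q$truth$active_pairs$target_id[i]) {
      top1 <- top1 + 1
    }
  }
  expect_gte(top1 / 12, 0.9)

  # orthogonal query -> empty result
  empty <- predict_targets(integer(256), u, model, z_min = -Inf)
  expect_equal(nrow(empty), 0)
})

test_that("active pairs outscore decoys in Z (end-to-end separation)", {
  u <- generate_ligand_universe(10, 5, fp_length = 256,
                                within_set_similarity = 0.7, seed = 41)
  q <- generate_query_compounds(u, n_actives = 10, n_decoys = 10,
                                perturb_bits = 4, seed = 42)
  model <- calibrate_background(u, n_samples = 600, seed = 43)
  pred <- predict_targets_all(q$fingerprints, u, model, z_min = -Inf)
  is_active <- pred$compound_id %in% q$truth$active_pairs$compound_id
  expect_gt(median(pred$z[is_active]),
            if (any(!is_active)) median(pred$z[!is_active]) else 0)
})
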