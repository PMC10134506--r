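test_that("every algorithm separates a cleanly separable training set", {
  ds <- separable_dataset(20)
  f <- featurize_dataset(ds, "ECFP")
  for (alg in c("ADA", "BNB", "KNN", "RF", "SVM")) {
    m <- train(model_spec(alg, "ECFP", seed = 11), f$X, f$y)
    ccr <- carciprofiler:::.metrics_at_threshold(
      predict_probability(m, f$X), f$y)[["ccr"]]
    expect_equal(ccr, 1.0, label = paste(alg, "resubstitution CCR"))
  }
})

test_that("training is deterministic under a fixed spec and seed", {
  ds <- planted_dataset(40, seed = 13)
  for (alg in c("ADA", "RF", "SVM")) {
    f <- featurize_dataset(ds, "MACCS")
    m1 <- train(model_spec(alg, "MACCS", seed = 99), f$X, f$y)
    m2 <- train(model_spec(alg, "MACCS", seed = 99), f$X, f$y)
    expect_equal(predict_probability(m1, f$X), predict_probability(m2, f$X),
                 tolerance = 1e-12, label = paste(alg, "determinism"))
  }
})

test_that("an overfit 1-NN model predicts its own training labels", {
  ds <- planted_dataset(24, seed = 21)
  f <- featurize_dataset(ds, "ECFP")
  keep <- !duplicated(lapply(seq_len(nrow(f$X)), function(i) f$X[i, ]))
  m <- train(model_spec("KNN", "ECFP", grid = list(k = 1), seed = 1),
             f$X[keep, ], f$y[keep])
  expect_equal(predict_probability(m, f$X[keep, ]), as.numeric(f$y[keep]))
})

test_that("probabilities are bounded and dimension mismatches error", {
  ds <- planted_dataset(30, seed = 5)
  f <- featurize_dataset(ds, "MACCS")
  m <- train(model_spec("BNB", "MACCS", seed = 2), f$X, f$y)
  p <- predict_probability(m, f$X)
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_probability(m, f$X[, 1:100]), "mismatch")
  expect_error(train(model_spec("RF", "MACCS", seed = 1),
                     f$X, rep(1L, nrow(f$X))), "both classes")
})

test_that("hyperparameter tuning picks from the declared grid", {
  pb <- planted_bits(60, p = 64, seed = 8)
  m <- train(model_spec("KNN", "ECFP", grid = default_grid("KNN"), seed = 3),
             pb$X, pb$y)
  expect_true(m$params$k %in% default_grid("KNN")$k)
  m0 <- train(model_spec("KNN", "ECFP", seed = 3), pb$X, pb$y)
  expect_equal(m0$params$k, default_grid("KNN")$k[1])  # default, no tuning
})

test_that("five folds partition the data with near-equal, stratified sizes", {
  pb <- planted_bits(100, p = 64, seed = 2)
  cv <- carciprofiler:::.cv_matrix(model_spec("BNB", "ECFP", seed = 4),
                                   pb$X, pb$y, seed = 10)
  expect_equal(as.integer(table(cv$fold)), rep(20L, 5))
  expect_equal(sort(unique(cv$fold)), 1:5)
  # stratification: each fold is half active
  for (f in 1:5) expect_equal(sum(pb$y[cv$fold == f]), 10)
  expect_error(
    carciprofiler:::.cv_matrix(model_spec("BNB", "ECFP", seed = 4),
                               pb$X[1:8, ], pb$y[1:8], 1),
    "n >= 10")
  # odd sizes still differ by at most one
  cv2 <- carciprofiler:::.cv_matrix(model_spec("BNB", "ECFP", seed = 4),
                                    pb$X[1:97, ], pb$y[1:97], seed = 10)
  expect_lte(diff(range(table(cv2$fold))), 1)
})

test_that("random forest recovers a strong planted bit signal out of fold", {
  pb <- planted_bits(400, p = 1024, n_signal = 20, strength = 0.9, seed = 77)
  cv <- carciprofiler:::.cv_matrix(model_spec("RF", "ECFP", seed = 42),
                                   pb$X, pb$y, seed = 7)
  expect_gte(cv$metrics[["ccr"]], 0.85)
})

test_that("cross-validated CCR is centered at chance on label-free data", {
  ccrs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    X <- matrix(rbinom(60 * 128, 1, 0.2), nrow = 60)
    colnames(X) <- paste0("bit", 1:128)
    y <- rep(c(1L, 0L), each = 30)
    carciprofiler:::.cv_matrix(model_spec("BNB", "ECFP", seed = s),
                               X, y, seed = s)$metrics[["ccr"]]
  }, 0)
  expect_lt(abs(mean(ccrs) - 0.5), 0.08)
})

test_that("consensus averages member out-of-fold probabilities", {
  ds <- planted_dataset(50, seed = 14)
  cm <- build_consensus("AID1", ds, seed = 6)
  expect_length(cm$members, 15)
  expect_equal(cm$cv$prob, rowMeans(cm$member_oof))
  # bounded by member extremes
  expect_true(all(cm$cv$prob >= apply(cm$member_oof, 1, min) - 1e-12))
  expect_true(all(cm$cv$prob <= apply(cm$member_oof, 1, max) + 1e-12))
  # the 15 specs are the full algorithm x fingerprint grid
  specs <- consensus_specs(3)
  expect_length(specs, 15)
  combos <- unique(vapply(specs, function(s)
    paste(s$algorithm, s$fingerprint_kind), ""))
  expect_length(combos, 15)
})

test_that("consensus beats the median member in most seeded runs", {
  wins <- 0
  for (s in 1:20) {
    ds <- planted_dataset(60, signal = 0.85, seed = 300 + s)
    cm <- suppressWarnings(build_consensus("A", ds, seed = 300 + s))
    if (cm$cv$metrics[["ccr"]] >= stats::median(cm$member_cv$ccr)) {
      wins <- wins + 1
    }
  }
  expect_gte(wins, 16)  # >= 80% of runs
})

test_that("consensus predictions are calibrated on held-out planted data", {
  train_ds <- planted_dataset(150, signal = 0.9, seed = 501)
  test_ds <- planted_dataset(150, signal = 0.9, seed = 502)
  cm <- build_consensus("A", train_ds, seed = 501, evaluate = FALSE)
  p <- predict(cm, test_ds)
  bins <- cut(p, breaks = seq(0, 1, 0.1), include.lowest = TRUE)
  for (b in levels(bins)) {
    idx <- which(bins == b & !is.na(p))
    if (length(idx) < 20) next
    expect_lt(abs(mean(p[idx]) - mean(test_ds$y[idx])), 0.1,
              label = paste("reliability in bin", b))
  }
})
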