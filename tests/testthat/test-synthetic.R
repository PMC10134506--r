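test_that("every grammar fragment and generated structure parses", {
  frags <- c(carciprofiler:::.BENIGN_FRAGMENTS, carciprofiler:::.TOXIC_FRAGMENTS)
  expect_true(all(smiles_parses(frags)))
  for (s in c(1, 2, 3)) {
    labs <- rep(c("carcinogen", "noncarcinogen"), 40)
    g <- generate_structures(80, 0.9, labs, seed = s)
    expect_true(all(smiles_parses(g$smiles)), label = paste("seed", s))
  }
})

test_that("structure generation is byte-identical per seed", {
  labs <- rep(c("carcinogen", "noncarcinogen"), 15)
  g1 <- generate_structures(30, 0.5, labs, seed = 8)
  g2 <- generate_structures(30, 0.5, labs, seed = 8)
  expect_identical(g1, g2)
  g3 <- generate_structures(30, 0.5, labs, seed = 9)
  expect_false(identical(g2$smiles, g3$smiles))
})

test_that("structure_signal = 1 forces a toxic fragment into every carcinogen", {
  labs <- rep(c("carcinogen", "noncarcinogen"), 30)
  g <- generate_structures(60, 1.0, labs, seed = 12)
  carc <- g[g$label == "carcinogen", ]
  expect_true(all(carc$has_toxic_fragment))
  has_frag <- vapply(carc$smiles, function(s)
    any(vapply(carciprofiler:::.TOXIC_FRAGMENTS,
               function(f) grepl(f, s, fixed = TRUE), TRUE)), TRUE)
  expect_true(all(has_frag))
})

test_that("structure_signal = 0 decouples fragments from labels", {
  small_p <- 0
  for (s in 1:10) {
    labs <- rep(c("carcinogen", "noncarcinogen"), each = 100)
    g <- generate_structures(200, 0.0, labs, seed = 100 + s)
    tab <- table(g$label, g$has_toxic_fragment)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    if (p < 0.05) small_p <- small_p + 1
  }
  expect_lte(small_p, 2)
})

test_that("planted odds ratios are realized within sampling error", {
  ors <- c()
  for (s in 1:10) {
    spec <- plant_spec(seed = 600 + s)  # n_probe 300, OR 9, conclusive 0.8
    labels <- setNames(
      rep(c("carcinogen", "noncarcinogen"), c(52, 248)),
      sprintf("CP%05d", 1:300))
    bp <- generate_bioprofile(labels, spec)
    pa <- bp$truth$per_assay
    rel <- pa[pa$relevant, ]
    ors <- c(ors, (rel$a * rel$d) / pmax(1, rel$b * rel$c))
  }
  # realized per-assay sample OR within 2-fold of the planted 9 in >= 90%
  # of draws (about 42 conclusive carcinogens per assay; the log-OR
  # standard error is ~0.38, so 2-fold is ~1.8 sigma)
  expect_gte(mean(ors > 4.5 & ors < 18), 0.9)
})

test_that("null assays carry no planted association", {
  spec <- plant_spec(n_probe = 200, n_assays = 20, n_relevant = 0,
                     relevant_odds_ratio = 1, seed = 44)
  labels <- setNames(rep(c("carcinogen", "noncarcinogen"), c(40, 160)),
                     paste0("N", 1:200))
  bp <- generate_bioprofile(labels, spec)
  expect_length(bp$truth$relevant_assays, 0)
  ps <- vapply(seq_len(nrow(bp$truth$per_assay)), function(i) {
    r <- bp$truth$per_assay[i, ]
    fisher_exact_two_sided(r$a, r$b, r$c, r$d)
  }, 0)
  expect_lte(sum(ps < 0.05), 4)  # around alpha * 20, generous bound
})

test_that("conclusive_rate = 1 leaves no inconclusive or untested cells", {
  spec <- plant_spec(n_probe = 40, n_assays = 5, n_relevant = 1,
                     conclusive_rate = 1, seed = 2)
  labels <- setNames(rep(c("carcinogen", "noncarcinogen"), c(8, 32)),
                     paste0("C", 1:40))
  bp <- generate_bioprofile(labels, spec)
  s <- profile_summary(bp$profile)
  expect_equal(unname(s["n_inconclusive_or_untested"]), 0)
})

test_that("infeasible plant specifications fail loudly", {
  expect_error(plant_spec(relevant_odds_ratio = 0), "odds_ratio")
  expect_error(plant_spec(relevant_odds_ratio = Inf), "odds_ratio")
  expect_error(plant_spec(base_active_rate = 1), "base_active_rate")
  expect_error(plant_spec(conclusive_rate = 0))
})

test_that("libraries have tunable toxic prevalence and a disjoint id space", {
  clean <- generate_library(50, 0, seed = 3)
  expect_false(any(attr(clean, "truth")$toxic_like))
  expect_true(all(grepl("^LIB", clean$id)))
  dirty <- generate_library(50, 0.3, seed = 3)
  expect_equal(sum(attr(dirty, "truth")$toxic_like), 15)
  expect_identical(generate_library(50, 0.3, seed = 3), dirty)
})

test_that("fixture files round-trip through the workflow readers", {
  dir <- withr::local_tempdir()
  spec <- plant_spec(n_probe = 30, n_assays = 5, n_relevant = 1, seed = 5)
  simulate_fixture(spec, dir, n_library = 20)
  expect_true(all(file.exists(file.path(dir,
    c("probe.csv", "records.csv", "library_clean.csv", "library_dirty.csv",
      "truth.json")))))
  probe <- read_probe_csv(file.path(dir, "probe.csv"))
  expect_equal(nrow(probe), 30)
  bp <- read_bioprofile(file.path(dir, "records.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(length(truth$profile_truth$per_assay), 5)
})
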