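test_that("carcinogenicity probability is the mean of mixed evidence", {
  expect_equal(carcinogenicity_probability(rep(1, 8)), 1.0)
  expect_equal(carcinogenicity_probability(c(1, 0, 0.6, 0.8)), 0.6)
  # all-experimental evidence reduces to the fraction of active assays
  ev <- data.frame(source = rep("experimental", 5), value = c(1, 1, 0, 0, 0))
  expect_equal(carcinogenicity_probability(ev), 2 / 5)
  expect_error(carcinogenicity_probability(numeric(0)), "nonempty")
  bad <- data.frame(source = "experimental", value = 0.4)
  expect_error(carcinogenicity_probability(bad), "binary")
  expect_error(carcinogenicity_probability(c(0.2, 1.4)), "0, 1")
})

test_that("probability score is permutation-invariant and monotone", {
  set.seed(4)
  for (i in 1:25) {
    ev <- runif(8)
    expect_equal(carcinogenicity_probability(sample(ev)),
                 carcinogenicity_probability(ev))
    j <- sample(8, 1)
    bumped <- ev
    bumped[j] <- min(1, ev[j] + runif(1, 0, 1 - ev[j]))
    expect_gte(carcinogenicity_probability(bumped),
               carcinogenicity_probability(ev))
  }
})

test_that("classification threshold and applicability domain follow the bands", {
  # a mid-band probability (aniline-like 37.3%) is an unreliable noncarcinogen
  r <- classify_and_domain(0.373)
  expect_equal(r$classification, "noncarcinogen")
  expect_equal(r$ad_status, "out_of_domain")
  expect_equal(classify_and_domain(0.85),
               data.frame(classification = "carcinogen",
                          ad_status = "in_domain", stringsAsFactors = FALSE))
  # 0.5 tie goes to carcinogen but sits outside the confidence band
  tie <- classify_and_domain(0.5)
  expect_equal(tie$classification, "carcinogen")
  expect_equal(tie$ad_status, "out_of_domain")
  # band endpoints are in-domain (closed endpoints)
  expect_equal(classify_and_domain(c(0.3, 0.7))$ad_status,
               rep("in_domain", 2))
  # every probability is exactly one of in/out of domain, and widening the
  # band only removes compounds from the domain
  p <- seq(0, 1, 0.01)
  s1 <- classify_and_domain(p, ad_low = 0.3, ad_high = 0.7)$ad_status
  expect_true(all(s1 %in% c("in_domain", "out_of_domain")))
  s2 <- classify_and_domain(p, ad_low = 0.2, ad_high = 0.8)$ad_status
  expect_true(all(which(s2 == "in_domain") %in% which(s1 == "in_domain")))
})

test_that("probe scoring prefers experimental outcomes and ranks by id on ties", {
  models <- stub_models(c("a1", "a2", "a3", "a4"))
  probe <- data.frame(
    id = c("full", "none", "tieA", "tieB"),
    canonical_smiles = canonical_smiles(c("CCO", "CCN", "CCC", "CCCC")),
    label = c("carcinogen", "noncarcinogen", "unknown", "unknown"),
    stringsAsFactors = FALSE
  )
  # "full" tested everywhere (3 active / 1 inactive); ties share one profile
  rec <- rbind(
    records_df("full", c("a1", "a2", "a3", "a4"),
               c("active", "active", "active", "inactive")),
    records_df("tieA", c("a1", "a2", "a3", "a4"),
               c("active", "inactive", "active", "inactive")),
    records_df("tieB", c("a1", "a2", "a3", "a4"),
               c("inactive", "active", "inactive", "active"))
  )
  bp <- build_bioprofile(rec)
  sc <- score_probe_set(probe, bp, models)
  expect_equal(sc$n_predicted[sc$id == "full"], 0)
  expect_equal(sc$probability[sc$id == "full"], 0.75)
  expect_equal(sc$n_active_assays[sc$id == "full"], 3)
  expect_equal(sc$n_experimental[sc$id == "none"], 0)
  expect_equal(sc$n_predicted[sc$id == "none"], 4)
  # identical probabilities rank by compound id
  expect_lt(sc$rank[sc$id == "tieA"], sc$rank[sc$id == "tieB"])
  expect_equal(sc$rank, seq_len(nrow(sc)))
  m <- attr(sc, "metrics")
  expect_true(!is.null(m$overall))
})

test_that("library screening flags strict majorities only", {
  models <- stub_models(paste0("a", 1:8))
  lib <- data.frame(id = c("half", "five", "all"),
                    canonical_smiles = canonical_smiles(c("CCO", "CCN", "CCC")),
                    stringsAsFactors = FALSE)
  rec <- rbind(
    records_df("half", paste0("a", 1:8),
               rep(c("active", "inactive"), each = 4)),
    records_df("five", paste0("a", 1:8),
               rep(c("active", "inactive"), c(5, 3))),
    records_df("all", paste0("a", 1:8), rep("active", 8))
  )
  bp <- build_bioprofile(rec)
  rep <- screen_library(lib, models, profile_of_library = bp)
  cmp <- rep$compounds
  expect_false(cmp$flagged[cmp$id == "half"])  # 4/8 is not > 4
  expect_true(cmp$flagged[cmp$id == "five"])
  expect_true(cmp$flagged[cmp$id == "all"])
  # the all-assays-active stratum ranks on top
  expect_equal(cmp$id[1], "all")
  expect_equal(rep$summary[["frac_active_calls"]], (4 + 5 + 8) / 24)
  expect_equal(rep$summary[["frac_flagged"]], 2 / 3)
})

test_that("probe-overlapping library compounds are removed before screening", {
  models <- stub_models(c("a1", "a2"))
  probe <- data.frame(id = "p1", canonical_smiles = canonical_smiles("CCO"),
                      label = "carcinogen", stringsAsFactors = FALSE)
  lib <- data.frame(id = c("l1", "l2"),
                    canonical_smiles = canonical_smiles(c("OCC", "CCN")),
                    stringsAsFactors = FALSE)
  rep <- screen_library(lib, models, probe = probe)
  expect_equal(rep$n_removed_overlap, 1)
  expect_equal(rep$compounds$id, "l2")
  expect_error(screen_library(lib[1, ], models, probe = probe), "empty")
})

test_that("dirtier libraries yield higher flagged fractions than clean ones", {
  ds <- planted_dataset(70, signal = 0.9, seed = 900)
  cm <- build_consensus("A", ds, seed = 900, evaluate = FALSE)
  models <- list(a1 = cm, a2 = cm, a3 = cm)
  models <- Map(function(m, a) { m$assay_id <- a; m }, models, names(models))
  wins <- 0
  for (s in 1:20) {
    clean <- generate_library(60, 0.02, seed = 2000 + s)
    dirty <- generate_library(60, 0.30, seed = 4000 + s)
    cur_c <- suppressWarnings(curate_probe(clean))
    cur_d <- suppressWarnings(curate_probe(dirty))
    f_clean <- screen_library(cur_c, models)$summary[["frac_flagged"]]
    f_dirty <- screen_library(cur_d, models)$summary[["frac_flagged"]]
    if (f_dirty > f_clean) wins <- wins + 1
  }
  expect_gte(wins, 19)
})
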