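test_that("minimum-active filter applies the >= 5 boundary exactly", {
  rec <- rbind(
    records_df(paste0("c", 1:4), "a_four", rep("active", 4)),
    records_df(paste0("c", 1:5), "a_five", rep("active", 5)),
    records_df("c9", "a_none", "inactive")
  )
  bp <- build_bioprofile(rec)
  probe <- data.frame(id = paste0("c", 1:9),
                      canonical_smiles = "CCO", label = "carcinogen",
                      stringsAsFactors = FALSE)
  kept <- min_active_filter(bp, probe)
  expect_equal(kept, "a_five")
  expect_equal(min_active_filter(bp, probe, min_active = 4),
               c("a_four", "a_five"))
})

test_that("Fisher's exact test matches stats::fisher.test on fixed cases", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  expect_equal(fisher_exact_two_sided(0, 0, 3, 7), 1.0)  # degenerate margin
  expect_equal(fisher_exact_two_sided(3, 0, 0, 0), 1.0)
  expect_equal(fisher_exact_two_sided(8, 2, 1, 9),
               stats::fisher.test(matrix(c(8, 2, 1, 9), 2, byrow = TRUE))$p.value,
               tolerance = 1e-12)
  expect_error(fisher_exact_two_sided(0, 0, 0, 0), "empty")
})

test_that("Fisher p-values agree with the R oracle over random tables", {
  set.seed(42)
  for (i in 1:200) {
    t <- rmultinom(1, sample(4:40, 1), rep(0.25, 4))[, 1]
    mine <- fisher_exact_two_sided(t[1], t[2], t[3], t[4])
    oracle <- stats::fisher.test(matrix(t, 2, byrow = TRUE))$p.value
    expect_equal(mine, min(1, oracle), tolerance = 1e-10)
    g <- fisher_exact_two_sided(t[1], t[2], t[3], t[4], "greater")
    og <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                             alternative = "greater")$p.value
    expect_equal(g, min(1, og), tolerance = 1e-10)
  }
})

test_that("classification metrics follow the defining formulas", {
  m <- classification_metrics(tp = 3, fn = 1, tn = 2, fp = 2)
  expect_equal(as.numeric(m), c(0.75, 0.5, 0.625, 0.6))
  perfect <- classification_metrics(tp = 4, fn = 0, tn = 7, fp = 0)
  expect_equal(as.numeric(perfect), c(1, 1, 1, 1))
  deg <- classification_metrics(tp = 0, fn = 5, tn = 5, fp = 0)
  expect_equal(as.numeric(deg[1:3]), c(0, 1, 0.5))
  expect_true(is.na(deg[["ppv"]]))
  expect_equal(attr(deg, "undefined"), "ppv")
})

test_that("CCR is swap-invariant and label inversion maps ccr to 1 - ccr", {
  set.seed(9)
  for (i in 1:50) {
    cc <- sample(0:8, 4, replace = TRUE)
    if (cc[1] + cc[2] == 0 || cc[3] + cc[4] == 0) next
    m <- classification_metrics(cc[1], cc[2], cc[3], cc[4])
    swapped <- classification_metrics(cc[3], cc[4], cc[1], cc[2])
    expect_equal(swapped[["ccr"]], m[["ccr"]])
    inverted <- classification_metrics(cc[2], cc[1], cc[4], cc[3])
    expect_equal(inverted[["ccr"]], 1 - m[["ccr"]])
  }
})

test_that("assay-endpoint confusion maps outcomes to calls directly", {
  rec <- records_df(paste0("c", 1:7), "a1",
                    c("active", "active", "inactive",
                      "inactive", "inactive", "inactive", "active"))
  probe <- data.frame(
    id = paste0("c", 1:7), canonical_smiles = "CCO",
    label = c(rep("carcinogen", 3), rep("noncarcinogen", 4)),
    stringsAsFactors = FALSE
  )
  conf <- assay_endpoint_confusion(build_bioprofile(rec), probe, "a1")
  expect_equal(unname(conf), c(2, 1, 3, 1))
  expect_equal(classification_metrics(conf)[["ccr"]], (2/3 + 3/4) / 2)
  expect_error(
    assay_endpoint_confusion(build_bioprofile(records_df("c1", "a2", "inconclusive")),
                             probe, "a2"),
    "no conclusive")
})

test_that("selection stages apply in order and label first failure", {
  spec <- plant_spec(n_probe = 150, n_assays = 15, n_relevant = 3,
                     seed = 19)
  probe <- generate_probe(spec)
  cur <- suppressWarnings(curate_probe(probe))
  bp <- generate_bioprofile(setNames(probe$label, probe$id), spec)
  st <- select_relevant_assays(bp$profile, cur)
  expect_setequal(
    intersect(st$assay_id[st$selected], bp$truth$relevant_assays),
    bp$truth$relevant_assays)
  expect_true(all(st$reject_reason[!st$selected] %in%
                  c("min_active", "fisher_p", "ccr")))
  expect_true(all(is.na(st$reject_reason[st$selected])))
  expect_true(all(st$coverage >= 0 & st$coverage <= 1))
  expect_true(all(st$n_active <= st$n_tested))

  # monotonicity: stricter thresholds never enlarge the selected set
  st_strict_p <- select_relevant_assays(bp$profile, cur, p_threshold = 0.005)
  expect_true(all(st_strict_p$assay_id[st_strict_p$selected] %in%
                  st$assay_id[st$selected]))
  st_strict_ccr <- suppressWarnings(
    select_relevant_assays(bp$profile, cur, ccr_threshold = 0.8))
  expect_true(all(st_strict_ccr$assay_id[st_strict_ccr$selected] %in%
                  st$assay_id[st$selected]))
  # an impossible CCR bar empties the selection with a warning, not an error
  expect_warning(st_none <- select_relevant_assays(bp$profile, cur,
                                                   ccr_threshold = 1.01),
                 "no assay")
  expect_false(any(st_none$selected))
})

test_that("undersampling equalizes classes as a seeded subset", {
  ds <- data.frame(id = seq_len(342),
                   y = rep(c(1L, 0L), c(59, 283)))
  bal <- undersample_balance(ds, seed = 17)
  expect_equal(sum(bal$y == 1), 59)
  expect_equal(sum(bal$y == 0), 59)
  expect_true(all(bal$id %in% ds$id))
  expect_true(all(ds$id[ds$y == 1] %in% bal$id))  # minority untouched
  expect_equal(undersample_balance(ds, seed = 17), bal)  # deterministic
  even <- data.frame(id = 1:200, y = rep(c(1L, 0L), each = 100))
  expect_equal(undersample_balance(even, seed = 1), even)  # already balanced
  expect_error(undersample_balance(data.frame(id = 1:5, y = rep(1L, 5)), 1),
               "both classes")
})
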