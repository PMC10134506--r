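## Assay relevance screening: minimum-active filter -> Fisher's exact test
## -> endpoint-CCR screen, plus dataset balancing by undersampling.

#' Minimum-active filter
#'
#' Retains assays with at least `min_active` ACTIVE outcomes among the
#' probe compounds.
#'
#' @param profile a `bioprofile`.
#' @param probe a curated `probe_set`.
#' @param min_active minimum number of active probe results (default 5).
#' @return character vector of retained assay ids.
#' @export
min_active_filter <- function(profile, probe, min_active = 5) {
  stopifnot(inherits(profile, "bioprofile"))
  oc <- profile$outcomes
  oc <- oc[oc$compound_id %in% probe$id & oc$outcome == "active", , drop = FALSE]
  counts <- table(factor(oc$assay_id, levels = profile$assays))
  names(counts)[counts >= min_active]
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the exact two-sided p-value by the point-probability rule: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose point probability does not exceed that of the observed
#' table. With `alternative = "greater"` the upper tail (positive
#' association between carcinogenicity and assay activity) is summed
#' instead. A degenerate margin (an all-zero row or column) carries no
#' information about association and returns p = 1 by convention.
#'
#' @param a,b,c,d cell counts: `a` carcinogens active, `b` carcinogens
#'   inactive, `c` noncarcinogens active, `d` noncarcinogens inactive.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return p-value in (0, 1].
#' @examples
#' fisher_exact_two_sided(5, 5, 5, 5)  # 1: perfectly independent
#' @export
fisher_exact_two_sided <- function(a, b, c, d,
                                   alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  stopifnot(length(counts) == 4, all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) < 1) stop("empty table")
  m <- a + b      # carcinogens
  n <- c + d      # noncarcinogens
  k <- a + c      # active margin
  if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1.0)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  p <- if (alternative == "two.sided") {
    # relative tolerance guards against ties broken by floating-point noise
    sum(dens[dens <= p_obs * (1 + 1e-7)])
  } else {
    sum(dens[support >= a])
  }
  min(1, p)
}

#' Confusion counts of one assay against the probe endpoint
#'
#' Treats the assay response as a carcinogenicity call: ACTIVE predicts
#' carcinogen, INACTIVE predicts noncarcinogen. Only probe compounds with a
#' conclusive outcome in the assay are counted.
#'
#' @param profile a `bioprofile`.
#' @param probe a curated `probe_set` with labels.
#' @param assay_id assay identifier.
#' @return named integer vector `tp`, `fn`, `tn`, `fp`.
#' @export
assay_endpoint_confusion <- function(profile, probe, assay_id) {
  stopifnot(inherits(profile, "bioprofile"))
  oc <- profile$outcomes
  oc <- oc[oc$assay_id == assay_id & oc$outcome != "inconclusive" &
           oc$compound_id %in% probe$id, , drop = FALSE]
  lab <- probe$label[match(oc$compound_id, probe$id)]
  oc <- oc[lab != "unknown", , drop = FALSE]
  lab <- lab[lab != "unknown"]
  if (nrow(oc) == 0) {
    stop("assay ", assay_id, " has no conclusive outcomes on labeled probe compounds")
  }
  act <- oc$outcome == "active"
  carc <- lab == "carcinogen"
  c(tp = sum(carc & act), fn = sum(carc & !act),
    tn = sum(!carc & !act), fp = sum(!carc & act))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), the correct
#' classification rate (CCR, balanced accuracy) is their average, and
#' PPV = TP/(TP+FP). A metric whose denominator is zero is undefined and
#' reported as `NA` with the `undefined` attribute flagging which.
#'
#' @param tp,fn,tn,fp nonnegative integer confusion counts. Alternatively a
#'   single named vector as returned by [assay_endpoint_confusion()] may be
#'   passed as `tp`.
#' @return named numeric vector `sensitivity`, `specificity`, `ccr`, `ppv`
#'   (NA where undefined), with attribute `undefined`.
#' @examples
#' classification_metrics(tp = 3, fn = 1, tn = 2, fp = 2)
#' @export
classification_metrics <- function(tp, fn = NULL, tn = NULL, fp = NULL) {
  if (is.null(fn) && length(tp) == 4) {
    fn <- tp[["fn"]]; tn <- tp[["tn"]]; fp <- tp[["fp"]]; tp <- tp[["tp"]]
  }
  stopifnot(all(c(tp, fn, tn, fp) >= 0))
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ccr <- if (!is.na(sens) && !is.na(spec)) (sens + spec) / 2 else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  out <- c(sensitivity = sens, specificity = spec, ccr = ccr, ppv = ppv)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Select carcinogenicity-relevant assays
#'
#' Applies three screening stages in order: (1) the minimum-active filter,
#' (2) Fisher's exact test of independence between probe carcinogenicity
#' and assay response (keep p < `p_threshold`), and (3) the endpoint-CCR
#' screen (keep CCR >= `ccr_threshold`). Each rejected assay is labeled
#' with its first failing stage. No multiple-testing correction is applied
#' by default; `bh_correct = TRUE` switches stage 2 to Benjamini-Hochberg
#' adjusted p-values.
#'
#' @param profile a `bioprofile`.
#' @param probe a curated, labeled `probe_set`.
#' @param p_threshold Fisher p-value cutoff (default 0.05).
#' @param min_active minimum active-result count (default 5).
#' @param ccr_threshold endpoint-CCR cutoff, inclusive (default 0.65).
#' @param alternative sidedness of the Fisher test; see
#'   [fisher_exact_two_sided()].
#' @param bh_correct apply Benjamini-Hochberg correction across assays
#'   before thresholding p (default FALSE).
#' @return data.frame (one row per assay) with columns `assay_id`,
#'   `n_tested`, `n_active`, `fisher_p`, `ccr`, `ppv`, `coverage`,
#'   `selected`, `reject_reason`.
#' @export
select_relevant_assays <- function(profile, probe,
                                   p_threshold = 0.05, min_active = 5,
                                   ccr_threshold = 0.65,
                                   alternative = c("two.sided", "greater"),
                                   bh_correct = FALSE) {
  stopifnot(inherits(profile, "bioprofile"))
  alternative <- match.arg(alternative)
  labeled <- probe[probe$label != "unknown", , drop = FALSE]
  assays <- profile$assays
  oc <- profile$outcomes
  oc <- oc[oc$compound_id %in% labeled$id & oc$outcome != "inconclusive", ,
           drop = FALSE]
  lab <- labeled$label[match(oc$compound_id, labeled$id)]

  stats_list <- lapply(assays, function(aid) {
    sel <- oc$assay_id == aid
    act <- oc$outcome[sel] == "active"
    carc <- lab[sel] == "carcinogen"
    conf <- c(tp = sum(carc & act), fn = sum(carc & !act),
              tn = sum(!carc & !act), fp = sum(!carc & act))
    n_tested <- sum(sel)
    n_active <- sum(act)
    fisher_p <- if (n_tested > 0) {
      fisher_exact_two_sided(conf[["tp"]], conf[["fn"]], conf[["fp"]],
                             conf[["tn"]], alternative = alternative)
    } else 1.0
    met <- classification_metrics(conf)
    data.frame(assay_id = aid, n_tested = n_tested, n_active = n_active,
               fisher_p = fisher_p, ccr = met[["ccr"]], ppv = met[["ppv"]],
               coverage = n_tested / nrow(labeled),
               stringsAsFactors = FALSE)
  })
  st <- do.call(rbind, stats_list)
  p_screen <- if (bh_correct) stats::p.adjust(st$fisher_p, "BH") else st$fisher_p

  reject <- rep(NA_character_, nrow(st))
  fail1 <- st$n_active < min_active
  fail2 <- !fail1 & p_screen >= p_threshold
  fail3 <- !fail1 & !fail2 & (is.na(st$ccr) | st$ccr < ccr_threshold)
  reject[fail1] <- "min_active"
  reject[fail2] <- "fisher_p"
  reject[fail3] <- "ccr"
  st$selected <- is.na(reject)
  st$reject_reason <- reject
  if (!any(st$selected)) warning("no assay passed all selection stages")
  rownames(st) <- NULL
  st
}

#' Balance a binary dataset by undersampling the majority class
#'
#' Randomly discards majority-class rows (uniformly, driven by `seed`) so
#' both classes have the minority-class count; minority rows are untouched.
#'
#' @param dataset data.frame with a binary column `y` (0/1).
#' @param seed integer RNG seed; the same seed always yields the same
#'   selection.
#' @return data.frame subset of `dataset` with equal class counts,
#'   in original row order.
#' @export
undersample_balance <- function(dataset, seed) {
  stopifnot(is.data.frame(dataset), "y" %in% names(dataset))
  y <- dataset$y
  if (length(unique(y)) < 2) {
    stop("undersampling requires both classes present")
  }
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  target <- min(n1, n0)
  keep <- seq_len(nrow(dataset))
  maj <- if (n1 > n0) 1 else 0
  if (n1 != n0) {
    maj_rows <- which(y == maj)
    keep <- sort(c(which(y != maj),
                   local_seed(seed, sample(maj_rows, target))))
  }
  out <- dataset[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
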