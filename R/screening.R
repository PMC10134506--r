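## Virtual screening: mixed experimental/predicted carcinogenicity
## probability, 0.5 classification with a 0.3/0.7 confidence-based
## applicability domain, probe ranking, and library screening reports.

#' Carcinogenicity probability from mixed assay evidence
#'
#' The per-compound carcinogenicity probability is the arithmetic mean,
#' over the selected assays, of the assay-level evidence values:
#' experimental outcomes enter as binary 0/1 and consensus-model
#' predictions as probabilities in \[0, 1\]. With all-experimental
#' evidence the score reduces to the fraction of active assays.
#'
#' @param evidence numeric vector of evidence values in \[0, 1\] (one per
#'   assay), or a data.frame with columns `source`
#'   (`"experimental"`/`"predicted"`) and `value`, in which case
#'   experimental values are checked to be binary.
#' @return probability in \[0, 1\].
#' @examples
#' carcinogenicity_probability(c(1, 0, 0.6, 0.8))  # 0.6
#' @export
carcinogenicity_probability <- function(evidence) {
  if (is.data.frame(evidence)) {
    stopifnot(all(c("source", "value") %in% names(evidence)))
    exp_vals <- evidence$value[tolower(evidence$source) == "experimental"]
    if (!all(exp_vals %in% c(0, 1))) {
      stop("experimental evidence values must be binary 0/1")
    }
    evidence <- evidence$value
  }
  evidence <- as.numeric(evidence)
  if (length(evidence) == 0) stop("evidence must be nonempty")
  if (anyNA(evidence) || any(evidence < 0 | evidence > 1)) {
    stop("evidence values must lie in [0, 1]")
  }
  mean(evidence)
}

#' Classify a probability and assign applicability-domain status
#'
#' Compounds are classified carcinogen at probability >= `threshold` (a
#' 0.5 tie counts as carcinogen). The prediction is inside the
#' applicability domain only when the consensus probability expresses
#' confidence: <= `ad_low` or >= `ad_high`; values strictly inside the
#' band are considered unreliable.
#'
#' @param probability numeric vector in \[0, 1\].
#' @param threshold classification cutoff (default 0.5).
#' @param ad_low,ad_high applicability-domain band edges (defaults 0.3 and
#'   0.7, both inclusive for in-domain status).
#' @return data.frame with columns `classification`
#'   (`carcinogen`/`noncarcinogen`) and `ad_status`
#'   (`in_domain`/`out_of_domain`).
#' @examples
#' classify_and_domain(0.373)  # noncarcinogen, out_of_domain
#' @export
classify_and_domain <- function(probability, threshold = 0.5,
                                ad_low = 0.3, ad_high = 0.7) {
  stopifnot(all(is.na(probability) | (probability >= 0 & probability <= 1)))
  data.frame(
    classification = ifelse(is.na(probability), NA_character_,
                            ifelse(probability >= threshold,
                                   "carcinogen", "noncarcinogen")),
    ad_status = ifelse(is.na(probability), NA_character_,
                       ifelse(probability <= ad_low | probability >= ad_high,
                              "in_domain", "out_of_domain")),
    stringsAsFactors = FALSE
  )
}

# Assemble per-compound evidence for a set of consensus models:
# experimental outcome (1/0) where the profile holds a conclusive result,
# consensus prediction otherwise. Returns value matrix + source matrix.
.evidence_matrix <- function(ids, smiles, profile, models) {
  assays <- vapply(models, `[[`, "", "assay_id")
  val <- matrix(NA_real_, nrow = length(ids), ncol = length(models),
                dimnames = list(ids, assays))
  src <- matrix("predicted", nrow = length(ids), ncol = length(models),
                dimnames = list(ids, assays))
  newdata <- data.frame(id = ids, canonical_smiles = smiles,
                        stringsAsFactors = FALSE)
  # featurize once per fingerprint kind, shared across all member models
  kinds <- unique(unlist(lapply(models, function(cm)
    vapply(cm$members, function(m) m$spec$fingerprint_kind, ""))))
  nbits <- models[[1]]$nbits; radius <- models[[1]]$radius
  feats <- lapply(stats::setNames(kinds, kinds), function(k)
    tryCatch(featurize_dataset(newdata, k, nbits = nbits, radius = radius),
             error = function(e) NULL))
  for (j in seq_along(models)) {
    cm <- models[[j]]
    acc <- matrix(NA_real_, nrow = length(ids), ncol = length(cm$members))
    for (mi in seq_along(cm$members)) {
      m <- cm$members[[mi]]
      f <- feats[[m$spec$fingerprint_kind]]
      if (is.null(f) || length(f$ids) == 0) next
      acc[match(f$ids, ids), mi] <- predict_probability(m, f$X)
    }
    val[, j] <- rowMeans(acc)
  }
  if (!is.null(profile)) {
    conc <- profile$outcomes[profile$outcomes$outcome != "inconclusive" &
                             profile$outcomes$compound_id %in% ids &
                             profile$outcomes$assay_id %in% assays, ,
                             drop = FALSE]
    if (nrow(conc) > 0) {
      idx <- cbind(match(conc$compound_id, ids), match(conc$assay_id, assays))
      val[idx] <- as.numeric(conc$outcome == "active")
      src[idx] <- "experimental"
    }
  }
  list(value = val, source = src)
}

#' Score and rank a probe set
#'
#' Computes each probe compound's carcinogenicity probability from its
#' experimental outcomes in the selected assays (where present) and
#' consensus predictions (elsewhere), classifies at the 0.5 threshold,
#' assigns applicability-domain status, and ranks compounds by descending
#' probability (ties broken by compound id). When the probe carries labels,
#' ranking metrics are attached both overall and restricted to in-domain
#' compounds.
#'
#' @param probe curated `probe_set` (columns `id`, `canonical_smiles`,
#'   `label`).
#' @param profile a `bioprofile` holding the probe compounds' experimental
#'   outcomes (may be `NULL` for a purely predicted score).
#' @param models named list of `consensus_model`s, one per selected assay.
#' @param threshold,ad_low,ad_high see [classify_and_domain()].
#' @return data.frame (one row per compound, ranked) with columns `rank`,
#'   `id`, `canonical_smiles`, `probability`, `n_experimental`,
#'   `n_predicted`, `n_active_assays`, `classification`, `ad_status`,
#'   `label`; attribute `metrics` holds `overall` and `in_domain`
#'   classification metrics against the labels.
#' @export
score_probe_set <- function(probe, profile, models, threshold = 0.5,
                            ad_low = 0.3, ad_high = 0.7) {
  stopifnot(length(models) > 0)
  ids <- as.character(probe$id)
  ev <- .evidence_matrix(ids, probe$canonical_smiles, profile, models)
  scorable <- rowSums(!is.na(ev$value)) == ncol(ev$value)
  probability <- ifelse(scorable, rowMeans(ev$value), NA_real_)
  calls <- ev$value >= threshold  # assay-level active calls (ties active)
  cd <- classify_and_domain(probability, threshold, ad_low, ad_high)
  out <- data.frame(
    id = ids,
    canonical_smiles = probe$canonical_smiles,
    probability = probability,
    n_experimental = rowSums(ev$source == "experimental" & !is.na(ev$value)),
    n_predicted = rowSums(ev$source == "predicted" & !is.na(ev$value)),
    n_active_assays = rowSums(calls, na.rm = TRUE),
    classification = cd$classification,
    ad_status = cd$ad_status,
    label = if ("label" %in% names(probe)) probe$label else NA_character_,
    stringsAsFactors = FALSE
  )
  ord <- order(-ifelse(is.na(out$probability), -Inf, out$probability), out$id,
               method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("rank", setdiff(names(out), "rank"))]

  metrics <- NULL
  if ("label" %in% names(probe)) {
    lab_ok <- out$label %in% c("carcinogen", "noncarcinogen") &
      !is.na(out$probability)
    y <- as.integer(out$label[lab_ok] == "carcinogen")
    overall <- .metrics_at_threshold(out$probability[lab_ok], y, threshold)
    in_dom <- lab_ok & out$ad_status == "in_domain"
    y_dom <- as.integer(out$label[in_dom] == "carcinogen")
    domain <- if (sum(in_dom) > 0) {
      .metrics_at_threshold(out$probability[in_dom], y_dom, threshold)
    } else NULL
    metrics <- list(overall = overall, in_domain = domain,
                    n_overall = sum(lab_ok), n_in_domain = sum(in_dom))
  }
  attr(out, "metrics") <- metrics
  out
}

#' Screen an external compound library
#'
#' For every library compound, each selected assay contributes a binary
#' call: the experimental outcome where one exists in
#' `profile_of_library`, otherwise active iff the consensus prediction is
#' >= `threshold`. A compound is flagged as a potential carcinogen when
#' strictly more than half of its assay calls are active. Flagged
#' compounds are ranked by carcinogenicity probability with the
#' all-assays-active stratum on top.
#'
#' @param library data.frame with `id` and `canonical_smiles` (curated), or
#'   a character vector of SMILES.
#' @param models named list of `consensus_model`s.
#' @param profile_of_library optional `bioprofile` of experimental outcomes
#'   for library compounds.
#' @param probe optional curated `probe_set`; library compounds whose
#'   canonical structure occurs in the probe are removed before screening.
#' @param threshold assay-level call cutoff (default 0.5).
#' @return a `screen_report`: list with `compounds` (per-compound
#'   data.frame ranked with flagged compounds first), `summary` (named
#'   vector: `n_compounds`, `frac_active_calls` among all compound-assay
#'   results, `frac_flagged` among compounds), `n_removed_overlap`.
#' @export
screen_library <- function(library, models, profile_of_library = NULL,
                           probe = NULL, threshold = 0.5) {
  if (is.character(library)) {
    library <- data.frame(id = paste0("LIB", seq_along(library)),
                          canonical_smiles = library, stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(library), nrow(library) > 0, length(models) > 0)
  n_removed <- 0L
  if (!is.null(probe)) {
    overlap <- library$canonical_smiles %in% probe$canonical_smiles
    n_removed <- sum(overlap)
    library <- library[!overlap, , drop = FALSE]
  }
  if (nrow(library) == 0) stop("empty library after overlap removal")
  ids <- as.character(library$id)
  ev <- .evidence_matrix(ids, library$canonical_smiles,
                         profile_of_library, models)
  calls <- ev$value >= threshold
  n_calls <- rowSums(!is.na(calls))
  n_active <- rowSums(calls, na.rm = TRUE)
  flagged <- n_calls > 0 & n_active > n_calls / 2  # strict majority
  probability <- rowMeans(ev$value)
  all_active <- n_calls > 0 & n_active == n_calls

  out <- data.frame(
    id = ids,
    canonical_smiles = library$canonical_smiles,
    probability = probability,
    n_experimental = rowSums(ev$source == "experimental" & !is.na(ev$value)),
    n_predicted = rowSums(ev$source == "predicted" & !is.na(ev$value)),
    n_active_assays = n_active,
    flagged = flagged,
    all_assays_active = all_active,
    stringsAsFactors = FALSE
  )
  ord <- order(-out$flagged, -out$all_assays_active,
               -ifelse(is.na(out$probability), -Inf, out$probability),
               out$id, method = "radix")
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(list(
    compounds = out,
    summary = c(
      n_compounds = nrow(out),
      frac_active_calls = sum(n_active) / max(1, sum(n_calls)),
      frac_flagged = mean(flagged)
    ),
    n_removed_overlap = n_removed
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Screen of %d compounds: %.1f%% active calls, ",
                     "%.1f%% flagged as potential carcinogens\n"),
              s[["n_compounds"]], 100 * s[["frac_active_calls"]],
              100 * s[["frac_flagged"]]))
  if (x$n_removed_overlap > 0) {
    cat("  (", x$n_removed_overlap, " probe-overlapping compounds removed)\n",
        sep = "")
  }
  invisible(x)
}
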