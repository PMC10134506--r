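## End-to-end orchestration: curate -> profile -> select -> balance ->
## train 15-member consensus per selected assay -> score probe -> screen
## libraries, with a manifest sufficient to reproduce every number.

.default_config <- function() {
  list(
    p_threshold = 0.05,
    min_active = 5,
    ccr_threshold = 0.65,
    classify_threshold = 0.5,
    ad_low = 0.3,
    ad_high = 0.7,
    fisher_alternative = "two.sided",
    bh_correct = FALSE,
    duplicate_policy = "active-wins",
    conflict_policy = "drop",
    nbits = 1024,
    radius = 3,
    min_members = 8,
    grids = NULL,
    evaluate_members = TRUE,
    seed = 17L
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("workflow stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full carcinogenicity-profiling workflow
#'
#' Executes the three-step pipeline: (1) probe curation and bioprofile
#' construction, (2) assay selection, balancing, and consensus QSAR model
#' training, (3) probe scoring/ranking and external-library screening. The
#' returned bundle carries a manifest (all thresholds, seeds, and package
#' version) from which a rerun reproduces every emitted metric.
#'
#' @param probe_csv path to the probe CSV (`id,smiles,label`).
#' @param records_csv path to the long-form bioassay records CSV
#'   (`compound_id,assay_id,outcome`).
#' @param library_csvs named character vector of library CSV paths
#'   (`id,smiles`); may be empty.
#' @param config named list overriding the default configuration (see
#'   Details); unknown keys are rejected.
#' @param out_dir optional directory; when given, curated probe, assay
#'   statistics, probe scores, screen reports, and the manifest are written
#'   there as CSV/JSON.
#'
#' @details Configurable keys and defaults: `p_threshold` 0.05,
#'   `min_active` 5, `ccr_threshold` 0.65, `classify_threshold` 0.5,
#'   `ad_low` 0.3, `ad_high` 0.7, `fisher_alternative` "two.sided",
#'   `bh_correct` FALSE, `duplicate_policy` "active-wins",
#'   `conflict_policy` "drop", `nbits` 1024, `radius` 3, `min_members` 8,
#'   `grids` NULL (documented per-algorithm defaults, no tuning), `seed`
#'   17.
#'
#' @return a `workflow_bundle`: list with `probe`, `profile`,
#'   `assay_stats`, `models`, `probe_scores`, `screens`, `manifest`.
#' @export
run_full_workflow <- function(probe_csv, records_csv,
                              library_csvs = character(),
                              config = list(), out_dir = NULL) {
  cfg <- .default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(config)] <- config
  seed <- as.integer(cfg$seed)

  probe <- .stage("curate", {
    curate_probe(read_probe_csv(probe_csv), conflict_policy = cfg$conflict_policy)
  })
  profile <- .stage("profile", {
    read_bioprofile(records_csv, duplicate_policy = cfg$duplicate_policy)
  })
  assay_stats <- .stage("select", {
    select_relevant_assays(profile, probe,
                           p_threshold = cfg$p_threshold,
                           min_active = cfg$min_active,
                           ccr_threshold = cfg$ccr_threshold,
                           alternative = cfg$fisher_alternative,
                           bh_correct = cfg$bh_correct)
  })
  selected <- assay_stats$assay_id[assay_stats$selected]

  bundle <- list(probe = probe, profile = profile, assay_stats = assay_stats,
                 models = list(), probe_scores = NULL, screens = list())
  manifest <- list(
    package = "carciprofiler",
    version = as.character(utils::packageVersion("carciprofiler")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg,
    inputs = list(probe_csv = probe_csv, records_csv = records_csv,
                  library_csvs = as.list(library_csvs)),
    selected_assays = as.list(selected),
    seeds = list()
  )

  if (length(selected) == 0) {
    warning("no assays selected; stopping after the selection stage")
    bundle$manifest <- manifest
    class(bundle) <- "workflow_bundle"
    return(bundle)
  }

  structures <- stats::setNames(probe$canonical_smiles, probe$id)
  models <- list()
  for (aid in selected) {
    models[[aid]] <- .stage(paste0("train:", aid), {
      ds <- assay_dataset(profile, aid, structures, curated = TRUE)
      bal_seed <- derive_seed(seed, "balance", aid)
      ds <- undersample_balance(ds, bal_seed)
      cons_seed <- derive_seed(seed, "consensus", aid)
      manifest$seeds[[aid]] <- list(balance = bal_seed, consensus = cons_seed)
      build_consensus(aid, ds, specs = consensus_specs(cons_seed, cfg$grids),
                      seed = cons_seed, nbits = cfg$nbits,
                      radius = cfg$radius, min_members = cfg$min_members,
                      evaluate = cfg$evaluate_members)
    })
  }
  bundle$models <- models

  bundle$probe_scores <- .stage("score_probe", {
    score_probe_set(probe, profile, models,
                    threshold = cfg$classify_threshold,
                    ad_low = cfg$ad_low, ad_high = cfg$ad_high)
  })

  for (nm in names(library_csvs)) {
    bundle$screens[[nm]] <- .stage(paste0("screen:", nm), {
      lib_raw <- read_probe_csv(library_csvs[[nm]])
      lib <- curate_probe(lib_raw, conflict_policy = "first")
      screen_library(lib, models, probe = probe,
                     threshold = cfg$classify_threshold)
    })
  }

  bundle$manifest <- manifest
  class(bundle) <- "workflow_bundle"
  if (!is.null(out_dir)) write_workflow_bundle(bundle, out_dir)
  bundle
}

#' @export
print.workflow_bundle <- function(x, ...) {
  cat("carciprofiler workflow bundle\n")
  cat("  probe: ", nrow(x$probe), " compounds; assays selected: ",
      sum(x$assay_stats$selected), "/", nrow(x$assay_stats), "\n", sep = "")
  if (!is.null(x$probe_scores)) {
    m <- attr(x$probe_scores, "metrics")
    if (!is.null(m)) {
      cat(sprintf("  probe ranking: CCR=%.3f overall (n=%d), CCR=%.3f in-domain (n=%d)\n",
                  m$overall[["ccr"]], m$n_overall,
                  if (is.null(m$in_domain)) NA_real_ else m$in_domain[["ccr"]],
                  m$n_in_domain))
    }
  }
  for (nm in names(x$screens)) {
    cat("  screen '", nm, "': ", sep = "")
    print(x$screens[[nm]])
  }
  invisible(x)
}

#' Persist the artifacts of a workflow bundle
#'
#' @param bundle a `workflow_bundle`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_workflow_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_probe_csv(bundle$probe, file.path(out_dir, "curated_probe.csv"))
  utils::write.csv(bundle$assay_stats, file.path(out_dir, "assay_stats.csv"),
                   row.names = FALSE)
  if (!is.null(bundle$probe_scores)) {
    utils::write.csv(bundle$probe_scores,
                     file.path(out_dir, "probe_scores.csv"), row.names = FALSE)
  }
  for (nm in names(bundle$screens)) {
    utils::write.csv(bundle$screens[[nm]]$compounds,
                     file.path(out_dir, paste0("screen_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(out_dir)
}
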