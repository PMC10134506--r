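## Sparse compound x assay ternary outcome matrix ("bioprofile").
## Stored as tidy triples; untested cells are represented by absence and
## pooled with INCONCLUSIVE in summaries.

.OUTCOMES <- c("active", "inactive", "inconclusive")

#' Build a bioprofile from long-form bioassay records
#'
#' @param records data.frame with columns `compound_id`, `assay_id`,
#'   `outcome` (one of `active`, `inactive`, `inconclusive`;
#'   case-insensitive). Records with unknown outcome tokens are rejected
#'   and logged with their row numbers.
#' @param duplicate_policy how to resolve several records for the same
#'   (compound, assay) cell: `"active-wins"` (default; any active record
#'   makes the cell active, then inactive over inconclusive), `"majority"`
#'   (most frequent outcome, ties resolved active > inactive >
#'   inconclusive), or `"last-wins"`.
#' @param compounds,assays optional full id universes; defaults to the ids
#'   observed in `records`. Useful when untested compounds must still be
#'   part of the matrix.
#' @return a `bioprofile` object: list with `compounds`, `assays` (ordered
#'   ids) and `outcomes` (data.frame `compound_id`, `assay_id`, `outcome`),
#'   with attribute `rejected` (data.frame of rejected rows and reasons).
#' @export
build_bioprofile <- function(records,
                             duplicate_policy = c("active-wins", "majority", "last-wins"),
                             compounds = NULL, assays = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  stopifnot(is.data.frame(records),
            all(c("compound_id", "assay_id", "outcome") %in% names(records)))
  compound_id <- as.character(records$compound_id)
  assay_id <- as.character(records$assay_id)
  outcome <- tolower(trimws(as.character(records$outcome)))
  bad <- !outcome %in% .OUTCOMES
  rejected <- data.frame(line = which(bad), outcome = outcome[bad],
                         stringsAsFactors = FALSE)
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " record(s) rejected for unknown outcome token",
            " (lines ", paste(utils::head(rejected$line, 5), collapse = ", "),
            if (nrow(rejected) > 5) ", ..." else "", ")")
  }
  compound_id <- compound_id[!bad]; assay_id <- assay_id[!bad]
  outcome <- outcome[!bad]

  key <- paste(compound_id, assay_id, sep = "\r")
  if (anyDuplicated(key)) {
    resolve <- switch(duplicate_policy,
      "active-wins" = function(x) .OUTCOMES[min(match(x, .OUTCOMES))],
      "majority" = function(x) {
        tab <- table(factor(x, levels = .OUTCOMES))
        .OUTCOMES[which.max(tab)]  # which.max breaks ties active > inactive > inconclusive
      },
      "last-wins" = function(x) x[length(x)]
    )
    agg <- tapply(outcome, key, resolve)
    first <- !duplicated(key)
    compound_id <- compound_id[first]; assay_id <- assay_id[first]
    outcome <- as.character(agg[key[first]])
  }
  if (!is.null(compounds) &&
      !all(compound_id %in% compounds)) {
    stop("records reference compounds outside the declared universe")
  }
  if (!is.null(assays) && !all(assay_id %in% assays)) {
    stop("records reference assays outside the declared universe")
  }
  profile <- list(
    compounds = compounds %||% unique(compound_id),
    assays = assays %||% unique(assay_id),
    outcomes = data.frame(compound_id = compound_id, assay_id = assay_id,
                          outcome = outcome, stringsAsFactors = FALSE)
  )
  attr(profile, "rejected") <- rejected
  class(profile) <- "bioprofile"
  profile
}

#' @export
print.bioprofile <- function(x, ...) {
  s <- profile_summary(x)
  cat("Bioprofile: ", length(x$compounds), " compounds x ", length(x$assays),
      " assays\n  active=", s[["n_active"]], ", inactive=", s[["n_inactive"]],
      ", inconclusive/untested=", s[["n_inconclusive_or_untested"]], "\n",
      sep = "")
  invisible(x)
}

#' Summarize a bioprofile
#'
#' Inconclusive results and untested (absent) cells are pooled, so the three
#' counts always sum to `n_compounds * n_assays`.
#'
#' @param profile a `bioprofile`.
#' @return named numeric vector `n_active`, `n_inactive`,
#'   `n_inconclusive_or_untested`.
#' @export
profile_summary <- function(profile) {
  stopifnot(inherits(profile, "bioprofile"))
  n_active <- sum(profile$outcomes$outcome == "active")
  n_inactive <- sum(profile$outcomes$outcome == "inactive")
  total <- length(profile$compounds) * length(profile$assays)
  c(n_active = n_active, n_inactive = n_inactive,
    n_inconclusive_or_untested = total - n_active - n_inactive)
}

#' Extract the labeled modeling dataset of one assay
#'
#' Returns the conclusive outcomes of one assay as a binary-labeled,
#' structure-curated dataset (active = 1, inactive = 0). Inconclusive and
#' untested compounds are excluded; structures are curated (largest organic
#' fragment, neutralization, deduplication) before return.
#'
#' @param profile a `bioprofile`.
#' @param assay_id assay identifier present in `profile`.
#' @param structures named character vector mapping compound id to SMILES.
#' @param curated set TRUE when `structures` already hold curated canonical
#'   SMILES (e.g. from a `probe_set`) to skip re-curation.
#' @return data.frame with columns `id`, `canonical_smiles`, `y`.
#' @export
assay_dataset <- function(profile, assay_id, structures, curated = FALSE) {
  stopifnot(inherits(profile, "bioprofile"))
  if (!assay_id %in% profile$assays) stop("unknown assay: ", assay_id)
  rows <- profile$outcomes[profile$outcomes$assay_id == assay_id &
                           profile$outcomes$outcome != "inconclusive", ,
                           drop = FALSE]
  if (nrow(rows) == 0) {
    stop("assay ", assay_id, " has no conclusive (active/inactive) outcomes")
  }
  smi <- structures[rows$compound_id]
  raw <- data.frame(id = rows$compound_id, smiles = unname(smi),
                    stringsAsFactors = FALSE)
  raw <- raw[!is.na(raw$smiles), , drop = FALSE]
  if (curated) {
    cur <- raw[!duplicated(raw$id), , drop = FALSE]
    names(cur)[names(cur) == "smiles"] <- "canonical_smiles"
  } else {
    cur <- curate_probe(raw, conflict_policy = "first")
  }
  out <- data.frame(
    id = cur$id,
    canonical_smiles = cur$canonical_smiles,
    y = as.integer(rows$outcome[match(cur$id, rows$compound_id)] == "active"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Read and write bioprofiles as long-form CSV
#'
#' The persistence format is tidy triples (`compound_id,assay_id,outcome`),
#' respecting the sparsity of the matrix; a written-then-read profile
#' reproduces the identical outcome map.
#'
#' @param profile a `bioprofile`.
#' @param path CSV file path.
#' @export
write_bioprofile <- function(profile, path) {
  stopifnot(inherits(profile, "bioprofile"))
  utils::write.csv(profile$outcomes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bioprofile
#' @param ... passed to [build_bioprofile()].
#' @export
read_bioprofile <- function(path, ...) {
  if (!file.exists(path)) stop("bioprofile file not found: ", path)
  build_bioprofile(utils::read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = "character"), ...)
}

#' Export a dense ternary matrix for heat-map visualization
#'
#' @param profile a `bioprofile`.
#' @return character matrix (compounds x assays) with entries `active`,
#'   `inactive`, or `inconclusive/untested`.
#' @export
dense_profile_matrix <- function(profile) {
  stopifnot(inherits(profile, "bioprofile"))
  m <- matrix("inconclusive/untested",
              nrow = length(profile$compounds), ncol = length(profile$assays),
              dimnames = list(profile$compounds, profile$assays))
  conc <- profile$outcomes[profile$outcomes$outcome != "inconclusive", ,
                           drop = FALSE]
  m[cbind(conc$compound_id, conc$assay_id)] <- conc$outcome
  m
}
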