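## Structure curation: neutralize salts, keep the largest organic fragment,
## drop inorganics and unparseable records, deduplicate by canonical SMILES.

#' Largest organic fragment after neutralization
#'
#' Applies the probe-curation structure rules to each SMILES: neutralize
#' +1/-1 charged groups, split disconnected components, and keep the
#' connected fragment with the most heavy atoms among those containing at
#' least one carbon atom. Ties are broken by higher molecular weight, then
#' by lexicographically smaller canonical SMILES, so the result is
#' deterministic.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical fragment SMILES; `NA` where the
#'   input is unparseable or contains no carbon fragment (inorganic).
#' @examples
#' strip_to_largest_organic_fragment("[Na+].[O-]C(=O)c1ccccc1")
#' strip_to_largest_organic_fragment("[Na+].[Cl-]")  # NA: inorganic
#' @export
strip_to_largest_organic_fragment <- function(smiles) {
  can <- canonical_smiles(smiles, neutralize = TRUE)
  out <- rep(NA_character_, length(smiles))
  frag_lists <- strsplit(can, ".", fixed = TRUE)
  frag_lists[is.na(can)] <- list(character(0))
  all_frags <- unlist(frag_lists, use.names = FALSE)
  if (length(all_frags) == 0) return(out)
  owner <- rep(seq_along(smiles), lengths(frag_lists))
  mols <- parse_mol(all_frags)
  parsed <- !vapply(mols, is.null, TRUE)
  organic <- parsed & vapply(mols, function(m) !is.null(m) && mol_has_carbon(m), TRUE)
  nheavy <- ifelse(parsed, vapply(mols, function(m) if (is.null(m)) 0L else mol_n_heavy(m), 0L), 0L)
  mw <- ifelse(parsed, vapply(mols, function(m) if (is.null(m)) 0 else mol_weight(m), 0), 0)
  for (i in unique(owner)) {
    sel <- which(owner == i & organic)
    if (length(sel) == 0) next
    ord <- order(-nheavy[sel], -mw[sel], all_frags[sel], method = "radix")
    out[i] <- all_frags[sel[ord[1]]]
  }
  # re-canonicalize the chosen fragments so downstream keys are stable
  got <- !is.na(out)
  if (any(got)) out[got] <- canonical_smiles(out[got])
  out
}

.normalize_label <- function(label) {
  lab <- tolower(trimws(as.character(label)))
  lab[is.na(lab) | lab == ""] <- "unknown"
  bad <- !lab %in% c("carcinogen", "noncarcinogen", "unknown")
  if (any(bad)) {
    stop("unknown label value(s): ", paste(unique(lab[bad]), collapse = ", "))
  }
  lab
}

#' Deduplicate curated compounds by canonical structure
#'
#' Keeps at most one record per canonical SMILES. Same-structure records
#' with identical labels keep the first occurrence; records whose labels
#' contradict each other are handled per `conflict_policy`.
#'
#' @param curated data.frame with columns `id`, `canonical_smiles`, `label`.
#' @param conflict_policy `"drop"` (default) removes every record of a
#'   structure with contradictory labels; `"first"` keeps the first record.
#' @return data.frame of retained rows, with attribute `"conflicts"` naming
#'   the conflicting canonical SMILES.
#' @export
deduplicate <- function(curated, conflict_policy = c("drop", "first")) {
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(all(c("id", "canonical_smiles", "label") %in% names(curated)))
  if (nrow(curated) == 0) {
    attr(curated, "conflicts") <- character(0)
    return(curated)
  }
  lab_per_struct <- tapply(curated$label, curated$canonical_smiles,
                           function(x) length(unique(x)))
  conflicts <- names(lab_per_struct)[lab_per_struct > 1]
  if (length(conflicts) > 0) {
    warning(length(conflicts), " structure(s) with contradictory labels (policy: ",
            conflict_policy, ")")
  }
  keep <- !duplicated(curated$canonical_smiles)
  if (conflict_policy == "drop") {
    keep <- keep & !curated$canonical_smiles %in% conflicts
  }
  out <- curated[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Curate a raw probe set
#'
#' Runs the full structure-curation pipeline over raw records: neutralize,
#' keep the largest organic fragment, drop unparseable and inorganic
#' records, and deduplicate by canonical SMILES. Every dropped record is
#' logged with exactly one reason.
#'
#' @param raw data.frame with columns `id`, `smiles`, and optionally
#'   `label` (`carcinogen`, `noncarcinogen`, or `unknown`).
#' @param conflict_policy passed to [deduplicate()].
#' @return a `probe_set`: data.frame with columns `id`, `canonical_smiles`,
#'   `label`, `provenance`, with attributes `report` (named counts of drop
#'   reasons) and `dropped` (data.frame `id`, `reason`).
#' @export
curate_probe <- function(raw, conflict_policy = c("drop", "first")) {
  conflict_policy <- match.arg(conflict_policy)
  stopifnot(is.data.frame(raw), all(c("id", "smiles") %in% names(raw)))
  if (anyNA(raw$id) || any(!nzchar(as.character(raw$id)))) {
    stop("compound ids must be nonempty")
  }
  id <- as.character(raw$id)
  label <- if ("label" %in% names(raw)) .normalize_label(raw$label) else
    rep("unknown", nrow(raw))
  can_raw <- canonical_smiles(as.character(raw$smiles))
  frag <- strip_to_largest_organic_fragment(as.character(raw$smiles))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(can_raw)] <- "unparseable"
  reason[is.na(reason) & is.na(frag)] <- "inorganic"

  keep <- is.na(reason)
  provenance <- character(nrow(raw))
  multi <- keep & grepl(".", can_raw, fixed = TRUE)
  neut <- keep & !multi & !is.na(frag) & frag != can_raw
  provenance[keep] <- "as-is"
  provenance[multi] <- "largest-organic-fragment"
  provenance[neut] <- "neutralized"

  curated <- data.frame(
    id = id[keep],
    canonical_smiles = frag[keep],
    label = label[keep],
    provenance = provenance[keep],
    stringsAsFactors = FALSE
  )
  pre_dedup <- curated
  curated <- deduplicate(curated, conflict_policy)
  conflicts <- attr(curated, "conflicts")

  is_conflict <- pre_dedup$canonical_smiles %in% conflicts
  n_duplicate <- sum(duplicated(pre_dedup$canonical_smiles) & !is_conflict)
  n_conflict_dropped <- nrow(pre_dedup) - n_duplicate - nrow(curated)
  dropped <- data.frame(id = id[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  report <- c(
    input = nrow(raw),
    unparseable = sum(reason == "unparseable", na.rm = TRUE),
    inorganic = sum(reason == "inorganic", na.rm = TRUE),
    duplicate = n_duplicate,
    label_conflict_dropped = n_conflict_dropped,
    retained = nrow(curated)
  )
  if (nrow(curated) == 0) stop("curation dropped every compound")
  structure(curated,
            report = report,
            dropped = dropped,
            conflicts = conflicts,
            class = c("probe_set", "data.frame"))
}

#' @export
print.probe_set <- function(x, ...) {
  r <- attr(x, "report")
  cat("Curated probe set: ", nrow(x), " compounds (",
      sum(x$label == "carcinogen"), " carcinogens, ",
      sum(x$label == "noncarcinogen"), " noncarcinogens)\n", sep = "")
  if (!is.null(r)) {
    cat("Curation report: ",
        paste(names(r), r, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read/write probe CSV files
#'
#' `read_probe_csv` expects columns `id,smiles,label`;
#' `write_probe_csv` writes a curated probe set back to CSV.
#'
#' @param path file path.
#' @return `read_probe_csv`: data.frame of raw records.
#' @export
read_probe_csv <- function(path) {
  if (!file.exists(path)) stop("probe file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @param probe a curated `probe_set` (or raw records data.frame).
#' @rdname read_probe_csv
#' @export
write_probe_csv <- function(probe, path) {
  utils::write.csv(as.data.frame(probe), path, row.names = FALSE)
  invisible(path)
}

#' Read probe records from an SDF file
#'
#' Takes the first molecule block per record; the molecule title is used as
#' the compound id and the structure is exported as SMILES. Labels, if
#' needed, must be joined separately.
#'
#' @param path SDF file path.
#' @return data.frame with columns `id`, `smiles`, `label` (unknown).
#' @export
read_probe_sdf <- function(path) {
  if (!file.exists(path)) stop("SDF file not found: ", path)
  sdf <- ChemmineR::read.SDFset(path)
  smi <- ChemmineR::sdf2smiles(sdf)
  ids <- vapply(seq_along(sdf), function(i)
    ChemmineR::header(sdf[[i]])[["Molecule_Name"]], "")
  data.frame(id = ids, smiles = as.character(smi), label = "unknown",
             stringsAsFactors = FALSE)
}
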