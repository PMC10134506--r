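## Seedable synthetic fixtures: probe sets built from a valid-SMILES
## fragment grammar, bioassay profiles with planted assay-endpoint
## associations of configurable odds ratio, and screening libraries with
## tunable toxic-fragment prevalence. Every generator ships bookkeeping of
## the planted ground truth so tests never re-derive it.

# Chainable organic fragments: concatenating any sequence of them yields a
# valid SMILES. Each fragment starts with an atom that can accept one more
# bond, ends with an atom that can accept one more bond (saturating groups
# such as halogens, nitriles, and carbonyl oxygens sit in branches), and
# closes its ring digits internally.
.BENIGN_FRAGMENTS <- c(
  "C", "CC", "CCC", "CCCC", "CO", "CCO", "CN", "CCN", "COC", "CS",
  "C(C)C", "C(C)(C)C", "C(=O)C", "C(=O)N", "C(=O)OC", "C(=O)O",
  "C(C(F)(F)F)", "C(Cl)", "C(Br)", "C(C#N)", "C=CC", "CC(O)C", "CNC(=O)C",
  "C1CCCCC1", "C1CCCC1", "C1CCOC1", "C1CCNCC1",
  "c1ccccc1", "c1ccc(C)cc1", "c1ccc(O)cc1", "c1ccc(Cl)cc1",
  "c1ccncc1", "c1ccoc1", "c1ccsc1", "c1ccc2ccccc2c1"
)

# Designated label-informative ("toxic") fragments: azo, nitroaromatic,
# nitrosamine, fused-ring PAH, epoxide.
.TOXIC_FRAGMENTS <- c(
  "N=Nc1ccccc1",
  "c1ccc([N+](=O)[O-])cc1",
  "N(N=O)C",
  "c1ccc2cc3ccccc3cc2c1",
  "C1OC1"
)

# Counter-fragments exercising the curation rules (salts, mixtures).
.SALT_DECORATIONS <- c(".[Na+]", ".Cl", ".OS(=O)(=O)O", ".[K+]")

# Baseline probability that a toxic fragment appears regardless of label;
# structure_signal interpolates the active-class rate from this baseline
# (signal 0: independent of label) up to 1 (signal 1: every active carries
# a fragment).
.TOXIC_BASE_RATE <- 0.1

#' Specification of a planted synthetic study
#'
#' Defines the conditions under which synthetic probe sets and bioassay
#' profiles are generated: probe size and carcinogen prevalence, number of
#' assays and of planted carcinogenicity-relevant assays, the odds ratio
#' linking carcinogenicity to activity in relevant assays, the fraction of
#' conclusive (active/inactive) cells, and the structural label signal.
#'
#' @param n_probe number of probe compounds (default 300).
#' @param frac_carcinogen carcinogen fraction of the probe (default 59/342,
#'   the prevalence of a curated chronic-oral-exposure reference set).
#' @param n_assays number of assays in the profile (default 50).
#' @param n_relevant number of planted relevant assays (default 5).
#' @param relevant_odds_ratio odds ratio linking carcinogenicity to
#'   activity in relevant assays (default 9; must be > 1).
#' @param conclusive_rate probability that a (compound, assay) cell holds a
#'   conclusive outcome (default 0.8).
#' @param structure_signal probability scale at which designated toxic
#'   fragments are enriched in carcinogens (default 0.9).
#' @param base_active_rate activity rate of noncarcinogens in relevant
#'   assays and of all compounds in null assays (default 0.2).
#' @param seed integer seed (default 1).
#' @return a `plant_spec` object.
#' @export
plant_spec <- function(n_probe = 300, frac_carcinogen = 59 / 342,
                       n_assays = 50, n_relevant = 5,
                       relevant_odds_ratio = 9, conclusive_rate = 0.8,
                       structure_signal = 0.9, base_active_rate = 0.2,
                       seed = 1L) {
  stopifnot(n_probe >= 10, frac_carcinogen > 0, frac_carcinogen < 1,
            n_relevant <= n_assays, n_relevant >= 0,
            conclusive_rate > 0, conclusive_rate <= 1,
            structure_signal >= 0, structure_signal <= 1)
  if (relevant_odds_ratio <= 0 || !is.finite(relevant_odds_ratio)) {
    stop("relevant_odds_ratio must be a finite positive number; got ",
         relevant_odds_ratio)
  }
  if (base_active_rate <= 0 || base_active_rate >= 1) {
    stop("base_active_rate must lie strictly in (0, 1) or no odds ratio ",
         "can be realized")
  }
  structure(list(
    n_probe = as.integer(n_probe), frac_carcinogen = frac_carcinogen,
    n_assays = as.integer(n_assays), n_relevant = as.integer(n_relevant),
    relevant_odds_ratio = relevant_odds_ratio,
    conclusive_rate = conclusive_rate,
    structure_signal = structure_signal,
    base_active_rate = base_active_rate,
    seed = as.integer(seed)
  ), class = "plant_spec")
}

#' Generate labeled synthetic structures
#'
#' Builds valid SMILES by concatenating 2-4 fragments from a curated
#' grammar. Compounds labeled `carcinogen` carry one of the designated
#' toxic fragments with probability
#' `base + (1 - base) * structure_signal` (base 0.1), noncarcinogens at
#' the base rate, so `structure_signal = 0` makes fragment occurrence
#' independent of the label and `structure_signal = 1` forces a fragment
#' into every carcinogen. About 10% of compounds are decorated as salts or
#' mixtures to exercise the curation rules.
#'
#' @param n number of compounds.
#' @param structure_signal label-fragment association strength in
#'   \[0, 1\].
#' @param label_assignment character vector of length `n` with values
#'   `carcinogen`/`noncarcinogen` (anything else is treated as
#'   noncarcinogen-like, i.e. base fragment rate).
#' @param seed integer seed; byte-identical output per seed.
#' @param id_prefix prefix for generated compound ids.
#' @return data.frame with columns `id`, `smiles`, `label`,
#'   `has_toxic_fragment`.
#' @export
generate_structures <- function(n, structure_signal, label_assignment, seed,
                                id_prefix = "CP") {
  stopifnot(length(label_assignment) == n)
  local_seed(derive_seed(seed, "structures"), {
    p_frag <- ifelse(label_assignment == "carcinogen",
                     .TOXIC_BASE_RATE + (1 - .TOXIC_BASE_RATE) * structure_signal,
                     .TOXIC_BASE_RATE)
    has_frag <- stats::runif(n) < p_frag
    smiles <- character(n)
    for (i in seq_len(n)) {
      k <- sample(2:4, 1)
      parts <- sample(.BENIGN_FRAGMENTS, k, replace = TRUE)
      if (has_frag[i]) {
        pos <- sample(k + 1, 1)
        parts <- append(parts, sample(.TOXIC_FRAGMENTS, 1), after = pos - 1)
      }
      smi <- paste(parts, collapse = "")
      if (stats::runif(1) < 0.1) {
        smi <- paste0(smi, sample(.SALT_DECORATIONS, 1))
      }
      smiles[i] <- smi
    }
    data.frame(
      id = sprintf("%s%05d", id_prefix, seq_len(n)),
      smiles = smiles,
      label = label_assignment,
      has_toxic_fragment = has_frag,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic probe set
#'
#' @param spec a [plant_spec()].
#' @return data.frame of raw probe records (`id`, `smiles`, `label`) with
#'   attribute `truth` (per-compound fragment bookkeeping).
#' @export
generate_probe <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  n_carc <- round(spec$n_probe * spec$frac_carcinogen)
  labels <- local_seed(derive_seed(spec$seed, "labels"),
                       sample(rep(c("carcinogen", "noncarcinogen"),
                                  c(n_carc, spec$n_probe - n_carc))))
  out <- generate_structures(spec$n_probe, spec$structure_signal, labels,
                             spec$seed)
  truth <- out[, c("id", "label", "has_toxic_fragment")]
  out$has_toxic_fragment <- NULL
  attr(out, "truth") <- truth
  out
}

#' Generate a bioprofile with planted assay-endpoint associations
#'
#' Relevant assays activate carcinogens and noncarcinogens at rates chosen
#' to realize `relevant_odds_ratio` (noncarcinogen rate =
#' `base_active_rate`); null assays activate every compound at the base
#' rate independent of the label. Each (compound, assay) cell is conclusive
#' with probability `conclusive_rate`; otherwise it is recorded as
#' inconclusive or left untested with equal probability.
#'
#' @param probe_labels named character vector (`carcinogen` /
#'   `noncarcinogen`) keyed by compound id, e.g. built from
#'   [generate_probe()] output.
#' @param spec a [plant_spec()].
#' @return list with `profile` (a `bioprofile` over the full compound and
#'   assay universe), `records` (the raw triples), and `truth`
#'   (bookkeeping: planted rates, relevant assay ids, and realized
#'   per-assay and total tallies).
#' @export
generate_bioprofile <- function(probe_labels, spec) {
  stopifnot(inherits(spec, "plant_spec"), !is.null(names(probe_labels)))
  ids <- names(probe_labels)
  assays <- sprintf("AID%03d", seq_len(spec$n_assays))
  odds0 <- spec$base_active_rate / (1 - spec$base_active_rate)
  odds1 <- spec$relevant_odds_ratio * odds0
  p_active_carc <- odds1 / (1 + odds1)
  p_active_noncarc <- spec$base_active_rate

  local_seed(derive_seed(spec$seed, "bioprofile"), {
    relevant <- sort(sample(assays, spec$n_relevant))
    carc <- probe_labels == "carcinogen"
    rec_list <- vector("list", length(assays))
    per_assay <- vector("list", length(assays))
    for (j in seq_along(assays)) {
      aid <- assays[j]
      p_act <- if (aid %in% relevant) {
        ifelse(carc, p_active_carc, p_active_noncarc)
      } else rep(spec$base_active_rate, length(ids))
      conclusive <- stats::runif(length(ids)) < spec$conclusive_rate
      active <- stats::runif(length(ids)) < p_act
      inconclusive <- !conclusive & stats::runif(length(ids)) < 0.5
      outcome <- rep(NA_character_, length(ids))
      outcome[conclusive] <- ifelse(active[conclusive], "active", "inactive")
      outcome[inconclusive] <- "inconclusive"
      keep <- !is.na(outcome)
      rec_list[[j]] <- data.frame(compound_id = ids[keep], assay_id = aid,
                                  outcome = outcome[keep],
                                  stringsAsFactors = FALSE)
      cc <- conclusive & carc; cn <- conclusive & !carc
      per_assay[[j]] <- data.frame(
        assay_id = aid, relevant = aid %in% relevant,
        n_tested = sum(conclusive),
        n_active = sum(active & conclusive),
        n_inconclusive = sum(inconclusive),
        a = sum(cc & active), b = sum(cc & !active),
        c = sum(cn & active), d = sum(cn & !active),
        stringsAsFactors = FALSE
      )
    }
    records <- do.call(rbind, rec_list)
    per_assay <- do.call(rbind, per_assay)
    profile <- build_bioprofile(records, compounds = ids, assays = assays)
    truth <- list(
      relevant_assays = relevant,
      p_active_carcinogen = p_active_carc,
      p_active_noncarcinogen = p_active_noncarc,
      per_assay = per_assay,
      totals = c(
        n_active = sum(per_assay$n_active),
        n_inactive = sum(per_assay$n_tested - per_assay$n_active),
        n_inconclusive_or_untested =
          length(ids) * length(assays) -
          sum(per_assay$n_tested)
      )
    )
    list(profile = profile, records = records, truth = truth)
  })
}

#' Generate a synthetic screening library
#'
#' @param n number of library compounds.
#' @param frac_toxic_like fraction of compounds built like carcinogens
#'   (carrying a designated toxic fragment with certainty).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `smiles` and attribute `truth`
#'   (which compounds are toxic-like); the id space (`LIB*`) is disjoint
#'   from probe ids.
#' @export
generate_library <- function(n, frac_toxic_like, seed) {
  stopifnot(frac_toxic_like >= 0, frac_toxic_like <= 1)
  n_tox <- round(n * frac_toxic_like)
  labels <- local_seed(derive_seed(seed, "liblabels"),
                       sample(rep(c("carcinogen", "noncarcinogen"),
                                  c(n_tox, n - n_tox))))
  out <- generate_structures(n, 1.0, labels, derive_seed(seed, "libstruct"),
                             id_prefix = "LIB")
  truth <- data.frame(id = out$id, toxic_like = labels == "carcinogen",
                      stringsAsFactors = FALSE)
  out <- out[, c("id", "smiles")]
  attr(out, "truth") <- truth
  out
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `probe.csv`, `records.csv`, `library_clean.csv`,
#' `library_dirty.csv`, and `truth.json` into a directory so the full
#' workflow can run from files alone.
#'
#' @param spec a [plant_spec()].
#' @param dir output directory.
#' @param n_library compounds per library (default 200).
#' @param frac_clean,frac_dirty toxic-like fractions of the two libraries
#'   (defaults 0.02 and 0.30).
#' @return `dir`, invisibly.
#' @export
simulate_fixture <- function(spec, dir, n_library = 200,
                             frac_clean = 0.02, frac_dirty = 0.30) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  probe <- generate_probe(spec)
  bp <- generate_bioprofile(stats::setNames(probe$label, probe$id), spec)
  lib_clean <- generate_library(n_library, frac_clean,
                                derive_seed(spec$seed, "clean"))
  lib_dirty <- generate_library(n_library, frac_dirty,
                                derive_seed(spec$seed, "dirty"))
  utils::write.csv(probe, file.path(dir, "probe.csv"), row.names = FALSE)
  utils::write.csv(bp$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(lib_clean, file.path(dir, "library_clean.csv"),
                   row.names = FALSE)
  utils::write.csv(lib_dirty, file.path(dir, "library_dirty.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    spec = unclass(spec),
    probe_truth = attr(probe, "truth"),
    profile_truth = bp$truth,
    library_truth = list(clean = attr(lib_clean, "truth"),
                         dirty = attr(lib_dirty, "truth"))
  ), file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
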