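## Low-level structure handling on top of Open Babel (via ChemmineOB).
## All conversions are batched: each compound is tagged with a synthetic
## title so that records dropped by the toolkit (unparseable SMILES) can be
## re-aligned with their inputs.

#' @importFrom ChemmineOB convertFormat
ob_convert_raw <- function(smiles, to, ops = character()) {
  ids <- paste0("cpmol", seq_along(smiles))
  src <- paste0(paste(smiles, ids, collapse = "\n"), "\n")
  # "e" = continue after per-record errors instead of aborting the batch
  names <- c(ops, "e")
  opts <- data.frame(names = names, args = rep("", length(names)))
  out <- suppressWarnings(convertFormat("SMI", to, source = src, options = opts))
  list(ids = ids, text = out)
}

#' Canonical SMILES
#'
#' Canonicalizes SMILES strings with Open Babel, optionally applying the
#' charge-neutralization operation (protonating/deprotonating singly charged
#' groups such as carboxylates and ammoniums; quaternary nitrogens, which
#' carry no removable proton, are left charged).
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize logical; apply +1/-1 charge neutralization first.
#' @return character vector parallel to `smiles`; `NA` where a string could
#'   not be parsed.
#' @examples
#' canonical_smiles(c("OCC", "CCO"))
#' @export
canonical_smiles <- function(smiles, neutralize = FALSE) {
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  res <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(res)
  ops <- if (neutralize) "neutralize" else character()
  conv <- ob_convert_raw(smiles[ok], "CAN", ops = ops)
  lines <- strsplit(conv$text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got_id <- vapply(parts, function(p) trimws(p[length(p)]), "")
  got_smi <- vapply(parts, function(p) p[1], "")
  res[ok][match(got_id, conv$ids)] <- got_smi
  res
}

#' Test whether SMILES strings parse
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
smiles_parses <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# Average atomic masses for the elements the fragment rules care about.
.atomic_mass <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.99, Mg = 24.305, Al = 26.982, Si = 28.085, P = 30.974, S = 32.06,
  Cl = 35.45, K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546,
  Zn = 65.38, As = 74.922, Se = 78.971, Br = 79.904, Ag = 107.87,
  Cd = 112.41, Sn = 118.71, I = 126.9, Ba = 137.33, Pt = 195.08,
  Hg = 200.59, Pb = 207.2
)

.mol2_bond_order <- function(type) {
  # "ar" aromatic gets its own code so kekulization cannot leak into
  # fingerprint invariants; "am" amide is a single bond.
  out <- suppressWarnings(as.numeric(type))
  out[type == "ar"] <- 4
  out[type == "am"] <- 1
  out[is.na(out)] <- 1
  out
}

.parse_one_mol2 <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  tag <- grepl("^@<TRIPOS>", lines)
  sec <- cumsum(tag)
  secname <- character(max(sec) + 1)
  secname[unique(sec[tag]) + 1] <- sub("^@<TRIPOS>", "", lines[tag])
  get_section <- function(name) {
    idx <- which(secname == name) - 1
    if (length(idx) == 0) return(character(0))
    body <- lines[sec == idx[1] & !tag]
    body[nzchar(trimws(body))]
  }
  atom_lines <- get_section("ATOM")
  if (length(atom_lines) == 0) return(NULL)
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  type <- vapply(af, `[`, "", 6)
  elem <- sub("\\..*$", "", type)
  n <- length(elem)
  charge <- integer(n)
  attr_lines <- get_section("UNITY_ATOM_ATTR")
  i <- 1
  while (i <= length(attr_lines)) {
    hdr <- as.integer(strsplit(trimws(attr_lines[i]), "[[:space:]]+")[[1]])
    for (k in seq_len(hdr[2])) {
      kv <- strsplit(trimws(attr_lines[i + k]), "[[:space:]]+")[[1]]
      if (kv[1] == "charge") charge[hdr[1]] <- as.integer(kv[2])
    }
    i <- i + 1 + hdr[2]
  }
  bond_lines <- get_section("BOND")
  if (length(bond_lines) > 0) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    a1 <- vapply(bf, function(p) as.integer(p[2]), 1L)
    a2 <- vapply(bf, function(p) as.integer(p[3]), 1L)
    order <- .mol2_bond_order(vapply(bf, `[`, "", 4))
  } else {
    a1 <- a2 <- integer(0); order <- numeric(0)
  }
  heavy <- which(elem != "H")
  hcount <- integer(n)
  for (b in seq_along(a1)) {
    if (elem[a1[b]] == "H" && elem[a2[b]] != "H") hcount[a2[b]] <- hcount[a2[b]] + 1L
    if (elem[a2[b]] == "H" && elem[a1[b]] != "H") hcount[a1[b]] <- hcount[a1[b]] + 1L
  }
  keep_bond <- elem[a1] != "H" & elem[a2] != "H"
  remap <- match(seq_len(n), heavy)
  mol <- list(
    elem = elem[heavy],
    charge = charge[heavy],
    aromatic = grepl("\\.ar$", type[heavy]),
    hcount = hcount[heavy],
    bonds = data.frame(
      a1 = remap[a1[keep_bond]],
      a2 = remap[a2[keep_bond]],
      order = order[keep_bond]
    )
  )
  class(mol) <- "mol_graph"
  mol
}

#' Parse SMILES into light molecular graphs
#'
#' Converts SMILES to heavy-atom graphs (element, formal charge, aromatic
#' flag, attached-hydrogen count, bond list) used by the circular
#' fingerprints. Aromaticity and hydrogen counts are those perceived by
#' Open Babel.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list parallel to `smiles`; `NULL` entries mark unparseable
#'   records.
#' @export
parse_mol <- function(smiles) {
  if (length(smiles) == 0) return(list())
  res <- vector("list", length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(res)
  conv <- ob_convert_raw(smiles[ok], "MOL2", ops = "h")
  blocks <- strsplit(conv$text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  got <- vapply(blocks, function(b) {
    trimws(strsplit(b, "\n", fixed = TRUE)[[1]][2])
  }, "", USE.NAMES = FALSE)
  pos <- match(got, conv$ids)
  parsed <- lapply(blocks, .parse_one_mol2)
  res[ok][pos[!is.na(pos)]] <- parsed[!is.na(pos)]
  res
}

mol_n_heavy <- function(mol) length(mol$elem)

mol_weight <- function(mol) {
  m <- .atomic_mass[mol$elem]
  m[is.na(m)] <- 0
  sum(m) + 1.008 * sum(mol$hcount)
}

mol_has_carbon <- function(mol) any(mol$elem == "C")
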