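## Binary chemical fingerprints: 166-bit MACCS substructure keys (computed
## by Open Babel) and 1024-bit Morgan-style circular fingerprints with
## either atom-property invariants (ECFP) or functional-class invariants
## (FCFP), both at bond radius 3.

.FP_KINDS <- c("MACCS", "ECFP", "FCFP")
.MACCS_NBITS <- 166L

.atomic_number <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12, Al = 13,
  Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26, Cu = 29,
  Zn = 30, As = 33, Se = 34, Br = 35, Ag = 47, Cd = 48, Sn = 50, I = 53,
  Ba = 56, Pt = 78, Hg = 80, Pb = 82
)

# Order-stable polynomial hash of nonnegative integers onto [0, 2^31).
# Hashed identifiers only need to be stable across runs and platforms,
# not to match any external toolkit's bit positions.
.hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + (v %% 2000000011) + 1) %% 2000000011
  h
}

# Atoms lying on any cycle: endpoints of non-bridge edges. Molecule graphs
# are tiny, so bridges are found by direct reachability checks.
.ring_atoms <- function(mol) {
  n <- mol_n_heavy(mol)
  b <- mol$bonds
  in_ring <- logical(n)
  if (nrow(b) == 0) return(in_ring)
  adj <- lapply(seq_len(n), function(i) integer(0))
  for (k in seq_len(nrow(b))) {
    adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], k)
    adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], k)
  }
  reaches <- function(from, to, skip_edge) {
    seen <- logical(n); stack <- from; seen[from] <- TRUE
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (k in adj[[v]]) {
        if (k == skip_edge) next
        w <- if (b$a1[k] == v) b$a2[k] else b$a1[k]
        if (w == to) return(TRUE)
        if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
      }
    }
    FALSE
  }
  for (k in seq_len(nrow(b))) {
    if (in_ring[b$a1[k]] && in_ring[b$a2[k]]) next
    if (reaches(b$a1[k], b$a2[k], k)) {
      in_ring[b$a1[k]] <- TRUE; in_ring[b$a2[k]] <- TRUE
    }
  }
  in_ring
}

# Initial atom identifiers. ECFP: atomic number, heavy degree, attached H,
# formal charge, ring membership, aromaticity. FCFP: six pharmacophoric
# flags (H-bond donor/acceptor, positively/negatively ionizable, aromatic,
# halogen) assigned by structural heuristics.
.atom_invariants <- function(mol, kind) {
  n <- mol_n_heavy(mol)
  deg <- integer(n)
  b <- mol$bonds
  if (nrow(b) > 0) {
    t1 <- table(factor(b$a1, levels = seq_len(n)))
    t2 <- table(factor(b$a2, levels = seq_len(n)))
    deg <- as.integer(t1 + t2)
  }
  in_ring <- .ring_atoms(mol) | mol$aromatic
  if (kind == "ECFP") {
    z <- .atomic_number[mol$elem]
    z[is.na(z)] <- 0
    return(vapply(seq_len(n), function(i) {
      .hash_ints(c(z[i], deg[i], mol$hcount[i], mol$charge[i] + 8,
                   in_ring[i], mol$aromatic[i]))
    }, 0))
  }
  # FCFP functional classes
  elem <- mol$elem
  # neighbors double-bonded to O (acidic OH detection)
  acidic_o <- logical(n)
  if (nrow(b) > 0) {
    dbl_o <- unique(c(b$a1[b$order == 2 & elem[b$a2] == "O"],
                      b$a2[b$order == 2 & elem[b$a1] == "O"]))
    for (k in seq_len(nrow(b))) {
      if (b$order[k] != 1) next
      if (elem[b$a1[k]] == "O" && mol$hcount[b$a1[k]] > 0 && b$a2[k] %in% dbl_o)
        acidic_o[b$a1[k]] <- TRUE
      if (elem[b$a2[k]] == "O" && mol$hcount[b$a2[k]] > 0 && b$a1[k] %in% dbl_o)
        acidic_o[b$a2[k]] <- TRUE
    }
  }
  only_single <- rep(TRUE, n)
  if (nrow(b) > 0) {
    multi <- unique(c(b$a1[b$order != 1], b$a2[b$order != 1]))
    only_single[multi] <- FALSE
  }
  donor <- elem %in% c("N", "O", "S") & mol$hcount > 0
  acceptor <- elem %in% c("N", "O") & mol$charge <= 0
  pos_ion <- mol$charge > 0 |
    (elem == "N" & !mol$aromatic & mol$hcount > 0 & only_single)
  neg_ion <- mol$charge < 0 | acidic_o
  halogen <- elem %in% c("F", "Cl", "Br", "I")
  cls <- donor * 1L + acceptor * 2L + pos_ion * 4L + neg_ion * 8L +
    mol$aromatic * 16L + halogen * 32L
  vapply(cls, function(v) .hash_ints(v), 0)
}

.morgan_bits <- function(mol, kind, nbits, radius) {
  n <- mol_n_heavy(mol)
  if (n == 0) return(integer(0))
  inv <- .atom_invariants(mol, kind)
  bits <- inv %% nbits
  b <- mol$bonds
  nbrs <- lapply(seq_len(n), function(i) {
    k1 <- which(b$a1 == i); k2 <- which(b$a2 == i)
    data.frame(atom = c(b$a2[k1], b$a1[k2]), order = c(b$order[k1], b$order[k2]))
  })
  for (r in seq_len(radius)) {
    inv_new <- numeric(n)
    for (i in seq_len(n)) {
      nb <- nbrs[[i]]
      if (nrow(nb) > 0) {
        key <- order(nb$order * 2000000011 + inv[nb$atom])
        parts <- as.numeric(rbind(nb$order[key], inv[nb$atom][key]))
      } else parts <- numeric(0)
      inv_new[i] <- .hash_ints(c(r, inv[i], parts))
    }
    inv <- inv_new
    bits <- c(bits, inv %% nbits)
  }
  sort(unique(as.integer(bits)))
}

.maccs_matrix <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("m", seq_along(smiles))))
  m <- ChemmineR::fingerprintOB(sdf, "MACCS")@fpma
  m <- m[, seq_len(.MACCS_NBITS), drop = FALSE]
  storage.mode(m) <- "integer"
  dimnames(m) <- NULL
  m
}

#' Compute a binary chemical fingerprint
#'
#' `MACCS` yields the 166-bit substructure keys; `ECFP` and `FCFP` yield
#' hashed circular fingerprints of `nbits` bits built by iterative
#' neighborhood hashing to bond radius `radius`, with atom-property
#' invariants (ECFP) or functional-class invariants (FCFP). Fingerprints
#' are computed on the canonicalized structure, so different SMILES of the
#' same molecule give identical bit vectors.
#'
#' @param smiles a single SMILES string.
#' @param kind one of `"MACCS"`, `"ECFP"`, `"FCFP"`.
#' @param nbits vector length for ECFP/FCFP (default 1024; ignored for
#'   MACCS).
#' @param radius bond radius for ECFP/FCFP (default 3; ignored for MACCS).
#' @return integer 0/1 vector of length 166 (MACCS) or `nbits`.
#' @export
fingerprint <- function(smiles, kind = c("MACCS", "ECFP", "FCFP"),
                        nbits = 1024, radius = 3) {
  kind <- match.arg(kind)
  stopifnot(length(smiles) == 1)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparseable SMILES: ", smiles)
  if (kind == "MACCS") return(as.integer(.maccs_matrix(can)[1, ]))
  mol <- parse_mol(can)[[1]]
  v <- integer(nbits)
  v[.morgan_bits(mol, kind, nbits, radius) + 1L] <- 1L
  v
}

#' Featurize a labeled dataset into a fingerprint matrix
#'
#' @param dataset data.frame with columns `canonical_smiles` (or `smiles`),
#'   `y`, and `id`. Compounds whose structure fails fingerprinting are
#'   dropped and reported in the `dropped` element.
#' @param kind fingerprint kind; see [fingerprint()].
#' @param nbits,radius see [fingerprint()].
#' @return list with `X` (integer 0/1 matrix, one row per kept compound),
#'   `y` (labels), `ids` (kept compound ids), `dropped` (ids that failed).
#' @export
featurize_dataset <- function(dataset, kind = c("MACCS", "ECFP", "FCFP"),
                              nbits = 1024, radius = 3) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(dataset), nrow(dataset) > 0)
  smi_col <- if ("canonical_smiles" %in% names(dataset)) "canonical_smiles" else "smiles"
  smi <- as.character(dataset[[smi_col]])
  ids <- if ("id" %in% names(dataset)) as.character(dataset$id) else
    as.character(seq_along(smi))
  can <- canonical_smiles(smi)
  ok <- !is.na(can)
  if (!any(ok)) stop("no compound could be fingerprinted")
  if (kind == "MACCS") {
    X <- .maccs_matrix(can[ok])
  } else {
    mols <- parse_mol(can[ok])
    parsed <- !vapply(mols, is.null, TRUE)
    ok[ok] <- parsed
    mols <- mols[parsed]
    X <- matrix(0L, nrow = length(mols), ncol = nbits)
    for (i in seq_along(mols)) {
      X[i, .morgan_bits(mols[[i]], kind, nbits, radius) + 1L] <- 1L
    }
  }
  colnames(X) <- paste0("bit", seq_len(ncol(X)))
  list(
    X = X,
    y = if ("y" %in% names(dataset)) dataset$y[ok] else NULL,
    ids = ids[ok],
    dropped = ids[!ok]
  )
}

# Tanimoto (Jaccard) similarity between rows of two binary matrices.
tanimoto_similarity <- function(A, B) {
  inter <- A %*% t(B)
  ra <- rowSums(A); rb <- rowSums(B)
  denom <- outer(ra, rb, "+") - inter
  out <- ifelse(denom == 0, 1, inter / denom)
  out
}
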