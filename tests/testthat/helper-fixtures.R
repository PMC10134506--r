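# Shared fixture builders. Everything is generated in code with pinned
# seeds; nothing is read from disk.

# A small raw probe exercising every curation rule.
tiny_probe_raw <- function() {
  data.frame(
    id = c("benzoate_na", "salt", "benzene", "ethanol", "ethanol_dup",
           "badsmiles"),
    smiles = c("[Na+].[O-]C(=O)c1ccccc1", "[Na+].[Cl-]", "c1ccccc1",
               "OCC", "CCO", "xx((x"),
    label = c("carcinogen", "noncarcinogen", "noncarcinogen",
              "noncarcinogen", "noncarcinogen", "carcinogen"),
    stringsAsFactors = FALSE
  )
}

# Two structurally disjoint families (azo-aromatics vs short alkanols):
# separable in any of the three fingerprint spaces.
separable_dataset <- function(n_per_class = 20) {
  actives <- paste0(strrep("C", seq_len(n_per_class)), "N=Nc1ccccc1")
  inactives <- paste0(strrep("C", seq_len(n_per_class)), "CO")
  data.frame(
    id = sprintf("S%03d", seq_len(2 * n_per_class)),
    canonical_smiles = canonical_smiles(c(actives, inactives)),
    y = rep(c(1L, 0L), each = n_per_class),
    stringsAsFactors = FALSE
  )
}

# A labeled, structure-bearing planted dataset for model tests: balanced,
# with the toxic-fragment signal tied to y.
planted_dataset <- function(n, signal = 0.9, seed = 1) {
  labs <- rep(c("carcinogen", "noncarcinogen"), length.out = n)
  g <- generate_structures(n, signal, labs, seed)
  data.frame(id = g$id,
             canonical_smiles = canonical_smiles(g$smiles),
             y = as.integer(labs == "carcinogen"),
             stringsAsFactors = FALSE)
}

# Bit-level planted design matrix: `n_signal` informative bits, the rest
# noise. Used where model behaviour should be tested independently of the
# chemistry layer.
planted_bits <- function(n, p = 256, n_signal = 12, strength = 0.9,
                         seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n / 2)
  X <- matrix(rbinom(n * p, 1, 0.1), nrow = n)
  for (j in seq_len(n_signal)) {
    X[, j] <- rbinom(n, 1, ifelse(y == 1, strength, 1 - strength))
  }
  colnames(X) <- paste0("bit", seq_len(p))
  list(X = X, y = y)
}

# Long-form records for a tiny hand-built profile.
records_df <- function(compound_id, assay_id, outcome) {
  data.frame(compound_id = compound_id, assay_id = assay_id,
             outcome = outcome, stringsAsFactors = FALSE)
}

# Stub consensus models sharing one cheap trained member; useful when only
# experimental evidence matters.
stub_models <- function(assay_ids, seed = 5) {
  ds <- planted_dataset(16, signal = 1, seed = seed)
  cm <- suppressWarnings(
    build_consensus(assay_ids[1], ds,
                    specs = list(KNN_MACCS = model_spec("KNN", "MACCS", seed = seed)),
                    seed = seed, min_members = 1, evaluate = FALSE))
  out <- lapply(assay_ids, function(a) { cm2 <- cm; cm2$assay_id <- a; cm2 })
  names(out) <- assay_ids
  out
}
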