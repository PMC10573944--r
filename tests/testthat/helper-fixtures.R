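# Shared fixtures, all built in code at test time.

# A tiny ChEMBL-dialect activity table on disk; returns the path.
write_chembl_fixture <- function(rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      `Molecule ChEMBL ID` = c("CHEMBL1", "CHEMBL2", "CHEMBL3"),
      Smiles = c("CCO", "c1ccccc1", "CCN"),
      `pChEMBL Value` = c(7.2, 5.5, 9.4),
      check.names = FALSE)
  }
  path <- tempfile(fileext = ".csv")
  write.csv(rows, path, row.names = FALSE)
  path
}

# Random 0/1 fingerprint of given width and density.
random_bits <- function(n_bits, p = 0.1) {
  as.integer(runif(n_bits) < p)
}

# Set-arithmetic Jaccard oracle, independent of tanimoto().
jaccard_oracle <- function(a, b) {
  sa <- which(a == 1); sb <- which(b == 1)
  u <- length(union(sa, sb))
  if (u == 0) 0 else length(intersect(sa, sb)) / u
}

# Small labeled feature set drawn from the synthetic generator, with
# fingerprints at reduced width so NN unit tests stay fast.
tiny_feature_set <- function(seed = 5, n_scaffolds = 6, subs = 15,
                             n_bits = 256, noise_sd = 0) {
  ds <- clean_dataset(generate_receptor_library(
    generator_spec(n_scaffolds = n_scaffolds,
                   substituents_per_scaffold = subs,
                   noise_sd = noise_sd, seed = seed)))
  X <- fingerprint_matrix(ds$records$smiles, ds$records$compound_id,
                          n_bits = n_bits)
  list(X = X, classes = ds$records$activity_class, ds = ds)
}

# Fast NN spec for unit tests.
tiny_spec <- function(n_bits = 256, epochs = 20, seed = 3) {
  nn_spec(input_width = n_bits, hidden = c(32L, 16L), epochs = epochs,
          seed = seed)
}

# One-hot probability matrix for given classes.
one_hot <- function(classes) {
  P <- matrix(0, length(classes), 7)
  P[cbind(seq_along(classes), classes)] <- 1
  P
}
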