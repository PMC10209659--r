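# Shared fixtures and small utilities for the test suite.

# 3-hydroxybenzamide SDF block numbered as in the worked graph example:
# n1 = amide N, n2 = carbonyl O, n3 = carbonyl C, n4-n9 the aromatic ring,
# n10 = phenolic O; e1 is the N-C single bond (endpoints n1, n3).
hba_sdf <- function() {
  c("3-hydroxybenzamide",
    "  fixture",
    "",
    " 10 10  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  3  1  0  0  0  0",
    "  2  3  2  0  0  0  0",
    "  3  4  1  0  0  0  0",
    "  4  5  4  0  0  0  0",
    "  5  6  4  0  0  0  0",
    "  6  7  4  0  0  0  0",
    "  7  8  4  0  0  0  0",
    "  8  9  4  0  0  0  0",
    "  4  9  4  0  0  0  0",
    "  6 10  1  0  0  0  0",
    "M  END",
    "$$$$")
}

.fixture_cache <- new.env(parent = emptyenv())

# memoized fixture pairs so expensive generation runs once per test session
cached_pairs <- function(n, seed = 11L, noise_sd = 0) {
  key <- sprintf("pairs_%d_%d_%g", n, seed, noise_sd)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- fixture_pairs(
      fixture_config(n_molecules = n, seed = seed, noise_sd = noise_sd))
  }
  .fixture_cache[[key]]
}

# reorder the atoms of a parsed structure; perm maps new index -> old index
permute_structure <- function(st, perm) {
  inv <- integer(length(perm))
  inv[perm] <- seq_along(perm)
  out <- st
  out$atoms <- st$atoms[perm]
  out$bonds$a <- inv[st$bonds$a]
  out$bonds$b <- inv[st$bonds$b]
  out
}

# spectrum with k seeded random peaks (for oracle libraries)
random_spectrum <- function(k = 8L, seed = 1L) {
  set.seed(seed)
  peaks_to_vector(cbind(sample(20:400, k), runif(k, 0.05, 1)))
}

# assemble a pei_library directly from (id, formula, spectrum) triples
manual_library <- function(ids, formulas, spectra) {
  recs <- Map(function(i, f, s) {
    list(id = i, formula = f, spectrum = s, provenance = "predicted")
  }, ids, formulas, spectra)
  graphei:::.new_library(unname(recs))
}
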