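# Synthetic structure/spectrum fixtures.
#
# generate_molecules() assembles small single-component molecules from a
# curated scaffold/substituent grammar (alkyl chains, alcohols, amines,
# halobenzenes, esters, heteroaromatics); pseudo_fragment_spectrum() gives
# each one a deterministic rule-based "EI" spectrum. The fragmenter is not
# a physical model: it exists to give the pipeline learnable, identifiable
# structure-spectrum regularities at desk scale, and its rules are fixed so
# downstream numbers are stable.

#' Fixture generator configuration
#'
#' @param n_molecules Number of molecules to generate.
#' @param max_heavy_atoms Upper bound on heavy-atom count (default 24).
#' @param noise_sd Gaussian intensity noise standard deviation applied to
#'   pseudo-spectrum peaks (default 0: noiseless).
#' @param include_violations Also append one specimen per library exclusion
#'   reason (multi-component record, molecular weight over 1000 Da, a
#'   disallowed element).
#' @param seed Integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_molecules = 50L, max_heavy_atoms = 24L,
                           noise_sd = 0, include_violations = FALSE,
                           seed = 1L) {
  stopifnot(n_molecules >= 1L, max_heavy_atoms >= 1L, noise_sd >= 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 noise_sd = noise_sd,
                 include_violations = isTRUE(include_violations),
                 seed = as.integer(seed)),
            class = "fixture_config")
}

# scaffold suffixes (rings and chains the substituent prefix attaches to)
.FIXTURE_SCAFFOLDS <- c(
  "", "c1ccccc1", "c1ccc(C)cc1", "c1ccc(Cl)cc1", "c1ccc(OC)cc1",
  "c1ccncc1", "c1ccco1", "c1cccs1", "C1CCCCC1", "C1CCCC1", "c1ccc2ccccc2c1"
)
# substituent prefixes (functional terminations written head-first)
.FIXTURE_TERMINI <- c(
  "", "O", "N", "Cl", "Br", "F", "I", "OC(=O)", "COC(=O)", "NC(=O)",
  "N#C", "C(C)O", "S"
)

# rule-violating specimens, one per exclusion reason
.FIXTURE_VIOLATIONS <- data.frame(
  id = c("viol-multi", "viol-heavy", "viol-element"),
  smiles = c("CCO.CCN", strrep("C", 72L), "CC(=O)O[Na]")
)

#' Generate a deterministic set of fixture molecules
#'
#' Draws unique valid single-component SMILES from the scaffold grammar,
#' seeded by `config$seed`. With `include_violations = TRUE` the list ends
#' with one specimen per exclusion reason (see [exclusion_filter()]).
#'
#' @param config A [fixture_config()].
#' @return Data frame with columns `id` and `smiles`.
#' @examples
#' \donttest{
#' generate_molecules(fixture_config(n_molecules = 10, seed = 7))
#' }
#' @export
generate_molecules <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  grid <- expand.grid(term = .FIXTURE_TERMINI, chain = 0:8,
                      scaf = .FIXTURE_SCAFFOLDS,
                      stringsAsFactors = FALSE)
  smiles <- paste0(grid$term, strrep("C", grid$chain), grid$scaf)
  smiles <- unique(smiles[nzchar(smiles)])
  # cheap heavy-atom estimate: count element letters, skip ring digits
  heavy <- nchar(gsub("[^A-Za-z]", "", gsub("Cl|Br", "X", smiles)))
  smiles <- smiles[heavy <= config$max_heavy_atoms & heavy >= 1L]
  # reject fragments that are not chemically assemblable as written
  # (the grammar guarantees validity; this guards future edits)
  set.seed(config$seed)
  if (config$n_molecules > length(smiles)) {
    stop("fixture grammar provides only ", length(smiles),
         " distinct molecules under max_heavy_atoms = ",
         config$max_heavy_atoms, call. = FALSE)
  }
  pick <- sample(smiles, config$n_molecules)
  out <- data.frame(id = sprintf("fix%04d", seq_along(pick)), smiles = pick)
  if (config$include_violations) {
    viol <- .FIXTURE_VIOLATIONS
    out <- rbind(out, viol)
  }
  out
}

#' Rule-based pseudo EI spectrum of a structure
#'
#' Deterministic surrogate for a measured spectrum: a molecular-ion peak at
#' the rounded molecular weight, one peak per fragment created by cleaving
#' each acyclic (non-ring) bond, with intensity decaying geometrically in
#' the fragment's heavy-atom count, plus optional seeded Gaussian intensity
#' noise truncated at zero. Fragment masses use average atomic weights with
#' hydrogens assigned by a standard-valence rule.
#'
#' @param structure A [parse_structure()] result (single component, allowed
#'   elements).
#' @param noise_sd Standard deviation of Gaussian noise added to each peak
#'   (default 0).
#' @param seed Seed for the noise draw (ignored when `noise_sd = 0`).
#' @return An `ei_spectrum`, normalized to base peak 1.0.
#' @export
pseudo_fragment_spectrum <- function(structure, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(structure, "mol_structure"))
  atoms <- structure$atoms
  bonds <- structure$bonds
  n <- length(atoms)

  # implicit hydrogens by standard valence minus bond-order sum
  valence <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3, Si = 4,
               F = 1, Cl = 1, Br = 1, I = 1)
  ord_val <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
  bsum <- numeric(n)
  if (nrow(bonds)) {
    v <- ord_val[bonds$order]
    bsum <- bsum + .scatter_rows(matrix(v), bonds$a, n, 1L) +
      .scatter_rows(matrix(v), bonds$b, n, 1L)
  }
  n_h <- pmax(0, round(valence[atoms] - bsum))
  atom_mass <- ATOMIC_WEIGHTS[atoms] + n_h * ATOMIC_WEIGHTS[["H"]]

  peaks <- list(c(.round_half_up(structure$mol_weight), 0.6))
  acyclic <- which(nrow(bonds) > 0 & !bonds$in_ring)
  if (length(acyclic)) {
    g <- igraph::make_graph(rbind(bonds$a, bonds$b), n = n, directed = FALSE)
    for (e in acyclic) {
      gcut <- igraph::delete_edges(g, e)
      member <- igraph::components(gcut)$membership
      for (side in unique(member)) {
        frag <- which(member == side)
        mass <- sum(atom_mass[frag])
        peaks[[length(peaks) + 1L]] <- c(.round_half_up(mass),
                                         0.85^length(frag))
      }
    }
  }
  pk <- do.call(rbind, peaks)
  in_range <- pk[, 1] >= MZ_MIN & pk[, 1] <= MZ_MAX
  if (!any(in_range)) {
    stop("degenerate pseudo-spectrum: every fragment of ",
         structure$formula, " falls outside m/z ", MZ_MIN, "-", MZ_MAX,
         call. = FALSE)
  }
  spec <- suppressWarnings(peaks_to_vector(pk, normalize = FALSE))
  x <- .as_spectrum(spec)
  if (noise_sd > 0) {
    set.seed(seed)
    nz <- which(x > 0)
    x[nz] <- pmax(0, x[nz] + rnorm(length(nz), sd = noise_sd))
  }
  spectrum_vector(x, normalize = TRUE)
}

#' Generate paired fixture graphs and spectra
#'
#' Convenience wrapper producing ready-to-train pairs: molecules from
#' [generate_molecules()] (violating specimens excluded), parsed,
#' featurized, and given noiseless pseudo-spectra. Molecules whose
#' pseudo-spectra collide with an earlier pair are dropped and replaced so
#' that every returned spectrum is unique - real libraries contain
#' near-duplicates, but identifiability tests need exact self-retrieval.
#'
#' @param config A [fixture_config()]; `noise_sd` is applied to the
#'   returned spectra (uniqueness is checked on the noiseless versions).
#' @return List of `list(id, smiles, structure, graph, spectrum)` of length
#'   `config$n_molecules`.
#' @export
fixture_pairs <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  pool_cfg <- config
  pool_cfg$include_violations <- FALSE
  pool_cfg$n_molecules <- config$n_molecules
  pairs <- list()
  seen <- character(0)
  tries <- 0L
  while (length(pairs) < config$n_molecules && tries < 8L) {
    tries <- tries + 1L
    pool_cfg$n_molecules <- min(
      4000L, config$n_molecules + 40L * tries + length(seen))
    pool_cfg$seed <- config$seed + tries - 1L
    mols <- generate_molecules(pool_cfg)
    for (i in seq_len(nrow(mols))) {
      if (length(pairs) >= config$n_molecules) break
      st <- parse_structure(mols$smiles[i])
      if (exclusion_filter(st)$keep == FALSE) next
      base <- pseudo_fragment_spectrum(st, noise_sd = 0)
      key <- paste(which(base > 0), signif(base[base > 0], 10),
                   collapse = ";")
      if (key %in% seen) next
      seen <- c(seen, key)
      spec <- if (config$noise_sd > 0) {
        pseudo_fragment_spectrum(st, noise_sd = config$noise_sd,
                                 seed = config$seed + length(pairs))
      } else base
      st$id <- sprintf("fix%04d", length(pairs) + 1L)
      g <- to_graph(st)
      pairs[[length(pairs) + 1L]] <- list(
        id = st$id, smiles = mols$smiles[i], structure = st,
        graph = g, spectrum = spec)
    }
  }
  if (length(pairs) < config$n_molecules) {
    stop("could not assemble ", config$n_molecules,
         " fixtures with unique spectra (got ", length(pairs), ")",
         call. = FALSE)
  }
  pairs
}
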