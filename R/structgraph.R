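# Structure parsing and graph featurization.
#
# Records (SMILES or SDF) are converted by Open Babel (via ChemmineOB) to
# SYBYL MOL2, the one interchange format that both preserves the input atom
# order and keeps aromatic bond types explicit ("ar"). Hydrogens are made
# explicit during conversion so the molecular formula and weight can be
# computed from element counts, then dropped from the graph: hydrogen
# atoms are never nodes.

.mol2_convert <- function(record, format) {
  fmt <- toupper(format)
  src <- switch(fmt,
    SMI = , SMILES = {
      fmt <- "SMI"
      # isotopic labels are irrelevant at unit m/z; strip before conversion.
      # A bare isotope-element bracket loses the brackets too, since a
      # bracket atom would otherwise lose its implicit hydrogens.
      rec <- gsub("\\[[0-9]+(Cl|Br|B|C|N|O|P|S|F|I|c|n|o|p|s)\\]", "\\1",
                  record)
      paste0(gsub("\\[([0-9]+)", "[", rec), "\n")
    },
    SDF = , MOL = {
      fmt <- "SDF"
      rec <- paste(record, collapse = "\n")
      if (!grepl("\\$\\$\\$\\$", rec)) rec <- paste0(rec, "\n$$$$\n")
      rec
    },
    stop("unsupported structure format: ", format, call. = FALSE)
  )
  out <- suppressWarnings(ChemmineOB::convertFormat(
    fmt, "MOL2", src, options = data.frame(names = "h", args = "")
  ))
  if (!nzchar(out) || !grepl("@<TRIPOS>ATOM", out, fixed = TRUE)) {
    stop("cannot parse structure record: ",
         sQuote(substr(paste(record, collapse = " "), 1, 60)), call. = FALSE)
  }
  out
}

.mol2_section <- function(lines, tag) {
  starts <- grep("^@<TRIPOS>", lines)
  at <- which(lines == paste0("@<TRIPOS>", tag))
  if (!length(at)) return(character(0))
  at <- at[1]
  stop_at <- c(starts[starts > at], length(lines) + 1L)[1]
  body <- lines[seq(at + 1L, stop_at - 1L)]
  body[nzchar(trimws(body))]
}

# Parse the first molecule of a MOL2 string into atom/bond tables.
.parse_mol2 <- function(mol2) {
  lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  atom_lines <- .mol2_section(lines, "ATOM")
  bond_lines <- .mol2_section(lines, "BOND")
  atoms <- if (length(atom_lines)) {
    fields <- strsplit(trimws(atom_lines), "[[:space:]]+")
    type <- vapply(fields, `[`, "", 6L)
    elem <- sub("\\..*$", "", type)
    # normalize case: "CL" -> "Cl"
    paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, nchar(elem))))
  } else character(0)
  bonds <- if (length(bond_lines)) {
    fields <- strsplit(trimws(bond_lines), "[[:space:]]+")
    data.frame(
      a = as.integer(vapply(fields, `[`, "", 2L)),
      b = as.integer(vapply(fields, `[`, "", 3L)),
      type = vapply(fields, `[`, "", 4L)
    )
  } else data.frame(a = integer(0), b = integer(0), type = character(0))
  list(atoms = atoms, bonds = bonds)
}

.BOND_ORDER_MAP <- c(
  "1" = "single", "2" = "double", "3" = "triple",
  "ar" = "aromatic", "am" = "single", "du" = "single", "un" = "single"
)

#' Parse a molecular structure record
#'
#' Reads one SMILES string or one SDF (MDL V2000) molecule block into a
#' heavy-atom structure. Hydrogens (implicit or explicit) are counted for
#' the molecular formula and weight but do not appear as atoms.
#' Stereochemical annotations (cis/trans, R/S) are discarded, so geometric
#' isomers yield identical structures; isotopic labels are stripped.
#'
#' @param record A SMILES string, or a character vector holding one SDF
#'   molecule block.
#' @param format `"smiles"` (default) or `"sdf"`.
#' @param id Optional identifier attached to the result.
#' @return A `mol_structure` object: `atoms` (heavy-atom element symbols in
#'   input order), `bonds` (data frame of endpoint indices, bond order in
#'   `single`/`double`/`triple`/`aromatic`, and ring membership flag),
#'   `formula` (Hill notation, hydrogens included), `mol_weight` (average
#'   molecular weight, Da), `n_components` (covalently disconnected
#'   components), `n_hydrogens`.
#' @examples
#' \donttest{
#' parse_structure("NC(=O)c1cccc(O)c1", id = "3-hydroxybenzamide")
#' }
#' @export
parse_structure <- function(record, format = c("smiles", "sdf"), id = NULL) {
  format <- match.arg(format)
  mol <- .parse_mol2(.mol2_convert(record, format))
  heavy <- which(!(mol$atoms %in% c("H", "D", "T")))
  if (!length(heavy)) {
    stop("record has no heavy atoms: ", sQuote(record[1]), call. = FALSE)
  }
  n_h <- length(mol$atoms) - length(heavy)
  remap <- integer(length(mol$atoms))
  remap[heavy] <- seq_along(heavy)
  keep <- mol$bonds$a %in% heavy & mol$bonds$b %in% heavy
  bonds <- mol$bonds[keep, , drop = FALSE]
  order <- .BOND_ORDER_MAP[as.character(bonds$type)]
  if (anyNA(order)) {
    stop("unsupported bond type in record: ",
         paste(unique(bonds$type[is.na(order)]), collapse = ", "),
         call. = FALSE)
  }
  bonds <- data.frame(
    a = remap[bonds$a], b = remap[bonds$b],
    order = unname(order), row.names = NULL
  )

  atoms <- mol$atoms[heavy]
  g <- igraph::make_graph(rbind(bonds$a, bonds$b),
                          n = length(atoms), directed = FALSE)
  # a bond lies in a ring iff it is not a cut edge
  bonds$in_ring <- if (nrow(bonds)) {
    !(seq_len(nrow(bonds)) %in% as.integer(igraph::bridges(g)))
  } else logical(0)

  counts <- table(c(atoms, rep("H", n_h)))
  counts <- setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0]
  structure(list(
    id = id,
    atoms = atoms,
    bonds = bonds,
    formula = hill_formula(counts),
    mol_weight = formula_weight(counts),
    n_components = igraph::components(g)$no,
    n_hydrogens = n_h
  ), class = "mol_structure")
}

#' @export
print.mol_structure <- function(x, ...) {
  cat(sprintf("<mol_structure%s> %s  MW %.2f  %d heavy atoms, %d bonds, %d component(s)\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$formula, x$mol_weight, length(x$atoms), nrow(x$bonds),
              x$n_components))
  invisible(x)
}

#' Check that a structure contains only GC-MS-amenable elements
#'
#' Heavy atoms must all be C, O, N, B, F, P, S, Cl, Si, Br or I; hydrogen is
#' always permitted.
#'
#' @param structure A [parse_structure()] result.
#' @return `TRUE` or `FALSE`.
#' @export
has_allowed_elements <- function(structure) {
  stopifnot(inherits(structure, "mol_structure"))
  all(structure$atoms %in% ALLOWED_ELEMENTS)
}

#' Convert a structure to its attributed graph
#'
#' One node per heavy atom and one edge per bond, numbered in the input
#' record's atom and bond order. Node features one-hot encode the element
#' over the columns (C, O, N, B, F, P, S, Cl, Si, Br, I); edge features set
#' exactly one bond-order column (single, double, triple, aromatic) plus an
#' independent ring-membership column.
#'
#' @param structure A single-component [parse_structure()] result whose
#'   elements pass [has_allowed_elements()].
#' @return A `mol_graph` object with `n_nodes`, `n_edges`, `adjacency`
#'   (n_nodes x n_nodes, binary symmetric), `incidence` (n_edges x n_nodes,
#'   one row per edge with 1 at each endpoint), `node_features`
#'   (n_nodes x 11) and `edge_features` (n_edges x 5).
#' @export
to_graph <- function(structure) {
  stopifnot(inherits(structure, "mol_structure"))
  if (!has_allowed_elements(structure)) {
    bad <- setdiff(unique(structure$atoms), ALLOWED_ELEMENTS)
    stop("structure contains disallowed element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (structure$n_components != 1L) {
    stop("structure has ", structure$n_components,
         " disconnected components; graphs are built per single component",
         call. = FALSE)
  }
  n <- length(structure$atoms)
  m <- nrow(structure$bonds)
  node_features <- matrix(0L, n, length(ALLOWED_ELEMENTS),
                          dimnames = list(NULL, ALLOWED_ELEMENTS))
  node_features[cbind(seq_len(n), match(structure$atoms, ALLOWED_ELEMENTS))] <- 1L

  edge_cols <- c("single", "double", "triple", "aromatic", "ring")
  edge_features <- matrix(0L, m, 5L, dimnames = list(NULL, edge_cols))
  adjacency <- matrix(0L, n, n)
  incidence <- matrix(0L, m, n)
  if (m) {
    a <- structure$bonds$a
    b <- structure$bonds$b
    edge_features[cbind(seq_len(m), match(structure$bonds$order, edge_cols))] <- 1L
    edge_features[structure$bonds$in_ring, "ring"] <- 1L
    adjacency[cbind(a, b)] <- 1L
    adjacency[cbind(b, a)] <- 1L
    incidence[cbind(seq_len(m), a)] <- 1L
    incidence[cbind(seq_len(m), b)] <- 1L
  }
  structure(list(
    id = structure$id,
    n_nodes = n, n_edges = m,
    adjacency = adjacency, incidence = incidence,
    node_features = node_features, edge_features = edge_features
  ), class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph%s> %d nodes, %d edges\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$n_nodes, x$n_edges))
  invisible(x)
}

#' Edge feature row of a molecular graph
#'
#' @param graph A [to_graph()] result.
#' @param edge_index 1-based edge index.
#' @return The length-5 feature vector (single, double, triple, aromatic,
#'   ring) of that edge; a non-ring single bond yields `c(1, 0, 0, 0, 0)`.
#' @export
single_bond_feature_row <- function(graph, edge_index) {
  stopifnot(inherits(graph, "mol_graph"))
  if (!is.numeric(edge_index) || length(edge_index) != 1L ||
      edge_index < 1 || edge_index > graph$n_edges) {
    stop("edge index out of range: ", edge_index,
         " (graph has ", graph$n_edges, " edges)", call. = FALSE)
  }
  graph$edge_features[as.integer(edge_index), ]
}

#' Read a SMILES file
#'
#' One record per line: a SMILES string, optionally followed by a
#' tab-separated identifier. Blank lines are skipped.
#'
#' @param path File path.
#' @return Data frame with columns `id` and `smiles`.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smiles <- vapply(parts, `[`, "", 1L)
  id <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) > 1L && nzchar(parts[[i]][2L])) parts[[i]][2L]
    else sprintf("mol%04d", i)
  }, "")
  data.frame(id = id, smiles = trimws(smiles))
}

#' Split a multi-molecule SDF file into records
#'
#' @param path File path to an MDL V2000 SD file.
#' @return List of character vectors, one molecule block each.
#' @export
read_sdf_records <- function(path) {
  lines <- readLines(path)
  ends <- grep("^\\$\\$\\$\\$", lines)
  if (!length(ends)) return(list(lines))
  starts <- c(1L, head(ends, -1L) + 1L)
  out <- Map(function(s, e) lines[s:e], starts, ends)
  Filter(function(b) any(grepl("V2000|M  END", b)), out)
}
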