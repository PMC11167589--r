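# Coordinate-free molecular graphs: element list, Pauling electronegativity
# vector, topology matrix (bond-type codes) and binary adjacency matrix.

# Pauling electronegativities. Values identify the atomic type only; they
# carry no further physical meaning in this model.
.PAULING <- c(
  H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98,
  P = 2.19, S = 2.58, Cl = 3.16, Br = 2.96, I = 2.66
)

#' Pauling electronegativity of an element
#'
#' Returns the tabulated Pauling electronegativity (dimensionless) used to
#' label atomic types in the molecular graph.
#'
#' @param element Element symbol, e.g. `"C"`, `"Cl"`. Case-sensitive.
#' @return A positive scalar.
#' @examples
#' electronegativity("H")  # 2.20
#' electronegativity("O")  # 3.44
#' @export
electronegativity <- function(element) {
  if (length(element) != 1L || !is.character(element)) {
    stop("`element` must be a single character string")
  }
  if (!element %in% names(.PAULING)) {
    stop(errorCondition(
      sprintf("unsupported element symbol: '%s' (supported: %s)",
              element, paste(names(.PAULING), collapse = ", ")),
      class = c("mpf_unsupported_element", "error", "condition")
    ))
  }
  unname(.PAULING[[element]])
}

#' Elements with a tabulated electronegativity
#' @return Character vector of supported element symbols.
#' @export
supported_elements <- function() names(.PAULING)

#' Default bond-type code map
#'
#' Maps the five supported bond labels to distinct nonzero numeric codes used
#' in the topology matrix; the absence of a bond is coded 0. The downstream
#' featurizer only requires the codes to be distinct and nonzero, and a
#' trained model records the map it was featurized with.
#'
#' @return Named numeric vector with entries single, double, triple, amide,
#'   aromatic.
#' @export
default_bond_codes <- function() {
  c(single = 1, double = 2, triple = 3, amide = 4, aromatic = 5)
}

#' Numeric code for a bond-type label
#'
#' @param label One of `"single"`, `"double"`, `"triple"`, `"amide"`,
#'   `"aromatic"`, or `"none"` (no bond).
#' @param map Bond-code map, as [default_bond_codes()].
#' @return Numeric code; 0 for `"none"`.
#' @export
bond_code <- function(label, map = default_bond_codes()) {
  stopifnot(is.numeric(map), length(map) == 5L)
  if (!setequal(names(map), c("single", "double", "triple", "amide", "aromatic")) ||
      anyDuplicated(map) || any(map == 0)) {
    stop("`map` must assign distinct nonzero codes to the five bond labels")
  }
  if (identical(label, "none")) return(0)
  if (!is.character(label) || length(label) != 1L || !label %in% names(map)) {
    stop(errorCondition(
      sprintf("unsupported bond type: '%s' (single, double, triple, amide and aromatic bonds only)",
              as.character(label)[1]),
      class = c("mpf_unsupported_bond", "error", "condition")
    ))
  }
  unname(map[[label]])
}

# mol2 bond-type column -> label
.MOL2_BOND_LABEL <- c("1" = "single", "2" = "double", "3" = "triple",
                      "am" = "amide", "ar" = "aromatic")

#' Construct a molecular graph from atoms and bonds
#'
#' Low-level constructor. Atom indices are 1-based; hydrogens must be
#' explicit atoms.
#'
#' @param elements Character vector of element symbols, one per atom.
#' @param bonds Data frame (or NULL for a molecule with no bonds) with
#'   columns `i`, `j` (atom indices) and `type` (bond label as in
#'   [bond_code()]).
#' @param bond_codes Bond-code map.
#' @param charges Optional numeric vector of per-atom partial charges
#'   (training labels), or NULL.
#' @return An object of class `molecular_graph` with fields `n_atoms`,
#'   `elements`, `chi`, `topology`, `adjacency`, `charges`, `bond_codes`.
#' @export
molecular_graph <- function(elements, bonds = NULL,
                            bond_codes = default_bond_codes(),
                            charges = NULL) {
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  chi <- vapply(elements, electronegativity, numeric(1), USE.NAMES = FALSE)
  topo <- matrix(0, n, n)
  if (!is.null(bonds) && nrow(bonds) > 0L) {
    i <- as.integer(bonds$i); j <- as.integer(bonds$j)
    if (any(i < 1L | i > n | j < 1L | j > n)) stop("bond atom index out of range")
    if (any(i == j)) stop("self-bonds are not allowed")
    code <- vapply(as.character(bonds$type), bond_code, numeric(1),
                   map = bond_codes, USE.NAMES = FALSE)
    topo[cbind(i, j)] <- code
    topo[cbind(j, i)] <- code
  }
  adj <- (topo != 0) + 0
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n) stop("`charges` must have one entry per atom")
  }
  structure(
    list(n_atoms = n, elements = as.character(elements), chi = chi,
         topology = topo, adjacency = adj, charges = charges,
         bond_codes = bond_codes),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  comp <- table(x$elements)
  cat(sprintf("<molecular_graph> %d atoms (%s), %d bonds%s\n",
              x$n_atoms,
              paste0(names(comp), comp, collapse = " "),
              sum(x$adjacency) / 2,
              if (is.null(x$charges)) "" else ", charges attached"))
  invisible(x)
}

#' Validate molecular-graph invariants
#'
#' Checks symmetry and zero diagonal of the topology and adjacency matrices,
#' consistency between the two, positivity of the electronegativity vector
#' against the tabulated values, and dimension agreement.
#'
#' @param graph A `molecular_graph`.
#' @return `TRUE` invisibly; otherwise an error.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  n <- graph$n_atoms
  T <- graph$topology; A <- graph$adjacency
  if (!all(dim(T) == n) || !all(dim(A) == n)) stop("matrix dimension mismatch")
  if (!isTRUE(all.equal(T, t(T))) || !isTRUE(all.equal(A, t(A)))) {
    stop("topology/adjacency must be symmetric")
  }
  if (any(diag(T) != 0) || any(diag(A) != 0)) stop("nonzero diagonal")
  if (!all((T != 0) == (A == 1))) stop("adjacency inconsistent with topology")
  chi_ref <- vapply(graph$elements, electronegativity, numeric(1))
  if (!all(graph$chi > 0) || !isTRUE(all.equal(unname(chi_ref), graph$chi))) {
    stop("chi does not match the tabulated Pauling values")
  }
  invisible(TRUE)
}

#' Relabel the atoms of a graph by a permutation
#'
#' @param graph A `molecular_graph`.
#' @param perm Integer permutation of `1:n_atoms`; atom `i` of the result is
#'   atom `perm[i]` of the input.
#' @return The permuted `molecular_graph`.
#' @export
permute_graph <- function(graph, perm) {
  stopifnot(inherits(graph, "molecular_graph"),
            length(perm) == graph$n_atoms,
            setequal(perm, seq_len(graph$n_atoms)))
  out <- graph
  out$elements <- graph$elements[perm]
  out$chi <- graph$chi[perm]
  out$topology <- graph$topology[perm, perm, drop = FALSE]
  out$adjacency <- graph$adjacency[perm, perm, drop = FALSE]
  if (!is.null(graph$charges)) out$charges <- graph$charges[perm]
  out
}

.parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("mpf_parse_error", "error", "condition")))
}

# Parse one @<TRIPOS>MOLECULE record (character vector of lines).
.parse_mol2_record <- function(lines, bond_codes) {
  section <- function(name) {
    hdr <- grep(sprintf("^@<TRIPOS>%s\\s*$", name), lines)
    if (length(hdr) != 1L) return(NULL)
    ends <- grep("^@<TRIPOS>", lines)
    nxt <- ends[ends > hdr]
    body <- lines[(hdr + 1L):(if (length(nxt)) nxt[1] - 1L else length(lines))]
    body <- trimws(body)
    body[nzchar(body) & !startsWith(body, "#")]
  }
  atom_lines <- section("ATOM")
  bond_lines <- section("BOND")
  if (is.null(atom_lines)) .parse_error("mol2 record lacks an @<TRIPOS>ATOM section")
  if (is.null(bond_lines)) .parse_error("mol2 record lacks an @<TRIPOS>BOND section")

  atoms <- strsplit(atom_lines, "\\s+")
  if (any(lengths(atoms) < 6L)) .parse_error("malformed @<TRIPOS>ATOM line")
  # SYBYL atom type (field 6): element is the stem before the dot ("C.3" -> C);
  # the atom-name column is free-form in database exports and is ignored.
  sybyl <- vapply(atoms, `[[`, character(1), 6L)
  elements <- sub("\\..*$", "", sybyl)
  ids <- as.integer(vapply(atoms, `[[`, character(1), 1L))
  if (anyNA(ids) || !setequal(ids, seq_along(ids))) {
    .parse_error("mol2 atom ids must be 1..n")
  }
  elements <- elements[order(ids)]
  charges <- NULL
  if (all(lengths(atoms) >= 9L)) {
    q <- suppressWarnings(as.numeric(vapply(atoms, `[[`, character(1), 9L)))
    if (!anyNA(q)) charges <- q[order(ids)]
  }

  bonds <- strsplit(bond_lines, "\\s+")
  if (any(lengths(bonds) < 4L)) .parse_error("malformed @<TRIPOS>BOND line")
  btype <- vapply(bonds, `[[`, character(1), 4L)
  unknown <- setdiff(unique(btype), names(.MOL2_BOND_LABEL))
  if (length(unknown)) {
    stop(errorCondition(
      sprintf("unsupported bond type: '%s' (single, double, triple, amide and aromatic bonds only)",
              unknown[1]),
      class = c("mpf_unsupported_bond", "error", "condition")
    ))
  }
  bond_df <- data.frame(
    i = as.integer(vapply(bonds, `[[`, character(1), 2L)),
    j = as.integer(vapply(bonds, `[[`, character(1), 3L)),
    type = unname(.MOL2_BOND_LABEL[btype])
  )
  molecular_graph(elements, bond_df, bond_codes = bond_codes, charges = charges)
}

#' Build a molecular graph from a TRIPOS mol2 record
#'
#' Parses the `@<TRIPOS>ATOM` and `@<TRIPOS>BOND` sections of a single mol2
#' record. Coordinates are ignored (the model is coordinate-free); the
#' element is taken from the SYBYL atom-type stem; the ninth ATOM column, if
#' numeric, is kept as optional per-atom charge labels. Bond types must be
#' `1`, `2`, `3`, `am` or `ar`.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   lines holding one mol2 record.
#' @inheritParams molecular_graph
#' @return A `molecular_graph`.
#' @export
graph_from_mol2 <- function(text, bond_codes = default_bond_codes()) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  .parse_mol2_record(lines, bond_codes)
}

#' Read molecular graphs from a mol2 file
#'
#' Splits a (possibly multi-molecule) mol2 file on `@<TRIPOS>MOLECULE`
#' delimiters and parses each record with [graph_from_mol2()].
#'
#' @param path Path to a mol2 file.
#' @inheritParams molecular_graph
#' @return Named list of `molecular_graph` objects (names from the MOLECULE
#'   record where present).
#' @export
read_mol2 <- function(path, bond_codes = default_bond_codes()) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE\\s*$", lines)
  if (!length(starts)) .parse_error("no @<TRIPOS>MOLECULE record in file")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  nms <- character(length(starts))
  for (k in seq_along(starts)) {
    rec <- lines[starts[k]:ends[k]]
    nm <- trimws(rec[2])
    nms[k] <- if (nzchar(nm) && nm != "*****") nm else sprintf("mol%d", k)
    out[[k]] <- .parse_mol2_record(rec, bond_codes)
  }
  names(out) <- make.unique(nms)
  out
}

#' Build a molecular graph from a SMILES string
#'
#' The string is converted to mol2 format by Open Babel without generating
#' atomic coordinates, with hydrogens made explicit, and the result is parsed
#' by [graph_from_mol2()]. Aromatic bonds map to `ar`, amide linkages to
#' `am`, and other bonds to `1`/`2`/`3`. Formal charges in the SMILES do not
#' alter the graph. Multi-fragment SMILES (with `.`) are accepted; message
#' passing stays within connected components.
#'
#' @param smiles A single SMILES string.
#' @inheritParams molecular_graph
#' @return A `molecular_graph`.
#' @export
graph_from_smiles <- function(smiles, bond_codes = default_bond_codes()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (Sys.which("obabel") == "") {
    stop("the `obabel` executable is required for SMILES input but was not found on PATH")
  }
  out <- suppressWarnings(system2(
    "obabel", c(shQuote(paste0("-:", smiles)), "-omol2", "-h"),
    stdout = TRUE, stderr = FALSE
  ))
  if (!length(grep("^@<TRIPOS>ATOM", out))) {
    .parse_error(sprintf("Open Babel could not parse SMILES '%s'", smiles))
  }
  g <- graph_from_mol2(out, bond_codes = bond_codes)
  g$charges <- NULL  # obabel emits Gasteiger placeholders; not training labels
  g
}

#' Per-atom degree
#' @param graph A `molecular_graph`.
#' @return Integer vector of explicit-bond counts per atom.
#' @export
atom_degree <- function(graph) {
  as.integer(rowSums(graph$adjacency))
}

#' Write molecular graphs to a TRIPOS mol2 file
#'
#' Emits one `@<TRIPOS>MOLECULE` record per graph with zero coordinates (the
#' representation is coordinate-free), SYBYL atom types equal to the element
#' symbol, the supported bond dialect (`1`, `2`, `3`, `am`, `ar`), and the
#' graph's charges in the charge column when present (0 otherwise). Internal
#' 1-based atom indices are written as mol2 atom ids.
#'
#' @param graphs A `molecular_graph` or (optionally named) list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mol2 <- function(graphs, path) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(mol1 = graphs)
  if (is.null(names(graphs))) names(graphs) <- sprintf("mol%d", seq_along(graphs))
  code_to_mol2 <- function(codes, map) {
    names(.MOL2_BOND_LABEL)[match(names(map)[match(codes, map)], .MOL2_BOND_LABEL)]
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    ut <- upper.tri(g$topology) & g$topology != 0
    bi <- row(g$topology)[ut]; bj <- col(g$topology)[ut]
    bc <- code_to_mol2(g$topology[ut], g$bond_codes)
    q <- if (is.null(g$charges)) rep(0, g$n_atoms) else g$charges
    writeLines(c(
      "@<TRIPOS>MOLECULE", names(graphs)[k],
      sprintf(" %d %d 0 0 0", g$n_atoms, length(bi)),
      "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM",
      sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %3d UNL1 %12.8f",
              seq_len(g$n_atoms),
              paste0(g$elements, seq_len(g$n_atoms)),
              0, 0, 0, g$elements, 1L, q),
      "@<TRIPOS>BOND",
      if (length(bi)) sprintf("%6d %5d %5d %4s", seq_along(bi), bi, bj, bc) else character(0)
    ), con)
  }
  invisible(path)
}
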