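#' Carhart-style atom codes and canonical atom pairs
#'
#' An atom code is the triple (element, heavy-atom degree, pi electrons): the
#' element symbol, the number of bonded non-hydrogen neighbours, and the
#' number of pi-bonding electrons the atom contributes. Pi electrons are
#' counted from the kekulized bond orders as the sum over incident bonds of
#' (order - 1), so an aromatic ring carbon (one double + one single ring bond
#' in any Kekule assignment) contributes 1 and a nitrile nitrogen contributes
#' 2. Hydrogens never receive codes.
#'
#' @param molecule a `qap_mol` (from [parse_smiles()]) or a SMILES string.
#' @param atom_index 1-based index into the parsed atom table; must address a
#'   non-hydrogen atom.
#' @return A `qap_atom_code`: list with `element`, `heavy_degree`,
#'   `pi_electrons`.
#' @examples
#' atom_code("CC#N", 3)   # nitrile N: (N, 1, 2)
#' @export
atom_code <- function(molecule, atom_index) {
  mol <- as_qap_mol(molecule)
  if (!is.numeric(atom_index) || length(atom_index) != 1L ||
      atom_index < 1L || atom_index > mol$n_atoms) {
    stop("atom_index out of range (1..", mol$n_atoms, ")", call. = FALSE)
  }
  atom_index <- as.integer(atom_index)
  if (mol$is_h[atom_index]) {
    stop("atom ", atom_index, " is a hydrogen; hydrogens carry no atom code",
         call. = FALSE)
  }
  codes <- .atom_codes(mol)
  i <- match(atom_index, which(!mol$is_h))
  structure(list(element = codes$element[i],
                 heavy_degree = codes$heavy_degree[i],
                 pi_electrons = codes$pi_electrons[i]),
            class = "qap_atom_code")
}

#' @export
format.qap_atom_code <- function(x, ...) {
  paste(x$element, x$heavy_degree, x$pi_electrons, sep = ".")
}

#' @export
print.qap_atom_code <- function(x, ...) {
  cat("<atom code> ", format(x), "\n", sep = "")
  invisible(x)
}

# Vectorised atom codes for all heavy atoms of a molecule.
# Returns a list of parallel vectors, one entry per heavy atom (in original
# atom order).
.atom_codes <- function(mol) {
  heavy <- which(!mol$is_h)
  deg <- integer(length(heavy))
  pi_e <- integer(length(heavy))
  remap <- integer(mol$n_atoms)
  remap[heavy] <- seq_along(heavy)
  b <- mol$bonds
  if (nrow(b) > 0L) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, 1]; j <- b[r, 2]; o <- b[r, 3]
      hi <- !mol$is_h[i]; hj <- !mol$is_h[j]
      if (hi && hj) {
        deg[remap[i]] <- deg[remap[i]] + 1L
        deg[remap[j]] <- deg[remap[j]] + 1L
      }
      if (o > 1L) {
        # pi electrons accrue from multiple bonds regardless of partner;
        # H never participates in multiple bonds in valid molecules
        if (hi) pi_e[remap[i]] <- pi_e[remap[i]] + (o - 1L)
        if (hj) pi_e[remap[j]] <- pi_e[remap[j]] + (o - 1L)
      }
    }
  }
  list(atom_index = heavy, element = mol$elements[heavy],
       heavy_degree = deg, pi_electrons = pi_e)
}

#' Topological distance between two atoms
#'
#' Length in bonds of the shortest path between two heavy atoms of a molecule.
#'
#' @inheritParams atom_code
#' @param i,j 1-based atom indices of two distinct heavy atoms.
#' @return Integer bond count, or `NA_integer_` when the atoms lie in
#'   different fragments (no path), with a warning.
#' @examples
#' topological_distance("CCC", 1, 3)  # 2
#' @export
topological_distance <- function(molecule, i, j) {
  mol <- as_qap_mol(molecule)
  i <- as.integer(i); j <- as.integer(j)
  if (i == j) stop("i and j must differ", call. = FALSE)
  for (k in c(i, j)) {
    if (k < 1L || k > mol$n_atoms) stop("atom index out of range", call. = FALSE)
    if (mol$is_h[k]) stop("atom ", k, " is a hydrogen", call. = FALSE)
  }
  d <- .heavy_dist_matrix(mol)
  v <- d[as.character(i), as.character(j)]
  if (!is.finite(v)) {
    warning("atoms ", i, " and ", j, " are in different fragments; no path")
    return(NA_integer_)
  }
  as.integer(v)
}

# ---- canonical pair codes ---------------------------------------------------

# A pair code is serialized as "El.deg.pi-El.deg.pi@d" with the two atom code
# triples in a fixed total order: lexicographic on (element, heavy_degree,
# pi_electrons). This makes pair_code(a, b, d) == pair_code(b, a, d).
.code_str <- function(element, degree, pi_e) {
  paste(element, degree, pi_e, sep = ".")
}

# TRUE where code a = (el, deg, pi) sorts at-or-before code b.
.code_le <- function(el_a, dg_a, pi_a, el_b, dg_b, pi_b) {
  ifelse(el_a != el_b, el_a < el_b,
         ifelse(dg_a != dg_b, dg_a < dg_b, pi_a <= pi_b))
}

pair_string <- function(el_a, dg_a, pi_a, el_b, dg_b, pi_b, distance) {
  a_first <- .code_le(el_a, dg_a, pi_a, el_b, dg_b, pi_b)
  lo <- ifelse(a_first, .code_str(el_a, dg_a, pi_a), .code_str(el_b, dg_b, pi_b))
  hi <- ifelse(a_first, .code_str(el_b, dg_b, pi_b), .code_str(el_a, dg_a, pi_a))
  paste0(lo, "-", hi, "@", distance)
}

# Parse "El.deg.pi-El.deg.pi@d" back into a data.frame of components.
parse_pair_string <- function(s) {
  m <- regmatches(s, regexec(
    "^([A-Za-z]+)\\.(\\d+)\\.(\\d+)-([A-Za-z]+)\\.(\\d+)\\.(\\d+)@(\\d+)$", s))
  bad <- vapply(m, length, integer(1)) != 8L
  if (any(bad)) stop("malformed pair code(s): ",
                     paste(utils::head(s[bad], 3), collapse = ", "),
                     call. = FALSE)
  mm <- do.call(rbind, m)
  data.frame(el_lo = mm[, 2], deg_lo = as.integer(mm[, 3]),
             pi_lo = as.integer(mm[, 4]), el_hi = mm[, 5],
             deg_hi = as.integer(mm[, 6]), pi_hi = as.integer(mm[, 7]),
             distance = as.integer(mm[, 8]), stringsAsFactors = FALSE)
}

# Canonical ordering of pair strings: lexicographic on the parsed tuple
# (el_lo, deg_lo, pi_lo, el_hi, deg_hi, pi_hi, distance). Radix sort with the
# C collation keeps the order locale-independent.
order_pair_strings <- function(s) {
  p <- parse_pair_string(s)
  order(p$el_lo, p$deg_lo, p$pi_lo, p$el_hi, p$deg_hi, p$pi_hi, p$distance,
        method = "radix")
}

sort_pair_strings <- function(s) s[order_pair_strings(s)]

#' Enumerate canonical atom pairs of a molecule
#'
#' Enumerates every unordered pair of heavy atoms whose topological distance
#' lies in `1..max_distance` and aggregates them into a multiset of canonical
#' pair codes `"El.deg.pi-El.deg.pi@d"`. The result is independent of the
#' atom input order of the SMILES. For multi-fragment inputs, pairs are
#' enumerated within fragments only (distance is undefined across fragments)
#' and a warning is attached.
#'
#' @inheritParams atom_code
#' @param max_distance maximum topological distance in bonds (default 4).
#' @return A named integer vector of class `qap_pairs`: names are canonical
#'   pair codes, values are occurrence counts, sorted canonically. Attribute
#'   `n_heavy` carries the heavy-atom count.
#' @examples
#' enumerate_pairs("CCC")
#' @export
enumerate_pairs <- function(molecule, max_distance = 4L) {
  mol <- as_qap_mol(molecule)
  max_distance <- as.integer(max_distance)
  stopifnot(max_distance >= 1L)
  codes <- .atom_codes(mol)
  nh <- length(codes$atom_index)
  empty <- structure(stats::setNames(integer(0), character(0)),
                     n_heavy = nh, class = "qap_pairs")
  if (nh < 2L) return(empty)
  d <- .heavy_dist_matrix(mol)
  ut <- upper.tri(d)
  sel <- ut & is.finite(d) & d >= 1 & d <= max_distance
  if (mol$n_heavy >= 2L && any(ut & !is.finite(d))) {
    warning("multi-fragment input: pairs enumerated within fragments only")
  }
  if (!any(sel)) return(empty)
  idx <- which(sel, arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  ps <- pair_string(codes$element[a], codes$heavy_degree[a], codes$pi_electrons[a],
                    codes$element[b], codes$heavy_degree[b], codes$pi_electrons[b],
                    as.integer(d[sel]))
  tab <- table(ps)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts <- counts[order_pair_strings(names(counts))]
  structure(counts, n_heavy = nh, class = "qap_pairs")
}

#' @export
print.qap_pairs <- function(x, ...) {
  cat("<atom pair multiset> ", length(x), " distinct pairs, total count ",
      sum(x), "\n", sep = "")
  if (length(x) > 0L) print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

# Elements a pair code may contain when entering a lookup.
QAP_ELEMENTS <- c("C", "N", "O", "F", "S", "Cl", "Br")
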