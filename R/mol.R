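#' Parse SMILES strings into molecular graphs
#'
#' Converts SMILES into lightweight molecular-graph objects via OpenBabel
#' (through \pkg{ChemmineR}/\pkg{ChemmineOB}). Aromatic systems are kekulized
#' by the parser, so every bond carries an integer order (1, 2 or 3), which is
#' what the pi-electron count of an atom code is defined on. Hydrogens present
#' in the input (explicit atoms) are kept in the atom table but flagged; they
#' never enter atom codes or pairs.
#'
#' @param smiles character vector of SMILES strings.
#' @param ids optional identifiers (defaults to names of `smiles` or
#'   `mol1..molN`).
#' @return A list of `qap_mol` objects (one per input). Entries that fail to
#'   parse are `NULL`, with the failure recorded in the `"n_failed"` attribute.
#' @examples
#' mols <- parse_smiles(c("CCO", "c1ccccc1"))
#' mols[[2]]$elements
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    out <- list()
    attr(out, "n_failed") <- 0L
    return(out)
  }
  if (is.null(ids)) ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  nm <- make.unique(ids)
  out <- vector("list", length(smiles))
  names(out) <- nm
  for (k in seq_along(smiles)) {
    # one conversion per molecule: OpenBabel returns an empty string on
    # parse failure, and batch conversion would silently drop such rows
    sdf_txt <- tryCatch(
      ChemmineOB::convertFormat("SMILES", "SDF", smiles[[k]]),
      error = function(e) "")
    if (!nzchar(sdf_txt)) next
    lines <- strsplit(sdf_txt, "\n", fixed = TRUE)[[1L]]
    n_atoms <- suppressWarnings(as.integer(substr(lines[4L], 1L, 3L)))
    if (is.na(n_atoms) || n_atoms < 1L) next
    if (n_atoms == 1L) {
      # ChemmineR's SDF reader mangles single-atom (zero-bond) molfiles;
      # take the element straight from the one atom line
      el <- strsplit(trimws(lines[5L]), "\\s+")[[1L]][4L]
      out[[k]] <- .mol_single_atom(el, smiles[[k]], nm[[k]])
    } else {
      sdfset <- suppressWarnings(ChemmineR::read.SDFset(lines))
      out[[k]] <- .mol_from_sdf(sdfset[[1L]], smiles[[k]], nm[[k]])
    }
  }
  attr(out, "n_failed") <- sum(vapply(out, is.null, logical(1)))
  out
}

.mol_single_atom <- function(element, smiles, id) {
  structure(
    list(id = id, smiles = smiles, elements = element,
         bonds = matrix(integer(0), ncol = 3L,
                        dimnames = list(NULL, c("i", "j", "order"))),
         is_h = element == "H", n_atoms = 1L,
         n_heavy = as.integer(element != "H")),
    class = "qap_mol")
}

# Build a qap_mol from a ChemmineR SDF object. Atom symbols in the atom block
# are rownames like "C_1", "Cl_5"; bond block columns 1:3 are (i, j, order).
.mol_from_sdf <- function(sdf, smiles, id) {
  ab <- ChemmineR::atomblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- matrix(integer(0), ncol = 3L,
                    dimnames = list(NULL, c("i", "j", "order")))
  } else {
    bonds <- cbind(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                   order = as.integer(bb[, 3]))
  }
  is_h <- elements == "H"
  structure(
    list(id = id, smiles = smiles, elements = elements,
         bonds = bonds, is_h = is_h, n_atoms = n,
         n_heavy = sum(!is_h)),
    class = "qap_mol")
}

#' @export
print.qap_mol <- function(x, ...) {
  cat("<qap_mol> ", x$id, ": ", x$smiles, "\n", sep = "")
  cat("  ", x$n_heavy, " heavy atoms, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

# Accept either a qap_mol or a single SMILES string everywhere a molecule is
# expected.
as_qap_mol <- function(molecule) {
  if (inherits(molecule, "qap_mol")) return(molecule)
  if (is.character(molecule) && length(molecule) == 1L) {
    m <- parse_smiles(molecule)[[1L]]
    if (is.null(m)) stop("unparseable SMILES: ", molecule, call. = FALSE)
    return(m)
  }
  stop("expected a qap_mol or a single SMILES string", call. = FALSE)
}

# Topological distance matrix over heavy atoms only (hydrogens are terminal,
# so heavy-heavy shortest paths never pass through them). Rows/cols indexed by
# original atom index of the heavy atoms; Inf across fragments.
.heavy_dist_matrix <- function(mol) {
  heavy <- which(!mol$is_h)
  nh <- length(heavy)
  if (nh == 0L) return(matrix(numeric(0), 0, 0))
  remap <- integer(mol$n_atoms)
  remap[heavy] <- seq_len(nh)
  b <- mol$bonds
  keep <- b[, 1] %in% heavy & b[, 2] %in% heavy
  el <- cbind(remap[b[keep, 1]], remap[b[keep, 2]])
  g <- igraph::make_empty_graph(n = nh, directed = FALSE)
  if (nrow(el) > 0L) g <- igraph::add_edges(g, t(el))
  d <- igraph::distances(g)
  dimnames(d) <- list(heavy, heavy)
  d
}
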