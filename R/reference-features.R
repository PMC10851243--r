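#' Reference molecular representations
#'
#' Standard cheminformatics feature matrices used as comparison points for
#' the QAP descriptors:
#'
#' * `morgan` — circular (ECFP4-style) fingerprint, 4096 bits, via OpenBabel.
#' * `path_fingerprint` — linear-path fingerprint (OpenBabel FP2), 1024 bits.
#' * `atom_pairs_classic` — Carhart atom-pair counts over the unique pair
#'   descriptors observed in the dataset (ChemmineR implementation).
#' * `topological_torsion` — counts of canonical 4-atom linear paths, each
#'   atom labelled with its (element, heavy degree, pi electrons) code.
#' * `descriptor_panel` — whole-molecule property panel (OpenBabel: MW, logP,
#'   TPSA, MR, H-bond donors/acceptors, fluorine count) plus heavy-atom,
#'   bond and ring counts from the molecular graph.
#'
#' The same variance filter applied to QAP features applies downstream.
#'
#' @param molecules character vector of SMILES, optionally named.
#' @param scheme one of the five names above.
#' @return Numeric matrix, one row per molecule.
#' @export
reference_features <- function(molecules,
                               scheme = c("morgan", "atom_pairs_classic",
                                          "topological_torsion",
                                          "path_fingerprint",
                                          "descriptor_panel")) {
  scheme <- tryCatch(match.arg(scheme), error = function(e) {
    stop("unknown scheme '", scheme[1L], "'; valid schemes: ",
         "morgan, atom_pairs_classic, topological_torsion, ",
         "path_fingerprint, descriptor_panel", call. = FALSE)
  })
  stopifnot(is.character(molecules), length(molecules) >= 1L)
  ids <- names(molecules)
  if (is.null(ids)) ids <- paste0("mol", seq_along(molecules))
  mols <- parse_smiles(molecules, ids)
  bad <- which(vapply(mols, is.null, logical(1)))
  if (length(bad) > 0L) {
    stop("unparseable molecule(s) at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  m <- switch(scheme,
              morgan = .ob_fp_matrix(molecules, "ECFP4"),
              path_fingerprint = .ob_fp_matrix(molecules, "FP2"),
              atom_pairs_classic = .classic_ap_matrix(molecules),
              topological_torsion = .torsion_matrix(mols),
              descriptor_panel = .descriptor_panel(molecules, mols))
  rownames(m) <- ids
  m
}

# OpenBabel bit fingerprints, one row per molecule.
.ob_fp_matrix <- function(smiles, fp_name) {
  rows <- lapply(smiles, function(s) {
    ref <- ChemmineOB::forEachMol("SMILES", s, identity)
    ChemmineOB::fingerprint_OB(ref, fp_name)
  })
  m <- do.call(rbind, rows)
  colnames(m) <- paste0(tolower(fp_name), "_bit", seq_len(ncol(m)))
  m
}

# Carhart atom-pair counts via ChemmineR: tabulate each molecule's pair
# descriptors over the union observed in the dataset.
.classic_ap_matrix <- function(smiles) {
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles, paste0("m", seq_along(smiles)))))
  apset <- ChemmineR::sdf2ap(sdfset)
  descs <- lapply(seq_along(smiles), function(k) ChemmineR::ap(apset[[k]]))
  universe <- sort(unique(unlist(descs)))
  m <- matrix(0, nrow = length(smiles), ncol = length(universe))
  for (k in seq_along(descs)) {
    tab <- table(descs[[k]])
    m[k, match(as.numeric(names(tab)), universe)] <- as.integer(tab)
  }
  colnames(m) <- paste0("ap_", universe)
  m
}

# Topological torsions: every linear path i-j-k-l of four distinct bonded
# heavy atoms, labelled by the four atom codes; canonical direction is the
# lexicographically smaller of forward/reverse label sequences.
.torsion_matrix <- function(mols) {
  per_mol <- lapply(mols, .torsions_of)
  universe <- sort(unique(unlist(lapply(per_mol, names))))
  m <- matrix(0, nrow = length(mols), ncol = length(universe))
  if (length(universe) > 0L) {
    for (k in seq_along(per_mol)) {
      m[k, match(names(per_mol[[k]]), universe)] <- as.integer(per_mol[[k]])
    }
    colnames(m) <- paste0("tt_", universe)
  }
  m
}

.torsions_of <- function(mol) {
  codes <- .atom_codes(mol)
  heavy <- codes$atom_index
  if (length(heavy) < 4L) return(stats::setNames(integer(0), character(0)))
  remap <- integer(mol$n_atoms)
  remap[heavy] <- seq_along(heavy)
  adj <- vector("list", length(heavy))
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    if (mol$is_h[i] || mol$is_h[j]) next
    adj[[remap[i]]] <- c(adj[[remap[i]]], remap[j])
    adj[[remap[j]]] <- c(adj[[remap[j]]], remap[i])
  }
  lab <- .code_str(codes$element, codes$heavy_degree, codes$pi_electrons)
  out <- character(0)
  for (j in seq_along(heavy)) {
    for (k in adj[[j]]) {
      if (k <= j) next               # each central bond j-k once
      for (i in setdiff(adj[[j]], k)) {
        for (l in setdiff(adj[[k]], c(j, i))) {
          fwd <- paste(lab[c(i, j, k, l)], collapse = ":")
          rev <- paste(lab[c(l, k, j, i)], collapse = ":")
          out <- c(out, if (fwd <= rev) fwd else rev)
        }
      }
    }
  }
  if (length(out) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(out)
  stats::setNames(as.integer(tab), names(tab))
}

# Whole-molecule property panel.
.descriptor_panel <- function(smiles, mols) {
  rows <- lapply(seq_along(smiles), function(k) {
    ref <- ChemmineOB::forEachMol("SMILES", smiles[[k]], identity)
    p <- ChemmineOB::prop_OB(ref)
    num <- vapply(p[, c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF",
                        "TPSA")], as.numeric, numeric(1))
    mol <- mols[[k]]
    nb_heavy <- sum(!mol$is_h[mol$bonds[, 1]] & !mol$is_h[mol$bonds[, 2]])
    c(num, n_heavy = mol$n_heavy, n_bonds = nb_heavy,
      n_rings = nb_heavy - mol$n_heavy + 1L)  # cyclomatic count (connected)
  })
  do.call(rbind, rows)
}
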