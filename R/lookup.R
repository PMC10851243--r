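#' Canonical names of the eleven quantum properties
#'
#' Column order follows the reference-database convention: dipole moment
#' (Debye), isotropic polarizability (a.u.), HOMO and LUMO energies and their
#' gap (Hartree), zero-point vibrational energy, internal energies at 0 K and
#' 298.15 K, enthalpy and free energy at 298.15 K (Hartree), and heat
#' capacity at 298.15 K (cal/(mol K)).
#'
#' @export
qap_property_names <- function() {
  c("mu", "alpha", "homo", "lumo", "gap", "zpve",
    "u0", "u298", "h298", "g298", "cv")
}

#' Read a quantum-property reference database
#'
#' Reads a delimited table with one row per molecule: a SMILES column plus the
#' eleven quantum-property columns. Rows whose SMILES fail to parse or whose
#' properties are missing/non-finite are dropped, with the count reported via
#' message and the `"n_rejected"` attribute. Row order is preserved.
#'
#' @param path CSV file path (header required).
#' @param smiles_col name of the SMILES column (default `"smiles"`).
#' @param property_cols names of the 11 property columns, in property order
#'   (default [qap_property_names()]).
#' @return A data.frame of class `qap_qdb` with columns `smiles` plus the 11
#'   properties (renamed to the canonical names).
#' @export
read_quantum_database <- function(path, smiles_col = "smiles",
                                  property_cols = qap_property_names()) {
  stopifnot(length(property_cols) == 11L)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty reference table: ", path, call. = FALSE)
  missing_cols <- setdiff(c(smiles_col, property_cols), names(tab))
  if (length(missing_cols) > 0L) {
    stop("reference table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  db <- data.frame(smiles = as.character(tab[[smiles_col]]),
                   stringsAsFactors = FALSE)
  for (k in seq_len(11L)) {
    db[[qap_property_names()[k]]] <- as.numeric(tab[[property_cols[k]]])
  }
  ok_prop <- apply(as.matrix(db[, qap_property_names()]), 1L,
                   function(r) all(is.finite(r)))
  mols <- parse_smiles(db$smiles)
  ok_smi <- !vapply(mols, is.null, logical(1))
  keep <- ok_prop & ok_smi
  n_rej <- sum(!keep)
  if (n_rej > 0L) {
    message("read_quantum_database: dropped ", n_rej, " of ", nrow(db),
            " rows (unparseable SMILES or missing properties)")
  }
  out <- db[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rej
  class(out) <- c("qap_qdb", "data.frame")
  out
}

#' Per-pair property contributions of one molecule
#'
#' For each distinct atom pair in a molecule, the molecule contributes its
#' property vector divided by the pair's occurrence count in that molecule
#' (occurrence division). Each molecule thus contributes exactly one vector
#' per distinct pair it contains.
#'
#' @inheritParams atom_code
#' @param properties named numeric vector of the 11 quantum properties
#'   (names as [qap_property_names()]).
#' @param max_distance maximum pair distance in bonds.
#' @return Numeric matrix, one row per distinct pair (rownames are canonical
#'   pair codes, canonically ordered), 11 property columns. Zero rows when the
#'   molecule has no pairs.
#' @export
pair_contributions <- function(molecule, properties, max_distance = 4L) {
  props <- properties[qap_property_names()]
  if (anyNA(props)) stop("properties must contain all 11 named components",
                         call. = FALSE)
  pairs <- enumerate_pairs(molecule, max_distance)
  out <- matrix(numeric(0), nrow = 0L, ncol = 11L,
                dimnames = list(NULL, qap_property_names()))
  if (length(pairs) == 0L) return(out)
  contrib <- outer(1 / as.numeric(pairs), as.numeric(props))
  dimnames(contrib) <- list(names(pairs), qap_property_names())
  contrib
}

#' Build a quantum atom-pair lookup from reference records
#'
#' Aggregates per-pair statistics over a reference database: for every atom
#' pair observed in at least one record, the arithmetic mean over molecules of
#' that pair's occurrence-divided contributions, a per-property binned
#' histogram of those same contributions, and the number of contributing
#' molecules (support). Records containing heavy elements outside
#' C/N/O/F/S/Cl/Br are skipped (the element restriction of the reference
#' database defines the applicability domain).
#'
#' Histogram bins are equal-width over the observed contribution range of that
#' pair and property; a degenerate range (all contributions equal) puts all
#' mass in the center bin. Histograms are stored as relative frequencies
#' (summing to 1) by default, or raw counts with `hist_mode = "count"`.
#'
#' @param records a `qap_qdb` data.frame (see [read_quantum_database()] or
#'   [generate_quantum_db()]).
#' @param max_distance maximum pair distance in bonds (default 4).
#' @param n_bins histogram bins per property (default 10).
#' @param hist_mode `"frequency"` (default) or `"count"`.
#' @param source identifier recorded in the provenance block.
#' @return A `qap_lookup` object: `entries` (named list keyed by canonical
#'   pair code, each with `mean`, `hist` (11 x n_bins matrix), `breaks`
#'   (11 x (n_bins+1) matrix of bin edges) and `support`), `pair_order`,
#'   `property_names`, `max_distance`, `n_bins`, `hist_mode`, `provenance`.
#' @export
build_lookup <- function(records, max_distance = 4L, n_bins = 10L,
                         hist_mode = c("frequency", "count"),
                         source = "unspecified") {
  hist_mode <- match.arg(hist_mode)
  stopifnot(is.data.frame(records), nrow(records) >= 1L, n_bins >= 1L)
  pn <- qap_property_names()
  props <- as.matrix(records[, pn])
  mols <- parse_smiles(records$smiles)

  contribs <- new.env(parent = emptyenv())  # pair code -> list of rows
  n_skipped_element <- 0L
  n_contributing <- 0L
  for (k in seq_along(mols)) {
    mol <- mols[[k]]
    if (is.null(mol)) next
    heavy_elems <- unique(mol$elements[!mol$is_h])
    if (!all(heavy_elems %in% QAP_ELEMENTS)) {
      n_skipped_element <- n_skipped_element + 1L
      next
    }
    pairs <- suppressWarnings(enumerate_pairs(mol, max_distance))
    if (length(pairs) == 0L) next
    n_contributing <- n_contributing + 1L
    for (p in seq_along(pairs)) {
      key <- names(pairs)[p]
      row <- props[k, ] / as.numeric(pairs[p])
      contribs[[key]] <- c(contribs[[key]], list(row))
    }
  }
  keys <- ls(contribs)
  if (length(keys) == 0L) {
    stop("no atom pairs observed in any record", call. = FALSE)
  }
  if (n_skipped_element > 0L) {
    message("build_lookup: skipped ", n_skipped_element,
            " record(s) containing elements outside ",
            paste(QAP_ELEMENTS, collapse = "/"))
  }
  keys <- sort_pair_strings(keys)
  entries <- vector("list", length(keys))
  names(entries) <- keys
  for (key in keys) {
    m <- do.call(rbind, contribs[[key]])
    entries[[key]] <- .pair_statistics(m, n_bins, hist_mode)
  }
  structure(
    list(entries = entries, pair_order = keys, property_names = pn,
         max_distance = as.integer(max_distance), n_bins = as.integer(n_bins),
         hist_mode = hist_mode,
         provenance = list(source = source,
                           n_records = nrow(records),
                           n_contributing = n_contributing,
                           n_skipped_element = n_skipped_element)),
    class = "qap_lookup")
}

# Aggregate one pair's contribution matrix (support x 11) into statistics.
.pair_statistics <- function(m, n_bins, hist_mode) {
  pn <- qap_property_names()
  support <- nrow(m)
  means <- colMeans(m)
  hist <- matrix(0, nrow = 11L, ncol = n_bins,
                 dimnames = list(pn, paste0("bin", seq_len(n_bins))))
  breaks <- matrix(0, nrow = 11L, ncol = n_bins + 1L,
                   dimnames = list(pn, NULL))
  for (p in seq_len(11L)) {
    v <- m[, p]
    lo <- min(v); hi <- max(v)
    if (hi > lo) {
      edges <- seq(lo, hi, length.out = n_bins + 1L)
      idx <- pmin(pmax(findInterval(v, edges, all.inside = TRUE), 1L), n_bins)
    } else {
      # degenerate range: unit-width bins centered so all mass falls in the
      # middle bin
      center <- as.integer(ceiling(n_bins / 2))
      edges <- lo + seq(-center, n_bins - center, by = 1)
      idx <- rep(center, length(v))
    }
    counts <- tabulate(idx, nbins = n_bins)
    hist[p, ] <- if (hist_mode == "frequency") counts / support else counts
    breaks[p, ] <- edges
  }
  list(mean = stats::setNames(means, pn), hist = hist, breaks = breaks,
       support = support)
}

#' @export
print.qap_lookup <- function(x, ...) {
  cat("<qap_lookup> ", length(x$pair_order), " atom pairs (max distance ",
      x$max_distance, ", ", x$n_bins, " bins, ", x$hist_mode, " histograms)\n",
      sep = "")
  cat("  source: ", x$provenance$source, " (",
      x$provenance$n_contributing, " contributing record(s))\n", sep = "")
  supp <- vapply(x$entries, `[[`, numeric(1), "support")
  cat("  support: min ", min(supp), ", median ", stats::median(supp),
      ", max ", max(supp), "\n", sep = "")
  invisible(x)
}

#' @export
summary.qap_lookup <- function(object, ...) {
  supp <- vapply(object$entries, `[[`, numeric(1), "support")
  d <- parse_pair_string(object$pair_order)$distance
  out <- list(n_pairs = length(object$pair_order),
              support = summary(supp),
              pairs_by_distance = table(d))
  class(out) <- "summary.qap_lookup"
  out
}

#' @export
print.summary.qap_lookup <- function(x, ...) {
  cat("Atom pairs:", x$n_pairs, "\n")
  cat("Pairs by distance:\n"); print(x$pairs_by_distance)
  cat("Support distribution:\n"); print(x$support)
  invisible(x)
}

# ---- serialization ----------------------------------------------------------

QAP_SCHEMA_VERSION <- "1.0"

#' Save / load a lookup as JSON
#'
#' The lookup is serialized as a single JSON document (schema version,
#' provenance, entries keyed by the canonical pair code). Numeric values are
#' written at full precision so that a load of a save reproduces the lookup
#' exactly, including pair order and bin edges.
#'
#' @param lookup a `qap_lookup`.
#' @param path file path.
#' @return `save_lookup` returns `path` invisibly; `load_lookup` returns the
#'   `qap_lookup`.
#' @export
save_lookup <- function(lookup, path) {
  stopifnot(inherits(lookup, "qap_lookup"))
  doc <- list(
    schema_version = QAP_SCHEMA_VERSION,
    provenance = lookup$provenance,
    property_names = lookup$property_names,
    max_distance = lookup$max_distance,
    n_bins = lookup$n_bins,
    hist_mode = lookup$hist_mode,
    pair_order = lookup$pair_order,
    entries = lapply(lookup$entries, function(e) {
      list(mean = unname(e$mean),
           hist = lapply(seq_len(nrow(e$hist)), function(i) unname(e$hist[i, ])),
           breaks = lapply(seq_len(nrow(e$breaks)), function(i) unname(e$breaks[i, ])),
           support = e$support)
    }))
  # I(17) significant digits: lossless round trip for IEEE doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
  invisible(path)
}

#' @rdname save_lookup
#' @export
load_lookup <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot parse lookup file ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (is.null(doc$schema_version) || !identical(doc$schema_version,
                                                QAP_SCHEMA_VERSION)) {
    stop("lookup schema version mismatch: found ",
         if (is.null(doc$schema_version)) "<none>" else doc$schema_version,
         ", expected ", QAP_SCHEMA_VERSION, call. = FALSE)
  }
  pn <- unlist(doc$property_names)
  n_bins <- doc$n_bins
  entries <- lapply(doc$entries, function(e) {
    # whole-valued rows parse as integer; lookups always hold doubles
    hist <- do.call(rbind, lapply(e$hist, function(v) as.numeric(unlist(v))))
    breaks <- do.call(rbind, lapply(e$breaks,
                                    function(v) as.numeric(unlist(v))))
    dimnames(hist) <- list(pn, paste0("bin", seq_len(n_bins)))
    dimnames(breaks) <- list(pn, NULL)
    list(mean = stats::setNames(as.numeric(unlist(e$mean)), pn), hist = hist,
         breaks = breaks, support = as.integer(e$support))
  })
  structure(
    list(entries = entries, pair_order = unlist(doc$pair_order),
         property_names = pn, max_distance = as.integer(doc$max_distance),
         n_bins = as.integer(n_bins), hist_mode = doc$hist_mode,
         provenance = doc$provenance),
    class = "qap_lookup")
}
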