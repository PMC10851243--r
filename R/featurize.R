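#' Applicability-domain test for one molecule
#'
#' A molecule lies in the applicability domain of a lookup when it parses,
#' all its heavy atoms are drawn from C/N/O/F/S/Cl/Br, it has at least one
#' atom pair within the lookup's distance limit, and every one of its pair
#' codes exists in the lookup. The restriction mirrors the element coverage of
#' the reference database the lookup was built from: a pair never seen there
#' has no quantum aggregate, so the molecule cannot be featurized.
#'
#' @inheritParams atom_code
#' @param lookup a `qap_lookup`.
#' @return Logical scalar; when `FALSE`, the attribute `"reason"` is one of
#'   `"parse_error"`, `"forbidden_element"`, `"no_pairs"`, `"unknown_pair"`.
#' @export
in_domain <- function(molecule, lookup) {
  stopifnot(inherits(lookup, "qap_lookup"))
  mol <- tryCatch(as_qap_mol(molecule), error = function(e) NULL)
  if (is.null(mol)) {
    return(structure(FALSE, reason = "parse_error"))
  }
  heavy_elems <- unique(mol$elements[!mol$is_h])
  if (!all(heavy_elems %in% QAP_ELEMENTS)) {
    return(structure(FALSE, reason = "forbidden_element"))
  }
  pairs <- suppressWarnings(enumerate_pairs(mol, lookup$max_distance))
  if (length(pairs) == 0L) {
    return(structure(FALSE, reason = "no_pairs"))
  }
  unknown <- !(names(pairs) %in% lookup$pair_order)
  if (any(unknown)) {
    return(structure(FALSE, reason = "unknown_pair"))
  }
  TRUE
}

#' Filter a molecule set to the applicability domain
#'
#' @param molecules character vector of SMILES (optionally named with
#'   identifiers).
#' @param lookup a `qap_lookup`.
#' @return List with `molecules` (the in-domain subset, input order
#'   preserved) and `report`, a `qap_domain_report` with counts and the
#'   per-molecule rejection reasons.
#' @export
filter_domain <- function(molecules, lookup) {
  stopifnot(is.character(molecules))
  ids <- names(molecules)
  if (is.null(ids)) ids <- paste0("mol", seq_along(molecules))
  ok <- logical(length(molecules))
  reasons <- character(length(molecules))
  for (k in seq_along(molecules)) {
    v <- in_domain(molecules[[k]], lookup)
    ok[k] <- isTRUE(as.logical(v))
    reasons[k] <- if (ok[k]) NA_character_ else attr(v, "reason")
  }
  rejected <- data.frame(id = ids[!ok], smiles = unname(molecules[!ok]),
                         reason = reasons[!ok], stringsAsFactors = FALSE)
  report <- structure(
    list(n_input = length(molecules), n_in_domain = sum(ok),
         rejected = rejected),
    class = "qap_domain_report")
  list(molecules = molecules[ok], report = report)
}

#' @export
print.qap_domain_report <- function(x, ...) {
  cat("<domain report> ", x$n_in_domain, " of ", x$n_input,
      " molecule(s) in domain\n", sep = "")
  if (nrow(x$rejected) > 0L) {
    cat("Rejections by reason:\n")
    print(table(x$rejected$reason))
  }
  invisible(x)
}

.require_in_domain <- function(mol, lookup) {
  v <- in_domain(mol, lookup)
  if (!isTRUE(as.logical(v))) {
    stop("molecule is outside the applicability domain (",
         attr(v, "reason"), "); run filter_domain() first", call. = FALSE)
  }
  invisible(TRUE)
}

#' sumQAP: summed quantum properties (11 descriptors)
#'
#' Sums the lookup's mean property vectors over the molecule's atom pairs.
#' With `count_weighted = TRUE` (default) each distinct pair contributes its
#' mean vector multiplied by its occurrence count, which makes the descriptor
#' additive over disconnected fragments.
#'
#' @inheritParams in_domain
#' @param count_weighted multiply each pair's contribution by its occurrence
#'   count (default `TRUE`).
#' @return Named numeric vector of length 11.
#' @export
featurize_sum <- function(molecule, lookup, count_weighted = TRUE) {
  mol <- as_qap_mol(molecule)
  .require_in_domain(mol, lookup)
  pairs <- enumerate_pairs(mol, lookup$max_distance)
  w <- if (count_weighted) as.numeric(pairs) else rep(1, length(pairs))
  out <- stats::setNames(numeric(11L), lookup$property_names)
  for (p in seq_along(pairs)) {
    out <- out + w[p] * lookup$entries[[names(pairs)[p]]]$mean
  }
  out
}

#' hQAP: summed per-pair histograms (110 descriptors)
#'
#' Sums the lookup's per-pair property histograms over the molecule's atom
#' pairs, concatenated property-by-property (11 properties x 10 bins = 110
#' values with the default binning).
#'
#' @inheritParams featurize_sum
#' @return Named numeric vector of length `11 * n_bins`.
#' @export
featurize_hist <- function(molecule, lookup, count_weighted = TRUE) {
  mol <- as_qap_mol(molecule)
  .require_in_domain(mol, lookup)
  pairs <- enumerate_pairs(mol, lookup$max_distance)
  w <- if (count_weighted) as.numeric(pairs) else rep(1, length(pairs))
  acc <- matrix(0, nrow = 11L, ncol = lookup$n_bins)
  for (p in seq_along(pairs)) {
    acc <- acc + w[p] * lookup$entries[[names(pairs)[p]]]$hist
  }
  out <- as.numeric(t(acc))  # property-major: prop1 bin1..binB, prop2 ...
  names(out) <- as.vector(vapply(lookup$property_names, function(pn) {
    paste0(pn, "|bin", seq_len(lookup$n_bins))
  }, character(lookup$n_bins)))
  out
}

#' spQAP: sparse per-pair property vector
#'
#' Lays out one 11-value block per pair in the lookup's canonical pair order.
#' The block for a pair present in the molecule holds that pair's mean
#' property vector (presence-gated by default; multiplied by the occurrence
#' count when `count_weighted = TRUE`); absent pairs contribute zero blocks.
#' With a 1089-pair lookup this yields 11,979 values.
#'
#' @inheritParams featurize_sum
#' @param count_weighted multiply blocks by occurrence counts (default
#'   `FALSE`: presence only).
#' @return Named numeric vector of length `11 * length(lookup$pair_order)`.
#' @export
featurize_sparse <- function(molecule, lookup, count_weighted = FALSE) {
  mol <- as_qap_mol(molecule)
  .require_in_domain(mol, lookup)
  pairs <- enumerate_pairs(mol, lookup$max_distance)
  npair <- length(lookup$pair_order)
  out <- numeric(11L * npair)
  pos <- match(names(pairs), lookup$pair_order)
  w <- if (count_weighted) as.numeric(pairs) else rep(1, length(pairs))
  for (p in seq_along(pairs)) {
    block <- (pos[p] - 1L) * 11L + seq_len(11L)
    out[block] <- w[p] * lookup$entries[[names(pairs)[p]]]$mean
  }
  names(out) <- as.vector(vapply(lookup$pair_order, function(ps) {
    paste0("qap|", ps, "|", lookup$property_names)
  }, character(11L)))
  out
}

#' Featurize a molecule set into a descriptor matrix
#'
#' @param molecules character vector of SMILES, optionally named with
#'   identifiers; all must be in-domain (see [filter_domain()]).
#' @param lookup a `qap_lookup`.
#' @param method one of `"sum"`, `"hist"`, `"sparse"`.
#' @param count_weighted passed to the featurizer; `NULL` (default) uses each
#'   method's own default (`TRUE` for sum/hist, `FALSE` for sparse).
#' @return Numeric matrix, one row per molecule (rownames are identifiers),
#'   stable descriptor names as colnames.
#' @export
featurize_matrix <- function(molecules, lookup,
                             method = c("sum", "hist", "sparse"),
                             count_weighted = NULL) {
  method <- match.arg(method)
  stopifnot(is.character(molecules), length(molecules) >= 1L)
  ids <- names(molecules)
  if (is.null(ids)) ids <- paste0("mol", seq_along(molecules))
  fn <- switch(method, sum = featurize_sum, hist = featurize_hist,
               sparse = featurize_sparse)
  default_cw <- switch(method, sum = TRUE, hist = TRUE, sparse = FALSE)
  cw <- if (is.null(count_weighted)) default_cw else count_weighted
  rows <- vector("list", length(molecules))
  for (k in seq_along(molecules)) {
    rows[[k]] <- tryCatch(
      fn(molecules[[k]], lookup, count_weighted = cw),
      error = function(e) {
        stop("featurize_matrix: row '", ids[k], "' (", molecules[[k]], "): ",
             conditionMessage(e), call. = FALSE)
      })
  }
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  if (method == "sum") {
    colnames(m) <- paste0("qap_sum|", lookup$property_names)
  } else if (method == "hist") {
    colnames(m) <- paste0("qap_hist|", colnames(m))
  }
  m
}

#' Drop low-variance descriptors
#'
#' Removes every column whose population standard deviation (denominator n)
#' falls strictly below `min_std`, computed once on the full matrix. Column
#' order is preserved.
#'
#' @param m numeric feature matrix.
#' @param min_std dismissal threshold (default 0.05); columns with standard
#'   deviation exactly equal to `min_std` are retained.
#' @return The filtered matrix; the `"n_dropped"` attribute counts removed
#'   columns.
#' @export
variance_filter <- function(m, min_std = 0.05) {
  stopifnot(is.matrix(m), nrow(m) >= 1L)
  mu <- colMeans(m)
  sd_pop <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  keep <- sd_pop >= min_std
  if (!any(keep)) {
    stop("variance_filter: all ", ncol(m),
         " feature(s) fall below min_std = ", min_std, call. = FALSE)
  }
  out <- m[, keep, drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}
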