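#' Specification for the synthetic reference database
#'
#' Describes a seeded generator that emulates the schema of a small-organic
#' quantum-property database: valence-legal molecules over a chosen element
#' pool (acyclic plus optionally one simple ring, single bonds), each carrying
#' 11 correlated continuous properties. Properties are additive over atom
#' pairs by construction -- each pair code has an 11-value latent weight and a
#' molecule's property is the occurrence-weighted sum of its pairs' weights
#' plus Gaussian noise -- so the sumQAP descriptor is the correct sufficient
#' feature and recovery by the benchmark is a provable property.
#'
#' @param n_molecules number of molecules to generate.
#' @param seed integer seed; every downstream draw derives from it.
#' @param element_pool subset of C/N/O/F/S/Cl/Br (default all seven).
#' @param max_heavy_atoms largest molecule size (default 9 heavy atoms, the
#'   usual small-organic reference range).
#' @param property_noise_sd Gaussian noise added to each property (default
#'   0.1).
#' @param latent_weights optional matrix (pair codes x 11) of latent pair
#'   weights; drawn from seeded standard normals when `NULL`.
#' @param ring_prob probability that a molecule receives one ring closure
#'   (default 0.3).
#' @return A `qap_synth_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 100L, seed = 1L,
                           element_pool = c("C", "N", "O", "F", "S", "Cl", "Br"),
                           max_heavy_atoms = 9L, property_noise_sd = 0.1,
                           latent_weights = NULL, ring_prob = 0.3) {
  stopifnot(n_molecules >= 1L, length(element_pool) >= 1L,
            all(element_pool %in% QAP_ELEMENTS), max_heavy_atoms >= 1L,
            property_noise_sd >= 0, ring_prob >= 0, ring_prob <= 1)
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed), element_pool = element_pool,
                 max_heavy_atoms = as.integer(max_heavy_atoms),
                 property_noise_sd = property_noise_sd,
                 latent_weights = latent_weights, ring_prob = ring_prob),
            class = "qap_synth_spec")
}

# Standard valences of the neutral elements in the pool.
.VALENCE <- c(C = 4L, N = 3L, O = 2L, F = 1L, S = 2L, Cl = 1L, Br = 1L)

# Element sampling weights: carbon-rich organic composition; monovalent
# halogens kept rare so chains can grow.
.ELEMENT_WEIGHT <- c(C = 0.60, N = 0.14, O = 0.14, F = 0.04, S = 0.04,
                     Cl = 0.02, Br = 0.02)

#' Sample valence-legal molecules as SMILES
#'
#' Grows each molecule by seeded random attachment: a first atom, then
#' single-bonded attachment of new atoms to open-valence sites, then (with
#' probability `ring_prob`) one ring closure between two non-adjacent atoms
#' 3-5 bonds apart with free valence. All outputs reparse and survive
#' sanitization; generation is deterministic given the spec seed.
#'
#' @param spec a [synthetic_spec()].
#' @return Character vector of `n_molecules` SMILES strings.
#' @export
sample_molecules <- function(spec) {
  stopifnot(inherits(spec, "qap_synth_spec"))
  rs <- .seeded_rng(spec$seed)
  w <- .ELEMENT_WEIGHT[spec$element_pool]
  w <- w / sum(w)
  out <- character(spec$n_molecules)
  for (m in seq_len(spec$n_molecules)) {
    out[m] <- .grow_molecule(rs, spec$element_pool, w,
                             spec$max_heavy_atoms, spec$ring_prob)
  }
  out
}

.grow_molecule <- function(rs, pool, w, max_heavy, ring_prob) {
  n_target <- if (max_heavy <= 2L) max_heavy else
    rs$choice(2:max_heavy, 1L)
  elements <- character(0)
  edges <- matrix(integer(0), ncol = 2L)
  free <- integer(0)  # remaining valence per atom
  # first atom must be able to grow when n_target > 1
  repeat {
    e1 <- rs$choice(pool, 1L, prob = w)
    if (n_target == 1L || .VALENCE[[e1]] >= 1L) break
  }
  elements <- e1
  free <- .VALENCE[[e1]]
  while (length(elements) < n_target) {
    open <- which(free > 0L)
    if (length(open) == 0L) break
    at <- if (length(open) == 1L) open else open[rs$sample_int(length(open))]
    el <- rs$choice(pool, 1L, prob = w)
    elements <- c(elements, el)
    k <- length(elements)
    edges <- rbind(edges, c(at, k))
    free[at] <- free[at] - 1L
    free <- c(free, .VALENCE[[el]] - 1L)
  }
  ring_edge <- NULL
  if (length(elements) >= 5L && rs$unif(1) < ring_prob) {
    d <- .tree_dists(length(elements), edges)
    cand <- which(d >= 3 & d <= 5 &
                  outer(free > 0L, free > 0L, `&`) &
                  upper.tri(d), arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      pick <- cand[rs$sample_int(nrow(cand)), ]
      ring_edge <- as.integer(pick)
      free[pick[1]] <- free[pick[1]] - 1L
      free[pick[2]] <- free[pick[2]] - 1L
    }
  }
  .write_smiles(elements, edges, ring_edge)
}

# BFS all-pairs distances on the growth tree.
.tree_dists <- function(n, edges) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    q <- s
    while (length(q) > 0L) {
      v <- q[1L]; q <- q[-1L]
      for (u in adj[[v]]) if (!is.finite(d[s, u])) {
        d[s, u] <- d[s, v] + 1
        q <- c(q, u)
      }
    }
  }
  d
}

# DFS SMILES writer for a tree plus at most one ring-closure edge (all
# single bonds). Two-letter halogens are valid organic-subset symbols.
.write_smiles <- function(elements, edges, ring_edge = NULL) {
  n <- length(elements)
  adj <- vector("list", n)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }
  ring_at <- if (is.null(ring_edge)) integer(0) else ring_edge
  emit <- function(v, parent) {
    s <- elements[v]
    if (v %in% ring_at) s <- paste0(s, "1")
    kids <- setdiff(adj[[v]], parent)
    parts <- lapply(kids, emit, parent = v)
    if (length(parts) == 0L) return(s)
    last <- parts[[length(parts)]]
    inner <- if (length(parts) > 1L)
      paste0("(", unlist(parts[-length(parts)]), ")", collapse = "") else ""
    paste0(s, inner, last)
  }
  emit(1L, 0L)
}

#' Generate a synthetic quantum-property database
#'
#' Samples molecules per the spec and assigns each of the 11 properties as the
#' occurrence-weighted sum of its atom pairs' latent weights plus Gaussian
#' noise. Latent weights are drawn once from seeded standard normals over the
#' pair universe of the sampled molecules (unless supplied in the spec).
#'
#' @param spec a [synthetic_spec()].
#' @param max_distance pair distance limit used for the additive property
#'   model (default 4).
#' @return A `qap_qdb` data.frame (`smiles` + 11 properties) with the latent
#'   weight matrix in the `"latent_weights"` attribute.
#' @export
generate_quantum_db <- function(spec, max_distance = 4L) {
  stopifnot(inherits(spec, "qap_synth_spec"))
  smiles <- sample_molecules(spec)
  pairs_by_mol <- lapply(parse_smiles(smiles), function(m) {
    suppressWarnings(enumerate_pairs(m, max_distance))
  })
  universe <- sort_pair_strings(unique(unlist(lapply(pairs_by_mol, names))))
  pn <- qap_property_names()
  lw <- spec$latent_weights
  rs <- .seeded_rng(spec$seed + 104729L)  # decoupled from molecule sampling
  if (is.null(lw)) {
    lw <- matrix(rs$norm(length(universe) * 11L), nrow = length(universe),
                 dimnames = list(universe, pn))
  } else {
    stopifnot(is.matrix(lw), ncol(lw) == 11L)
    missing_pairs <- setdiff(universe, rownames(lw))
    if (length(missing_pairs) > 0L) {
      stop("latent_weights lacks rows for ", length(missing_pairs),
           " observed pair code(s)", call. = FALSE)
    }
  }
  props <- matrix(0, nrow = length(smiles), ncol = 11L,
                  dimnames = list(NULL, pn))
  for (k in seq_along(smiles)) {
    pr <- pairs_by_mol[[k]]
    base <- if (length(pr) == 0L) numeric(11L) else
      as.numeric(crossprod(lw[names(pr), , drop = FALSE], as.numeric(pr)))
    noise <- if (spec$property_noise_sd > 0)
      rs$norm(11L, sd = spec$property_noise_sd) else numeric(11L)
    props[k, ] <- base + noise
  }
  db <- data.frame(smiles = smiles, props, stringsAsFactors = FALSE)
  attr(db, "latent_weights") <- lw
  class(db) <- c("qap_qdb", "data.frame")
  db
}

#' Generate a benchmark task with known ground truth
#'
#' Builds a lookup from the records, computes sumQAP features, and constructs
#' a target that is a known sparse linear combination of those features plus
#' Gaussian noise: `n_active` of the 11 property aggregates (seeded draw)
#' carry standard-normal coefficients and the rest are inert, mirroring how
#' measured endpoints track a small number of underlying quantum properties.
#' The signal is standardized to unit variance, so `noise_sd` is the
#' reciprocal signal-to-noise ratio (default 0.2, SNR 5). For classification,
#' the continuous score is thresholded at the quantile that yields the
#' requested minority:majority ratio.
#'
#' @param records a `qap_qdb`.
#' @param task `"regression"` or `"classification"`.
#' @param seed integer seed for coefficients, noise and thresholding.
#' @param noise_sd noise standard deviation relative to unit signal sd.
#' @param imbalance_ratio minority/majority ratio for classification (e.g.
#'   `1/12`); achieved minority count must land within 10% of the request.
#' @param n_active number of property aggregates with nonzero coefficients
#'   (default 3).
#' @return List: `molecules` (SMILES), `targets`, `lookup` (the internally
#'   built `qap_lookup`), `features` (the sumQAP matrix), and `beta` (true
#'   coefficients).
#' @export
generate_task <- function(records, task = c("regression", "classification"),
                          seed = 1L, noise_sd = 0.2, imbalance_ratio = 1,
                          n_active = 3L) {
  task <- match.arg(task)
  stopifnot(is.data.frame(records), nrow(records) >= 1L, noise_sd >= 0)
  lookup <- build_lookup(records, source = "synthetic")
  kept <- filter_domain(stats::setNames(records$smiles,
                                        paste0("mol", seq_len(nrow(records)))),
                        lookup)
  x <- featurize_matrix(kept$molecules, lookup, method = "sum")
  sds <- apply(x, 2L, stats::sd)
  xs <- scale(x[, sds > 0, drop = FALSE])
  rs <- .seeded_rng(seed + 15485863L)
  n_active <- min(as.integer(n_active), ncol(xs))
  active <- sort(rs$choice(ncol(xs), n_active))
  beta <- numeric(ncol(xs))
  beta[active] <- rs$norm(n_active)
  raw <- as.numeric(xs %*% beta)
  signal <- raw / stats::sd(raw)
  noise <- if (noise_sd > 0) rs$norm(length(signal), sd = noise_sd)
           else numeric(length(signal))
  score <- signal + noise
  if (task == "regression") {
    targets <- score
  } else {
    min_frac <- imbalance_ratio / (1 + imbalance_ratio)
    thr <- stats::quantile(score, probs = 1 - min_frac, names = FALSE)
    targets <- ifelse(score > thr, "active", "inactive")
    n_min <- sum(targets == "active")
    want <- min_frac * length(score)
    if (abs(n_min - want) > 0.1 * want + 1) {
      stop("requested imbalance unattainable: got ", n_min,
           " minority of ", length(score), call. = FALSE)
    }
  }
  list(molecules = kept$molecules, targets = targets, lookup = lookup,
       features = x, beta = stats::setNames(beta, colnames(xs)))
}
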