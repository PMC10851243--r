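# Independent oracles used across the suite. These deliberately re-derive
# atom codes, shortest paths and pair multisets with naive per-atom loops so
# they share no code path with the package internals they check.

# Adjacency list over all atoms of a qap_mol.
oracle_adjacency <- function(mol) {
  adj <- vector("list", mol$n_atoms)
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b[r, 1]; j <- b[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Single-source BFS distance (in bonds) from atom s, over heavy atoms only.
oracle_bfs_dist <- function(mol, s) {
  adj <- oracle_adjacency(mol)
  d <- rep(Inf, mol$n_atoms)
  d[s] <- 0
  queue <- s
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    for (u in adj[[v]]) {
      if (mol$is_h[u]) next
      if (!is.finite(d[u])) {
        d[u] <- d[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  d
}

# Atom code of one atom computed by direct loops over the bond table.
oracle_atom_code <- function(mol, i) {
  stopifnot(!mol$is_h[i])
  deg <- 0L; pi_e <- 0L
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    if (b[r, 1] == i || b[r, 2] == i) {
      other <- if (b[r, 1] == i) b[r, 2] else b[r, 1]
      if (!mol$is_h[other]) deg <- deg + 1L
      if (b[r, 3] > 1L) pi_e <- pi_e + (b[r, 3] - 1L)
    }
  }
  c(element = mol$elements[i], degree = deg, pi = pi_e)
}

# Brute-force pair multiset: double loop over heavy atom index pairs with a
# fresh BFS per source atom; codes ordered by simple string comparison of the
# dotted triple (single-digit degrees make this equivalent to tuple order).
oracle_enumerate_pairs <- function(mol, max_distance = 4L) {
  heavy <- which(!mol$is_h)
  out <- character(0)
  for (a in heavy) {
    d <- oracle_bfs_dist(mol, a)
    for (b in heavy) {
      if (b <= a) next
      if (!is.finite(d[b]) || d[b] < 1 || d[b] > max_distance) next
      ca <- oracle_atom_code(mol, a)
      cb <- oracle_atom_code(mol, b)
      sa <- paste(ca, collapse = ".")
      sb <- paste(cb, collapse = ".")
      lo <- min(sa, sb); hi <- max(sa, sb)
      out <- c(out, paste0(lo, "-", hi, "@", d[b]))
    }
  }
  if (length(out) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(out)
  setNames(as.integer(tab), names(tab))
}

# Compare a qap_pairs multiset with an oracle multiset (order-free).
expect_same_multiset <- function(pairs, oracle) {
  expect_setequal(names(pairs), names(oracle))
  expect_identical(as.integer(pairs[names(oracle)]), unname(oracle))
}

# Naive two-pass lookup means: for each pair code, collect occurrence-divided
# contributions per molecule and average them.
oracle_lookup_means <- function(db, max_distance = 4L) {
  acc <- list()
  for (k in seq_len(nrow(db))) {
    mol <- parse_smiles(db$smiles[k])[[1L]]
    pr <- oracle_enumerate_pairs(mol, max_distance)
    props <- as.numeric(db[k, qap_property_names()])
    for (p in names(pr)) {
      acc[[p]] <- c(acc[[p]], list(props / pr[[p]]))
    }
  }
  lapply(acc, function(rows) colMeans(do.call(rbind, rows)))
}
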