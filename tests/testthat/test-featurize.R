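test_that("in_domain reports the first failing reason", {
  lk <- toy_lookup()
  expect_true(in_domain("CCC", lk))         # built from this record
  v1 <- in_domain("CP", lk)                  # phosphorus
  expect_false(as.logical(v1))
  expect_identical(attr(v1, "reason"), "forbidden_element")
  v2 <- in_domain("C", lk)                   # single heavy atom
  expect_identical(attr(v2, "reason"), "no_pairs")
  v3 <- in_domain("C1CC", lk)                # OpenBabel rejects this string
  expect_identical(attr(v3, "reason"), "parse_error")
  v4 <- in_domain("CCO", lk)                 # oxygen pair never seen in toy db
  expect_identical(attr(v4, "reason"), "unknown_pair")
})

test_that("filter_domain preserves order and accounts for every input", {
  lk <- toy_lookup()
  mols <- c(a = "CC", b = "CCO", c = "CCC", d = "C1CC", e = "CCCC")
  res <- filter_domain(mols, lk)
  expect_identical(res$molecules, mols[c("a", "c", "e")])
  rep <- res$report
  expect_identical(rep$n_input, 5L)
  expect_identical(rep$n_in_domain, 3L)
  expect_identical(rep$n_input, rep$n_in_domain + nrow(rep$rejected))
  expect_identical(rep$rejected$id, c("b", "d"))
  expect_identical(rep$rejected$reason, c("unknown_pair", "parse_error"))
  # empty input and all-in-domain identity
  res0 <- filter_domain(character(0), lk)
  expect_identical(res0$report$n_input, 0L)
  resid <- filter_domain(c(x = "CC", y = "CCC"), lk)
  expect_identical(resid$molecules, c(x = "CC", y = "CCC"))
})

test_that("sumQAP sums mean property vectors with occurrence weights", {
  lk <- toy_lookup()
  # ethane: one pair, count 1 -> identity with that pair's means
  v <- featurize_sum("CC", lk)
  expect_identical(unname(v), unname(lk$entries[["C.1.0-C.1.0@1"]]$mean))
  expect_length(v, 11L)
  # propane: pair counts 2 and 1 -> 2*v1 + v2
  v2 <- featurize_sum("CCC", lk)
  hand <- 2 * lk$entries[["C.1.0-C.2.0@1"]]$mean +
    lk$entries[["C.1.0-C.1.0@2"]]$mean
  expect_equal(v2, hand, tolerance = 1e-15)
  # unweighted switch
  v3 <- featurize_sum("CCC", lk, count_weighted = FALSE)
  hand3 <- lk$entries[["C.1.0-C.2.0@1"]]$mean +
    lk$entries[["C.1.0-C.1.0@2"]]$mean
  expect_equal(v3, hand3, tolerance = 1e-15)
  expect_error(featurize_sum("CCO", lk), "applicability domain")
})

test_that("hQAP concatenates 11 properties x 10 bins and sums pair histograms", {
  lk <- toy_lookup()
  v <- featurize_hist("CC", lk)
  expect_length(v, 110L)
  e <- lk$entries[["C.1.0-C.1.0@1"]]
  expect_identical(unname(v), as.numeric(t(e$hist)))
  # two-pair molecule: componentwise sum with counts
  v2 <- featurize_hist("CCC", lk)
  hand <- 2 * lk$entries[["C.1.0-C.2.0@1"]]$hist +
    lk$entries[["C.1.0-C.1.0@2"]]$hist
  expect_equal(unname(v2), as.numeric(t(hand)), tolerance = 1e-15)
})

test_that("spQAP lays out 11-value blocks in canonical pair order", {
  lk <- toy_lookup()
  v <- featurize_sparse("CC", lk)
  expect_length(v, 11L * length(lk$pair_order))
  pos <- match("C.1.0-C.1.0@1", lk$pair_order)
  block <- v[(pos - 1L) * 11L + 1:11]
  expect_identical(unname(block), unname(lk$entries[["C.1.0-C.1.0@1"]]$mean))
  expect_identical(sum(v != 0), sum(lk$entries[["C.1.0-C.1.0@1"]]$mean != 0))
  # presence-gated by default: propane's double pair not multiplied
  v2 <- featurize_sparse("CCC", lk)
  pos2 <- match("C.1.0-C.2.0@1", lk$pair_order)
  expect_identical(unname(v2[(pos2 - 1L) * 11L + 1:11]),
                   unname(lk$entries[["C.1.0-C.2.0@1"]]$mean))
  # count-weighted switch doubles that block
  v3 <- featurize_sparse("CCC", lk, count_weighted = TRUE)
  expect_equal(unname(v3[(pos2 - 1L) * 11L + 1:11]),
               unname(2 * lk$entries[["C.1.0-C.2.0@1"]]$mean),
               tolerance = 1e-15)
})

test_that("summing spQAP blocks with count weights recovers sumQAP", {
  db <- shared_db()
  lk <- build_lookup(db)
  kept <- filter_domain(db$smiles, lk)$molecules
  for (smi in kept[1:10]) {
    sp <- featurize_sparse(smi, lk, count_weighted = TRUE)
    blocks <- matrix(sp, nrow = 11L)
    expect_equal(unname(rowSums(blocks)),
                 unname(featurize_sum(smi, lk)), tolerance = 1e-12)
  }
})

test_that("featurizers are invariant to SMILES spelling", {
  lk <- build_lookup(shared_db())
  pairs_of_spellings <- list(c("CCCC", "C(CC)C"),
                             c("OCC", "C(O)C"),
                             c("CCOC", "O(C)CC"))
  for (sp in pairs_of_spellings) {
    if (!as.logical(in_domain(sp[1], lk))) next
    expect_identical(featurize_sum(sp[1], lk), featurize_sum(sp[2], lk))
    expect_identical(featurize_hist(sp[1], lk), featurize_hist(sp[2], lk))
    expect_identical(featurize_sparse(sp[1], lk), featurize_sparse(sp[2], lk))
  }
})

test_that("sumQAP is additive over disconnected fragments", {
  lk <- build_lookup(shared_db())
  frags <- c("CCO", "CCC")
  if (all(vapply(c(frags, paste(frags, collapse = ".")), function(s)
    as.logical(in_domain(s, lk)), logical(1)))) {
    both <- suppressWarnings(
      featurize_sum(paste(frags, collapse = "."), lk))
    expect_equal(both, featurize_sum(frags[1], lk) +
                   featurize_sum(frags[2], lk), tolerance = 1e-12)
  }
})

test_that("featurize_matrix aligns rows, keeps stable names, flags bad rows", {
  lk <- toy_lookup()
  mols <- c(m1 = "CC", m2 = "CCC", m3 = "CCCC")
  x <- featurize_matrix(mols, lk, "sum")
  expect_identical(dim(x), c(3L, 11L))
  expect_identical(rownames(x), c("m1", "m2", "m3"))
  x2 <- featurize_matrix(mols, lk, "sum")
  expect_identical(x, x2)
  xh <- featurize_matrix(mols, lk, "hist")
  expect_identical(ncol(xh), 110L)
  xs <- featurize_matrix(mols, lk, "sparse")
  expect_identical(ncol(xs), 11L * length(lk$pair_order))
  expect_error(featurize_matrix(c(bad = "CCO", m1 = "CC"), lk, "sum"), "bad")
})

test_that("no missing-key event ever follows filter_domain", {
  db <- shared_db()
  lk <- build_lookup(db)
  extra <- c("CCOP", "C[Si](C)C", "C", "CCCCCCCCCCCCC(Br)I")
  kept <- filter_domain(c(db$smiles, extra), lk)
  x <- featurize_matrix(kept$molecules, lk, "sum")
  expect_identical(nrow(x), length(kept$molecules))
  expect_true(all(is.finite(x)))
})

test_that("variance_filter dismisses below-threshold columns, strictly", {
  # column a constant, column b has population sd exactly 0.05, column c wide
  m <- cbind(a = rep(1, 4), b = c(0.95, 1.05, 0.95, 1.05), c = c(0, 1, 2, 3))
  got <- variance_filter(m)
  expect_identical(colnames(got), c("b", "c"))  # sd == min_std retained
  expect_identical(attr(got, "n_dropped"), 1L)
  # population (not sample) statistic: sample sd of b would be ~0.0577
  m2 <- cbind(b = c(0.95, 1.05, 0.95, 1.05))
  expect_identical(colnames(variance_filter(m2, min_std = 0.05)), "b")
  # identity when everything passes
  expect_identical(variance_filter(m[, 2:3]), m[, 2:3],
                   ignore_attr = "n_dropped")
  expect_error(variance_filter(m[, 1, drop = FALSE]), "all 1 feature")
})
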