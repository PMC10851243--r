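# Shared fixtures, built in code.

# Hand-computable reference database: ethane, propane, butane with constant
# property vectors 6, 12 and 24. Every aggregate below is derivable on paper:
#   C.1.0-C.1.0@1 : ethane only, 1 occurrence        -> mean 6,  support 1
#   C.1.0-C.2.0@1 : propane (x2 -> 6), butane (x2 -> 12) -> mean 9, support 2
#   C.1.0-C.1.0@2 : propane only                     -> mean 12, support 1
#   C.2.0-C.2.0@1 : butane only                      -> mean 24, support 1
#   C.1.0-C.2.0@2 : butane, 2 occurrences            -> mean 12, support 1
#   C.1.0-C.1.0@3 : butane only                      -> mean 24, support 1
toy_db <- function() {
  props <- rbind(rep(6, 11), rep(12, 11), rep(24, 11))
  colnames(props) <- qap_property_names()
  db <- data.frame(smiles = c("CC", "CCC", "CCCC"), props,
                   stringsAsFactors = FALSE)
  class(db) <- c("qap_qdb", "data.frame")
  db
}

toy_lookup <- function(...) build_lookup(toy_db(), source = "toy", ...)

# Write a qap_qdb to a CSV the reader accepts.
write_db_csv <- function(db, path = tempfile(fileext = ".csv")) {
  write.csv(as.data.frame(db), path, row.names = FALSE)
  path
}

# Small seeded synthetic database reused by several files (kept modest so the
# suite stays fast).
shared_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_quantum_db(synthetic_spec(n_molecules = 60, seed = 42))
    }
    cache
  }
})
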