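# Independent brute-force oracles used to cross-check the package's
# implementations on small instances.

# Exhaustive enumeration of nonnegative fluxes on a half-integer lattice:
# returns all AcP net outputs of flux vectors consuming exactly 1 source
# with zero net internal species. The linear solver must agree with the
# unique lattice solution.
brute_force_acp <- function(design, max_flux = 3, step = 0.5) {
  S <- stoich_matrix(design)
  src <- design$source
  term <- rownames(S)[apply(S, 1, function(r) all(r >= 0))]
  internal <- setdiff(rownames(S), c(src, term))
  vals <- seq(0, max_flux, by = step)
  grid <- as.matrix(expand.grid(rep(list(vals), ncol(S))))
  net <- grid %*% t(S)  # candidates x species
  ok <- abs(net[, src] + 1) < 1e-9
  if (length(internal) > 0) {
    ok <- ok & apply(abs(net[, internal, drop = FALSE]) < 1e-9, 1, all)
  }
  unique(net[ok, "AcP"])
}

# Naive per-column tally consensus (independent of consensus_of)
naive_consensus <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  out <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j][m[, j] != "-"]
    if (length(col) == 0) { out[j] <- "-"; next }
    best <- NA; best_n <- -1
    for (res in sort(unique(col))) {
      n <- sum(col == res)
      if (n > best_n) { best <- res; best_n <- n }
    }
    out[j] <- best
  }
  paste(out, collapse = "")
}

# Naive exhaustive pairwise scoring of sequences against a consensus
naive_closest <- function(seqs) {
  cons <- strsplit(naive_consensus(seqs), "")[[1]]
  best_i <- NA_integer_; best_n <- -1L
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[[i]], "")[[1]]
    n <- 0L
    for (j in seq_along(s)) {
      if (s[j] != "-" && cons[j] != "-" && s[j] == cons[j]) n <- n + 1L
    }
    if (n > best_n) { best_i <- i; best_n <- n }
  }
  list(index = best_i, matches = best_n)
}

# Sources that the default capability tables can route to acetyl-phosphate
routable_sources <- c("HCHO", "GALD", "DHA", "G3P", "DHAP", "D-ETS", "D-EUS",
                      "L-EUS", "E4P", "Xu5P", "F6P",
                      "methanol", "ethylene_glycol", "ethanolamine",
                      "glycerol", "erythritol")
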