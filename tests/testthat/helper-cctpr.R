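# Shared fixtures built in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Human Hop TPR2a reference motifs (the packaged reference row)
hop_motifs <- function() {
  fix <- load_motif_fixture("arabidopsis")
  fix[fix$protein_name == "HsHop", ]
}

# profiles trained on the packaged tables, computed once per test run
cached_profiles <- local({
  profs <- NULL
  function() {
    if (is.null(profs)) profs <<- default_profiles()
    profs
  }
})

# tpr_domain straight from a fixture protein's printed triplet
domain_for <- function(fixture, protein) {
  cctpr:::fixture_domains(fixture[fixture$protein_name == protein, ])[[1]]
}

# Brute-force 4-taxon oracle: enumerate the three unrooted quartet
# topologies, solve each 6x5 path-length system by least squares, and return
# the topology (as the non-trivial split) whose fit is exact.
quartet_oracle <- function(d) {
  taxa <- rownames(d)
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  y <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  # branch order: e1..e4 pendant edges of taxa 1..4, e5 internal
  topo <- list(c(1, 2), c(1, 3), c(1, 4))  # split partner of taxon 1
  best <- NULL
  for (t in topo) {
    A <- matrix(0, 6, 5)
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      A[k, p] <- 1
      same <- setequal(p, t) || setequal(p, setdiff(1:4, t))
      if (!same) A[k, 5] <- 1
    }
    b <- qr.solve(crossprod(A), crossprod(A, y))
    if (max(abs(A %*% b - y)) < 1e-9 && all(b > -1e-12))
      best <- list(split = sort(taxa[t]), lengths = as.numeric(b))
  }
  best
}

additive_matrix_4 <- function() {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> exact path distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 5; d["A", "C"] <- 7; d["A", "D"] <- 8
  d["B", "C"] <- 8; d["B", "D"] <- 9; d["C", "D"] <- 9
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}
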