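test_that("p-distances from global alignment behave like proportions", {
  expect_equal(pairwise_distance("MEEVDKL", "MEEVDKL"), 0)
  expect_equal(pairwise_distance("AAAA", "AAAT"), 0.25)
  set.seed(5)
  for (i in 1:25) {
    a <- random_protein(sample(30:60, 1))
    b <- random_protein(sample(30:60, 1))
    dab <- pairwise_distance(a, b)
    expect_equal(dab, pairwise_distance(b, a), tolerance = 1e-12)
    expect_gte(dab, 0); expect_lte(dab, 1)
  }
})

test_that("neighbor joining recovers additive trees exactly", {
  # two taxa: a single split edge
  t2 <- neighbor_joining(matrix(c(0, 0.4, 0.4, 0), 2,
                                dimnames = list(c("A", "B"), c("A", "B"))))
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sum(t2$edge.length), 0.4, tolerance = 1e-12)
  expect_equal(ape::cophenetic.phylo(t2)["A", "B"], 0.4, tolerance = 1e-12)

  d <- additive_matrix_4()
  tree <- neighbor_joining(d)
  co <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
  expect_equal(co, d, tolerance = 1e-9)
  # topology agrees with the brute-force quartet oracle
  oracle <- quartet_oracle(d)
  expect_equal(oracle$split, c("A", "B"))
  splits <- cctpr:::tree_bipartitions(tree)
  expect_true(paste(oracle$split, collapse = "|") %in% splits ||
                paste(setdiff(LETTERS[1:4], oracle$split), collapse = "|") %in% splits)

  # larger random additive matrices: path distances reproduced within 1e-9
  set.seed(9)
  for (i in 1:10) {
    rt <- ape::rtree(sample(5:12, 1))
    dm <- ape::cophenetic.phylo(rt)
    nj <- neighbor_joining(dm)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)], dm,
                 tolerance = 1e-9)
    # independent route: ape's own NJ gives the same unrooted topology
    expect_equal(ape::dist.topo(ape::unroot(nj), ape::unroot(ape::nj(dm))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("neighbor joining rejects malformed matrices and is label-invariant", {
  d <- additive_matrix_4()
  bad <- d; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")
  baddiag <- d; diag(baddiag) <- 1
  expect_error(neighbor_joining(baddiag), "diagonal")

  perm <- c("C", "A", "D", "B")
  t1 <- neighbor_joining(d)
  t2 <- neighbor_joining(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(t2)[rownames(d), colnames(d)],
               ape::cophenetic.phylo(t1)[rownames(d), colnames(d)],
               tolerance = 1e-9)
})

test_that("bootstrap supports are seed-reproducible and handle degeneracy", {
  # identical rows: zero distances, supports defined as n_replicates
  aln <- matrix(rep(strsplit("MEEVDKLMEEVDKL", "")[[1]], 4), nrow = 4,
                byrow = TRUE, dimnames = list(paste0("t", 1:4), NULL))
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 1)
  sup <- suppressWarnings(as.integer(tr$node.label[nzchar(tr$node.label)]))
  expect_true(all(sup == 50))

  set.seed(21)
  aln2 <- do.call(rbind, lapply(1:6, function(i)
    sample(AA20, 60, replace = TRUE)))
  rownames(aln2) <- paste0("s", 1:6)
  a <- bootstrap_support(aln2, n_replicates = 30, seed = 7)
  b <- bootstrap_support(aln2, n_replicates = 30, seed = 7)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_error(bootstrap_support(c("AAA", "AAAA")), "equal length")
})

test_that("two clearly separated clades earn near-maximal support", {
  set.seed(13)
  n_inf <- 40
  clade1 <- c("a1", "a2", "a3", "a4"); clade2 <- c("b1", "b2", "b3", "b4")
  inf1 <- sample(AA20, n_inf, replace = TRUE)
  inf2 <- vapply(inf1, function(r) sample(setdiff(AA20, r), 1), character(1))
  mk_row <- function(base) c(base, sample(AA20, 15, replace = TRUE))
  aln <- rbind(do.call(rbind, lapply(clade1, function(i) mk_row(inf1))),
               do.call(rbind, lapply(clade2, function(i) mk_row(inf2))))
  rownames(aln) <- c(clade1, clade2)
  tr <- bootstrap_support(aln, n_replicates = 200, seed = 2)
  splits <- cctpr:::tree_bipartitions(tr)
  key <- paste(sort(clade2), collapse = "|")
  expect_true(key %in% splits)
  node <- as.integer(names(splits)[splits == key]) - length(tr$tip.label)
  expect_gte(min(as.integer(tr$node.label[node])), 190)
})

test_that("the curated-family motif alignment yields a full desk-scale tree", {
  aln <- motif_alignment()
  expect_equal(dim(aln), c(71, 102))  # 36 Arabidopsis + 35 rice proteins
  tree <- fixture_tree()
  expect_equal(length(tree$tip.label), 71)
  expect_true(all(c("AtTTL1", "AtTTL2", "AtTTL3", "AtTTL4",
                    "Os01g11920", "Os05g11990", "Os01g42960") %in%
                    tree$tip.label))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  expect_equal(length(ape::read.tree(f)$tip.label), 71)
})
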