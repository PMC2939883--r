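test_that("substitution classes partition the 20 residues", {
  cls <- substitution_classes()
  all_res <- unlist(cls)
  expect_length(all_res, 20)
  expect_false(anyDuplicated(all_res) > 0)
})

test_that("substitution typing matches the documented conservative/radical calls", {
  expect_equal(substitution_status("K", "K"), "consensus")
  expect_equal(substitution_status("K", "R"), "conservative")
  expect_equal(substitution_status("N", "Q"), "conservative")
  expect_equal(substitution_status("K", "E"), "radical")
  expect_equal(substitution_status("R", "A"), "radical")
  expect_equal(substitution_status("R", "M"), "radical")
  expect_equal(substitution_status("N", "S"), "radical")
  expect_equal(substitution_status("N", "X"), "radical")  # unknown residue
  # vectorized
  expect_equal(substitution_status(c("K", "K"), c("R", "E")),
               c("conservative", "radical"))
})

test_that("clamp evaluation reproduces the reference and published special cases", {
  at <- load_motif_fixture("arabidopsis")

  ev <- evaluate_clamp(domain_for(at, "HsHop"))
  expect_equal(nrow(ev), 5)
  expect_equal(ev$status, rep("consensus", 5))
  expect_equal(attr(ev, "n_match"), 5L)

  # AtHop1 at the printed register: K2 -> R conservative, R6 -> A radical
  ev <- evaluate_clamp(domain_for(at, "AtHop1"))
  expect_equal(ev$status,
               c("consensus", "consensus", "consensus", "conservative", "radical"))
  expect_equal(attr(ev, "n_match"), 4L)

  # AtTPR4: two radical clamp losses, still 3 exact matches
  ev <- evaluate_clamp(domain_for(at, "AtTPR4"))
  expect_equal(ev$status,
               c("consensus", "radical", "consensus", "radical", "consensus"))
  expect_equal(attr(ev, "n_match"), 3L)

  # statuses always partition into the three categories over both tables
  for (fx in c("arabidopsis", "rice")) {
    fix <- load_motif_fixture(fx)
    for (p in unique(fix$protein_name)) {
      ev <- evaluate_clamp(register_rescue(domain_for(fix, p)))
      expect_equal(nrow(ev), 5)
      expect_true(all(ev$status %in% c("consensus", "conservative", "radical")))
    }
  }
})

test_that("protein verdicts select the best domain and apply min_matches", {
  at <- load_motif_fixture("arabidopsis")
  good <- domain_for(at, "HsHop")
  # all five clamp residues mutated to G -> 0 matches -> negative
  mut <- good
  brk <- function(w, pos) { substr(w, pos, pos) <- "G"; w }
  mut$motifs$window[1] <- brk(brk(mut$motifs$window[1], 5), 9)
  mut$motifs$window[2] <- brk(mut$motifs$window[2], 6)
  mut$motifs$window[3] <- brk(brk(mut$motifs$window[3], 2), 6)
  v <- classify_protein(mut)
  expect_false(v$is_cc_tpr)
  expect_equal(v$n_match, 0L)
  # no domains -> negative, not an error
  expect_false(classify_protein(list())$is_cc_tpr)
  # best-domain selection prefers higher clamp conservation
  good$motifs$score <- 1; mut$motifs$score <- 100
  v <- classify_protein(list(mut, good))
  expect_true(v$is_cc_tpr)
  expect_equal(v$n_domains, 2L)
  expect_equal(v$best_domain$motifs$window, good$motifs$window)
})

test_that("both curated families classify fully positive at min_matches = 3", {
  at <- classify_motif_table("arabidopsis")
  os <- classify_motif_table("rice")
  expect_true(all(at$is_cc_tpr))
  expect_true(all(os$is_cc_tpr))
  expect_true(all(at$n_match >= 3))
  expect_true(all(os$n_match >= 3))
})

test_that("architecture census reproduces the published split for the novel set", {
  at <- classify_motif_table("arabidopsis")
  at <- at[grepl("^AT", at$locus_id), ]
  expect_equal(nrow(at), 36)
  meta <- load_protein_metadata()
  cens <- architecture_census(at, meta, novel = TRUE)
  expect_equal(cens, c(single_TPR = 8L, single_TPR_plus_domain = 7L,
                       multi_TPR = 3L, multi_TPR_plus_domain = 6L))
  all36 <- architecture_census(at, meta)
  expect_equal(sum(all36), 36L)
  # empty verdict list -> all zero counts
  none <- at[0, ]
  expect_equal(sum(architecture_census(none, meta)), 0L)
  # unmatched protein: warned and excluded
  odd <- at; odd$locus_id[1] <- "ATXXXXX"
  expect_warning(architecture_census(odd, meta), "no metadata")
})
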