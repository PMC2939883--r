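test_that("an embedded reference motif is found at its exact coordinate", {
  profs <- cached_profiles()
  hop <- hop_motifs()
  motif1 <- hop$motif_seq[hop$motif_index == "I"]
  set.seed(3)
  protein <- paste0(random_protein(10), motif1, random_protein(40))
  hits <- scan_protein(protein, profs)
  h1 <- hits[hits$motif_index == "I", ]
  expect_equal(h1$start, 11)
  expect_equal(h1$window, motif1)
  expect_equal(h1$end - h1$start, 33)
})

test_that("proteins shorter than a motif yield no hits", {
  expect_equal(nrow(scan_protein(random_protein(33), cached_profiles())), 0)
})

test_that("a concatenated fixture triplet produces ordered I, II, III hits", {
  profs <- cached_profiles()
  at <- load_motif_fixture("arabidopsis")
  rof1 <- at[at$protein_name == "AtROF1", ]
  rof1 <- rof1[match(c("I", "II", "III"), rof1$motif_index), ]
  protein <- paste(rof1$motif_seq, collapse = "")
  hits <- scan_protein(protein, profs)
  # tandem TPR motifs are homologous, so a window may also pass a sister
  # profile's threshold; the best hit per index must sit at the true repeat
  best <- vapply(c("I", "II", "III"), function(mi) {
    h <- hits[hits$motif_index == mi, ]
    h$start[which.max(h$score)]
  }, numeric(1))
  expect_equal(unname(best), c(1, 35, 69))
  # and assembly resolves the cross-matches to the single true domain
  doms <- assemble_domains(hits)
  expect_length(doms, 1)
  expect_equal(doms[[1]]$motifs$start, c(1L, 35L, 69L))
  expect_equal(doms[[1]]$motifs$motif_index, c("I", "II", "III"))
  # every emitted window matches the sequence at its coordinates
  expect_equal(hits$window, substring(protein, hits$start, hits$end))
  # scanning is deterministic
  expect_identical(hits, scan_protein(protein, profs))
})

test_that("domain assembly respects the published linker spacings", {
  mk <- function(idx, start, score = 10) data.frame(
    motif_index = idx, start = start, end = start + 33L,
    window = strrep("A", 34), score = score, register_shift = 0L,
    stringsAsFactors = FALSE)
  # Hop spacing: starts 225/259/300 -> linkers 0 and 7
  hop <- rbind(mk("I", 225), mk("II", 259), mk("III", 300))
  doms <- assemble_domains(hop)
  expect_length(doms, 1)
  expect_equal(doms[[1]]$linkers, c(0L, 7L))
  # incomplete triplet -> no domain
  expect_length(assemble_domains(rbind(mk("I", 225), mk("II", 259))), 0)
  # AtTPR5 spacing: starts 84/118/151 -> linker2 = -1 (allowed overlap)
  t5 <- rbind(mk("I", 84), mk("II", 118), mk("III", 151))
  doms <- assemble_domains(t5)
  expect_length(doms, 1)
  expect_equal(doms[[1]]$linkers, c(0L, -1L))
  # linker beyond range breaks the chain
  far <- rbind(mk("I", 1), mk("II", 120), mk("III", 160))
  expect_length(assemble_domains(far), 0)
  # two disjoint triplets -> two domains
  two <- rbind(mk("I", 1), mk("II", 40), mk("III", 80),
               mk("I", 200), mk("II", 240), mk("III", 280))
  expect_length(assemble_domains(two), 2)
})

test_that("register rescue relocates the AtTPR5 motif-II Asn to position 6", {
  at <- load_motif_fixture("arabidopsis")
  d <- register_rescue(domain_for(at, "AtTPR5"))
  m2 <- d$motifs[d$motifs$motif_index == "II", ]
  expect_equal(m2$start, 117)
  expect_equal(m2$register_shift, -1L)
  expect_equal(substr(m2$window, 6, 6), "N")
  expect_equal(substr(m2$window, 1, 1), "X")  # unknown flank in fixture mode
  expect_equal(nchar(m2$window), 34)
})

test_that("register rescue leaves fully consensus domains unchanged", {
  at <- load_motif_fixture("arabidopsis")
  hop <- register_rescue(domain_for(at, "HsHop"))
  expect_equal(hop$motifs$register_shift, c(0L, 0L, 0L))
  expect_equal(hop$motifs$start, c(225L, 259L, 300L))
})

test_that("rescue keeps shift 0 on ties and respects sequence bounds", {
  # consensus at both position 5 and 4: shifting cannot strictly improve
  w1 <- paste0("AAAKKAAANA", strrep("A", 24))  # K at 4 and 5, N at 9... build explicitly
  aa <- rep("A", 34); aa[4] <- "K"; aa[5] <- "K"; aa[9] <- "N"
  w1 <- paste(aa, collapse = "")
  trip <- data.frame(motif_index = c("I", "II", "III"),
                     start = c(1L, 40L, 80L), end = c(34L, 73L, 113L),
                     window = c(w1, strrep("A", 34), strrep("A", 34)),
                     score = 0, register_shift = 0L, stringsAsFactors = FALSE)
  d <- cctpr:::new_tpr_domain(trip, c(5L, 6L))
  r <- register_rescue(d)
  expect_equal(r$motifs$register_shift[1], 0L)
  # motif at sequence start: -1 shift is skipped, not an error
  seqs <- paste0(w1, strrep("A", 80))
  trip2 <- trip; trip2$window <- substring(seqs, trip2$start, trip2$end)
  d2 <- cctpr:::new_tpr_domain(trip2, c(5L, 6L))
  expect_silent(register_rescue(d2, sequence = seqs))
})
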