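#' Screen a set of proteins for CC-TPR candidates
#'
#' End-to-end pipeline: scan each protein for TPR motifs, assemble
#' three-motif domains, apply the register-shift rescue against the full
#' sequence, and issue a protein-level verdict.
#'
#' @param records Named character vector of protein sequences, an
#'   `AAStringSet` (e.g. from [read_fasta()]), or a path to a FASTA file.
#' @param profiles Motif profiles, see [default_profiles()].
#' @param config A [scan_config()].
#' @return List with `verdicts` (one row per protein: `protein_id`,
#'   `is_cc_tpr`, `n_match`, `n_domains`, best-domain motif starts),
#'   `motifs` (all motif hits of accepted domains, with any register shifts
#'   applied) and `domains` (list of per-protein domain lists).
#' @export
cc_screen <- function(records, profiles = default_profiles(),
                      config = scan_config()) {
  if (is.character(records) && length(records) == 1L && file.exists(records))
    records <- read_fasta(records)
  seqs <- if (is.character(records)) records else
    setNames(as.character(records), names(records))
  if (is.null(names(seqs))) stop("protein sequences must be named")
  thresholds <- vapply(profiles, function(p)
    p$training_min_score - config$threshold_offset, numeric(1))
  verdicts <- list(); motif_rows <- list(); domains <- list()
  for (id in names(seqs)) {
    hits <- scan_protein(seqs[[id]], profiles, thresholds, config)
    doms <- assemble_domains(hits, config)
    doms <- lapply(doms, register_rescue, sequence = seqs[[id]])
    v <- classify_protein(doms, protein_id = id,
                          min_matches = config$min_matches)
    domains[[id]] <- doms
    starts <- if (is.null(v$best_domain)) c(NA, NA, NA) else v$best_domain$motifs$start
    verdicts[[id]] <- data.frame(
      protein_id = id, is_cc_tpr = v$is_cc_tpr, n_match = v$n_match,
      n_domains = v$n_domains, start_I = starts[1], start_II = starts[2],
      start_III = starts[3], stringsAsFactors = FALSE)
    for (d in doms) {
      m <- d$motifs
      m$protein_id <- id
      motif_rows[[length(motif_rows) + 1L]] <- m
    }
  }
  motifs <- if (length(motif_rows)) do.call(rbind, motif_rows) else
    data.frame(motif_index = character(0), start = integer(0),
               end = integer(0), window = character(0), score = numeric(0),
               register_shift = integer(0), protein_id = character(0))
  verdicts <- do.call(rbind, verdicts)
  rownames(verdicts) <- rownames(motifs) <- NULL
  list(verdicts = verdicts,
       motifs = motifs[, c("protein_id", "motif_index", "start", "end",
                           "score", "register_shift", "window")],
       domains = domains)
}

#' Write a scan/verdict table as TSV
#'
#' Tab-separated with a header row; deterministic output for a given input.
#'
#' @param x data.frame.
#' @param path Output path.
#' @export
write_report_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consistency checks of the packaged motif tables against the classifier
#'
#' Recomputes, from the packaged tables alone, the headline quantities of
#' the screen -- positive counts for both families, the novelty split, the
#' architecture census of the newly identified Arabidopsis proteins, the
#' AtTPR5 register rescue, and motif window lengths -- and compares them
#' with their expected values. Machine-readable; intended for
#' `jsonlite::toJSON()` or the command-line `validate` subcommand.
#'
#' @return data.frame with columns `check`, `value`, `expected`, `pass`.
#' @export
validate_fixtures <- function() {
  at <- classify_motif_table("arabidopsis")
  os <- classify_motif_table("rice")
  at_only <- at[grepl("^AT", at$locus_id), ]
  meta <- load_protein_metadata()
  cens <- architecture_census(at_only, meta, novel = TRUE)
  attpr5 <- at[at$protein_name == "AtTPR5", ]
  fix <- rbind(load_motif_fixture("arabidopsis"), load_motif_fixture("rice"))
  checks <- list(
    list("arabidopsis_positive", sum(at_only$is_cc_tpr), 36),
    list("rice_positive", sum(os$is_cc_tpr), 35),
    list("novel_count", sum(meta$novel), 24),
    list("known_count", sum(!meta$novel), 12),
    list("census_single_TPR", cens[["single_TPR"]], 8),
    list("census_single_TPR_plus_domain", cens[["single_TPR_plus_domain"]], 7),
    list("census_multi_TPR", cens[["multi_TPR"]], 3),
    list("census_multi_TPR_plus_domain", cens[["multi_TPR_plus_domain"]], 6),
    list("attpr5_motif_II_rescued_start", attpr5$start_II, 117),
    list("full_length_motif_rows", sum(!fix$length_anomaly), nrow(fix) - 2))
  out <- do.call(rbind, lapply(checks, function(k)
    data.frame(check = k[[1]], value = as.numeric(k[[2]]),
               expected = as.numeric(k[[3]]), stringsAsFactors = FALSE)))
  out$pass <- out$value == out$expected
  out
}

#' Build the desk-scale NJ tree over the curated CC-TPR families
#'
#' Tree from p-distances over the concatenated 102-column motif alignment
#' (see [motif_alignment()]); optionally with bootstrap supports.
#'
#' @param proteomes Packaged motif tables to include.
#' @param bootstrap Number of bootstrap replicates (0 for none).
#' @param seed Seed for the bootstrap resampling.
#' @return An [ape::phylo] tree.
#' @export
fixture_tree <- function(proteomes = c("arabidopsis", "rice"),
                         bootstrap = 0L, seed = 1L) {
  aln <- motif_alignment(proteomes)
  if (bootstrap > 0L) bootstrap_support(aln, n_replicates = bootstrap, seed = seed)
  else neighbor_joining(alignment_pdistance(aln))
}
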