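#' Carboxylate-clamp consensus positions
#'
#' The five positions of a three-motif TPR domain whose side chains clamp the
#' acidic EEVD tail of Hsp90/Hsp70: Lys5 and Asn9 of motif I, Asn6 of motif
#' II, Lys2 and Arg6 of motif III (positions 1-based within each 34-residue
#' motif).
#'
#' @return Named list with one named character vector per motif index.
#' @export
clamp_consensus <- function() {
  list(I   = c("5" = "K", "9" = "N"),
       II  = c("6" = "N"),
       III = c("2" = "K", "6" = "R"))
}

#' Structure-maintaining TPR consensus positions
#'
#' Eight positions within a 34-residue TPR motif with elevated conservation
#' that stabilise the helix-turn-helix fold; each admits three residues.
#'
#' @return Named list mapping position to its allowed residue set.
#' @export
structural_consensus <- function() {
  list("4"  = c("W", "L", "F"), "7"  = c("L", "I", "M"),
       "8"  = c("G", "A", "S"), "11" = c("Y", "L", "F"),
       "20" = c("A", "S", "E"), "24" = c("F", "Y", "L"),
       "27" = c("A", "S", "L"), "32" = c("P", "K", "E"))
}

#' Build a position profile for one TPR motif
#'
#' Builds a 34-column log-odds scoring model from an alignment of excised
#' motifs. Column scores are
#' `log2((count(a, c) + pseudocount) / (N + 20 * pseudocount) / background(a))`;
#' with a positive pseudocount all scores are finite. Training rows whose
#' printed motif is not 34 residues (`length_anomaly`) are excluded from
#' counting. The minimum self-score over the full-length training rows is
#' recorded as `training_min_score` and anchors the default scan threshold.
#'
#' @param rows Motif-table rows (see [load_motif_fixture()]) sharing one
#'   `motif_index`, or a character vector of 34-residue strings.
#' @param motif_index Motif index (`"I"`, `"II"` or `"III"`); taken from
#'   `rows` when they are a data.frame.
#' @param pseudocount Positive Laplace pseudocount added per residue
#'   (default 1).
#' @param background Named vector of 20 background probabilities summing to
#'   1; default uniform.
#' @return An object of class `tpr_profile`: log-odds matrix (34 x 20),
#'   per-column probabilities, pseudocount, background, `training_min_score`
#'   and the number of training rows.
#' @export
build_profile <- function(rows, motif_index = NULL, pseudocount = 1,
                          background = rep(1 / 20, 20)) {
  if (is.data.frame(rows)) {
    mi <- unique(rows$motif_index)
    if (length(mi) != 1L) stop("training rows must share one motif_index")
    if (is.null(motif_index)) motif_index <- mi
    seqs <- rows$motif_seq
  } else {
    seqs <- rows
    if (is.null(motif_index)) motif_index <- "I"
  }
  stopifnot(pseudocount > 0)
  background <- setNames(as.numeric(background), AA20)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  seqs <- seqs[nchar(seqs) == MOTIF_LENGTH]
  if (length(seqs) == 0L)
    stop("no full-length training motifs for motif ", motif_index)
  n <- length(seqs)
  chars <- matrix(unlist(strsplit(seqs, "")), nrow = n, byrow = TRUE)
  counts <- t(apply(chars, 2, function(col) table(factor(col, levels = AA20))))
  probs <- (counts + pseudocount) / (n + 20 * pseudocount)
  log_odds <- log2(sweep(probs, 2, background, "/"))
  dimnames(log_odds) <- dimnames(probs) <- list(seq_len(MOTIF_LENGTH), AA20)
  prof <- structure(
    list(motif_index = motif_index, length = MOTIF_LENGTH,
         log_odds = log_odds, probs = probs, pseudocount = pseudocount,
         background = background, n_train = n, training_min_score = NA_real_),
    class = "tpr_profile")
  prof$training_min_score <- min(vapply(seqs, function(s) score_window(prof, s),
                                        numeric(1)))
  prof
}

#' Score a 34-residue window against a profile
#'
#' Sum of per-column log-odds; the unknown residue `X` contributes 0 at its
#' column.
#'
#' @param profile A `tpr_profile`.
#' @param window A 34-character residue string.
#' @return Numeric score in bits.
#' @export
score_window <- function(profile, window) {
  stopifnot(inherits(profile, "tpr_profile"))
  if (nchar(window) != profile$length)
    stop("window must be ", profile$length, " residues, got ", nchar(window))
  aa <- strsplit(window, "")[[1]]
  s <- profile$log_odds[cbind(seq_len(profile$length), match(aa, AA20))]
  sum(s, na.rm = TRUE)  # X (or any non-standard residue) scores 0
}

#' @export
print.tpr_profile <- function(x, ...) {
  cat("TPR motif profile (motif ", x$motif_index, "): ", x$length,
      " columns, ", x$n_train, " training motifs, pseudocount ",
      x$pseudocount, ", min self-score ",
      round(x$training_min_score, 2), " bits\n", sep = "")
  invisible(x)
}

#' Default motif profiles trained on the packaged alignments
#'
#' Trains one profile per motif index on the pooled Arabidopsis (including
#' the human Hop TPR2a reference row) and rice motif tables; length-anomalous
#' rows are excluded by [build_profile()].
#'
#' @param proteomes Which packaged tables to pool (default both).
#' @inheritParams build_profile
#' @return Named list of three `tpr_profile` objects (`I`, `II`, `III`).
#' @export
default_profiles <- function(proteomes = c("arabidopsis", "rice"),
                             pseudocount = 1, background = rep(1 / 20, 20)) {
  rows <- do.call(rbind, lapply(proteomes, load_motif_fixture))
  lapply(setNames(c("I", "II", "III"), c("I", "II", "III")), function(mi)
    build_profile(rows[rows$motif_index == mi, ],
                  pseudocount = pseudocount, background = background))
}

#' Serialize a profile to JSON
#'
#' Profiles round-trip bit-exactly so that scans are reproducible from a
#' stored model.
#'
#' @param profile A `tpr_profile`.
#' @param path Output JSON path.
#' @export
write_profile_json <- function(profile, path) {
  stopifnot(inherits(profile, "tpr_profile"))
  x <- profile
  class(x) <- NULL
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(x, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a profile from JSON
#' @param path JSON file written by [write_profile_json()].
#' @return A `tpr_profile`.
#' @export
read_profile_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$log_odds <- matrix(as.numeric(x$log_odds), nrow = x$length,
                       dimnames = list(seq_len(x$length), AA20))
  x$probs <- matrix(as.numeric(x$probs), nrow = x$length,
                    dimnames = list(seq_len(x$length), AA20))
  x$background <- setNames(as.numeric(x$background), AA20)
  structure(x, class = "tpr_profile")
}
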