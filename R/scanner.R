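#' Default scanner / classifier configuration
#'
#' @param threshold_offset Bits subtracted from each profile's
#'   `training_min_score` to form its scan threshold. The default (2) admits
#'   the curated motifs and near relatives while rejecting random windows.
#' @param linker_range Allowed residue gap between consecutive motifs,
#'   `start(next) - end(prev) - 1`. The default `[-2, 60]` covers the
#'   spacings observed in the curated families (-1 to 56).
#' @param suppress_window Overlapping same-index hits within this many
#'   residues are collapsed to the local score maximum, so one repeat is
#'   never reported twice.
#' @param min_matches Minimum number of clamp positions with consensus or
#'   conservative status for a positive CC-TPR verdict.
#' @export
scan_config <- function(threshold_offset = 2, linker_range = c(-2L, 60L),
                        suppress_window = 17L, min_matches = 3L) {
  stopifnot(linker_range[1] <= linker_range[2], suppress_window >= 1L,
            min_matches >= 0L)
  list(threshold_offset = threshold_offset, linker_range = linker_range,
       suppress_window = suppress_window, min_matches = min_matches)
}

# Score every 34-mer window of `sequence` against `profile`; returns a
# numeric vector of length nchar(sequence) - 33 (empty if shorter).
score_all_windows <- function(profile, sequence) {
  L <- nchar(sequence)
  nwin <- L - profile$length + 1L
  if (nwin < 1L) return(numeric(0))
  aa <- match(strsplit(sequence, "")[[1]], AA20)  # X -> NA, scores 0
  s <- numeric(nwin)
  for (col in seq_len(profile$length)) {
    v <- profile$log_odds[col, aa[col:(col + nwin - 1L)]]
    v[is.na(v)] <- 0
    s <- s + v
  }
  s
}

#' Scan a protein for candidate TPR motifs
#'
#' Slides a 34-residue window over the protein, scores every window against
#' the three motif profiles, and emits windows meeting a profile's threshold
#' as motif hits of that index. Overlapping hits of the same index within
#' `suppress_window` residues are collapsed to the local score maximum.
#' Proteins shorter than 34 residues yield no hits.
#'
#' @param sequence Protein sequence string (or a length-1 named character /
#'   `AAStringSet` element coerced with `as.character`).
#' @param profiles Named list of three `tpr_profile` objects (`I`,`II`,`III`).
#' @param thresholds Named numeric scan thresholds per motif index; default
#'   `training_min_score - threshold_offset` per profile.
#' @param config A [scan_config()].
#' @return data.frame of motif hits sorted by start: `motif_index`, `start`,
#'   `end` (1-based inclusive), `window`, `score`, `register_shift` (0 at
#'   this stage).
#' @export
scan_protein <- function(sequence, profiles, thresholds = NULL,
                         config = scan_config()) {
  sequence <- as.character(sequence)
  stopifnot(length(sequence) == 1L)
  if (is.null(thresholds))
    thresholds <- vapply(profiles, function(p)
      p$training_min_score - config$threshold_offset, numeric(1))
  hits <- list()
  for (mi in names(profiles)) {
    s <- score_all_windows(profiles[[mi]], sequence)
    keep <- which(s >= thresholds[[mi]])
    if (!length(keep)) next
    # non-maximum suppression: best-scoring hit wins within suppress_window
    keep <- keep[order(-s[keep], keep)]
    acc <- integer(0)
    for (i in keep)
      if (!length(acc) || all(abs(acc - i) >= config$suppress_window))
        acc <- c(acc, i)
    acc <- sort(acc)
    hits[[mi]] <- data.frame(
      motif_index = mi, start = acc, end = acc + MOTIF_LENGTH - 1L,
      window = substring(sequence, acc, acc + MOTIF_LENGTH - 1L),
      score = s[acc], register_shift = 0L, stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(motif_index = character(0), start = integer(0),
                      end = integer(0), window = character(0),
                      score = numeric(0), register_shift = integer(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$motif_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble motif hits into three-motif TPR domains
#'
#' Every I -> II -> III chain whose two consecutive linkers
#' (`start(next) - end(prev) - 1`) fall within `linker_range` is a candidate
#' domain; a maximal non-overlapping set is then chosen greedily by summed
#' profile score (ties broken by smallest start). A protein may yield more
#' than one domain.
#'
#' @param motifs Motif hit data.frame from [scan_protein()], sorted by start.
#' @param config A [scan_config()] supplying `linker_range`.
#' @return List of `tpr_domain` objects; each holds the ordered motif triplet
#'   (a 3-row data.frame) and the two linker lengths.
#' @export
assemble_domains <- function(motifs, config = scan_config()) {
  lr <- config$linker_range
  m1 <- motifs[motifs$motif_index == "I", , drop = FALSE]
  m2 <- motifs[motifs$motif_index == "II", , drop = FALSE]
  m3 <- motifs[motifs$motif_index == "III", , drop = FALSE]
  cand <- list()
  for (i in seq_len(nrow(m1))) for (j in seq_len(nrow(m2))) {
    l1 <- m2$start[j] - m1$end[i] - 1L
    if (l1 < lr[1] || l1 > lr[2]) next
    for (k in seq_len(nrow(m3))) {
      l2 <- m3$start[k] - m2$end[j] - 1L
      if (l2 < lr[1] || l2 > lr[2]) next
      trip <- rbind(m1[i, ], m2[j, ], m3[k, ])
      rownames(trip) <- NULL
      cand[[length(cand) + 1L]] <- new_tpr_domain(trip, c(l1, l2))
    }
  }
  if (!length(cand)) return(list())
  total <- vapply(cand, function(d) sum(d$motifs$score), numeric(1))
  first <- vapply(cand, function(d) d$motifs$start[1], numeric(1))
  cand <- cand[order(-total, first)]
  acc <- list()
  for (d in cand) {
    span <- c(d$motifs$start[1], d$motifs$end[3])
    clash <- any(vapply(acc, function(a)
      span[1] <= a$motifs$end[3] && a$motifs$start[1] <= span[2], logical(1)))
    if (!clash) acc[[length(acc) + 1L]] <- d
  }
  acc[order(vapply(acc, function(d) d$motifs$start[1], numeric(1)))]
}

new_tpr_domain <- function(motifs, linkers) {
  structure(list(motifs = motifs, linkers = as.integer(linkers)),
            class = "tpr_domain")
}

#' @export
print.tpr_domain <- function(x, ...) {
  cat("Three-motif TPR domain [", x$motifs$start[1], "-", x$motifs$end[3],
      "], linkers ", x$linkers[1], "/", x$linkers[2], "\n", sep = "")
  print(x$motifs[, c("motif_index", "start", "end", "score", "register_shift")])
  invisible(x)
}

#' Rescue a one-residue register slip in an assembled domain
#'
#' A motif's assigned start can be off by one residue, displacing clamp
#' residues from their canonical positions (the AtTPR5 case: the consensus
#' Asn of motif II appears at position 5 of the printed window; re-initiating
#' the motif one residue earlier restores it to position 6). For each motif,
#' the start is shifted by -1 or +1 only if that strictly increases the
#' number of clamp positions holding their exact consensus residue; ties
#' keep shift 0, and a tie between -1 and +1 prefers -1. With the full
#' protein sequence the shifted window is re-excised; in fixture-only mode
#' (no sequence) the printed window is shifted and the unknown flanking
#' residue is written as `X`.
#'
#' @param domain A `tpr_domain`.
#' @param sequence Full protein sequence, or `NULL` for fixture-only mode.
#' @param clamp Clamp consensus, see [clamp_consensus()].
#' @return The domain with any applied shifts reflected in `start`, `end`,
#'   `window` and `register_shift`.
#' @export
register_rescue <- function(domain, sequence = NULL, clamp = clamp_consensus()) {
  stopifnot(inherits(domain, "tpr_domain"))
  for (r in seq_len(nrow(domain$motifs))) {
    mi <- domain$motifs$motif_index[r]
    cons <- clamp[[mi]]
    pos <- as.integer(names(cons))
    w0 <- domain$motifs$window[r]
    start0 <- domain$motifs$start[r]
    shifted_window <- function(s) {
      if (!is.null(sequence)) {
        st <- start0 + s
        if (st < 1L || st + MOTIF_LENGTH - 1L > nchar(sequence)) return(NA_character_)
        return(substring(sequence, st, st + MOTIF_LENGTH - 1L))
      }
      if (s == 0L) return(w0)
      if (start0 + s < 1L) return(NA_character_)
      if (s == -1L) w <- paste0("X", substr(w0, 1L, MOTIF_LENGTH - 1L))
      else          w <- paste0(substr(w0, 2L, nchar(w0)), "X")
      # pad printed short rows out to the canonical motif length
      paste0(w, strrep("X", max(0L, MOTIF_LENGTH - nchar(w))))
    }
    n_exact <- function(w) {
      if (is.na(w)) return(-1L)
      sum(substring(w, pos, pos) == cons)
    }
    base <- n_exact(shifted_window(0L))
    best_s <- 0L; best_n <- base
    for (s in c(-1L, 1L)) {
      n <- n_exact(shifted_window(s))
      if (n > best_n) { best_n <- n; best_s <- s }
    }
    if (best_s != 0L) {
      domain$motifs$window[r] <- shifted_window(best_s)
      domain$motifs$start[r] <- start0 + best_s
      domain$motifs$end[r] <- start0 + best_s + MOTIF_LENGTH - 1L
      domain$motifs$register_shift[r] <- best_s
    }
  }
  domain
}
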