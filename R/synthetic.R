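#' Specification for a synthetic proteome
#'
#' Defines the ground-truth composition of a generated proteome: background
#' proteins drawn i.i.d. from a residue background, proteins with one
#' planted three-motif TPR domain whose clamp residues are forced to
#' consensus, and decoy proteins whose planted domain carries radical
#' substitutions at a chosen number of clamp positions. Motif residues are
#' sampled per column from the motif profiles, and linker lengths from the
#' range observed in the curated families.
#'
#' @param n_background,n_planted,n_decoys Protein counts per category.
#' @param protein_length Length sampling range in residues.
#' @param linker_length Linker length sampling range (within `[0, 60]`).
#' @param decoy_radical_positions Number of clamp positions (3-5) broken per
#'   decoy domain; breakage always crosses substitution classes, so a decoy
#'   can match at most `5 - decoy_radical_positions` clamp positions.
#' @param residue_background 20 residue probabilities (default uniform).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @export
synthetic_spec <- function(n_background = 50L, n_planted = 50L, n_decoys = 50L,
                           protein_length = c(200L, 800L),
                           linker_length = c(0L, 56L),
                           decoy_radical_positions = 3L,
                           residue_background = rep(1 / 20, 20),
                           seed = 1L) {
  stopifnot(n_background >= 0L, n_planted >= 0L, n_decoys >= 0L,
            length(protein_length) == 2L, protein_length[1] <= protein_length[2],
            linker_length[1] >= 0L, linker_length[2] <= 60L,
            linker_length[1] <= linker_length[2],
            decoy_radical_positions >= 3L, decoy_radical_positions <= 5L,
            abs(sum(residue_background) - 1) < 1e-9)
  structure(list(n_background = n_background, n_planted = n_planted,
                 n_decoys = n_decoys, protein_length = protein_length,
                 linker_length = linker_length,
                 decoy_radical_positions = decoy_radical_positions,
                 residue_background = setNames(as.numeric(residue_background), AA20),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Flat list of the 5 clamp positions: motif index, position, consensus residue.
clamp_position_table <- function(clamp = clamp_consensus()) {
  do.call(rbind, lapply(names(clamp), function(mi)
    data.frame(motif_index = mi, position = as.integer(names(clamp[[mi]])),
               consensus = unname(clamp[[mi]]), stringsAsFactors = FALSE)))
}

#' Sample one 34-residue motif from a profile
#'
#' Residues are drawn per column from the profile's probability columns.
#' With `force_clamp`, the motif's clamp positions are overwritten with
#' their consensus residues; positions listed in `break_positions` are
#' instead overwritten with a residue from a different substitution class
#' than the consensus, guaranteeing a radical substitution. Uses the current
#' R random number generator state.
#'
#' @param profile A `tpr_profile`.
#' @param force_clamp Force consensus residues at clamp positions.
#' @param break_positions Integer clamp positions (within this motif) to
#'   break radically; only meaningful for decoy generation.
#' @param clamp,classes See [clamp_consensus()], [substitution_classes()].
#' @return A 34-character string.
#' @export
sample_motif <- function(profile, force_clamp = TRUE,
                         break_positions = integer(0),
                         clamp = clamp_consensus(),
                         classes = substitution_classes()) {
  stopifnot(inherits(profile, "tpr_profile"))
  aa <- vapply(seq_len(profile$length), function(c)
    sample(AA20, 1L, prob = profile$probs[c, ]), character(1))
  cons <- clamp[[profile$motif_index]]
  if (force_clamp)
    aa[as.integer(names(cons))] <- unname(cons)
  for (p in break_positions) {
    e <- unname(cons[as.character(p)])
    if (is.na(e)) stop("position ", p, " is not a clamp position of motif ",
                       profile$motif_index)
    own <- names(which(vapply(classes, function(cl) e %in% cl, logical(1))))
    pool <- setdiff(AA20, unlist(classes[own]))
    aa[p] <- sample(pool, 1L)
  }
  if (length(break_positions)) {
    # decoy motifs must stay broken under a +/-1 register shift: residues
    # flanking any clamp position may not carry that position's consensus
    cpos <- as.integer(names(cons))
    for (p in cpos) for (q in c(p - 1L, p + 1L)) {
      if (q < 1L || q > profile$length || q %in% cpos) next
      if (aa[q] == cons[[as.character(p)]]) {
        pr <- profile$probs[q, ]
        pr[cons[[as.character(p)]]] <- 0
        aa[q] <- sample(AA20, 1L, prob = pr)
      }
    }
  }
  paste(aa, collapse = "")
}

#' Generate a synthetic proteome with known ground truth
#'
#' Background proteins are i.i.d. residue draws; planted proteins embed one
#' I-II-III motif triplet (clamp residues forced to consensus) with sampled
#' linkers at a random interior offset; decoys embed a triplet with
#' `decoy_radical_positions` clamp positions broken radically (chosen
#' uniformly among the five). Linker upper bounds are tightened when needed
#' so a domain always fits the sampled protein length.
#'
#' @param spec A [synthetic_spec()].
#' @param profiles Motif profiles used for sampling, see
#'   [default_profiles()].
#' @return List with `records` (named character vector of sequences) and
#'   `truth` (data.frame: `protein_id`, `category`, motif starts,
#'   `broken_positions` as `"motif:pos"` tokens, planted motif windows).
#' @export
generate_proteome <- function(spec, profiles = default_profiles()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  min_needed <- 3L * MOTIF_LENGTH + 2L * spec$linker_length[1]
  if (spec$protein_length[2] < min_needed)
    stop("protein_length too small to host a three-motif domain (needs >= ",
         min_needed, ")")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  bg_draw <- function(n) paste(
    sample(AA20, n, replace = TRUE, prob = spec$residue_background), collapse = "")
  rlen <- function() sample(seq(spec$protein_length[1], spec$protein_length[2]), 1L)
  cpt <- clamp_position_table()
  records <- character(0)
  truth <- list()
  emit <- function(id, seq, category, starts = c(NA, NA, NA), broken = "",
                   windows = c(NA, NA, NA)) {
    records[[id]] <<- seq
    truth[[length(truth) + 1L]] <<- data.frame(
      protein_id = id, category = category,
      start_I = starts[1], start_II = starts[2], start_III = starts[3],
      broken_positions = broken,
      window_I = windows[1], window_II = windows[2], window_III = windows[3],
      stringsAsFactors = FALSE)
  }
  plant <- function(id, category, break_idx = integer(0)) {
    L <- rlen()
    lmax <- min(spec$linker_length[2],
                (L - 3L * MOTIF_LENGTH - 2L) %/% 2L)
    lmax <- max(lmax, spec$linker_length[1])
    linkers <- sample(seq(spec$linker_length[1], lmax), 2L, replace = TRUE)
    broken <- cpt[break_idx, , drop = FALSE]
    wins <- vapply(c("I", "II", "III"), function(mi)
      sample_motif(profiles[[mi]], force_clamp = TRUE,
                   break_positions = broken$position[broken$motif_index == mi]),
      character(1))
    dom <- paste0(wins[1], bg_draw(linkers[1]), wins[2], bg_draw(linkers[2]), wins[3])
    dl <- nchar(dom)
    off <- sample(seq_len(L - dl + 1L), 1L)
    seq <- paste0(bg_draw(off - 1L), dom, bg_draw(L - dl - off + 1L))
    starts <- c(off, off + MOTIF_LENGTH + linkers[1],
                off + 2L * MOTIF_LENGTH + sum(linkers))
    emit(id, seq, category, starts,
         broken = paste(broken$motif_index, broken$position,
                        sep = ":", collapse = ","),
         windows = wins)
  }
  for (i in seq_len(spec$n_background))
    emit(sprintf("bg%03d", i), bg_draw(rlen()), "background")
  for (i in seq_len(spec$n_planted))
    plant(sprintf("planted%03d", i), "planted")
  for (i in seq_len(spec$n_decoys))
    plant(sprintf("decoy%03d", i), "decoy",
          break_idx = sort(sample.int(5L, spec$decoy_radical_positions)))
  list(records = records, truth = do.call(rbind, truth))
}
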