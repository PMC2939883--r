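#' Pairwise alignment parameters
#'
#' Global (Needleman-Wunsch) protein alignment with BLOSUM62 scoring and
#' affine gaps; used to derive p-distances between full-length proteins.
#'
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_ext Affine gap opening / extension penalties.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 10, gap_ext = 0.5) {
  list(substitution_matrix = substitution_matrix,
       gap_open = gap_open, gap_ext = gap_ext)
}

#' p-distance between two protein sequences
#'
#' Globally aligns the two sequences and returns
#' `1 - identities / aligned non-gap columns`, a value in `[0, 1]`.
#'
#' @param a,b Protein sequence strings.
#' @param params See [alignment_params()].
#' @export
pairwise_distance <- function(a, b, params = alignment_params()) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  # co-optimal alignments can differ between (a,b) and (b,a); fixing the
  # argument order makes the distance exactly symmetric
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_ext)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ok <- pa != "-" & pb != "-"
  if (!any(ok)) stop("no aligned non-gap columns; distance undefined")
  1 - sum(pa[ok] == pb[ok]) / sum(ok)
}

#' Distance matrix over a set of protein sequences
#'
#' @param seqs Named character vector (or `AAStringSet`) of sequences.
#' @param params See [alignment_params()].
#' @return Symmetric matrix of pairwise p-distances with zero diagonal.
#' @export
distance_matrix <- function(seqs, params = alignment_params()) {
  seqs <- as.character(seqs)
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- pairwise_distance(seqs[i], seqs[j], params)
  d
}

# p-distances over the rows of an alignment (character matrix, rows = taxa);
# per pair only columns where both rows are non-gap count.
alignment_pdistance <- function(aln) {
  n <- nrow(aln)
  lab <- rownames(aln)
  d <- matrix(0, n, n, dimnames = list(lab, lab))
  gap <- aln == "-"
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) stop("rows ", i, " and ", j, " share no aligned columns")
    d[i, j] <- d[j, i] <- mean(aln[i, ok] != aln[j, ok])
  }
  d
}

#' Concatenated motif alignment of the curated CC-TPR families
#'
#' Joins each protein's motif I, II and III windows into one 102-column row
#' (printed short rows are right-padded with gaps), giving an alignment that
#' requires no alignment step and supports desk-scale trees over the curated
#' families.
#'
#' @param proteomes Packaged motif tables to include (default both families;
#'   the human Hop reference row is excluded).
#' @param include_reference Keep the human Hop TPR2a row (default FALSE).
#' @return Character matrix, one row per protein, one aligned column per cell.
#' @export
motif_alignment <- function(proteomes = c("arabidopsis", "rice"),
                            include_reference = FALSE) {
  rows <- do.call(rbind, lapply(proteomes, load_motif_fixture))
  if (!include_reference)
    rows <- rows[!grepl("^HsHop", rows$protein_name), , drop = FALSE]
  pad <- function(s) paste0(s, strrep("-", MOTIF_LENGTH - nchar(s)))
  prots <- unique(rows$protein_name)
  cat102 <- vapply(prots, function(p) {
    r <- rows[rows$protein_name == p, ]
    paste0(pad(r$motif_seq[r$motif_index == "I"]),
           pad(r$motif_seq[r$motif_index == "II"]),
           pad(r$motif_seq[r$motif_index == "III"]))
  }, character(1))
  do.call(rbind, strsplit(setNames(cat102, prots), ""))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining: at each step the pair minimising the
#' Q-criterion is joined (ties broken by lowest label index), branch lengths
#' follow the closed-form NJ formulas and are clamped at zero, and the final
#' two clusters are connected by an edge split equally to give a rooted
#' binary representation. On an additive distance matrix the tree reproduces
#' all pairwise path distances exactly.
#'
#' @param d Symmetric numeric matrix (or `dist`) with zero diagonal and
#'   labelled rows.
#' @return An [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("t", seq_len(n))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (any(diag(D) != 0)) stop("distance matrix must have zero diagonal")
  lab <- rownames(D)
  fmt <- function(x) format(max(x, 0), digits = 15, scientific = FALSE, trim = TRUE)
  nodes <- as.list(lab)  # newick fragments for the active clusters
  while (n > 2L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    lj <- D[i, j] - li
    merged <- paste0("(", nodes[[i]], ":", fmt(li), ",",
                     nodes[[j]], ":", fmt(lj), ")")
    dk <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    nodes <- c(nodes[keep], list(merged))
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], paste0("__m", n))
    D <- D2
    n <- n - 1L
  }
  half <- D[1, 2] / 2
  nwk <- paste0("(", nodes[[1]], ":", fmt(half), ",",
                nodes[[2]], ":", fmt(half), ");")
  ape::read.tree(text = nwk)
}

# Canonical keys for the non-trivial bipartitions (internal splits) of a
# tree: for each internal node, the tip set of its subtree, represented by
# the side not containing the reference tip and serialized sorted. Returns a
# named character vector keyed by internal node number.
tree_bipartitions <- function(tree) {
  tips <- tree$tip.label
  ref <- sort(tips)[1]
  parts <- ape::prop.part(tree)
  keys <- vapply(seq_along(parts), function(k) {
    side <- tips[parts[[k]]]
    if (ref %in% side) side <- setdiff(tips, side)
    paste(sort(side), collapse = "|")
  }, character(1))
  names(keys) <- length(tips) + seq_along(parts)
  keys[nzchar(keys)]  # drop the trivial root split (empty complement)
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the point-estimate NJ tree from p-distances over an alignment,
#' then resamples alignment columns with replacement `n_replicates` times,
#' rebuilds the tree for each replicate, and counts for every internal
#' bipartition of the point tree the number of replicates containing it.
#' Fully identical rows give zero distances and a deterministic (degenerate)
#' topology whose splits recur in every replicate, so supports equal
#' `n_replicates`.
#'
#' @param alignment Character matrix of aligned residues (rows = taxa), or a
#'   vector of equal-length strings.
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @return The point-estimate [ape::phylo] tree with integer supports in
#'   `node.label` (empty label on the root).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  if (!is.matrix(alignment)) {
    if (length(unique(nchar(alignment))) != 1L)
      stop("alignment rows must have equal length")
    alignment <- do.call(rbind, strsplit(alignment, ""))
  }
  stopifnot(n_replicates >= 1L)
  if (is.null(rownames(alignment)))
    rownames(alignment) <- paste0("t", seq_len(nrow(alignment)))
  tree <- neighbor_joining(alignment_pdistance(alignment))
  keys <- tree_bipartitions(tree)
  counts <- setNames(integer(length(keys)), keys)
  L <- ncol(alignment)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_keys <- tree_bipartitions(
      neighbor_joining(alignment_pdistance(alignment[, cols, drop = FALSE])))
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  nl <- character(tree$Nnode)
  node_ids <- as.integer(names(keys)) - length(tree$tip.label)
  nl[node_ids] <- as.character(counts)
  tree$node.label <- nl
  tree
}
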