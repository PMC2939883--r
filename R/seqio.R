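#' Read a protein FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()] and enforces the conventions used
#' throughout the package: the record id is the first whitespace-delimited
#' token of the header (matching AGI / rice locus identifiers), the remainder
#' of the header is kept as a description, sequences are uppercased, and only
#' the 20 standard residues plus `X` are accepted.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by record id; the free-text
#'   remainder of each header is stored in `mcols(x)$description`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)  # no alphabet coercion: validate raw
  if (length(raw) == 0L) stop("empty FASTA input: ", path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  chars <- strsplit(seqs, "")
  ok <- c(AA20, "X")
  for (i in seq_along(chars)) {
    if (length(chars[[i]]) == 0L) stop("empty sequence for record ", ids[i])
    bad <- which(!chars[[i]] %in% ok)
    if (length(bad))
      stop("illegal residue '", chars[[i]][bad[1]], "' in record ", ids[i],
           " at position ", bad[1])
  }
  aa <- Biostrings::AAStringSet(setNames(seqs, ids))
  S4Vectors::mcols(aa)$description <- desc
  aa
}

#' Write protein sequences as FASTA
#'
#' @param x Named character vector of sequences, or an
#'   [Biostrings::AAStringSet].
#' @param path Output path. Sequences are wrapped at 60 columns.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("all sequences must be named")
    x <- Biostrings::AAStringSet(x)
  }
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Load a curated TPR motif table
#'
#' The package ships, under `inst/extdata`, the excised three-motif TPR
#' alignments of the Arabidopsis CC-TPR family (with the human Hop TPR2a
#' reference row) and of the rice family, transcribed together with their
#' typographic residue markup: per position, `C` marks a conserved clamp
#' residue, `S` a substitution at a clamp position, and `.` an unannotated
#' position. Rows whose printed motif is not 34 residues carry
#' `length_anomaly = TRUE` and are kept exactly as printed.
#'
#' @param path Path to a motif TSV, or one of the shortcuts
#'   `"arabidopsis"` / `"rice"` for the packaged tables.
#' @return A data.frame with columns `protein_name`, `locus_id`,
#'   `motif_index` (`I`/`II`/`III`), `start` (1-based), `motif_seq`,
#'   `residue_markup`, `length_anomaly`. Rows are grouped per protein as
#'   ordered triplets.
#' @export
load_motif_fixture <- function(path) {
  if (path %in% c("arabidopsis", "rice"))
    path <- fixture_path(paste0(path, "_tpr_motifs.tsv"))
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(start = "integer", length_anomaly = "logical"))
  need <- c("protein_name", "locus_id", "motif_index", "start",
            "motif_seq", "residue_markup", "length_anomaly")
  if (!all(need %in% names(x)))
    stop("motif table is missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  bad <- nchar(x$motif_seq) != nchar(x$residue_markup)
  if (any(bad))
    stop("markup/sequence length mismatch for ",
         paste(x$protein_name[bad], x$motif_index[bad], collapse = ", "))
  if (any(x$start < 1L)) stop("motif starts must be 1-based (>= 1)")
  for (p in split(x, x$protein_name)) {
    if (nrow(p) != 3L || !setequal(p$motif_index, c("I", "II", "III")))
      stop("protein ", p$protein_name[1], " does not have exactly motifs I, II, III")
    p <- p[match(c("I", "II", "III"), p$motif_index), ]
    if (any(diff(p$start) <= 0L))
      stop("motif starts not strictly increasing for ", p$protein_name[1])
  }
  x
}

#' Load the curated Arabidopsis CC-TPR protein metadata
#'
#' Per-protein properties of the 36 Arabidopsis CC-TPR proteins: locus id,
#' name, protein length(s) (splice variants split into a list), additional
#' functional domains, whether the protein carries one or more than one TPR
#' domain, whether it was newly identified by the screen, and the number of
#' mRNA species.
#'
#' @param path Path to a metadata TSV; defaults to the packaged table.
#' @return A data.frame with list-column `lengths` and character list-column
#'   `additional_domains`.
#' @export
load_protein_metadata <- function(path = fixture_path("arabidopsis_cc_tpr_metadata.tsv")) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(novel = "logical", mrna_species = "integer"))
  if (anyDuplicated(x$locus_id))
    stop("duplicate locus_id in metadata: ",
         paste(unique(x$locus_id[duplicated(x$locus_id)]), collapse = ", "))
  if (any(x$mrna_species < 1L)) stop("mrna_species must be >= 1")
  x$lengths <- lapply(strsplit(x$lengths, "/", fixed = TRUE), as.integer)
  x$additional_domains <- lapply(strsplit(x$additional_domains, ";", fixed = TRUE),
                                 function(d) d[nzchar(d)])
  x
}

#' Path to a packaged data file
#' @param file File name under the package's `extdata` directory.
#' @export
fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "cctpr", mustWork = FALSE)
  if (!nzchar(p)) stop("no packaged file named ", file)
  p
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree An [ape::phylo] tree with named leaves; internal node labels
#'   (bootstrap supports) and branch lengths are preserved.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2L) stop("tree must have at least 2 leaves")
  if (any(is.na(tree$tip.label) | !nzchar(tree$tip.label)))
    stop("all leaves must be named")
  ape::write.tree(tree, file = path)
  invisible(path)
}
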