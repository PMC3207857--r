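ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a haplotype alignment
#'
#' The basic container of the package: an aligned set of haplotype sequences,
#' each tagged with the species it was sampled from.  Sequences are stored as
#' a character matrix (one row per haplotype, one column per alignment
#' column) over the alphabet `A,C,G,T,-,N`; case is normalised on input.
#'
#' @param sequences character vector of aligned sequences (equal length).
#' @param haplotype_ids character vector of unique haplotype identifiers.
#' @param species_ids character vector assigning each haplotype to a species.
#' @return An object of class `haplotype_alignment` with elements `mat`
#'   (character matrix, rownames = haplotype ids), `species` (named character
#'   vector) and `length` (number of columns).
#' @examples
#' aln <- haplotype_alignment(c("ACGT-A", "ACGTTA"), c("me_h1", "si_h1"),
#'                            c("me", "si"))
#' aln$length
#' @export
haplotype_alignment <- function(sequences, haplotype_ids, species_ids) {
  if (length(sequences) < 1L) stop("alignment must contain at least one sequence")
  if (length(haplotype_ids) != length(sequences) ||
      length(species_ids) != length(sequences))
    stop("sequences, haplotype_ids and species_ids must have equal length")
  if (anyDuplicated(haplotype_ids)) stop("duplicate haplotype ids")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences have unequal lengths")
  if (lens[1L] < 1L) stop("alignment of length zero")
  mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(mat)), ALN_ALPHABET)
  if (length(bad))
    stop("alphabet error: disallowed characters: ", paste(bad, collapse = ", "))
  rownames(mat) <- haplotype_ids
  structure(list(mat = mat,
                 species = stats::setNames(as.character(species_ids), haplotype_ids),
                 length = ncol(mat)),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat("haplotype_alignment:", nrow(x$mat), "haplotypes,",
      length(unique(x$species)), "species,", x$length, "columns\n")
  invisible(x)
}

#' Species ids present in an alignment
#' @param aln a `haplotype_alignment`.
#' @return character vector of species ids, in order of first appearance.
#' @export
alignment_species <- function(aln) unique(unname(aln$species))

#' Restrict an alignment to one or more species
#' @param aln a `haplotype_alignment`.
#' @param species character vector of species ids to keep.
#' @return a `haplotype_alignment` with only the selected haplotypes.
#' @export
subset_species <- function(aln, species) {
  keep <- aln$species %in% species
  if (!any(keep)) stop("no haplotypes for species: ", paste(species, collapse = ","))
  haplotype_alignment(apply(aln$mat[keep, , drop = FALSE], 1L, paste, collapse = ""),
                      rownames(aln$mat)[keep], unname(aln$species[keep]))
}

#' Read an aligned FASTA file into a haplotype alignment
#'
#' Headers are mapped to species ids by `species_parser`; the default takes
#' the prefix before the first underscore, so `me_h1` belongs to species
#' `me`.
#'
#' @param path path to an aligned FASTA file.
#' @param species_parser function mapping a header string to a species id.
#' @return a `haplotype_alignment`.
#' @export
read_fasta_alignment <- function(path,
                                 species_parser = function(h) sub("_.*$", "", h)) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("format error: empty FASTA file")
  ids <- sub("\\s.*$", "", names(seqs))
  haplotype_alignment(as.character(seqs), ids, vapply(ids, species_parser, ""))
}

#' Write a haplotype alignment to FASTA
#' @param aln a `haplotype_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  seqs <- apply(aln$mat, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Columns free of gaps and missing data
#'
#' Returns the alignment columns at which no in-scope sequence carries a gap;
#' `N` is treated as missing and excluded as well (toggle with `drop_n`).
#' These are the "sites excluding gaps" used by all diversity statistics
#' (complete-deletion filter).
#'
#' @param aln a `haplotype_alignment`.
#' @param scope species ids defining the sequence set, or `NULL` for all.
#' @param drop_n if `TRUE` (default) columns containing `N` are excluded too.
#' @return integer vector of 0-based column indices.
#' @export
complete_deletion_sites <- function(aln, scope = NULL, drop_n = TRUE) {
  mat <- aln$mat
  if (!is.null(scope)) mat <- mat[aln$species %in% scope, , drop = FALSE]
  if (nrow(mat) == 0L) stop("no sequences in scope")
  bad <- colSums(mat == "-") > 0L
  if (drop_n) bad <- bad | colSums(mat == "N") > 0L
  which(!bad) - 1L
}

#' Map ungapped positions of one haplotype to alignment columns
#'
#' @param aln a `haplotype_alignment`.
#' @param haplotype_id row to use as the coordinate reference.
#' @return integer vector: element `u + 1` is the 0-based alignment column of
#'   the 0-based ungapped position `u` of the haplotype.
#' @export
ungapped_to_columns <- function(aln, haplotype_id) {
  row <- aln$mat[haplotype_id, ]
  which(row != "-") - 1L
}

#' Map alignment columns to ungapped positions of one haplotype
#'
#' Inverse of [ungapped_to_columns()]: gapped columns map to `NA`.
#'
#' @inheritParams ungapped_to_columns
#' @return integer vector of length `aln$length`; entry `c + 1` is the
#'   0-based ungapped position at 0-based column `c`, or `NA` at a gap.
#' @export
columns_to_ungapped <- function(aln, haplotype_id) {
  row <- aln$mat[haplotype_id, ]
  out <- rep(NA_integer_, length(row))
  ng <- row != "-"
  out[ng] <- seq_len(sum(ng)) - 1L
  out
}

#' Extract the ungapped sequence of one haplotype
#' @inheritParams ungapped_to_columns
#' @return single character string without gaps.
#' @export
ungapped_sequence <- function(aln, haplotype_id) {
  row <- aln$mat[haplotype_id, ]
  paste(row[row != "-"], collapse = "")
}

#' Read a newick species tree
#'
#' Leaf labels must match the species ids of the alignment the tree is used
#' with (the outgroup leaf, if any, may be absent from the alignment).
#'
#' @param path newick file.
#' @param outgroup optional outgroup leaf label; the tree is rooted on it.
#' @return an [ape::phylo] object, with attribute `outgroup`.
#' @export
read_species_tree <- function(path, outgroup = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick tree: ", path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in tree")
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not in tree: ", outgroup)
    tr <- ape::root(tr, outgroup, resolve.root = TRUE)
  }
  attr(tr, "outgroup") <- outgroup
  tr
}

#' Check that tree leaves cover the alignment species
#' @param aln a `haplotype_alignment`.
#' @param tree an [ape::phylo].
#' @return invisibly `TRUE`; stops if a species is missing from the tree.
#' @export
validate_tree_alignment <- function(aln, tree) {
  missing <- setdiff(alignment_species(aln), tree$tip.label)
  if (length(missing))
    stop("tree error: species absent from tree: ", paste(missing, collapse = ","))
  invisible(TRUE)
}
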