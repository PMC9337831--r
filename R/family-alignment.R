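#' Read a family multiple sequence alignment
#'
#' Loads an aligned FASTA (all sequences equal gapped length) and an
#' optional numbering sidecar giving, per sequence identifier, the author
#' residue number of its first residue. The sidecar is a two-column TSV
#' (`id`, `first_resno`); sequences without an entry start at 1. Author
#' numbering is what the conservation filter works in: kinase-domain
#' constructs rarely start at residue 1.
#'
#' @param path aligned FASTA file with >= 2 sequences.
#' @param numbering optional path to the numbering sidecar TSV, or a named
#'   integer vector.
#' @return a [FamilyAlignment-class]
#' @export
readMsa <- function(path, numbering = NULL) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) < 2L)
    stop("alignment must contain at least 2 sequences")
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers in ", path)
  if (length(unique(Biostrings::width(aa))) != 1L)
    stop("ragged alignment: sequences have unequal gapped lengths")
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids

  starts <- integer(0)
  if (is.character(numbering) && length(numbering) == 1L) {
    sidecar <- utils::read.table(numbering, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
    starts <- as.integer(sidecar[[2L]])
    names(starts) <- as.character(sidecar[[1L]])
  } else if (!is.null(numbering)) {
    starts <- as.integer(numbering)
    names(starts) <- names(numbering)
  }
  new("FamilyAlignment", sequences = seqs, numberingStart = starts)
}

#' Write a family alignment as aligned FASTA
#'
#' @param aln a [FamilyAlignment-class]
#' @param path output FASTA path
#' @param numberingPath optional path for the numbering sidecar TSV
#' @return `path`, invisibly
#' @export
writeMsa <- function(aln, path, numberingPath = NULL) {
  stopifnot(is(aln, "FamilyAlignment"))
  aa <- Biostrings::AAStringSet(aln@sequences)
  Biostrings::writeXStringSet(aa, path)
  if (!is.null(numberingPath)) {
    starts <- aln@numberingStart
    utils::write.table(
      data.frame(id = names(starts), first_resno = unname(starts)),
      numberingPath, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

.firstResno <- function(aln, target) {
  if (target %in% names(aln@numberingStart))
    aln@numberingStart[[target]]
  else 1L
}

#' Map an author residue number to an alignment column
#'
#' Returns the 1-based alignment column whose ungapped position in the
#' target sequence corresponds to `residueNumber` under the target's
#' declared first-residue number.
#'
#' @param aln a [FamilyAlignment-class]
#' @param target sequence identifier of the target (e.g. `"MERTK"`).
#' @param residueNumber author residue number in the target.
#' @return integer column index (1-based)
#' @export
mapPosition <- function(aln, target, residueNumber) {
  stopifnot(is(aln, "FamilyAlignment"))
  if (!target %in% names(aln@sequences))
    stop("target sequence not in alignment: ", target)
  seq <- strsplit(aln@sequences[[target]], "", fixed = TRUE)[[1L]]
  ungapped <- which(seq != "-")
  pos <- as.integer(residueNumber) - .firstResno(aln, target) + 1L
  if (is.na(pos) || pos < 1L || pos > length(ungapped))
    stop("residue number ", residueNumber,
         " is outside the numbering of target '", target, "'")
  ungapped[pos]
}

#' Does an alignment column vary across the family?
#'
#' `TRUE` if any non-target sequence differs from the target letter at the
#' column; a gap in a homolog counts as differing. Comparison is
#' case-insensitive. Family variation at a position disqualifies it as a
#' selective mutation site: the family already tolerates different side
#' chains there, so a substitution is unlikely to discriminate the
#' inhibitor from the nucleotide.
#'
#' @param aln a [FamilyAlignment-class]
#' @param column 1-based column index.
#' @param target identifier of the target sequence.
#' @return logical
#' @export
columnVaries <- function(aln, column, target) {
  stopifnot(is(aln, "FamilyAlignment"))
  if (!target %in% names(aln@sequences))
    stop("target sequence not in alignment: ", target)
  column <- as.integer(column)
  if (column < 1L || column > nchar(aln@sequences[[1L]]))
    stop("column index out of range: ", column)
  letters <- toupper(substr(aln@sequences, column, column))
  ref <- letters[[target]]
  any(letters[names(aln@sequences) != target] != ref)
}
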