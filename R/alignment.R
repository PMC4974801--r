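#' Multiple sequence alignment of haploid sequences
#'
#' Light S3 container for an alignment of \code{n} equal-length haploid
#' nucleotide sequences, the unit every statistic in the package consumes.
#' Sequences are stored uppercase over the alphabet \code{A C G T N -}.
#'
#' @param ids character vector of unique sequence identifiers.
#' @param seqs character vector of sequences, same length as \code{ids},
#'   all of identical nucleotide length.
#' @return An object of class \code{"rp_alignment"} with elements
#'   \code{ids}, \code{seqs}, \code{n} (sequence count) and \code{L}
#'   (alignment length in bp).
#' @examples
#' aln <- alignment(c("a", "b"), c("ACGTA", "ACGTT"))
#' aln$n
#' aln$L
#' @export
alignment <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("ids and seqs must have the same length", call. = FALSE)
  if (length(seqs) == 0L)
    stop("alignment must contain at least one sequence", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate sequence identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(lens)), collapse = ", "), call. = FALSE)
  if (lens[1] < 1L)
    stop("alignment length must be >= 1", call. = FALSE)
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("sequence(s) ", paste(ids[bad], collapse = ", "),
         " contain characters outside {A,C,G,T,N,-}", call. = FALSE)
  structure(list(ids = ids, seqs = seqs, n = length(seqs), L = lens[1]),
            class = "rp_alignment")
}

#' @export
print.rp_alignment <- function(x, ...) {
  cat(sprintf("Alignment of %d sequences, %d bp\n", x$n, x$L))
  invisible(x)
}

#' Convert an alignment to a character matrix
#'
#' @param aln an \code{rp_alignment}.
#' @return \code{n x L} character matrix with sequence ids as rownames.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "rp_alignment"))
  m <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  rownames(m) <- aln$ids
  m
}

#' Read a FASTA multiple sequence alignment
#'
#' Reads a FASTA file and validates it as an alignment: all records the
#' same length, unique identifiers, bases restricted to \code{A C G T N -}
#' (lowercase input is uppercased). Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @return an \code{rp_alignment}.
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path),
                 error = function(e) stop("malformed FASTA file: ", path,
                                          " (", conditionMessage(e), ")",
                                          call. = FALSE))
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  alignment(ids, as.character(ss))
}

#' Write an alignment as FASTA
#'
#' @param aln an \code{rp_alignment}.
#' @param path output file path.
#' @param width line-wrapping width in bases.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 70L) {
  stopifnot(inherits(aln, "rp_alignment"))
  ss <- Biostrings::BStringSet(aln$seqs)
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

## Columns usable under the complete-deletion missing-data policy:
## those containing neither N nor a gap in any sequence.
analysed_columns <- function(mat) {
  which(colSums(mat == "N" | mat == "-") == 0L)
}

#' Restrict an alignment to fully resolved columns
#'
#' Applies the complete-deletion missing-data policy: drops every column
#' in which any sequence carries \code{N} or a gap. All statistics in the
#' package operate on the result; the reported number of sites analysed is
#' the retained length.
#'
#' @param aln an \code{rp_alignment}.
#' @return list with \code{mat} (retained columns as a matrix),
#'   \code{sites} (indices of retained columns in the input), and
#'   \code{L} (number retained).
#' @export
complete_deletion <- function(aln) {
  mat <- alignment_matrix(aln)
  keep <- analysed_columns(mat)
  list(mat = mat[, keep, drop = FALSE], sites = keep, L = length(keep))
}
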