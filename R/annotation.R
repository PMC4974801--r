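#' Annotation table of CDS and intergenic features
#'
#' Builds and validates the package's annotation model: a set of
#' non-overlapping (within a replicon and kind) 1-based inclusive
#' intervals flagged as coding (\code{CDS}, strand-aware, length divisible
#' by 3) or intergenic (\code{IGR}), tied to the reference sequence the
#' coordinates index.
#'
#' @param features data.frame with columns \code{feature_id},
#'   \code{replicon}, \code{start}, \code{end}, \code{strand} (\code{+} or
#'   \code{-}) and \code{kind} (\code{CDS} or \code{IGR}).
#' @param reference_seq named character vector of replicon sequences
#'   (names are replicon identifiers), or a single unnamed sequence when
#'   all features live on one replicon.
#' @return object of class \code{"rp_annotation"}: list with validated
#'   \code{features} and \code{reference_seq}.
#' @export
annotation_table <- function(features, reference_seq) {
  req <- c("feature_id", "replicon", "start", "end", "strand", "kind")
  if (!all(req %in% names(features)))
    stop("annotation needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  features <- as.data.frame(features)[req]
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  reference_seq <- toupper(reference_seq)
  if (is.null(names(reference_seq))) {
    if (length(reference_seq) != 1L)
      stop("unnamed reference_seq must be a single sequence", call. = FALSE)
    names(reference_seq) <- unique(features$replicon)[1]
  }
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature ids", call. = FALSE)
  if (!all(features$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (!all(features$kind %in% c("CDS", "IGR")))
    stop("feature kind must be CDS or IGR", call. = FALSE)
  if (!all(features$replicon %in% names(reference_seq)))
    stop("features reference unknown replicon(s): ",
         paste(setdiff(features$replicon, names(reference_seq)),
               collapse = ", "), call. = FALSE)
  bad <- features$start > features$end | features$start < 1L
  if (any(bad))
    stop("coordinate error: start > end or start < 1 for ",
         paste(features$feature_id[bad], collapse = ", "), call. = FALSE)
  too_long <- features$end > nchar(reference_seq)[features$replicon]
  if (any(too_long))
    stop("coordinate error: feature(s) beyond replicon end: ",
         paste(features$feature_id[too_long], collapse = ", "),
         call. = FALSE)
  len <- features$end - features$start + 1L
  bad_cds <- features$kind == "CDS" & len %% 3L != 0L
  if (any(bad_cds))
    stop("annotation error: CDS length not divisible by 3: ",
         paste(features$feature_id[bad_cds], collapse = ", "),
         call. = FALSE)
  # same-replicon, same-kind features must not overlap
  for (key in split(seq_len(nrow(features)),
                    paste(features$replicon, features$kind))) {
    if (length(key) < 2L) next
    f <- features[key, ]
    f <- f[order(f$start), ]
    if (any(f$start[-1] <= f$end[-nrow(f)]))
      stop("annotation error: overlapping ", f$kind[1], " features on ",
           f$replicon[1], call. = FALSE)
  }
  structure(list(features = features, reference_seq = reference_seq),
            class = "rp_annotation")
}

#' Read an annotation table from TSV
#'
#' The annotation dialect is a plain tab-separated file with the column
#' order \code{feature_id replicon start end strand kind} (header
#' optional, detected from the first line), 1-based inclusive coordinates.
#' Only CDS/IGR intervals and strand are modelled; a GFF3 importer is a
#' documented extension point.
#'
#' @param path path to the TSV feature file.
#' @param reference_seq replicon sequence(s); see [annotation_table()].
#' @return an \code{rp_annotation}.
#' @export
read_annotation <- function(path, reference_seq) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  has_header <- grepl("feature_id", first, fixed = TRUE)
  tab <- utils::read.delim(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (!has_header)
    names(tab) <- c("feature_id", "replicon", "start", "end", "strand",
                    "kind")[seq_len(ncol(tab))]
  annotation_table(tab, reference_seq)
}

#' Write an annotation table as TSV
#'
#' @param ann an \code{rp_annotation}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "rp_annotation"))
  utils::write.table(ann$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a tree as newick text
#'
#' @param tree an [ape::phylo] rooted tree with branch lengths.
#' @return single newick string with branch lengths and leaf labels.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip.label) || any(is.na(tree$tip.label)) ||
      any(tree$tip.label == ""))
    stop("serialization error: unlabeled leaf", call. = FALSE)
  ape::write.tree(tree)
}
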