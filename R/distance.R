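#' Pairwise per-site distance matrix
#'
#' Symmetric matrix of per-site difference proportions between all
#' sequence pairs, on fully resolved columns.
#'
#' @param aln an \code{rp_alignment} with \code{n >= 2}.
#' @return symmetric numeric matrix with zero diagonal, sequence ids as
#'   dimnames.
#' @export
pairwise_distance_matrix <- function(aln) {
  st <- alignment_site_stats(aln)
  n <- aln$n
  d <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      k <- k + 1L
      d[i, j] <- d[j, i] <- if (st$L > 0) st$pair_diffs[k] / st$L else 0
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted average-linkage agglomeration producing a rooted
#' ultrametric tree (every leaf at equal height; a leaf joined at
#' distance d sits d/2 below the join). Ties are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels.
#'
#' @param d symmetric distance matrix with zero diagonal and
#'   non-negative entries, labels as dimnames.
#' @return an [ape::phylo] rooted ultrametric tree.
#' @export
upgma <- function(d) {
  d <- as.matrix(d)
  if (any(d < 0)) stop("input error: negative distance", call. = FALSE)
  if (any(abs(d - t(d)) > 1e-12) || any(diag(d) != 0))
    stop("input error: matrix must be symmetric with zero diagonal",
         call. = FALSE)
  if (is.null(rownames(d)))
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  if (nrow(d) == 1L) {
    tr <- list(edge = matrix(integer(0), 0, 2), tip.label = rownames(d),
               Nnode = 0L, edge.length = numeric(0))
    class(tr) <- "phylo"
    return(tr)
  }
  # lexicographic label order fixes hclust's index-based tie-breaking
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::as.phylo(hc)
}
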