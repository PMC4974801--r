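BASES <- c("A", "C", "G", "T")

## Standard genetic code, keyed by codon; "*" marks stops.
codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

is_stop_codon <- function(codon) {
  identical(codon_aa(codon), "*")
}

#' Degeneracy fold class of a codon position
#'
#' Counts how many of the four bases at a codon position leave the encoded
#' amino acid unchanged under the standard genetic code: 4 bases all
#' synonymous gives a 4-fold site, a unique base a 0-fold site, with
#' 2-fold and 3-fold (isoleucine third positions) in between. Changes that
#' create a stop codon never count as synonymous.
#'
#' @param codon 3-character string over \code{A C G T}, not a stop codon.
#' @param site_index codon position, 1, 2 or 3.
#' @return integer fold class: 0, 2, 3 or 4.
#' @examples
#' codon_degeneracy("GGG", 3) # 4-fold (glycine)
#' codon_degeneracy("ATG", 1) # 0-fold (methionine)
#' codon_degeneracy("ATT", 3) # 3-fold (isoleucine)
#' @export
codon_degeneracy <- function(codon, site_index) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || grepl("[^ACGT]", codon))
    stop("degeneracy error: codon must be 3 bases over ACGT, got '",
         codon, "'", call. = FALSE)
  if (!site_index %in% 1:3)
    stop("site_index must be 1, 2 or 3", call. = FALSE)
  aa <- codon_aa(codon)
  if (aa == "*")
    stop("excluded-codon error: stop codon ", codon, call. = FALSE)
  vars <- vapply(BASES, function(b) {
    mut <- codon
    substr(mut, site_index, site_index) <- b
    identical(codon_aa(mut), aa)
  }, logical(1))
  k <- sum(vars)
  c(`1` = 0L, `2` = 2L, `3` = 3L, `4` = 4L)[[as.character(k)]]
}

split_codons <- function(cds) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop("CDS length not divisible by 3", call. = FALSE)
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Count degenerate sites in a set of coding sequences
#'
#' Tallies 0-, 2-, 3- and 4-fold degenerate sites over all codon positions
#' of the supplied CDSs. Stop codons (terminal or otherwise) are excluded
#' from the tally; 3-fold sites are reported as their own class rather
#' than folded into the 2- or 4-fold bins.
#'
#' @param cds_seqs character vector of CDS sequences (each divisible by 3).
#' @return list with counts \code{zero_fold}, \code{two_fold},
#'   \code{three_fold}, \code{four_fold} and \code{total} (coding sites
#'   tallied, i.e. 3 per non-stop codon).
#' @export
degeneracy_counts <- function(cds_seqs) {
  if (length(cds_seqs) == 0L) stop("empty CDS set", call. = FALSE)
  counts <- c(`0` = 0L, `2` = 0L, `3` = 0L, `4` = 0L)
  for (cds in cds_seqs) {
    for (codon in split_codons(cds)) {
      if (is_stop_codon(codon)) next
      for (p in 1:3) {
        f <- as.character(codon_degeneracy(codon, p))
        counts[f] <- counts[f] + 1L
      }
    }
  }
  list(zero_fold = unname(counts["0"]), two_fold = unname(counts["2"]),
       three_fold = unname(counts["3"]), four_fold = unname(counts["4"]),
       total = sum(counts))
}

## Per-codon synonymous / non-synonymous mutation opportunities.
## Returns c(syn, nonsyn) counts over the 9 single-base changes.
codon_opportunities <- function(codon) {
  aa <- codon_aa(codon)
  syn <- 0L; nonsyn <- 0L
  for (p in 1:3) {
    for (b in setdiff(BASES, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      maa <- codon_aa(mut)
      # mutations creating a stop count as non-synonymous
      if (identical(maa, aa) && maa != "*") syn <- syn + 1L
      else nonsyn <- nonsyn + 1L
    }
  }
  c(syn = syn, nonsyn = nonsyn)
}

#' Expected non-synonymous/synonymous mutation-opportunity ratio
#'
#' Null expectation for the nsSNP/sSNP ratio under equal mutation
#' probability at every coding position and no selection: every one of the
#' three possible single-base changes at every CDS position is enumerated
#' and classified by the standard genetic code, and the ratio of
#' non-synonymous to synonymous opportunities is returned. Stop codons in
#' the input are skipped; changes that create a stop count as
#' non-synonymous.
#'
#' @param cds_seqs character vector of CDS sequences.
#' @return ratio (dimensionless) of non-synonymous to synonymous
#'   single-base mutation opportunities.
#' @examples
#' expected_ns_s_ratio("ATGGGG") # 15/3 = 5
#' @export
expected_ns_s_ratio <- function(cds_seqs) {
  if (length(cds_seqs) == 0L) stop("empty CDS set", call. = FALSE)
  tot <- c(syn = 0L, nonsyn = 0L)
  for (cds in cds_seqs) {
    for (codon in split_codons(cds)) {
      if (is_stop_codon(codon)) next
      tot <- tot + codon_opportunities(codon)
    }
  }
  if (tot["syn"] == 0L)
    stop("no synonymous opportunities in CDS set", call. = FALSE)
  unname(tot["nonsyn"] / tot["syn"])
}

#' Synonymous and non-synonymous site counts for a CDS set
#'
#' Counts synonymous and non-synonymous sites in the Nei-Gojobori sense:
#' each codon position contributes (number of synonymous one-step
#' changes)/3 synonymous sites and the complement non-synonymous sites.
#' Used as the per-class L when computing Tajima's D restricted to
#' synonymous or non-synonymous variation.
#'
#' @param cds_seqs character vector of CDS sequences.
#' @return list with \code{syn_sites} and \code{nonsyn_sites} (fractional
#'   site counts summing to 3 per non-stop codon).
#' @export
synonymous_site_counts <- function(cds_seqs) {
  if (length(cds_seqs) == 0L) stop("empty CDS set", call. = FALSE)
  syn <- 0
  total <- 0
  for (cds in cds_seqs) {
    for (codon in split_codons(cds)) {
      if (is_stop_codon(codon)) next
      op <- codon_opportunities(codon)
      syn <- syn + op["syn"] / 3
      total <- total + 3
    }
  }
  list(syn_sites = unname(syn), nonsyn_sites = unname(total - syn))
}
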