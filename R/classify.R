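#' Construct a SNP record
#'
#' @param replicon replicon name.
#' @param position 1-based position on the replicon.
#' @param ref_allele,alt_allele single reference / variant bases (differ).
#' @param snp_class one of \code{"sSNP"}, \code{"nsSNP"}, \code{"iSNP"}.
#' @param feature_id host CDS id, or \code{NA} for intergenic SNPs.
#' @return one-row data.frame of class \code{"rp_snp_record"}.
#' @export
snp_record <- function(replicon, position, ref_allele, alt_allele,
                       snp_class, feature_id = NA_character_) {
  if (ref_allele == alt_allele)
    stop("ref and alt alleles must differ", call. = FALSE)
  if (!snp_class %in% c("sSNP", "nsSNP", "iSNP"))
    stop("snp_class must be sSNP, nsSNP or iSNP", call. = FALSE)
  if (xor(snp_class == "iSNP", is.na(feature_id)))
    stop("iSNP records (and only those) must lack a feature_id",
         call. = FALSE)
  rec <- data.frame(replicon = replicon, position = as.integer(position),
                    ref_allele = ref_allele, alt_allele = alt_allele,
                    snp_class = snp_class, feature_id = feature_id,
                    stringsAsFactors = FALSE)
  class(rec) <- c("rp_snp_record", class(rec))
  rec
}

## Locate the CDS feature (if any) covering a position on a replicon.
host_cds <- function(ann, replicon, position) {
  f <- ann$features
  hit <- which(f$replicon == replicon & f$kind == "CDS" &
                 f$start <= position & f$end >= position)
  if (length(hit) == 0L) NULL else f[hit[1], ]
}

#' Classify a variant as synonymous, non-synonymous or intergenic
#'
#' A variant outside every annotated CDS is an iSNP. Inside a CDS the
#' affected codon is reconstructed strand-aware (reverse-complemented for
#' minus-strand features) and translated with the reference and the
#' alternate base: same amino acid gives an sSNP, anything else (including
#' a gained stop) an nsSNP. Start and stop codons are classified by the
#' same translation rule as any other codon.
#'
#' @param position 1-based position on the replicon.
#' @param ref single reference base; must match the reference sequence.
#' @param alt single alternate base.
#' @param annotation an \code{rp_annotation}.
#' @param replicon replicon name; defaults to the annotation's only
#'   replicon.
#' @return an \code{rp_snp_record} with the assigned class.
#' @export
classify_snp <- function(position, ref, alt, annotation,
                         replicon = names(annotation$reference_seq)[1]) {
  stopifnot(inherits(annotation, "rp_annotation"))
  ref <- toupper(ref); alt <- toupper(alt)
  refseq <- annotation$reference_seq[[replicon]]
  if (is.null(refseq) || is.na(refseq))
    stop("unknown replicon: ", replicon, call. = FALSE)
  if (position < 1L || position > nchar(refseq))
    stop("coordinate error: position ", position, " outside replicon ",
         replicon, call. = FALSE)
  at <- substr(refseq, position, position)
  if (at != ref)
    stop("consistency error: reference has ", at, " at ", replicon, ":",
         position, ", not ", ref, call. = FALSE)
  if (ref == alt) stop("ref and alt alleles must differ", call. = FALSE)
  cds <- host_cds(annotation, replicon, position)
  if (is.null(cds))
    return(snp_record(replicon, position, ref, alt, "iSNP"))
  # offset within the coding frame, on the coding strand
  if (cds$strand == "+") {
    off <- position - cds$start            # 0-based along coding strand
    ref_c <- ref; alt_c <- alt
  } else {
    off <- cds$end - position
    ref_c <- revcomp(ref); alt_c <- revcomp(alt)
  }
  codon_i <- off %/% 3L
  pos_in <- off %% 3L + 1L
  cds_seq <- substr(refseq, cds$start, cds$end)
  if (cds$strand == "-") cds_seq <- revcomp(cds_seq)
  codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  mut <- codon
  substr(mut, pos_in, pos_in) <- alt_c
  cls <- if (identical(codon_aa(codon), codon_aa(mut))) "sSNP" else "nsSNP"
  snp_record(replicon, position, ref, alt, cls, cds$feature_id)
}

revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]),
                                 collapse = ""))
}

#' Summarise SNP classes
#'
#' Per-class counts and percentages plus the observed nsSNP/sSNP ratio,
#' the accounting behind a segregating-nucleotide-types table. With zero
#' sSNPs the ratio is reported as \code{NA} (undefined), never infinity.
#'
#' @param records data.frame of SNP records (needs a \code{snp_class}
#'   column), e.g. rbind of [classify_snp()] results.
#' @return list with \code{counts} (named integer vector over
#'   sSNP/nsSNP/iSNP), \code{total}, \code{fractions} (percent, 1
#'   decimal), and \code{ns_s_ratio} (2 decimals, \code{NA} if undefined).
#' @export
snp_class_summary <- function(records) {
  if (NROW(records) == 0L) stop("no SNP records", call. = FALSE)
  cls <- factor(records$snp_class, levels = c("sSNP", "nsSNP", "iSNP"))
  counts <- table(cls)
  total <- sum(counts)
  fractions <- round(100 * as.numeric(counts) / total, 1)
  names(fractions) <- names(counts)
  ratio <- if (counts[["sSNP"]] > 0L)
    round(counts[["nsSNP"]] / counts[["sSNP"]], 2) else NA_real_
  list(counts = c(sSNP = counts[["sSNP"]], nsSNP = counts[["nsSNP"]],
                  iSNP = counts[["iSNP"]]),
       total = total, fractions = fractions, ns_s_ratio = ratio)
}

#' Default per-site variant filter thresholds
#'
#' Thresholds used for accepting a variant call at a site: minimum read
#' coverage 6, maximum variant P-value 6e-6, minimum strand-bias P-value
#' 5e-5 applied only when strand bias exceeds 65 %, and the variant base
#' required in at least 95 % of unique reads.
#'
#' @return named list of thresholds.
#' @export
default_filter_thresholds <- function() {
  list(min_coverage = 6L, max_variant_p = 6e-6,
       min_strand_bias_p = 5e-5, strand_bias_trigger = 0.65,
       min_alt_fraction_unique = 0.95)
}

#' Summary of read support for a candidate variant site
#'
#' @param coverage total reads at the site.
#' @param alt_reads reads supporting the variant (\code{<= coverage}).
#' @param variant_p variant quality P-value in [0,1].
#' @param strand_bias_p strand-bias P-value in [0,1].
#' @param alt_fraction_unique fraction of unique reads carrying the
#'   variant, in [0,1].
#' @param strand_bias fraction of variant reads on the majority strand
#'   (0.5 = perfectly balanced); drives whether the strand-bias P-value
#'   sub-filter applies.
#' @return list of class \code{"rp_site_summary"}.
#' @export
variant_site_summary <- function(coverage, alt_reads, variant_p,
                                 strand_bias_p, alt_fraction_unique,
                                 strand_bias = 0.5) {
  if (alt_reads > coverage || alt_reads < 0L || coverage < 0L)
    stop("input error: need 0 <= alt_reads <= coverage", call. = FALSE)
  probs <- c(variant_p, strand_bias_p, alt_fraction_unique, strand_bias)
  if (any(probs < 0 | probs > 1))
    stop("input error: probabilities/fractions must lie in [0,1]",
         call. = FALSE)
  structure(list(coverage = coverage, alt_reads = alt_reads,
                 variant_p = variant_p, strand_bias_p = strand_bias_p,
                 alt_fraction_unique = alt_fraction_unique,
                 strand_bias = strand_bias),
            class = "rp_site_summary")
}

#' Apply per-site variant filters
#'
#' Accepts a site iff every applicable condition holds: coverage at least
#' the minimum, variant P-value at most the maximum, variant base in at
#' least the required fraction of unique reads, and - only when strand
#' bias exceeds the trigger fraction - strand-bias P-value at least the
#' minimum. A rejection carries the codes of every failed condition.
#'
#' @param site an \code{rp_site_summary}.
#' @param thresholds list as from [default_filter_thresholds()].
#' @return list with \code{accept} (logical) and \code{reasons}
#'   (character vector of failed-condition codes, empty when accepted).
#' @export
apply_snp_filters <- function(site, thresholds = default_filter_thresholds()) {
  stopifnot(inherits(site, "rp_site_summary"))
  reasons <- character(0)
  if (site$coverage < thresholds$min_coverage)
    reasons <- c(reasons, "coverage")
  if (site$variant_p > thresholds$max_variant_p)
    reasons <- c(reasons, "variant-p")
  if (site$strand_bias > thresholds$strand_bias_trigger &&
      site$strand_bias_p < thresholds$min_strand_bias_p)
    reasons <- c(reasons, "strand-bias")
  if (site$alt_fraction_unique < thresholds$min_alt_fraction_unique)
    reasons <- c(reasons, "allele-fraction")
  list(accept = length(reasons) == 0L, reasons = reasons)
}

#' Read a variant TSV and classify every record
#'
#' Input columns: \code{replicon position ref alt} and optionally the
#' read-support columns \code{coverage alt_reads variant_p strand_bias_p
#' alt_fraction_unique [strand_bias]}; when present, sites failing
#' [apply_snp_filters()] are dropped before classification.
#'
#' @param path variant TSV (with header).
#' @param annotation an \code{rp_annotation}.
#' @param thresholds filter thresholds; see [default_filter_thresholds()].
#' @return data.frame of classified SNP records.
#' @export
classify_variant_table <- function(path, annotation,
                                   thresholds = default_filter_thresholds()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  has_support <- all(c("coverage", "alt_reads", "variant_p",
                       "strand_bias_p", "alt_fraction_unique") %in%
                       names(tab))
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    if (has_support) {
      sb <- if ("strand_bias" %in% names(tab)) r$strand_bias else 0.5
      site <- variant_site_summary(r$coverage, r$alt_reads, r$variant_p,
                                   r$strand_bias_p,
                                   r$alt_fraction_unique, sb)
      if (!apply_snp_filters(site, thresholds)$accept) next
    }
    out[[i]] <- classify_snp(r$position, r$ref, r$alt, annotation,
                             replicon = r$replicon)
  }
  recs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(recs)) stop("no variants passed the filters", call. = FALSE)
  recs
}
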