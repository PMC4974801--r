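test_that("codon degeneracy fold classes follow the standard code", {
  expect_equal(codon_degeneracy("GGG", 3), 4) # glycine third position
  expect_equal(codon_degeneracy("ATG", 1), 0) # methionine, unique codon
  expect_equal(codon_degeneracy("AAT", 3), 2) # Asn AAT/AAC
  expect_equal(codon_degeneracy("ATT", 3), 3) # Ile ATT/ATC/ATA
  expect_equal(codon_degeneracy("TGG", 3), 0) # Trp; TGA change is a stop
  expect_error(codon_degeneracy("ANT", 3), "degeneracy error")
  expect_error(codon_degeneracy("TAA", 3), "excluded-codon")
})

test_that("degeneracy counts partition every non-stop coding site", {
  set.seed(21)
  for (rep in 1:5) {
    cds <- random_cds(sample(5:20, 1))
    dc <- degeneracy_counts(cds)
    expect_equal(dc$zero_fold + dc$two_fold + dc$three_fold +
                   dc$four_fold, dc$total)
    expect_equal(dc$total, nchar(cds)) # no stops inside random_cds
  }
})

test_that("expected ns/s ratio equals brute-force enumeration exactly", {
  expect_equal(expected_ns_s_ratio("ATGGGG"), 5) # 15 ns / 3 s changes
  set.seed(31)
  for (rep in 1:8) {
    cds_set <- vapply(seq_len(sample(1:4, 1)),
                      function(i) random_cds(sample(3:15, 1)),
                      character(1))
    expect_identical(expected_ns_s_ratio(cds_set),
                     oracle_ns_s_ratio(cds_set))
  }
  expect_error(expected_ns_s_ratio(character(0)), "empty")
})

test_that("classify_snp resolves coding and intergenic variants", {
  ref <- c(chr = "ATGGGGTTTTTT")
  ann <- annotation_table(
    data.frame(feature_id = "g1", replicon = "chr", start = 1, end = 6,
               strand = "+", kind = "CDS"), ref)
  expect_equal(classify_snp(6, "G", "A", ann)$snp_class, "sSNP")
  expect_equal(classify_snp(4, "G", "A", ann)$snp_class, "nsSNP")
  r <- classify_snp(10, "T", "C", ann)
  expect_equal(r$snp_class, "iSNP")
  expect_true(is.na(r$feature_id))
  expect_error(classify_snp(4, "C", "A", ann), "consistency error")
  expect_error(classify_snp(99, "G", "A", ann), "coordinate error")
})

test_that("minus-strand classification equals the reverse-complement construction", {
  set.seed(41)
  for (rep in 1:10) {
    cds <- random_cds(6) # 18 bp
    rc <- rhizopop:::revcomp(cds)
    ann_plus <- annotation_table(
      data.frame(feature_id = "g", replicon = "chr", start = 1, end = 18,
                 strand = "+", kind = "CDS"), c(chr = cds))
    ann_minus <- annotation_table(
      data.frame(feature_id = "g", replicon = "chr", start = 1, end = 18,
                 strand = "-", kind = "CDS"), c(chr = rc))
    pos <- sample(18, 1)
    ref_p <- substr(cds, pos, pos)
    alt_p <- sample(setdiff(c("A", "C", "G", "T"), ref_p), 1)
    cls_plus <- classify_snp(pos, ref_p, alt_p, ann_plus)$snp_class
    # same biological change seen from the minus strand
    mpos <- 18 - pos + 1
    cls_minus <- classify_snp(mpos, rhizopop:::revcomp(ref_p),
                              rhizopop:::revcomp(alt_p),
                              ann_minus)$snp_class
    expect_identical(cls_plus, cls_minus)
  }
})

test_that("SNP class summary reports counts, fractions and the ns/s ratio", {
  recs <- data.frame(snp_class = rep(c("sSNP", "nsSNP", "iSNP"),
                                     c(109, 178, 83)))
  s <- snp_class_summary(recs)
  expect_equal(s$total, 370)
  expect_equal(s$ns_s_ratio, 1.63)
  expect_equal(unname(s$fractions), c(29.5, 48.1, 22.4))
  expect_equal(sum(s$fractions), 100, tolerance = 0.1)
  s2 <- snp_class_summary(data.frame(snp_class = c("sSNP", "nsSNP")))
  expect_equal(s2$ns_s_ratio, 1)
  expect_equal(unname(s2$fractions), c(50, 50, 0))
  s3 <- snp_class_summary(data.frame(snp_class = rep("nsSNP", 5)))
  expect_true(is.na(s3$ns_s_ratio))
})

test_that("variant filters implement the two-part acceptance rule", {
  th <- default_filter_thresholds()
  ok <- variant_site_summary(60, 60, 1e-8, 1, 1.0)
  expect_true(apply_snp_filters(ok, th)$accept)
  low_cov <- variant_site_summary(5, 5, 1e-8, 1, 1.0)
  r <- apply_snp_filters(low_cov, th)
  expect_false(r$accept); expect_equal(r$reasons, "coverage")
  low_frac <- variant_site_summary(60, 58, 1e-8, 1, 0.94)
  r <- apply_snp_filters(low_frac, th)
  expect_false(r$accept); expect_equal(r$reasons, "allele-fraction")
  # strand-bias P threshold applies only above 65 % bias
  biased <- variant_site_summary(60, 60, 1e-8, 1e-6, 1.0,
                                 strand_bias = 0.9)
  expect_equal(apply_snp_filters(biased, th)$reasons, "strand-bias")
  balanced <- variant_site_summary(60, 60, 1e-8, 1e-6, 1.0,
                                   strand_bias = 0.5)
  expect_true(apply_snp_filters(balanced, th)$accept)
  expect_error(variant_site_summary(5, 6, 0.5, 0.5, 0.5),
               "input error")
})

test_that("classifier recovers planted SNP classes from variant tables", {
  genome <- generate_toy_genome(n_cds = 6, cds_len = 30, igr_len = 15,
                                seed = 7)
  snps <- plant_snps(genome, n_ssnp = 8, n_nssnp = 12, n_isnp = 5,
                     seed = 8)
  for (i in seq_len(nrow(snps))) {
    got <- classify_snp(snps$position[i], snps$ref_allele[i],
                        snps$alt_allele[i], genome$annotation)
    expect_identical(got$snp_class, snps$snp_class[i])
  }
  # through the TSV path, with read support columns and one failing site
  tab <- data.frame(replicon = snps$replicon, position = snps$position,
                    ref = snps$ref_allele, alt = snps$alt_allele,
                    coverage = 50, alt_reads = 50, variant_p = 1e-8,
                    strand_bias_p = 1, alt_fraction_unique = 1)
  tab$coverage[1] <- 3; tab$alt_reads[1] <- 3 # fails the coverage filter
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- classify_variant_table(f, genome$annotation)
  expect_equal(nrow(recs), nrow(snps) - 1)
})
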