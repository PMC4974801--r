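test_that("segregating sites and pi match naive scans on random alignments", {
  set.seed(101)
  for (rep in 1:8) {
    aln <- random_alignment(5, 50, alphabet = c("A", "C", "G", "T",
                                                "N", "-"))
    expect_equal(segregating_sites(aln), oracle_segregating_sites(aln$seqs))
    if (sum(!grepl("N|-", strsplit(aln$seqs[1], "")[[1]])) > 0)
      expect_equal(nucleotide_diversity(aln), oracle_pi(aln$seqs),
                   tolerance = 1e-12)
  }
  ident <- alignment(c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(segregating_sites(ident), 0)
  expect_equal(nucleotide_diversity(ident), 0)
  two <- alignment(c("a", "b"), c("ACGTACGTAC", "TCGTACGTAT"))
  expect_equal(segregating_sites(two), 2)
  expect_equal(nucleotide_diversity(two), 0.2)
})

test_that("Watterson's theta follows S/(a1 L)", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(5, 2, 100), 0.05) # a1 = 1 at n = 2
  expect_equal(signif(watterson_theta(123, 14, 146721), 3), 0.000264)
})

test_that("Tajima's D matches the textbook constant formula", {
  set.seed(111)
  for (rep in 1:10) {
    n <- sample(4:20, 1); S <- sample(1:200, 1)
    k_bar <- runif(1, 0, S)
    expect_equal(tajima_d(k_bar, S, n), oracle_tajima_d(k_bar, S, n),
                 tolerance = 1e-12)
  }
  a1 <- sum(1 / (1:13))
  expect_equal(tajima_d(50 / a1, 50, 14), 0, tolerance = 1e-12)
  expect_true(is_undefined_stat(tajima_d(0, 0, 14)))
})

test_that("Fu & Li's D* and F* match an independent transcription", {
  set.seed(121)
  for (rep in 1:12) {
    n <- sample(5:10, 1)
    eta <- sample(1:100, 1)
    eta_s <- sample(0:eta, 1)
    k_bar <- runif(1, 0, eta)
    o <- oracle_fu_li(eta, eta_s, k_bar, n)
    expect_equal(fu_li_d_star(eta, eta_s, n), o$d_star,
                 tolerance = 1e-12)
    expect_equal(fu_li_f_star(k_bar, eta, eta_s, n), o$f_star,
                 tolerance = 1e-12)
  }
  expect_true(is_undefined_stat(fu_li_d_star(0, 0, 14)))
  expect_true(is_undefined_stat(fu_li_f_star(1, 0, 0, 14)))
})

test_that("Ewens haplotype distribution matches the CRP recursion", {
  for (n in 3:6) for (theta in c(0.3, 1, 4.7)) {
    pkg <- ewens_haplotype_pmf(n, theta)
    crp <- oracle_ewens_K(n, theta)
    expect_equal(pkg, crp, tolerance = 1e-12)
    expect_equal(sum(pkg), 1, tolerance = 1e-12)
  }
})

test_that("Fu's Fs behaves across tails and degenerate cases", {
  # tail beyond k_obs via the pmf
  pmf <- ewens_haplotype_pmf(5, 2)
  sp <- sum(pmf[3:5])
  expect_equal(fu_fs(2, 3, 5), log(sp / (1 - sp)), tolerance = 1e-12)
  # every sequence identical in state: S' = 1, flagged infinity
  f <- fu_fs(2, 1, 5)
  expect_true(is.infinite(f) && f > 0)
  expect_true(is_undefined_stat(f))
  expect_true(is_undefined_stat(fu_fs(0, 1, 5)))
})

test_that("R2 equals its closed form at n = 2 and a hand-computed n = 4 case", {
  aln2 <- alignment(c("a", "b"), c("ACGTACGTAC", "TCGTACGTAT"))
  expect_equal(r2_statistic(aln2), 0.5)
  # n = 4, S = 2: one singleton in s1 (col 1), one in s2 (col 5)
  aln4 <- alignment(c("a", "b", "c", "d"),
                    c("TAAAA", "AAAAC", "AAAAA", "AAAAA"))
  # U = (1,1,0,0); k_bar = (2 cols: each differs in 3 of 6 pairs) = 1
  U <- c(1, 1, 0, 0); k_bar <- 1; S <- 2
  expect_equal(r2_statistic(aln4),
               sqrt(mean((U - k_bar / 2)^2)) / S)
  # permutation invariance
  perm <- alignment(c("d", "c", "b", "a"),
                    c("AAAAA", "AAAAA", "AAAAC", "TAAAA"))
  expect_equal(r2_statistic(perm), r2_statistic(aln4))
})

test_that("neutrality summary bundles consistent components", {
  m <- demographic_model("constant", theta = 5)
  sim <- simulate_coalescent(8, m, 1e5, seed = 99)
  ns <- neutrality_summary(sim$alignment)
  p <- sim$parts
  expect_equal(ns$S, p$S)
  expect_equal(ns$eta, p$eta)
  expect_equal(ns$eta_singletons, p$eta_singletons)
  expect_equal(ns$k_bar, p$k_bar, tolerance = 1e-12)
  expect_equal(ns$n_haplotypes, p$n_haplotypes)
  expect_true(ns$S <= ns$eta)
  expect_equal(ns$pi, ns$k_bar / ns$L)
})

test_that("per-class Tajima's D matches a split-then-compute oracle", {
  genome <- generate_toy_genome(n_cds = 8, cds_len = 60, igr_len = 0,
                                seed = 17)
  L <- nchar(genome$reference)
  # plant synonymous and non-synonymous variants into 6 copies
  snps <- plant_snps(genome, n_ssnp = 10, n_nssnp = 14, n_isnp = 0,
                     seed = 18)
  n <- 6
  mat <- matrix(rep(strsplit(genome$reference, "")[[1]], n), nrow = n,
                byrow = TRUE)
  set.seed(19)
  carriers <- lapply(seq_len(nrow(snps)), function(i)
    sample(n, sample(1:(n - 1), 1)))
  for (i in seq_len(nrow(snps)))
    mat[carriers[[i]], snps$position[i]] <- snps$alt_allele[i]
  aln <- alignment(sprintf("s%d", 1:n), apply(mat, 1, paste,
                                              collapse = ""))
  for (cls in c("synonymous", "non-synonymous")) {
    res <- tajima_d_by_class(aln, genome$annotation, cls)
    want_cls <- if (cls == "synonymous") "sSNP" else "nsSNP"
    keep <- snps$position[snps$snp_class == want_cls]
    sub <- alignment(aln$ids,
                     apply(mat[, keep, drop = FALSE], 1, paste,
                           collapse = ""))
    st <- rhizopop:::alignment_site_stats(sub)
    expect_equal(res$S, st$S)
    expect_equal(as.numeric(res$D), as.numeric(tajima_d(st$k_bar, st$S, n)),
                 tolerance = 1e-12)
  }
  # monomorphic alignment: both classes undefined
  mono <- alignment(sprintf("s%d", 1:n),
                    rep(genome$reference, n))
  expect_true(is_undefined_stat(
    tajima_d_by_class(mono, genome$annotation, "synonymous")$D))
})

test_that("significance buckets are deterministic and centered nulls are ns", {
  b1 <- neutrality_significance("tajima_d", -0.05, 10, 20, reps = 400,
                                seed = 7)
  b2 <- neutrality_significance("tajima_d", -0.05, 10, 20, reps = 400,
                                seed = 7)
  expect_identical(as.character(b1), as.character(b2))
  expect_identical(as.character(b1), "ns")
  expect_error(neutrality_significance("unknown", 0, 10, 20),
               "dispatch error")
})

test_that("UPGMA produces the hand-derived ultrametric tree", {
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(d)
  expect_true(ape::is.ultrametric(tr))
  # ((A,B),C) with join heights 1 and 3
  depth <- ape::node.depth.edgelength(tr)
  expect_equal(max(depth[1:3]), 3)
  mrca_ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(max(depth) - depth[mrca_ab], 0 + 1, tolerance = 1e-12)
  # identical sequences join at height zero
  aln <- alignment(c("x", "y", "z"), c("AAAA", "AAAA", "TTAA"))
  dz <- pairwise_distance_matrix(aln)
  trz <- upgma(dz)
  expect_equal(min(trz$edge.length), 0)
  # taxon input order does not change the topology
  ord <- c(3, 1, 2)
  tr2 <- upgma(d[ord, ord])
  expect_true(ape::all.equal.phylo(tr2, tr, use.edge.length = FALSE))
  expect_error(upgma(matrix(c(0, -1, -1, 0), 2, 2)), "negative")
})
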