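## Flagged undefined statistic: NA carrying the reason, never a silent NaN.
undefined_stat <- function(reason) {
  structure(NA_real_, undefined = reason)
}

#' Is a statistic flagged as undefined?
#' @param x value returned by a statistic in this package.
#' @return logical; the flag reason is in \code{attr(x, "undefined")}.
#' @export
is_undefined_stat <- function(x) {
  !is.null(attr(x, "undefined"))
}

harmonic <- function(m) if (m < 1) 0 else sum(1 / seq_len(m))
harmonic2 <- function(m) if (m < 1) 0 else sum(1 / seq_len(m)^2)

## Column-level summaries of an alignment under complete deletion.
## Everything downstream (S, eta, singletons, k_bar, haplotypes, R2's U_i)
## derives from the per-column allele counts computed here.
alignment_site_stats <- function(aln) {
  stopifnot(inherits(aln, "rp_alignment"))
  if (aln$n < 2L) stop("need n >= 2 sequences", call. = FALSE)
  cd <- complete_deletion(aln)
  mat <- cd$mat
  n <- aln$n
  L <- cd$L
  if (L == 0L)
    return(list(n = n, L = 0L, S = 0L, eta = 0L, eta_singletons = 0L,
                k_bar = 0, U = rep(0L, n), n_haplotypes = 1L,
                seg_cols = integer(0), pair_diffs = rep(0L, n * (n - 1) / 2)))
  counts <- vapply(BASES, function(b) .colSums(mat == b, n, L), numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, BASES))
  n_alleles <- rowSums(counts > 0)
  seg <- which(n_alleles >= 2L)
  S <- length(seg)
  eta_col <- pmax(n_alleles - 1L, 0L)
  eta <- sum(eta_col)
  single_alleles <- rowSums(counts == 1L)
  eta_s <- sum(pmin(single_alleles, eta_col))
  # pairs differing at each column, from allele counts
  same_pairs <- rowSums(counts * (counts - 1)) / 2
  diff_pairs <- n * (n - 1) / 2 - same_pairs
  k_bar <- sum(diff_pairs) / (n * (n - 1) / 2)
  # per-sequence singleton loads (alleles seen exactly once)
  U <- integer(n)
  if (S > 0L) {
    segmat <- mat[, seg, drop = FALSE]
    segcnt <- counts[seg, , drop = FALSE]
    for (i in seq_len(n)) {
      ci <- segcnt[cbind(seq_len(S), match(segmat[i, ], BASES))]
      U[i] <- sum(ci == 1L)
    }
    haps <- apply(segmat, 1L, paste, collapse = "")
  } else haps <- rep("", n)
  # full pairwise difference counts (mismatch distribution input)
  pair_diffs <- integer(n * (n - 1) / 2)
  if (S > 0L) {
    k <- 0L
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        k <- k + 1L
        pair_diffs[k] <- sum(segmat[i, ] != segmat[j, ])
      }
    }
  }
  list(n = n, L = L, S = S, eta = eta, eta_singletons = eta_s,
       k_bar = k_bar, U = U, n_haplotypes = length(unique(haps)),
       seg_cols = cd$sites[seg], pair_diffs = pair_diffs)
}

#' Number of segregating sites
#'
#' Counts alignment columns holding two or more distinct bases, after
#' complete deletion of columns containing \code{N} or gaps.
#'
#' @param aln an \code{rp_alignment} with \code{n >= 2}.
#' @return integer count S.
#' @export
segregating_sites <- function(aln) {
  alignment_site_stats(aln)$S
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site pairwise difference over all n(n-1)/2 sequence pairs on
#' the analysed (fully resolved) sites. Raw proportions; no multiple-hit
#' correction is applied, appropriate at the low diversities
#' (pi ~ 1e-4) this package targets.
#'
#' @param aln an \code{rp_alignment} with \code{n >= 2}.
#' @return pi, per site.
#' @export
nucleotide_diversity <- function(aln) {
  st <- alignment_site_stats(aln)
  if (st$L == 0L) return(0)
  st$k_bar / st$L
}

#' Watterson's theta per site
#'
#' \eqn{\theta_W = S / (a_1 L)} with \eqn{a_1 = \sum_{i=1}^{n-1} 1/i}.
#'
#' @param S segregating sites.
#' @param n sequence count (>= 2).
#' @param L sites analysed (>= 1).
#' @return theta per site.
#' @examples
#' watterson_theta(123, 14, 146721) # ~0.000264
#' @export
watterson_theta <- function(S, n, L) {
  stopifnot(n >= 2, L >= 1, S >= 0)
  S / (harmonic(n - 1) * L)
}

## Tajima (1989) normalizing constants.
tajima_constants <- function(n) {
  a1 <- harmonic(n - 1)
  a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-difference and
#' segregating-sites estimators of theta:
#' \eqn{D = (\bar k - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}}. Negative D
#' indicates an excess of rare variants, as after a population expansion
#' or under purifying selection.
#'
#' @param k_bar mean pairwise differences per sequence pair (per locus,
#'   not per site).
#' @param S segregating sites (>= 1 for a defined value).
#' @param n sequence count.
#' @return D, or a flagged undefined value when S = 0
#'   (see [is_undefined_stat()]).
#' @examples
#' tajima_d(0.000135 * 146721, 123, 14) # ~ -2.18
#' @export
tajima_d <- function(k_bar, S, n) {
  stopifnot(n >= 2)
  if (S == 0) return(undefined_stat("S = 0"))
  cst <- tajima_constants(n)
  (k_bar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

## Fu & Li (1993) D*/F* constants, corrected variance version
## (the transcription used by DnaSP / libsequence).
fu_li_constants <- function(n) {
  an <- harmonic(n - 1)
  bn <- harmonic2(n - 1)
  an1 <- harmonic(n) # a_{n+1}
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (1.5 - (2 * an1 - 3) / (n - 2) - 1 / n)
  v_dstar <- ((n / (n - 1))^2 * bn + an^2 * dn -
                2 * (n * an * (an + 1)) / (n - 1)^2) / (an^2 + bn)
  u_dstar <- (n / (n - 1)) * (an - n / (n - 1)) - v_dstar
  v_fstar <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
                2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  u_fstar <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
                (3 * n * (n - 1))) / an - v_fstar
  list(an = an, bn = bn, u_dstar = u_dstar, v_dstar = v_dstar,
       u_fstar = u_fstar, v_fstar = v_fstar)
}

#' Fu and Li's D* (no outgroup)
#'
#' Contrasts the total number of mutations against the number carried by
#' a single sequence. Excess singletons, as produced by recent expansion,
#' drives D* negative. Uses the corrected variance constants.
#'
#' @param eta total number of mutations.
#' @param eta_singletons singleton mutations (minor-allele count 1).
#' @param n sequence count (>= 4 recommended).
#' @return D*, or a flagged undefined value when eta = 0.
#' @export
fu_li_d_star <- function(eta, eta_singletons, n) {
  stopifnot(n >= 3)
  if (eta == 0) return(undefined_stat("eta = 0"))
  cst <- fu_li_constants(n)
  num <- (n / (n - 1)) * eta - cst$an * eta_singletons
  num / sqrt(cst$u_dstar * eta + cst$v_dstar * eta^2)
}

#' Fu and Li's F* (no outgroup)
#'
#' Contrasts mean pairwise differences against singleton mutations;
#' negative under expansion. Uses the corrected variance constants.
#'
#' @param k_bar mean pairwise differences per pair (per locus).
#' @param eta total mutations.
#' @param eta_singletons singleton mutations.
#' @param n sequence count.
#' @return F*, or a flagged undefined value when eta = 0.
#' @export
fu_li_f_star <- function(k_bar, eta, eta_singletons, n) {
  stopifnot(n >= 3)
  if (eta == 0) return(undefined_stat("eta = 0"))
  cst <- fu_li_constants(n)
  num <- k_bar - ((n - 1) / n) * eta_singletons
  num / sqrt(cst$u_fstar * eta + cst$v_fstar * eta^2)
}

## Log unsigned Stirling numbers of the first kind, rows up to n.
## log_stirling1(n)[k] = log |s(n, k)|; recurrence kept in log space so
## n in the hundreds stays finite.
log_stirling1 <- function(n) {
  prev <- 0 # row 1: |s(1,1)| = 1
  if (n == 1L) return(prev)
  for (m in 2:n) {
    cur <- numeric(m)
    # |s(m,k)| = (m-1) |s(m-1,k)| + |s(m-1,k-1)|
    for (k in seq_len(m)) {
      terms <- c(if (k <= m - 1) log(m - 1) + prev[k],
                 if (k >= 2) prev[k - 1])
      cur[k] <- if (is.null(terms)) -Inf else max(terms) +
          log(sum(exp(terms - max(terms))))
    }
    prev <- cur
  }
  prev
}

#' Ewens haplotype-number distribution
#'
#' P(K = k) for the number of distinct haplotypes in a sample of n under
#' the Ewens sampling distribution with parameter theta:
#' \eqn{P(K=k) = |s(n,k)| \theta^k / \theta_{(n)}}, with unsigned Stirling
#' numbers of the first kind and the rising factorial
#' \eqn{\theta_{(n)}}.
#'
#' @param n sample size.
#' @param theta scaled mutation parameter (> 0).
#' @return numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewens_haplotype_pmf <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- log_stirling1(n)
  lrise <- sum(log(theta + 0:(n - 1)))
  exp(ls + seq_len(n) * log(theta) - lrise)
}

#' Fu's Fs
#'
#' Computes \eqn{S' = P(K \ge k_{obs})} under the Ewens sampling
#' distribution with \eqn{\theta = \bar k}, then
#' \eqn{F_s = \ln(S'/(1-S'))}. A sample carrying more haplotypes than a
#' neutral constant-size population would show (as after an expansion)
#' gives a small S' and a strongly negative Fs.
#'
#' @param k_bar mean pairwise differences per pair (per locus); plays the
#'   role of theta.
#' @param k_obs observed number of distinct haplotypes.
#' @param n sequence count.
#' @return Fs; flagged undefined when k_bar = 0; flagged signed infinity
#'   when S' is numerically 0 or 1.
#' @export
fu_fs <- function(k_bar, k_obs, n) {
  stopifnot(n >= 2, k_obs >= 1, k_obs <= n)
  if (k_bar <= 0) return(undefined_stat("k_bar = 0"))
  pmf <- ewens_haplotype_pmf(n, k_bar)
  s_prime <- sum(pmf[k_obs:n])
  if (s_prime >= 1 - 1e-15)
    return(structure(Inf, undefined = "S' = 1 (k_obs at lower tail)"))
  if (s_prime <= 1e-300)
    return(structure(-Inf, undefined = "S' = 0 (underflow)"))
  log(s_prime / (1 - s_prime))
}

#' Ramos-Onsins and Rozas R2
#'
#' \eqn{R_2 = \sqrt{\frac{1}{n}\sum_i (U_i - \bar k/2)^2} / S} with
#' \eqn{U_i} the number of singleton mutations carried by sequence i.
#' Low values indicate the star-like genealogies of recent expansion.
#'
#' @param aln an \code{rp_alignment} with \code{n >= 2}.
#' @return R2, or a flagged undefined value when S = 0.
#' @export
r2_statistic <- function(aln) {
  st <- alignment_site_stats(aln)
  r2_from_parts(st$U, st$k_bar, st$S, st$n)
}

r2_from_parts <- function(U, k_bar, S, n) {
  if (S == 0) return(undefined_stat("S = 0"))
  sqrt(mean((U - k_bar / 2)^2)) / S
}

#' Full neutrality summary of an alignment
#'
#' Computes the per-dataset bundle: n, sites analysed L, S, eta,
#' singletons, mean pairwise differences, pi, Watterson's theta, and the
#' test statistics Tajima's D, Fu and Li's D* and F*, Fu's Fs and R2.
#' Optionally attaches simulation-based significance buckets for the
#' statistics (see [neutrality_significance()]).
#'
#' @param aln an \code{rp_alignment}.
#' @param significance_reps coalescent replicates for significance; 0
#'   skips significance (the default).
#' @param seed RNG seed for the significance simulation.
#' @return object of class \code{"rp_neutrality"}: a list of statistics
#'   and (when requested) a named character vector \code{significance}
#'   with buckets in \code{ns, <0.05, <0.02, <0.01}.
#' @export
neutrality_summary <- function(aln, significance_reps = 0L, seed = 1L) {
  st <- alignment_site_stats(aln)
  res <- list(
    n = st$n, L = st$L, S = st$S, eta = st$eta,
    eta_singletons = st$eta_singletons, k_bar = st$k_bar,
    pi = if (st$L > 0) st$k_bar / st$L else 0,
    theta_w = if (st$L > 0) watterson_theta(st$S, st$n, st$L) else 0,
    n_haplotypes = st$n_haplotypes,
    tajima_d = tajima_d(st$k_bar, st$S, st$n),
    fu_li_d_star = fu_li_d_star(st$eta, st$eta_singletons, st$n),
    fu_li_f_star = fu_li_f_star(st$k_bar, st$eta, st$eta_singletons,
                                st$n),
    fu_fs = fu_fs(st$k_bar, st$n_haplotypes, st$n),
    r2 = r2_from_parts(st$U, st$k_bar, st$S, st$n))
  if (significance_reps > 0L && st$S > 0L) {
    stats <- c("tajima_d", "fu_li_d_star", "fu_li_f_star", "fu_fs", "r2")
    sig <- vapply(seq_along(stats), function(i) {
      obs <- res[[stats[i]]]
      if (is_undefined_stat(obs) && !is.finite(obs)) return("ns")
      neutrality_significance(stats[i], obs, st$n, st$S,
                              reps = significance_reps,
                              seed = seed + i)
    }, character(1))
    names(sig) <- stats
    res$significance <- sig
  }
  class(res) <- "rp_neutrality"
  res
}

#' @export
print.rp_neutrality <- function(x, ...) {
  cat(sprintf("n=%d  L=%d  S=%d  pi=%.6f  thetaW=%.6f\n",
              x$n, x$L, x$S, x$pi, x$theta_w))
  cat(sprintf("D=%.2f  D*=%.2f  F*=%.2f  Fs=%.2f  R2=%.4f\n",
              x$tajima_d, x$fu_li_d_star, x$fu_li_f_star, x$fu_fs, x$r2))
  invisible(x)
}

#' Tajima's D restricted to synonymous or non-synonymous sites
#'
#' Recomputes S and mean pairwise differences using only the alignment
#' columns whose variants are of the requested class (a site with any
#' non-synonymous change counts as non-synonymous), then forms Tajima's D
#' from those. The per-site quantities use the Nei-Gojobori estimated
#' number of synonymous (resp. non-synonymous) sites as L. Alignment
#' columns are assumed to map 1:1 onto the annotation's reference
#' coordinates.
#'
#' @param aln an \code{rp_alignment} with \code{L} equal to the reference
#'   length.
#' @param annotation an \code{rp_annotation} on the same coordinates.
#' @param class \code{"synonymous"} or \code{"non-synonymous"}.
#' @return list with \code{D} (flagged undefined when the class has no
#'   segregating sites), \code{S}, \code{k_bar}, \code{L_class},
#'   \code{pi}, \code{theta_w}.
#' @export
tajima_d_by_class <- function(aln, annotation,
                              class = c("synonymous", "non-synonymous")) {
  class <- match.arg(class)
  stopifnot(inherits(aln, "rp_alignment"), inherits(annotation,
                                                    "rp_annotation"))
  refseq <- annotation$reference_seq[[1]]
  replicon <- names(annotation$reference_seq)[1]
  if (nchar(refseq) != aln$L)
    stop("alignment length does not match the annotated reference",
         call. = FALSE)
  st <- alignment_site_stats(aln)
  mat <- alignment_matrix(aln)
  # classify each segregating column that lies inside a CDS
  site_class <- vapply(st$seg_cols, function(pos) {
    cds <- host_cds(annotation, replicon, pos)
    if (is.null(cds)) return(NA_character_)
    ref <- substr(refseq, pos, pos)
    alts <- setdiff(unique(mat[, pos]), c(ref, "N", "-"))
    if (length(alts) == 0L) return(NA_character_)
    cls <- vapply(alts, function(a)
      classify_snp(pos, ref, a, annotation, replicon)$snp_class,
      character(1))
    if (all(cls == "sSNP")) "synonymous" else "non-synonymous"
  }, character(1))
  keep <- st$seg_cols[!is.na(site_class) & site_class == class]
  # per-class site totals over the annotated CDSs
  f <- annotation$features
  cds_rows <- f[f$kind == "CDS", , drop = FALSE]
  cds_seqs <- vapply(seq_len(nrow(cds_rows)), function(i) {
    s <- substr(refseq, cds_rows$start[i], cds_rows$end[i])
    if (cds_rows$strand[i] == "-") revcomp(s) else s
  }, character(1))
  sites <- synonymous_site_counts(cds_seqs)
  L_class <- if (class == "synonymous") sites$syn_sites else
    sites$nonsyn_sites
  if (length(keep) == 0L)
    return(list(D = undefined_stat(paste0("no ", class, " sites")),
                S = 0L, k_bar = 0, L_class = L_class, pi = 0,
                theta_w = 0))
  sub <- alignment(aln$ids, apply(mat[, keep, drop = FALSE], 1L, paste,
                                  collapse = ""))
  sst <- alignment_site_stats(sub)
  list(D = tajima_d(sst$k_bar, sst$S, sst$n), S = sst$S,
       k_bar = sst$k_bar, L_class = L_class,
       pi = sst$k_bar / L_class,
       theta_w = watterson_theta(sst$S, sst$n, L_class))
}
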