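# Independent oracles kept alongside the tests. Each re-derives a
# quantity by a different route than the package implementation: brute
# enumeration, naive scans, textbook recursions, or numerical quadrature.

# --- naive alignment scans -------------------------------------------------

oracle_segregating_sites <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- apply(mat, 2, function(col) !any(col %in% c("N", "-")))
  sum(apply(mat[, ok, drop = FALSE], 2,
            function(col) length(unique(col)) > 1))
}

oracle_pi <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  ok <- apply(mat, 2, function(col) !any(col %in% c("N", "-")))
  mat <- mat[, ok, drop = FALSE]
  n <- nrow(mat)
  tot <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + mean(mat[i, ] != mat[j, ])
    pairs <- pairs + 1
  }
  tot / pairs
}

oracle_pair_diff_counts <- function(seqs) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(mat)
  out <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out <- c(out, sum(mat[i, ] != mat[j, ]))
  out
}

# --- codon enumeration -----------------------------------------------------

# Brute-force ns/s opportunity ratio: literal triple loop over codons,
# positions and alternative bases against the standard code.
oracle_ns_s_ratio <- function(cds_set) {
  code <- Biostrings::GENETIC_CODE
  syn <- 0; nonsyn <- 0
  for (cds in cds_set) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    for (codon in codons) {
      if (code[[codon]] == "*") next
      for (p in 1:3) for (b in c("A", "C", "G", "T")) {
        if (b == substr(codon, p, p)) next
        mut <- codon; substr(mut, p, p) <- b
        if (code[[mut]] == code[[codon]] && code[[mut]] != "*")
          syn <- syn + 1 else nonsyn <- nonsyn + 1
      }
    }
  }
  nonsyn / syn
}

random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  repeat {
    cd <- paste(sample(c("A", "C", "G", "T"), 3 * n_codons,
                       replace = TRUE), collapse = "")
    codons <- substring(cd, seq(1, nchar(cd), 3), seq(3, nchar(cd), 3))
    if (!any(codons %in% stops)) return(cd)
  }
}

# --- Ewens haplotype-number distribution via the CRP recursion -------------

# P(K = k | n, theta) from the Chinese-restaurant-process recursion,
# independent of Stirling numbers.
oracle_ewens_K <- function(n, theta) {
  P <- matrix(0, n, n)
  P[1, 1] <- 1
  if (n > 1) for (m in 2:n) for (k in 1:m) {
    stay <- P[m - 1, k] * (m - 1) / (theta + m - 1)
    new <- if (k > 1) P[m - 1, k - 1] * theta / (theta + m - 1) else 0
    P[m, k] <- stay + new
  }
  P[n, ]
}

# --- Fu & Li constants, second transcription -------------------------------

# Corrected-variance D*/F* constants transcribed independently, kept in
# the published arrangement (harmonic sums written out, no shared code
# with the package).
oracle_fu_li <- function(eta, eta_s, k_bar, n) {
  a <- sum(1 / seq_len(n - 1))
  b <- sum(1 / seq_len(n - 1)^2)
  a1 <- sum(1 / seq_len(n))
  cn <- 2 * (n * a - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- cn + (n - 2) / (n - 1)^2 +
    (2 / (n - 1)) * (3 / 2 - (2 * a1 - 3) / (n - 2) - 1 / n)
  vD <- ((n / (n - 1))^2 * b + a^2 * dn -
           2 * n * a * (a + 1) / (n - 1)^2) / (a^2 + b)
  uD <- (n / (n - 1)) * (a - n / (n - 1)) - vD
  Dstar <- ((n / (n - 1)) * eta - a * eta_s) /
    sqrt(uD * eta + vD * eta^2)
  vF <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
           2 * (n - 1) * a / n^2 - 8 * b / n) / (a^2 + b)
  uF <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * a1) /
           (3 * n * (n - 1))) / a - vF
  Fstar <- (k_bar - ((n - 1) / n) * eta_s) /
    sqrt(uF * eta + vF * eta^2)
  list(d_star = Dstar, f_star = Fstar)
}

# --- Tajima's D from the definition ----------------------------------------

oracle_tajima_d <- function(k_bar, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (k_bar - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# --- expansion mismatch by numerical quadrature ----------------------------

# Pair coalescence density through the size change, Poisson-mixed.
oracle_expansion_mismatch <- function(theta0, theta1, tau, i) {
  f1 <- function(T) exp(-T) * T^i / gamma(i + 1) *
    (1 / theta1) * exp(-T / theta1)
  a <- stats::integrate(f1, 0, tau, rel.tol = 1e-10)$value
  f2 <- function(s) exp(-(tau + s)) * (tau + s)^i / gamma(i + 1) *
    (1 / theta0) * exp(-s / theta0)
  b <- exp(-tau / theta1) *
    stats::integrate(f2, 0, 80 * (1 + theta0), rel.tol = 1e-10)$value
  a + b
}

# --- small random alignments ----------------------------------------------

random_alignment <- function(n, L, alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""),
    character(1))
  alignment(sprintf("s%02d", seq_len(n)), seqs)
}

# A mismatch-distribution object from an exact model curve.
model_curve_mismatch <- function(theta0, theta1, tau, d_max) {
  curve <- expansion_mismatch(theta0, theta1, tau, 0:d_max)
  structure(list(freqs = stats::setNames(curve, 0:d_max),
                 counts = curve, pair_count = 1, d_max = d_max),
            class = "rp_mismatch")
}
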