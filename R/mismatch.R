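#' Observed mismatch distribution
#'
#' Histogram of pairwise nucleotide difference counts over all
#' n(n-1)/2 sequence pairs, normalized to relative frequencies over the
#' difference classes 0..d_max.
#'
#' @param aln an \code{rp_alignment} with \code{n >= 2}.
#' @return object of class \code{"rp_mismatch"}: list with \code{freqs}
#'   (relative frequencies, names \code{"0"}..\code{"d_max"}),
#'   \code{counts}, \code{pair_count} and \code{d_max}.
#' @export
observed_mismatch <- function(aln) {
  st <- alignment_site_stats(aln)
  mismatch_from_pairs(st$pair_diffs)
}

#' Build a mismatch distribution from frequencies or pair counts
#'
#' Constructor for the mismatch-distribution container used by
#' [fit_sudden_expansion()] and [raggedness()]: supply either a
#' frequency vector over difference classes 0..d (normalized if needed)
#' or the raw per-pair difference counts.
#'
#' @param freqs numeric vector of class frequencies over 0..d.
#' @param pair_diffs integer vector of pairwise difference counts, one
#'   per sequence pair.
#' @return an \code{rp_mismatch}.
#' @export
mismatch_distribution <- function(freqs = NULL, pair_diffs = NULL) {
  if (!is.null(pair_diffs)) return(mismatch_from_pairs(pair_diffs))
  stopifnot(!is.null(freqs), all(freqs >= 0), sum(freqs) > 0)
  freqs <- freqs / sum(freqs)
  d_max <- length(freqs) - 1L
  names(freqs) <- 0:d_max
  structure(list(freqs = freqs, counts = freqs, pair_count = NA_integer_,
                 d_max = d_max), class = "rp_mismatch")
}

mismatch_from_pairs <- function(pair_diffs) {
  d_max <- max(pair_diffs)
  counts <- tabulate(pair_diffs + 1L, nbins = d_max + 1L)
  freqs <- counts / length(pair_diffs)
  names(freqs) <- names(counts) <- 0:d_max
  structure(list(freqs = freqs, counts = counts,
                 pair_count = length(pair_diffs), d_max = d_max),
            class = "rp_mismatch")
}

#' Equilibrium mismatch distribution
#'
#' Expected relative frequency of pairs differing at \code{i} sites in a
#' stationary population with per-locus theta:
#' \eqn{\hat F_i(\theta) = \theta^i / (\theta+1)^{i+1}} (geometric).
#'
#' @param theta per-locus scaled mutation rate (>= 0).
#' @param i difference class (vectorized, >= 0).
#' @return probability (vector over \code{i}).
#' @export
equilibrium_mismatch <- function(theta, i) {
  stopifnot(theta >= 0, all(i >= 0))
  if (theta == 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log(theta + 1))
}

#' Sudden-expansion mismatch distribution
#'
#' Expected mismatch frequencies \code{tau} mutational-time units after a
#' population jumps from scaled size \code{theta0} to \code{theta1}
#' (Rogers-Harpending non-equilibrium solution):
#' \deqn{F_i(\tau) = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{j=0}^{i} \frac{\tau^j}{j!}
#'   [\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)].}
#' Reduces to the equilibrium distribution at theta0 when tau = 0 and to
#' the one at theta1 as tau grows.
#'
#' @param theta0 pre-expansion per-locus theta (>= 0).
#' @param theta1 post-expansion per-locus theta (> 0, >= theta0).
#' @param tau time since expansion in mutational units (>= 0).
#' @param i difference class (vectorized).
#' @return probability (vector over \code{i}).
#' @export
expansion_mismatch <- function(theta0, theta1, tau, i) {
  stopifnot(theta0 >= 0, tau >= 0, all(i >= 0))
  if (tau == 0) return(equilibrium_mismatch(theta0, i))
  stopifnot(theta1 > 0)
  lead <- -tau * (theta1 + 1) / theta1
  out <- vapply(i, function(ii) {
    j <- 0:ii
    terms <- exp(lead + j * log(tau) - lgamma(j + 1)) *
      (equilibrium_mismatch(theta0, ii - j) -
         equilibrium_mismatch(theta1, ii - j))
    equilibrium_mismatch(theta1, ii) + sum(terms)
  }, numeric(1))
  # cancellation in the alternating sum can leave O(1e-17) negatives
  pmax(out, 0)
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{d_{max}} (x_i - x_{i-1})^2} over adjacent
#' relative frequencies, with d_max the largest observed difference
#' class; no wrap-around term. At most one zero class beyond the last
#' nonzero frequency enters the sum, so appending further empty classes
#' never changes r. Smooth unimodal distributions - the signature of
#' expansion - give small r.
#'
#' @param obs an \code{rp_mismatch} or a bare frequency vector over
#'   classes 0..d.
#' @return r (0 for a single-class distribution).
#' @export
raggedness <- function(obs) {
  x <- if (inherits(obs, "rp_mismatch")) obs$freqs else as.numeric(obs)
  nz <- which(x > 0)
  if (length(nz) == 0L) return(0)
  x <- x[seq_len(min(max(nz) + 1L, length(x)))]
  if (length(x) < 2L) return(0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Bounded nonlinear least squares for (theta0, theta1, tau): minimizes
#' the sum of squared deviations between observed and model frequencies
#' over the observed classes, from 16 multi-start points on a log grid
#' (theta0 in [0, theta_pi], theta1 in [theta0, 1e4], tau in
#' [0, 2 d_max], with theta_pi the observed mean pairwise difference).
#' Also reports Rogers' method-of-moments estimates
#' (\eqn{\hat\theta_0 = \sqrt{v - m}}, \eqn{\hat\tau = m - \hat\theta_0},
#' from the mean m and variance v of the distribution, assuming a large
#' post-expansion size).
#'
#' @param obs an \code{rp_mismatch}.
#' @return object of class \code{"rp_mismatch_fit"}: list with
#'   \code{theta0}, \code{theta1}, \code{tau}, \code{sse},
#'   \code{raggedness_r}, \code{fitted} (model curve over the observed
#'   classes), \code{tau_moment}, \code{theta0_moment} and
#'   \code{degenerate} (TRUE when all mass sits at class 0, fit flagged
#'   with tau = 0).
#' @export
fit_sudden_expansion <- function(obs) {
  stopifnot(inherits(obs, "rp_mismatch"))
  x <- obs$freqs
  classes <- as.numeric(names(x))
  m <- sum(classes * x)
  v <- sum((classes - m)^2 * x)
  theta0_mom <- sqrt(max(v - m, 0))
  tau_mom <- max(m - theta0_mom, 0)
  if (obs$d_max == 0L || all(x[-1] == 0)) {
    return(structure(list(theta0 = 0, theta1 = 0, tau = 0, sse = 0,
                          raggedness_r = raggedness(obs),
                          fitted = as.numeric(x == x[1]) * 0 + x,
                          tau_moment = 0, theta0_moment = 0,
                          degenerate = TRUE),
                     class = "rp_mismatch_fit"))
  }
  theta_pi <- m
  tau_hi <- 2 * obs$d_max
  sse_fun <- function(p) {
    # p = (theta0, delta = theta1 - theta0, tau)
    f <- expansion_mismatch(p[1], p[1] + p[2], p[3], classes)
    sum((x - f)^2)
  }
  lower <- c(0, 1e-8, 0)
  upper <- c(theta_pi, 1e4, tau_hi)
  starts <- expand.grid(
    theta0 = theta_pi * c(0.01, 0.5),
    delta = c(1, 10, 100, 1000),
    tau = c(0.5, 1) * min(m, tau_hi))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[s, ]), lower), upper)
    fit <- tryCatch(
      stats::optim(p0, sse_fun, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  p <- best$par
  fitted <- expansion_mismatch(p[1], p[1] + p[2], p[3], classes)
  structure(list(theta0 = p[1], theta1 = p[1] + p[2], tau = p[3],
                 sse = best$value, raggedness_r = raggedness(obs),
                 fitted = fitted, tau_moment = tau_mom,
                 theta0_moment = theta0_mom, degenerate = FALSE),
            class = "rp_mismatch_fit")
}

#' @export
print.rp_mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "sudden-expansion fit: theta0=%.4g theta1=%.4g tau=%.4g (sse=%.3g)\n",
    x$theta0, x$theta1, x$tau, x$sse))
  cat(sprintf("raggedness r=%.4g; moment estimator tau=%.4g\n",
              x$raggedness_r, x$tau_moment))
  invisible(x)
}

#' Molecular-clock parameters
#'
#' Bundles the strict-clock constants used to convert mutational time to
#' calendar time. Defaults describe soil rhizobia: a universal rate of
#' 0.0033 mutations per genome per generation on a 7,139,558 bp genome at
#' 44 generations per year, equivalent to 2.03e-8 mutations per site per
#' year.
#'
#' @param rate_per_site_per_year mutations per site per year; computed
#'   from the other constants when \code{NULL}.
#' @param rate_per_genome_per_generation mutations per genome per
#'   generation.
#' @param generations_per_year generations per year.
#' @param genome_length genome size in bp.
#' @param locus_length analysed (concatenated) locus length in bp.
#' @return list of class \code{"rp_clock"}.
#' @export
clock_parameters <- function(rate_per_site_per_year = NULL,
                             rate_per_genome_per_generation = 0.0033,
                             generations_per_year = 44,
                             genome_length = 7139558,
                             locus_length = 146721) {
  if (is.null(rate_per_site_per_year))
    rate_per_site_per_year <-
      convert_mutation_rate(rate_per_genome_per_generation,
                            genome_length, generations_per_year)
  vals <- c(rate_per_site_per_year, rate_per_genome_per_generation,
            generations_per_year, genome_length, locus_length)
  if (any(vals <= 0)) stop("clock parameters must be positive",
                           call. = FALSE)
  structure(list(rate_per_site_per_year = rate_per_site_per_year,
                 rate_per_genome_per_generation =
                   rate_per_genome_per_generation,
                 generations_per_year = generations_per_year,
                 genome_length = genome_length,
                 locus_length = locus_length),
            class = "rp_clock")
}

#' Convert a per-genome per-generation rate to per site per year
#'
#' \eqn{\upsilon = (rate / genome\_length) \times generations\_per\_year}.
#'
#' @param rate_per_genome_per_generation mutations per genome per
#'   generation.
#' @param genome_length genome size in bp.
#' @param generations_per_year generations per year.
#' @return mutations per site per year.
#' @examples
#' convert_mutation_rate(0.0033, 7139558, 44) # ~2.03e-8
#' @export
convert_mutation_rate <- function(rate_per_genome_per_generation,
                                  genome_length, generations_per_year) {
  stopifnot(rate_per_genome_per_generation > 0, genome_length > 0,
            generations_per_year > 0)
  rate_per_genome_per_generation / genome_length * generations_per_year
}

#' Calendar time since expansion
#'
#' Converts mutational time to years before sampling with
#' \eqn{t = \tau / (2 \upsilon L)}, where \eqn{\upsilon} is the per-site
#' per-year rate and L the analysed locus length, under a strict clock.
#'
#' @param tau time since expansion in mutational units (>= 0).
#' @param clock an \code{rp_clock}.
#' @return list with \code{years} (before sampling) and
#'   \code{generations}.
#' @export
time_since_expansion <- function(tau, clock = clock_parameters()) {
  stopifnot(inherits(clock, "rp_clock"), tau >= 0)
  years <- tau / (2 * clock$rate_per_site_per_year * clock$locus_length)
  list(years = years, generations = years * clock$generations_per_year)
}
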