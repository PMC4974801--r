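test_that("observed mismatch distribution matches direct pair enumeration", {
  ident <- alignment(c("a", "b"), c("ACGTA", "ACGTA"))
  m <- observed_mismatch(ident)
  expect_equal(as.numeric(m$freqs), 1)
  expect_equal(m$d_max, 0)
  two <- alignment(c("a", "b"), c("ACGTAACGTA", "TCGTAACGTT"))
  expect_equal(names(which(observed_mismatch(two)$freqs == 1)), "2")
  set.seed(201)
  aln <- random_alignment(4, 30)
  m <- observed_mismatch(aln)
  oracle <- oracle_pair_diff_counts(aln$seqs)
  expect_equal(m$pair_count, 6)
  expect_equal(as.numeric(m$counts),
               tabulate(oracle + 1, nbins = max(oracle) + 1) / 1)
  expect_equal(sum(m$freqs), 1, tolerance = 1e-12)
})

test_that("equilibrium mismatch is the geometric distribution", {
  expect_equal(equilibrium_mismatch(1, 0), 0.5)
  expect_equal(equilibrium_mismatch(1, 1), 0.25)
  for (theta in c(0.2, 1, 7))
    expect_equal(sum(equilibrium_mismatch(theta, 0:2000)), 1,
                 tolerance = 1e-9)
  expect_equal(equilibrium_mismatch(0, 0:3), c(1, 0, 0, 0))
})

test_that("expansion mismatch matches quadrature, sums to one, and hits both limits", {
  for (i in c(0, 1, 4, 9))
    expect_equal(expansion_mismatch(1, 100, 5, i),
                 oracle_expansion_mismatch(1, 100, 5, i),
                 tolerance = 1e-8)
  grid <- expand.grid(theta0 = c(0.3, 2), theta1 = c(10, 200),
                      tau = c(0.5, 4))
  for (g in seq_len(nrow(grid))) {
    p <- expansion_mismatch(grid$theta0[g], grid$theta1[g], grid$tau[g],
                            0:400)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
  # tau = 0 boundary and large-tau limit
  expect_equal(expansion_mismatch(1.3, 50, 0, 0:10),
               equilibrium_mismatch(1.3, 0:10))
  big_tau <- 10 * (1 + 40)
  expect_equal(expansion_mismatch(1, 40, big_tau, 0:10),
               equilibrium_mismatch(40, 0:10), tolerance = 1e-6)
})

test_that("expansion mismatch agrees with the coalescent simulator", {
  # the closed form and the simulator validate each other
  model <- demographic_model("sudden_expansion", theta0 = 1,
                             theta1 = 100, tau = 5)
  reps <- 3000
  counts <- numeric(40)
  set.seed(0)
  for (r in seq_len(reps)) {
    s <- simulate_coalescent(2, model, 2e5, seed = 400000 + r,
                             sequences = FALSE)
    d <- s$parts$pair_diffs + 1
    if (d <= 40) counts[d] <- counts[d] + 1
  }
  emp <- counts / reps
  theo <- expansion_mismatch(1, 100, 5, 0:39)
  se <- sqrt(theo * (1 - theo) / reps)
  expect_true(all(abs(emp - theo) < 4 * se + 1e-3))
})

test_that("raggedness follows its convention and ignores trailing empty classes", {
  expect_equal(raggedness(rep(0.1, 10)), 0)
  expect_equal(raggedness(c(1, 0)), 1)
  expect_equal(raggedness(c(0.5, 0.3, 0.2)),
               (0.3 - 0.5)^2 + (0.2 - 0.3)^2)
  # appending empty classes beyond the first changes nothing
  expect_equal(raggedness(c(0.5, 0.3, 0.2, 0, 0, 0)),
               raggedness(c(0.5, 0.3, 0.2, 0)))
  expect_equal(raggedness(c(1)), 0)
})

test_that("sudden-expansion fit recovers exact model curves", {
  obs <- model_curve_mismatch(1, 50, 6, 40)
  f <- fit_sudden_expansion(obs)
  expect_lte(f$sse, 1e-12)
  expect_equal(f$tau, 6, tolerance = 0.01)
  expect_equal(f$theta0, 1, tolerance = 0.1)
  expect_equal(f$theta1, 50, tolerance = 0.1 * 50)
  # degenerate distribution: all mass at zero differences
  degen <- structure(list(freqs = c(`0` = 1), counts = 1,
                          pair_count = 10, d_max = 0),
                     class = "rp_mismatch")
  fd <- fit_sudden_expansion(degen)
  expect_true(fd$degenerate)
  expect_equal(fd$tau, 0)
})

test_that("clock conversions are exact and invert", {
  expect_equal(signif(convert_mutation_rate(0.0033, 7139558, 44), 3),
               2.03e-8)
  expect_equal(convert_mutation_rate(5, 1, 1), 5)
  ups <- convert_mutation_rate(0.0033, 7139558, 44)
  # inverse conversion recovers the genome rate to machine precision
  expect_equal(ups * 7139558 / 44, 0.0033, tolerance = 1e-15)
  clock <- clock_parameters(locus_length = 146721)
  expect_equal(time_since_expansion(0, clock)$years, 0)
  tau <- 2 * 2.03e-8 * 146721 * 3000
  clock2 <- clock_parameters(rate_per_site_per_year = 2.03e-8,
                             locus_length = 146721)
  expect_equal(time_since_expansion(tau, clock2)$years, 3000)
  # linear in tau, inverse-linear in rate and L
  t1 <- time_since_expansion(1, clock2)$years
  expect_equal(time_since_expansion(2, clock2)$years, 2 * t1)
  clock3 <- clock_parameters(rate_per_site_per_year = 2 * 2.03e-8,
                             locus_length = 146721)
  expect_equal(time_since_expansion(1, clock3)$years, t1 / 2)
})

test_that("expansion time is recovered end-to-end from simulated data", {
  # simulate with a known expansion time, fit, convert back to years
  ups <- 2.03e-8
  L <- 150000
  true_years <- 3000
  true_tau <- 2 * ups * L * true_years
  # per-locus thetas chosen so tau is identifiable at this scale
  model <- demographic_model("sudden_expansion", theta0 = 0.3,
                             theta1 = 60, tau = true_tau)
  taus <- vapply(1:60, function(r) {
    p <- simulate_coalescent(14, model, 5e6, seed = 700000 + r,
                             sequences = FALSE)$parts
    fit_sudden_expansion(rhizopop:::mismatch_from_pairs(p$pair_diffs))$tau
  }, numeric(1))
  clock <- clock_parameters(rate_per_site_per_year = ups,
                            locus_length = L)
  est_years <- time_since_expansion(mean(taus), clock)$years
  expect_equal(est_years, true_years, tolerance = 0.25)
})
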