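#' Diversity statistics from printed summary inputs
#'
#' Recomputes Watterson's theta and Tajima's D from the summary columns a
#' published diversity table prints (n, S, pi, L) - the "summary mode"
#' that makes printed tables executable without the raw alignments. The
#' mean pairwise difference count is recovered as \code{k_bar = pi * L}.
#'
#' @param n sequence count.
#' @param S segregating sites.
#' @param pi nucleotide diversity per site.
#' @param L sites analysed (bp).
#' @return list with \code{theta_w} (per site), \code{tajima_d},
#'   \code{k_bar} and the echoed inputs.
#' @examples
#' neutrality_from_summary(14, 123, 0.000135, 146721)
#' @export
neutrality_from_summary <- function(n, S, pi, L) {
  stopifnot(n >= 2, S >= 0, pi >= 0, L >= 1)
  k_bar <- pi * L
  list(n = n, S = S, pi = pi, L = L, k_bar = k_bar,
       theta_w = watterson_theta(S, n, L),
       tajima_d = tajima_d(k_bar, S, n))
}

#' Render numbers at table precision
#'
#' Output-layer rounding (half-even) matching the precision diversity
#' tables print: theta and pi in 6-decimal fixed form, test statistics to
#' 2 decimals, percentages to 1 decimal. Internal computation is never
#' rounded.
#'
#' @param x numeric value.
#' @return character rendering.
#' @export
format_theta <- function(x) sprintf("%.6f", x)

#' @rdname format_theta
#' @export
format_stat <- function(x) sprintf("%.2f", x)

#' @rdname format_theta
#' @export
format_percent <- function(x) sprintf("%.1f", x)

#' Render a significance bucket as stars
#'
#' \code{<0.01} and \code{<0.02} render as \code{**}, \code{<0.05} as
#' \code{*}, \code{ns} as the empty string.
#'
#' @param bucket character bucket from [neutrality_significance()].
#' @return character stars.
#' @export
significance_stars <- function(bucket) {
  out <- vapply(as.character(bucket), function(b)
    switch(b, `<0.01` = "**", `<0.02` = "**", `<0.05` = "*", ns = "",
           stop("unknown significance bucket: ", b, call. = FALSE)),
    character(1), USE.NAMES = FALSE)
  names(out) <- names(bucket)
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: SNP-class accounting, neutrality statistics with
#' significance, and mismatch-distribution demography, written as TSV and
#' JSON tables plus a run log echoing the effective configuration and
#' seeds. Two input modes are supported: alignment mode (\code{alignment}
#' is a FASTA path or \code{rp_alignment}; everything is computed from
#' sequences) and summary mode (\code{summary} is a data.frame or TSV
#' with columns \code{dataset n S pi L}; only theta and D are
#' recomputed).
#'
#' @param config list with elements: one of \code{alignment} or
#'   \code{summary}; optional \code{annotation} (\code{rp_annotation},
#'   enables per-class D), optional \code{variants} (TSV path; enables
#'   SNP accounting), \code{clock} (default [clock_parameters()]),
#'   \code{significance_reps} (default 1000), \code{seed} (default 1),
#'   \code{outdir} (required).
#' @return invisible list of the result objects; files are written under
#'   \code{config$outdir}.
#' @export
run_full_analysis <- function(config) {
  if (is.null(config$outdir)) stop("config$outdir is required",
                                   call. = FALSE)
  for (field in c("alignment", "summary", "variants")) {
    p <- config[[field]]
    if (is.character(p) && length(p) == 1L && !file.exists(p))
      stop("input error: ", field, " file not found: ", p,
           call. = FALSE)
  }
  if (is.null(config$alignment) && is.null(config$summary))
    stop("input error: config needs 'alignment' or 'summary'",
         call. = FALSE)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  clock <- if (is.null(config$clock)) clock_parameters() else
    config$clock
  reps <- if (is.null(config$significance_reps)) 1000L else
    as.integer(config$significance_reps)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out <- list()
  log_lines <- c(sprintf("rhizopop %s",
                         as.character(utils::packageVersion("rhizopop"))),
                 sprintf("seed=%d significance_reps=%d", seed, reps),
                 sprintf("clock: %.3g /site/yr, %.4g /genome/gen, %g gen/yr, genome %d bp",
                         clock$rate_per_site_per_year,
                         clock$rate_per_genome_per_generation,
                         clock$generations_per_year,
                         clock$genome_length))

  if (!is.null(config$variants) && !is.null(config$annotation)) {
    recs <- classify_variant_table(config$variants, config$annotation)
    smry <- snp_class_summary(recs)
    tab <- data.frame(class = names(smry$counts),
                      count = as.integer(smry$counts),
                      fraction_pct = format_percent(smry$fractions))
    utils::write.table(tab, file.path(config$outdir, "snp_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$snp_summary <- smry
    log_lines <- c(log_lines,
                   sprintf("snp_summary: %d SNPs, ns/s ratio %s",
                           smry$total, format_stat(smry$ns_s_ratio)))
  }

  if (!is.null(config$summary)) {
    stab <- if (is.character(config$summary))
      utils::read.delim(config$summary, stringsAsFactors = FALSE) else
        as.data.frame(config$summary)
    rows <- lapply(seq_len(nrow(stab)), function(i) {
      r <- neutrality_from_summary(stab$n[i], stab$S[i], stab$pi[i],
                                   stab$L[i])
      data.frame(dataset = stab$dataset[i], n = r$n, L = r$L, S = r$S,
                 pi = format_theta(r$pi),
                 theta_w = format_theta(r$theta_w),
                 tajima_d = format_stat(r$tajima_d))
    })
    neut <- do.call(rbind, rows)
    utils::write.table(neut, file.path(config$outdir, "neutrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$neutrality <- neut
  }

  if (!is.null(config$alignment)) {
    aln <- if (inherits(config$alignment, "rp_alignment"))
      config$alignment else read_fasta_alignment(config$alignment)
    ns <- neutrality_summary(aln, significance_reps = reps, seed = seed)
    stars <- if (!is.null(ns$significance))
      significance_stars(ns$significance) else rep("", 5)
    neut <- data.frame(
      dataset = "alignment", n = ns$n, L = ns$L, S = ns$S,
      pi = format_theta(ns$pi), theta_w = format_theta(ns$theta_w),
      tajima_d = paste0(format_stat(ns$tajima_d), stars[1]),
      fu_li_d_star = paste0(format_stat(ns$fu_li_d_star), stars[2]),
      fu_li_f_star = paste0(format_stat(ns$fu_li_f_star), stars[3]),
      fu_fs = paste0(format_stat(ns$fu_fs), stars[4]),
      r2 = paste0(sprintf("%.4f", ns$r2), stars[5]))
    utils::write.table(neut, file.path(config$outdir, "neutrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$neutrality <- ns

    obs <- observed_mismatch(aln)
    fit <- fit_sudden_expansion(obs)
    clock$locus_length <- ns$L
    tt <- time_since_expansion(fit$tau, clock)
    mm <- data.frame(class = as.integer(names(obs$freqs)),
                     observed = as.numeric(obs$freqs),
                     fitted = fit$fitted)
    utils::write.table(mm, file.path(config$outdir, "mismatch.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(theta0 = fit$theta0, theta1 = fit$theta1, tau = fit$tau,
           tau_moment = fit$tau_moment, sse = fit$sse,
           raggedness_r = fit$raggedness_r, r2 = as.numeric(ns$r2),
           years_before_sampling = tt$years,
           generations = tt$generations),
      file.path(config$outdir, "mismatch.json"), auto_unbox = TRUE,
      digits = NA)
    out$mismatch <- fit
    out$time_since_expansion <- tt
    log_lines <- c(log_lines,
                   sprintf("mismatch: tau=%.3g -> %.3g years before sampling",
                           fit$tau, tt$years))
  }

  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(out)
}
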