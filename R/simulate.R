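#' Specify a demographic model for simulation
#'
#' Three generative regimes for the coalescent simulator, parameterized
#' in the same mutational-time units as the mismatch model so that
#' recovery tests are coherent: \code{constant} (per-locus
#' \code{theta}), \code{sudden_expansion} (\code{theta0} before,
#' \code{theta1} after a size jump \code{tau} mutational-time units
#' before present) and \code{exponential_growth} (present-day
#' \code{theta}, backward shrink rate \code{growth_rate} per
#' mutational-time unit).
#'
#' @param kind model kind.
#' @param theta per-locus scaled mutation rate (constant / exponential).
#' @param theta0,theta1,tau sudden-expansion parameters.
#' @param growth_rate exponential growth rate.
#' @return object of class \code{"rp_demography"}.
#' @export
demographic_model <- function(kind = c("constant", "sudden_expansion",
                                       "exponential_growth"),
                              theta = NULL, theta0 = NULL, theta1 = NULL,
                              tau = NULL, growth_rate = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    constant = {
      stopifnot(!is.null(theta), theta >= 0)
      list(kind = kind, theta = theta)
    },
    sudden_expansion = {
      stopifnot(!is.null(theta0), !is.null(theta1), !is.null(tau),
                theta0 >= 0, theta1 > 0, theta1 >= theta0, tau >= 0)
      list(kind = kind, theta0 = theta0, theta1 = theta1, tau = tau)
    },
    exponential_growth = {
      stopifnot(!is.null(theta), !is.null(growth_rate), theta > 0,
                growth_rate > 0)
      list(kind = kind, theta = theta, growth_rate = growth_rate)
    })
  structure(m, class = "rp_demography")
}

## Instantaneous per-locus theta at backward time t (mutational units).
model_theta_at <- function(model, t) {
  switch(model$kind,
         constant = model$theta,
         sudden_expansion = if (t < model$tau) model$theta1 else
           model$theta0,
         exponential_growth = model$theta * exp(-model$growth_rate * t))
}

## Draw the next coalescence time for k lineages from backward time t,
## under the model's piecewise / exponentially changing intensity.
## Pairwise coalescence rate is 1/theta per mutational-time unit.
next_coal_time <- function(k, t, model) {
  pairs <- k * (k - 1) / 2
  switch(model$kind,
    constant = t + stats::rexp(1, pairs / model$theta),
    sudden_expansion = {
      if (t < model$tau) {
        w <- stats::rexp(1, pairs / model$theta1)
        if (t + w < model$tau) t + w
        else if (model$theta0 == 0) model$tau
        else model$tau + stats::rexp(1, pairs / model$theta0)
      } else t + stats::rexp(1, pairs / model$theta0)
    },
    exponential_growth = {
      # integrated hazard from t: (pairs/theta) * (e^{g(t+w)}-e^{gt})/g
      g <- model$growth_rate
      E <- stats::rexp(1)
      log(exp(g * t) + g * model$theta * E / pairs) / g
    })
}

## Simulate one coalescent genealogy. Returns branch records: for every
## lineage (tip or internal), the leaves below it and its length in
## mutational-time units, plus merge bookkeeping for tree export.
sim_genealogy <- function(n, model) {
  # active lineages: id, birth time, leaf set
  ids <- seq_len(n)
  birth <- rep(0, n)
  leafsets <- lapply(seq_len(n), identity)
  active <- seq_len(n)
  t <- 0
  next_id <- n + 1L
  branch_leaves <- vector("list", 2L * n - 2L)
  branch_len <- numeric(2L * n - 2L)
  merges <- matrix(0L, nrow = n - 1L, ncol = 2L)
  merge_time <- numeric(n - 1L)
  node_of <- integer(2L * n - 1L) # lineage id -> tree node id
  m <- 0L
  while (length(active) > 1L) {
    k <- length(active)
    t <- next_coal_time(k, t, model)
    pick <- sample(seq_len(k), 2L)
    i <- active[pick[1]]; j <- active[pick[2]]
    m <- m + 1L
    branch_leaves[[i]] <- leafsets[[i]]
    branch_len[i] <- t - birth[i]
    branch_leaves[[j]] <- leafsets[[j]]
    branch_len[j] <- t - birth[j]
    merges[m, ] <- c(i, j)
    merge_time[m] <- t
    leafsets[[next_id]] <- c(leafsets[[i]], leafsets[[j]])
    birth[next_id] <- t
    active <- c(setdiff(active, c(i, j)), next_id)
    next_id <- next_id + 1L
  }
  list(n = n, branch_leaves = branch_leaves, branch_len = branch_len,
       merges = merges, merge_time = merge_time, tmrca = t,
       total_len = sum(branch_len))
}

## Newick text for a simulated genealogy (lengths in mutational units,
## optionally rescaled).
genealogy_newick <- function(gen, ids, scale = 1) {
  n <- gen$n
  lab <- vector("character", 2L * n - 1L)
  lab[seq_len(n)] <- ids
  for (m in seq_len(n - 1L)) {
    i <- gen$merges[m, 1]; j <- gen$merges[m, 2]
    node <- n + m
    lab[node] <- sprintf("(%s:%.10g,%s:%.10g)",
                         lab[i], gen$branch_len[i] * scale,
                         lab[j], gen$branch_len[j] * scale)
  }
  paste0(lab[2L * n - 1L], ";")
}

#' Simulate an alignment under the coalescent with infinite sites
#'
#' Draws a genealogy for \code{n} haploid samples under the demographic
#' model (coalescence intensity 1/theta per pair per mutational-time
#' unit, rescaled through epochs for non-constant size), drops mutations
#' on branches as a Poisson process with rate 1/2 per mutational-time
#' unit per lineage, and places each at a distinct uniformly chosen site
#' (infinite sites). The ancestral sequence is all-A; each mutation flips
#' its site to a uniformly chosen other base in every descendant of the
#' mutated branch.
#'
#' @param n sample size (>= 2).
#' @param model an \code{rp_demography}.
#' @param L number of sites; must be large enough that uniform placement
#'   of the drawn mutation count would collide with probability < 1 %.
#' @param seed integer RNG seed; identical seeds give bit-identical
#'   output.
#' @param ids sequence identifiers (default \code{iso01..}).
#' @param sequences build the full sequence alignment (default TRUE).
#'   With FALSE only the genealogy-derived site statistics are returned,
#'   which is orders of magnitude faster for calibration sweeps at the
#'   large L the infinite-sites collision bound demands.
#' @return object of class \code{"rp_simulated_sample"}: list with
#'   \code{alignment} (NULL when \code{sequences = FALSE}),
#'   \code{genealogy} (newick, branch lengths rescaled to coalescent
#'   units of the present-day theta), \code{tree_mut} (newick in
#'   mutational-time units), \code{mutation_positions},
#'   \code{derived_counts}, \code{parts} (the summary quantities every
#'   statistic consumes: \code{k_bar}, \code{S}, \code{eta},
#'   \code{eta_singletons}, \code{U}, \code{n_haplotypes},
#'   \code{pair_diffs}), \code{true_model} and \code{seed}.
#' @export
simulate_coalescent <- function(n, model, L, seed,
                                ids = sprintf("iso%02d", seq_len(n)),
                                sequences = TRUE) {
  stopifnot(n >= 2, L >= 1, inherits(model, "rp_demography"))
  set.seed(as.integer(seed))
  gen <- sim_genealogy(n, model)
  n_mut <- stats::rpois(1, gen$total_len / 2)
  # birthday bound on uniform placement: reject if collisions likely
  if (n_mut > 1 && n_mut * (n_mut - 1) / (2 * L) >= 0.01)
    stop("site-capacity error: ", n_mut, " mutations on L = ", L,
         " sites violates the infinite-sites collision bound",
         call. = FALSE)
  pos <- sort(sample.int(L, n_mut, replace = FALSE))
  # branch of each mutation, proportional to branch length
  br <- if (n_mut > 0)
    sample.int(length(gen$branch_len), n_mut, replace = TRUE,
               prob = gen$branch_len) else integer(0)
  # carrier incidence: X[i, m] = TRUE iff leaf i descends from the
  # branch carrying mutation m
  X <- matrix(FALSE, nrow = n, ncol = n_mut)
  for (m in seq_len(n_mut)) X[gen$branch_leaves[[br[m]]], m] <- TRUE
  derived <- as.integer(colSums(X))
  k_bar <- if (n_mut > 0) sum(derived * (n - derived)) /
      (n * (n - 1) / 2) else 0
  U <- integer(n)
  for (m in which(derived == 1L)) U[X[, m]] <- U[X[, m]] + 1L
  for (m in which(derived == n - 1L)) U[!X[, m]] <- U[!X[, m]] + 1L
  haps <- if (n_mut > 0) apply(X, 1L, paste, collapse = "") else
    rep("", n)
  Xi <- matrix(as.numeric(X), n, n_mut)
  DD <- Xi %*% t(1 - Xi)
  diffs <- DD + t(DD)
  pair_diffs <- as.integer(diffs[lower.tri(diffs)])
  parts <- list(k_bar = k_bar, S = n_mut, eta = n_mut,
                eta_singletons = sum(derived == 1L |
                                       derived == (n - 1L)),
                U = U, n_haplotypes = length(unique(haps)),
                pair_diffs = pair_diffs)
  aln <- NULL
  if (sequences) {
    mat <- matrix("A", nrow = n, ncol = L)
    for (m in seq_len(n_mut))
      mat[X[, m], pos[m]] <- sample(c("C", "G", "T"), 1L)
    aln <- alignment(ids, apply(mat, 1L, paste, collapse = ""))
  }
  theta_now <- model_theta_at(model, 0)
  structure(list(
    alignment = aln,
    genealogy = genealogy_newick(gen, ids,
                                 scale = if (theta_now > 0)
                                   1 / theta_now else 1),
    tree_mut = genealogy_newick(gen, ids),
    mutation_positions = pos, derived_counts = derived,
    parts = parts, true_model = model, seed = as.integer(seed)),
    class = "rp_simulated_sample")
}

#' Simulate a panel of independent coalescent replicates
#'
#' Replicate seeds derive from the master seed by a fixed counter scheme
#' (\code{seed * 1000 + replicate}, kept below 2^31), recorded in each
#' sample, so any replicate can be regenerated in isolation.
#'
#' @param model an \code{rp_demography}.
#' @param n sample size.
#' @param L sites per replicate.
#' @param reps number of replicates (>= 1).
#' @param seed master seed.
#' @param sequences build full sequences per replicate (see
#'   [simulate_coalescent()]).
#' @return list of \code{rp_simulated_sample}, length \code{reps}.
#' @export
simulate_population_panel <- function(model, n, L, reps, seed,
                                      sequences = TRUE) {
  stopifnot(reps >= 1)
  base <- (as.integer(seed) %% 2000000L) * 1000L
  lapply(seq_len(reps), function(r)
    simulate_coalescent(n, model, L, seed = base + r,
                        sequences = sequences))
}

## Fast path for null distributions: genealogy + fixed-S mutation
## placement, returning the summary parts every statistic needs without
## building sequences. Used by neutrality_significance().
sim_stats_fixed_s <- function(n, S, model = demographic_model("constant",
                                                              theta = 1)) {
  gen <- sim_genealogy(n, model)
  br <- sample.int(length(gen$branch_len), S, replace = TRUE,
                   prob = gen$branch_len)
  sizes <- lengths(gen$branch_leaves)[br]
  k_bar <- sum(sizes * (n - sizes)) / (n * (n - 1) / 2)
  eta_s <- sum(sizes == 1L | sizes == (n - 1L))
  # per-sequence singleton loads
  U <- integer(n)
  for (m in which(sizes == 1L))
    U[gen$branch_leaves[[br[m]]]] <- U[gen$branch_leaves[[br[m]]]] + 1L
  for (m in which(sizes == n - 1L)) {
    out <- setdiff(seq_len(n), gen$branch_leaves[[br[m]]])
    U[out] <- U[out] + 1L
  }
  # haplotypes: distinct mutation-carrier profiles
  prof <- vapply(seq_len(n), function(i)
    paste(which(vapply(br, function(b)
      i %in% gen$branch_leaves[[b]], logical(1))), collapse = ","),
    character(1))
  list(k_bar = k_bar, S = S, eta = S, eta_singletons = eta_s, U = U,
       n_haplotypes = length(unique(prof)))
}

eval_neutrality_stat <- function(statistic, parts, n) {
  switch(statistic,
         tajima_d = tajima_d(parts$k_bar, parts$S, n),
         fu_li_d_star = fu_li_d_star(parts$eta, parts$eta_singletons, n),
         fu_li_f_star = fu_li_f_star(parts$k_bar, parts$eta,
                                     parts$eta_singletons, n),
         fu_fs = fu_fs(parts$k_bar, parts$n_haplotypes, n),
         r2 = r2_from_parts(parts$U, parts$k_bar, parts$S, n),
         stop("dispatch error: unknown statistic '", statistic, "'",
              call. = FALSE))
}

#' Simulation-based significance for a neutrality statistic
#'
#' Builds the statistic's null distribution from constant-size coalescent
#' replicates conditioned on the observed number of segregating sites
#' (fixed-S conditioning: S mutations placed on each simulated genealogy
#' proportional to branch length), computes a two-sided p-value for the
#' observed value, and maps it to the buckets \code{ns}, \code{<0.05},
#' \code{<0.02}, \code{<0.01}.
#'
#' @param statistic one of \code{"tajima_d"}, \code{"fu_li_d_star"},
#'   \code{"fu_li_f_star"}, \code{"fu_fs"}, \code{"r2"}.
#' @param observed observed value of the statistic.
#' @param n sequence count.
#' @param S observed segregating sites (>= 1).
#' @param reps null replicates (>= 1000 recommended for the buckets).
#' @param seed RNG seed; fixed seed gives an identical bucket.
#' @return character bucket; the p-value is attached as
#'   \code{attr(, "p")}.
#' @export
neutrality_significance <- function(statistic, observed, n, S,
                                    reps = 2000L, seed = 1L) {
  stopifnot(S >= 1, reps >= 1)
  if (!statistic %in% c("tajima_d", "fu_li_d_star", "fu_li_f_star",
                        "fu_fs", "r2"))
    stop("dispatch error: unknown statistic '", statistic, "'",
         call. = FALSE)
  set.seed(as.integer(seed))
  null <- vapply(seq_len(reps), function(r) {
    v <- eval_neutrality_stat(statistic, sim_stats_fixed_s(n, S), n)
    as.numeric(v)
  }, numeric(1))
  null <- null[is.finite(null)]
  lo <- mean(null <= observed)
  hi <- mean(null >= observed)
  p <- min(1, 2 * min(lo, hi))
  bucket <- if (p < 0.01) "<0.01" else if (p < 0.02) "<0.02" else
    if (p < 0.05) "<0.05" else "ns"
  structure(bucket, p = p)
}

#' Generate a codon-structured toy genome with annotation
#'
#' Builds a random reference of alternating CDS and intergenic segments:
#' each CDS is a start codon, random internal codons free of stops, and a
#' stop codon, placed alternately on the + and - strand; each IGR is
#' random sequence. The companion annotation passes
#' [annotation_table()] validation by construction.
#'
#' @param n_cds number of CDS features.
#' @param cds_len length of each CDS in bp (divisible by 3, >= 6).
#' @param igr_len length of each intergenic segment in bp.
#' @param seed RNG seed.
#' @return list with \code{reference} (character sequence),
#'   \code{annotation} (an \code{rp_annotation}) and \code{replicon}
#'   (its name, \code{"toy"}).
#' @export
generate_toy_genome <- function(n_cds, cds_len, igr_len, seed) {
  stopifnot(n_cds >= 1, cds_len %% 3 == 0, cds_len >= 6, igr_len >= 0)
  set.seed(as.integer(seed))
  stops <- c("TAA", "TAG", "TGA")
  rand_codon <- function() {
    repeat {
      cd <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
      if (!cd %in% stops) return(cd)
    }
  }
  segs <- character(0)
  feats <- list()
  pos <- 1L
  for (g in seq_len(n_cds)) {
    n_internal <- cds_len / 3 - 2L
    cds <- paste0("ATG",
                  paste(vapply(seq_len(max(n_internal, 0L)),
                               function(i) rand_codon(), character(1)),
                        collapse = ""),
                  sample(stops, 1L))
    strand <- if (g %% 2L == 1L) "+" else "-"
    genomic <- if (strand == "+") cds else revcomp(cds)
    feats[[length(feats) + 1L]] <-
      data.frame(feature_id = sprintf("g%03d", g), replicon = "toy",
                 start = pos, end = pos + cds_len - 1L, strand = strand,
                 kind = "CDS", stringsAsFactors = FALSE)
    segs <- c(segs, genomic)
    pos <- pos + cds_len
    if (igr_len > 0L) {
      igr <- paste(sample(BASES, igr_len, replace = TRUE), collapse = "")
      feats[[length(feats) + 1L]] <-
        data.frame(feature_id = sprintf("i%03d", g), replicon = "toy",
                   start = pos, end = pos + igr_len - 1L, strand = "+",
                   kind = "IGR", stringsAsFactors = FALSE)
      segs <- c(segs, igr)
      pos <- pos + igr_len
    }
  }
  reference <- paste(segs, collapse = "")
  ann <- annotation_table(do.call(rbind, feats),
                          c(toy = reference))
  list(reference = reference, annotation = ann, replicon = "toy")
}

#' Plant SNPs of known class in a toy genome
#'
#' Chooses variant sites whose true class is known by construction:
#' sSNPs at coding positions where the chosen base change is synonymous,
#' nsSNPs where it is non-synonymous, iSNPs in intergenic segments. At
#' most one SNP is planted per position.
#'
#' @param genome list as returned by [generate_toy_genome()].
#' @param n_ssnp,n_nssnp,n_isnp desired counts per class.
#' @param seed RNG seed.
#' @return data.frame of SNP records with the ground-truth class in
#'   \code{snp_class}.
#' @export
plant_snps <- function(genome, n_ssnp, n_nssnp, n_isnp, seed) {
  set.seed(as.integer(seed))
  ann <- genome$annotation
  ref <- genome$reference
  f <- ann$features
  syn_pool <- list(); nonsyn_pool <- list()
  for (r in which(f$kind == "CDS")) {
    cds_seq <- substr(ref, f$start[r], f$end[r])
    if (f$strand[r] == "-") cds_seq <- revcomp(cds_seq)
    codons <- split_codons(cds_seq)
    for (ci in seq_along(codons)) {
      codon <- codons[ci]
      if (is_stop_codon(codon)) next
      for (p in 1:3) {
        off <- (ci - 1L) * 3L + p - 1L
        gpos <- if (f$strand[r] == "+") f$start[r] + off else
          f$end[r] - off
        for (b in setdiff(BASES, substr(codon, p, p))) {
          mut <- codon
          substr(mut, p, p) <- b
          gref <- substr(ref, gpos, gpos)
          galt <- if (f$strand[r] == "+") b else revcomp(b)
          entry <- list(position = gpos, ref = gref, alt = galt)
          if (identical(codon_aa(mut), codon_aa(codon)))
            syn_pool[[length(syn_pool) + 1L]] <- entry
          else nonsyn_pool[[length(nonsyn_pool) + 1L]] <- entry
        }
      }
    }
  }
  igr_pos <- unlist(lapply(which(f$kind == "IGR"), function(r)
    seq(f$start[r], f$end[r])))
  pick_distinct <- function(pool, k, taken) {
    pool <- pool[!vapply(pool, function(e) e$position %in% taken,
                         logical(1))]
    pos <- vapply(pool, `[[`, numeric(1), "position")
    keep <- !duplicated(pos)
    pool <- pool[keep]
    if (length(pool) < k)
      stop("capacity error: only ", length(pool),
           " candidate sites for ", k, " requested SNPs", call. = FALSE)
    pool[sample.int(length(pool), k)]
  }
  taken <- integer(0)
  recs <- list()
  add <- function(entries, cls) {
    for (e in entries) {
      fid <- if (cls == "iSNP") NA_character_ else
        host_cds(ann, genome$replicon, e$position)$feature_id
      recs[[length(recs) + 1L]] <<- snp_record(genome$replicon,
                                               e$position, e$ref, e$alt,
                                               cls, fid)
      taken <<- c(taken, e$position)
    }
  }
  if (n_ssnp > 0) add(pick_distinct(syn_pool, n_ssnp, taken), "sSNP")
  if (n_nssnp > 0) add(pick_distinct(nonsyn_pool, n_nssnp, taken),
                       "nsSNP")
  if (n_isnp > 0) {
    avail <- setdiff(igr_pos, taken)
    if (length(avail) < n_isnp)
      stop("capacity error: only ", length(avail),
           " intergenic sites for ", n_isnp, " requested iSNPs",
           call. = FALSE)
    pos <- sample(avail, n_isnp)
    ent <- lapply(pos, function(p) {
      gref <- substr(ref, p, p)
      list(position = p, ref = gref,
           alt = sample(setdiff(BASES, gref), 1L))
    })
    add(ent, "iSNP")
  }
  do.call(rbind, recs)
}
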