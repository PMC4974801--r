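---
title: "Diversity, neutrality and expansion-time inference for clonal bacterial populations"
author: "rhizopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, neutrality and expansion-time inference for clonal bacterial populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizopop)
```

## The problem

A localized clonal bacterial population — here modelled on
*Sinorhizobium meliloti* isolates sampled from a single alfalfa field —
carries very little nucleotide variation (on the order of 1–2 × 10⁻⁴
differences per site), yet the *shape* of that variation is informative:
an excess of rare variants, many distinct haplotypes, and a smooth
unimodal distribution of pairwise differences are the joint signature of
a recent demographic expansion. This package implements the full chain
from variant classification to expansion-time inference for such data:

1. **SNP-class accounting.** Variants are classified as synonymous
   (sSNP), non-synonymous (nsSNP) or intergenic (iSNP) against a
   CDS/IGR annotation, and the observed nsSNP/sSNP ratio is contrasted
   with a degeneracy-based null (the ratio of non-synonymous to
   synonymous single-base *mutation opportunities* under uniform
   mutation and no selection).
2. **Neutrality statistics.** Watterson's $\theta_W$, nucleotide
   diversity $\pi$, Tajima's $D$ (also restricted to synonymous or
   non-synonymous sites), Fu & Li's $D^*$ and $F^*$, Fu's $F_s$ and the
   Ramos-Onsins & Rozas $R_2$, with simulation-based significance.
3. **Mismatch-distribution demography.** The three-parameter sudden
   expansion model $(\theta_0, \theta_1, \tau)$ fitted to the pairwise
   difference distribution, Harpending's raggedness index, and the
   strict-clock conversion $t = \tau / (2 \upsilon L)$ from mutational
   time to years.
4. **A coalescent simulator** with infinite-sites mutation under
   constant size, sudden expansion or exponential growth, which both
   generates all test data and provides the null distributions for
   significance.

## Data model and missing data

The unit of analysis is an alignment of $n$ equal-length haploid
sequences over `A C G T N -`. All statistics apply **complete
deletion**: any column containing `N` or a gap is removed before
anything is counted, and the reported $L$ is the number of sites that
survive. This is the most conservative of the common policies (the
alternative, pairwise deletion, makes $\pi$ and the mismatch
distribution inconsistent with each other on the same data) and matches
the default of the widely used desktop packages for these statistics.

On real alignments a column with $a$ alleles contributes $a - 1$ to the
total mutation count $\eta$ and 1 to $S$; under the simulator's
infinite-sites output $\eta = S$ exactly. Singleton mutations are those
whose minor allele is carried by exactly one sequence; at $n = 2$ each
segregating site is a singleton.

## SNP classification and the degeneracy null

A variant inside an annotated CDS is classified by strand-aware codon
translation: the affected codon is reconstructed on the coding strand
(reverse-complementing for minus-strand features), translated with the
reference and the alternate base, and called synonymous exactly when
the amino acid is unchanged. Start and stop codons are classified by
the same rule; variants outside every CDS are intergenic.

Degeneracy counting tracks 0-, 2-, 3- and 4-fold classes. The 3-fold
sites (isoleucine third positions) are kept as their own class rather
than folded into the 2- or 4-fold bins, because the conventional 0/2/4
summary leaves their binning genuinely ambiguous; reports list them
separately. Stop codons are excluded from degeneracy counting and from
the null-ratio enumeration, while a mutation that *creates* a stop
counts as non-synonymous — the conventional choices.

The null nsSNP/sSNP ratio enumerates all $9$ single-base changes of
every codon and classifies each one; for a typical bacterial CDS
composition it lands near 3:1, so an observed ratio well below the null
(e.g. 1.6) indicates purifying selection and/or demographic loss of
diversity rather than neutrality.

The per-site variant filters mirror standard short-read calling
practice: minimum coverage 6, maximum variant P-value 6×10⁻⁶, variant
base in ≥ 95 % of unique reads, and a two-part strand-bias rule — the
strand-bias P-value threshold (5×10⁻⁵) applies *only* when more than
65 % of variant reads sit on one strand. Because the rule conditions on
the bias magnitude, the site summary carries a `strand_bias` fraction
(majority-strand share of variant reads, 0.5 = balanced, default when a
caller does not report it) alongside the P-values.

## Neutrality statistics

With $\bar k$ the mean number of pairwise differences per sequence pair
(per locus), $S$ segregating sites and $a_1 = \sum_{i=1}^{n-1} 1/i$:

$$\theta_W = \frac{S}{a_1 L}, \qquad
  D = \frac{\bar k - S/a_1}{\sqrt{e_1 S + e_2 S(S-1)}}$$

with Tajima's constants $e_1, e_2$ from $n$. Fu & Li's outgroup-free
$D^*$ and $F^*$ contrast the singleton count $\eta_s$ against $\eta$
and $\bar k$ respectively, using the corrected variance constants; the
test suite carries a second, independently coded transcription of those
constants as an oracle, plus the requirement that the means of $D$,
$D^*$ and $F^*$ sit within ±0.1 of zero over 2000 neutral coalescent
replicates.

Fu's $F_s$ computes $S' = P(K \ge k_{obs})$ under the Ewens sampling
distribution with $\theta = \bar k$, via unsigned Stirling numbers of
the first kind, and returns $\ln(S'/(1-S'))$. The Stirling recurrence
runs in log space so sample sizes well beyond $n = 14$ stay finite, and
it is checked to 12 significant digits against an exhaustive
Chinese-restaurant-process enumeration for $n \le 6$. $R_2$ combines
per-sequence singleton loads $U_i$ with $\bar k$:
$R_2 = \sqrt{n^{-1}\sum_i (U_i - \bar k/2)^2} / S$, which is $1/2$
exactly at $n = 2$.

Statistics that are undefined ($S = 0$, $\eta = 0$, $\bar k = 0$, or a
numerically degenerate $S'$) are returned as *flagged* values carrying
the reason (`is_undefined_stat()`), never as a silent zero or NaN.

### Significance

Published tables of these statistics mark significance with stars, but
the generating null is rarely stated. This package makes one explicit,
seedable choice: **fixed-S conditional coalescent simulation**. For each
replicate a constant-size genealogy is drawn, the observed number of
mutations is placed on branches proportional to branch length, the
statistic is recomputed, and a two-sided p-value is taken from the
resulting distribution, then bucketed as `ns`, `<0.05`, `<0.02`,
`<0.01` (rendered `*` / `**`). Conditioning on $S$ rather than
$\theta$ avoids having to estimate $\theta$ under the alternative and is
one of the two standard conventions; with 2000+ replicates the bucket
for values as extreme as $D = -2.2$ at $S \sim 120$, $n = 14$ is stably
`<0.01`.

### Per-class Tajima's D

For $D$ restricted to synonymous or non-synonymous variation, the
segregating columns inside CDSs are classified by the same codon rule
(a site whose changes are all synonymous is a synonymous site; any
non-synonymous change makes it non-synonymous), $\bar k$ and $S$ are
recomputed on that subset, and the per-site scalings use the
Nei–Gojobori estimated synonymous (resp. non-synonymous) site counts —
each codon position contributes (synonymous one-step changes)/3
synonymous sites. $D$ itself depends only on $\bar k$, $S$ and $n$, so
the site-count convention affects only the reported per-site $\pi$ and
$\theta$ for the class.

## The mismatch model

In a stationary population the probability that a random pair differs
at $i$ sites is geometric,
$\hat F_i(\theta) = \theta^i/(\theta+1)^{i+1}$. After a sudden jump
from scaled size $\theta_0$ to $\theta_1$ at mutational time $\tau$
before present, the non-equilibrium solution is the Poisson mixture

$$F_i(\tau) = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
  \sum_{j=0}^{i} \frac{\tau^j}{j!}
  \left[\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)\right].$$

Transcription errors in this formula are common, so the implementation
is validated two independent ways before use: against direct numerical
quadrature of the pair-coalescence integral through the size change,
and against the package's own coalescent simulator under the same
demography (the two modules validate each other). It reduces to
$\hat F_i(\theta_0)$ at $\tau = 0$ and to $\hat F_i(\theta_1)$ for
large $\tau$, and sums to 1 over classes.

### Fitting

`fit_sudden_expansion()` minimizes the sum of squared deviations
between observed and model frequencies over the observed classes, by
bounded quasi-Newton search from 16 multi-start points on a log grid.
Bounds are $\theta_0 \in [0, \hat\theta_\pi]$ (the observed mean
pairwise difference — pre-expansion diversity cannot exceed it),
$\theta_1 \in [\theta_0, 10^4]$ and $\tau \in [0, 2\,d_{max}]$. The
reparameterization $(\theta_0, \theta_1 - \theta_0, \tau)$ keeps the
ordering constraint inside a rectangular box. On an exact model curve
the fit recovers the parameters with SSE below $10^{-12}$; on simulated
expansion panels ($n = 14$) the mean fitted $\tau$ is within a few
percent of truth. Rogers' method-of-moments estimates
($\hat\theta_0 = \sqrt{v - m}$, $\hat\tau = m - \hat\theta_0$ from the
mean and variance, assuming a large post-expansion size) are reported
alongside the least-squares values, labelled, since "the" $\tau$
estimator differs between software traditions. A distribution with all
mass at zero differences is flagged degenerate with $\tau = 0$ rather
than fitted.

Harpending's raggedness
$r = \sum_{i=1}^{d_{max}} (x_i - x_{i-1})^2$ is computed over the
observed classes with at most one empty class beyond the last nonzero
frequency entering the sum (so padding with further empty classes never
changes $r$) and no wrap-around term; the literature is inconsistent on
both points, so the convention is fixed here.

### Calendar time

$\tau$ is in units of mutational time ($\tau = 2\upsilon t$ with
$\upsilon$ the per-locus mutation rate), so
$t = \tau / (2 \upsilon L)$ years with $\upsilon$ per site per year and
$L$ the analysed locus length. The default clock describes soil
rhizobia: 0.0033 mutations per genome per generation (a universal
bacterial rate), 44 generations per year (≈ 200 h per generation), and
a 7,139,558 bp genome, giving
$\upsilon = 0.0033 / 7{,}139{,}558 \times 44 = 2.03 \times 10^{-8}$
per site per year. Outputs are labelled years *before sampling*; no
calibration beyond the strict clock is attempted, and estimates scale
inversely with the assumed rate — a different universal rate shifts all
dates proportionally.

```{r clock}
convert_mutation_rate(0.0033, 7139558, 44)
time_since_expansion(2 * 2.03e-8 * 146721 * 3000,
                     clock_parameters(rate_per_site_per_year = 2.03e-8,
                                      locus_length = 146721))$years
```

## The simulator

The coalescent runs directly in mutational-time units: a pair of
lineages coalesces at rate $1/\theta(t)$ per unit, and each lineage
mutates at rate $1/2$, so a pair separated for time $T$ accumulates
Poisson($T$) differences and the stationary mismatch distribution is
exactly $\hat F_i(\theta)$ — the simulator and the mismatch model share
one parameterization, which is what makes the recovery tests coherent.
Sudden expansion rescales the coalescence intensity at backward time
$\tau$; exponential growth uses the closed-form inverse of the
integrated hazard.

Mutations are placed at distinct uniformly chosen sites. The
infinite-sites contract is enforced by a birthday bound: a replicate
drawing $m$ mutations on $L$ sites errors out if
$m(m-1)/2L \ge 1\,\%$. A consequence worth stating: at the real data's
scale ($S \approx 120$ on $\approx 147$ kb) this bound requires roughly
$L \ge 50\,S^2 \approx 0.75$ Mb of site capacity, so synthetic panels
use a larger $L$ (and hence lower per-site diversity) than the field
population they emulate. Every statistic in the package except the
per-site scalings of $\pi$ and $\theta_W$ is dimensionless in $L$, so
this changes nothing in the calibration tests.

The ancestral sequence is all-A and each mutation flips its site to a
uniformly chosen other base; all statistics here are allele-label
invariant, so this costs no generality. One master seed expands to
per-replicate seeds by a fixed counter scheme recorded in each output,
and a fixed seed reproduces alignments bit-identically. For large
calibration sweeps `sequences = FALSE` skips string construction and
returns the genealogy-derived summary parts; tests assert these equal
the alignment-derived statistics on the same seed.

Toy genomes for classifier testing alternate CDSs (start codon, random
stop-free interior, stop codon, alternating strands) with random
intergenic segments, and `plant_snps()` chooses variant sites whose
class is known by construction — the classifier is required to recover
100 % of planted labels across seeds.

## Worked example

```{r example, eval = FALSE}
model <- demographic_model("sudden_expansion", theta0 = 0.5,
                           theta1 = 50, tau = 5)
sim <- simulate_coalescent(14, model, 1.5e6, seed = 20260101)
ns <- neutrality_summary(sim$alignment, significance_reps = 2000,
                         seed = 42)
ns$tajima_d        # strongly negative
fit <- fit_sudden_expansion(observed_mismatch(sim$alignment))
fit$tau            # near the generating value 5
time_since_expansion(fit$tau,
                     clock_parameters(locus_length = sim$alignment$L))
```

## UPGMA and trees

Isolate dendrograms come from average-linkage agglomeration of the
per-site pairwise distance matrix. Labels are sorted before clustering
so ties resolve by the lexicographically smallest pair, making the tree
independent of input order; the result is ultrametric with a leaf
joined at distance $d$ sitting $d/2$ below the join. Trees serialize as
newick with branch lengths.

## Problem sizes and runtime choices

The shipped tests use the sizes at which the statistical claims are
actually made: 2000 constant-size replicates for the neutral
calibration of $D$, $D^*$, $F^*$ and the $E[S]$, $E[\pi]$ closed
forms; 200 expansion panels for the $\tau$-recovery bias bound
(< 15 %); 3000 pair-replicates for the simulator-vs-formula mismatch
cross-check; 5000 draws for the coalescent waiting-time
Kolmogorov–Smirnov test; 50 seeds for planted-class recovery. Null
distributions for significance default to 1000–2000 replicates, enough
to separate the `<0.01` bucket from `<0.05` at the observed effect
sizes.

## Limitations

* No recombination, gene conversion, selection or migration in the
  simulator, and no algorithmic recombination masking for real data —
  regions with recombination signatures must be excluded upstream, as
  is standard for these statistics.
* Infinite sites throughout: no multiple hits, no finite-sites
  correction to $\pi$ (negligible at the 10⁻⁴ diversities targeted,
  where the Jukes–Cantor correction would change $\pi$ in the sixth
  decimal).
* Only the sudden-expansion mismatch model is fitted; exponential
  growth is available in the simulator but not as a fitted model, and
  no bootstrap intervals on $\tau$ are produced.
* Significance buckets depend on the stated null convention (fixed-S,
  two-sided); other software may print different stars for the same
  data under a different null.
* Calendar dates inherit the strict clock's assumptions wholesale;
  they should be read as order-of-magnitude statements conditional on
  the assumed rate.
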