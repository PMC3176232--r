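---
title: "Selection scans on candidate defense genes: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection scans on candidate defense genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aspenselect)
```

## The scientific setting

`aspenselect` implements a per-gene molecular population genetics workflow
of the kind used to ask whether candidate defense genes in a forest tree —
here modeled on wound-inducible genes of European aspen (*Populus
tremula*), with *P. trichocarpa* as outgroup — evolve neutrally, under
recurrent selective sweeps, or under balancing selection. The unit of
analysis is a per-gene multiple sequence alignment of ingroup haplotypes
plus one outgroup sequence, with an exon map defining the reading frame.
From each such alignment the package computes:

* **Diversity and divergence**: segregating sites $S$; per-site pairwise
  diversity $\pi$ for all sites and, via Nei–Gojobori site counting, for
  synonymous and replacement sites separately; Jukes–Cantor corrected
  synonymous and replacement divergence $K_s$, $K_a$ from the outgroup.
* **SFS-shape neutrality tests**: Tajima's $D$ and the normalized Fay &
  Wu's $H$, the latter on the unfolded site frequency spectrum polarized
  by the outgroup.
* **McDonald–Kreitman tests**: the 2×2 table of fixed/polymorphic ×
  synonymous/replacement counts, the neutrality index
  $NI = (P_n/P_s)/(D_n/D_s)$, the likelihood-ratio $G$ statistic with its
  $\chi^2_1$ p-value, and Fisher's exact p.
* **Sliding-window scans**: synonymous diversity in 75 bp windows stepped
  by 8 bp; $D$, $H$ and both $K_a/K_s$ tracks (divergence ratio and the
  polymorphism ratio $\pi_{rep}/\pi_{syn}$) in 250 bp windows stepped by
  25 bp, with simulated 95% confidence bands.
* **Coalescent nulls**: empirical p-values and window bands from a
  Hudson-style coalescent without recombination, conditioned on the
  observed number of segregating sites, under constant size or a
  bottleneck demography supplied as posterior draws.

## Site bookkeeping: complete deletion and one shared mask

All statistics share one mask build (`build_site_masks()`): a column with
a gap or N in *any* ingroup haplotype is excluded everywhere (complete
deletion), and an outgroup gap/N additionally removes the column from
polarized analyses only. This makes every per-site denominator identical
across statistics, at the price of discarding some information relative
to pairwise deletion. Codons containing any masked column are excluded
whole, which keeps the reading-frame bookkeeping exact. Coordinates are
0-based half-open internally and 1-based inclusive in every emitted
table.

Haplotypes carrying a stop codon at a position where the ingroup
consensus is a sense codon are dropped with a warning naming the
sequence: such stops almost always indicate a frame or annotation error,
and silently keeping them would corrupt the synonymous/replacement
partition. Codons at which every sequence carries a stop (a conserved
terminal stop) are simply excluded from class-specific statistics.

## Synonymous/replacement partitioning

Site counts and difference classification follow Nei & Gojobori (1986):
each codon contributes fractional synonymous sites (the fraction of its
nine single-base neighbors that preserve the amino acid, with changes to
stop codons counted as replacement), averaged over the sampled sequences;
multi-base codon differences are decomposed by enumerating all orderings
of the differing positions, discarding pathways through stop codons, and
averaging the step classifications. When every pathway passes through a
stop, the package falls back to averaging over all pathways with
stop-creating steps counted as replacement, and flags the codon.
Within-species $\pi$ is left uncorrected; between-species divergence is
Jukes–Cantor corrected, $K = -\tfrac{3}{4}\ln(1 - \tfrac{4p}{3})$, with a
hard error at $p \ge 0.75$.

In the MK table, a site that is polymorphic within the ingroup *and*
different from the outgroup counts as polymorphism only; each derived
state of a multi-allelic site counts as one polymorphism and the site is
flagged. Pathway-averaged counts can be fractional and are kept exact
internally; only table-styled display rounds them.

## The coalescent null

The simulator is a standard n-coalescent without recombination. Time is
measured in coalescent units of $2N_0$ generations: with $k$ lineages in
an epoch of relative size $\lambda$, the waiting time to the next
coalescence is exponential with rate $k(k-1)/(2\lambda)$, integrated
piecewise across epoch boundaries for bottleneck models. With
$\theta = 4N_0\mu$, mutations in theta mode are
$\mathrm{Poisson}(\theta\,T_{total}/2)$, giving Watterson's expectation
$E[S] = \theta a_n$; expressed in units of $4N_0$ generations (halve the
times), $E[T_{MRCA}] = 0.5$ for a pair. Fixed-$S$ mode places exactly $S$
mutations on the realized genealogy with probability proportional to
branch length — Hudson's `-s` semantics, which is not identical to
rejection-sampling the $\theta$ model conditional on $S$; theta mode is
provided for sensitivity checks. Bottleneck demography is consumed as a
table of epoch-parameter draws (`start_i`/`size_i` columns), one row
sampled per replicate; a small synthetic three-epoch table, labeled
non-biological, ships in `inst/extdata/` for testing.

Empirical p-values use the add-one rank formula
$p = (1 + \#\{\text{at least as extreme}\})/(R_{valid} + 1)$; replicates
with an undefined statistic (e.g. $S = 0$ in theta mode) are excluded
from ranking and counted. Both one-tailed (in the direction of the
observed deviation) and two-tailed p-values are reported, since the tail
convention of published per-gene p-values is rarely stated. Gene-level
tests condition on the observed $S$ by default.

Two numerical properties of the null are worth knowing. First, the
*normalized* statistics do not have mean zero under neutrality: at
$n = 24$ the neutral mean of Tajima's $D$ is about $-0.08$ and of
normalized $H$ about $+0.08$. This is a property of the studentized
ratios (their numerators $\pi - \hat\theta_W$ and $\pi - \hat\theta_L$
are exactly centred), and the package's distributions agree with an
independent reference coalescent (msprime) to two-sample KS p > 0.8.
Second, the 95% band width of $D$ is *not* monotone in the window's $S$:
at $S = 2$ the conditional null is supported on few points and its band
is, if anything, narrower than at $S = 20$; low-polymorphism windows
mainly lose resolution, not spread.

Window bands are simulated per distinct $S$ (windows sharing $S$ share
bands, which also makes the track cheaper), at the gene's own $n$, under
the same demography as the gene-level test. No multiple-testing
correction is applied across windows — the scan is exploratory — and the
output metadata says so.

## The window engine

Windows run over alignment coordinates of the full sequenced region,
introns included, because the figures this reproduces draw gene structure
beneath full-length tracks; class-specific statistics then use only the
coding columns (whole codons) inside each window. Only full-width windows
are produced (`floor((L - width)/step) + 1` of them); a window in which a
statistic is undefined (no segregating site, no class sites, zero
synonymous denominator of a $K_a/K_s$ ratio) emits NA rather than an
infinity, so excursions are always finite and thresholdable. The outlier
cutoff for $K_a/K_s$ tracks is the interpolated 95th percentile of a
reference-locus panel, with 1.14 as the conventional default when no
panel is supplied.

## The synthetic-data generator

Because the study this package models deposits no sequences, the
generator is first-class: it produces coding alignments with outgroup
whose every mutation is recorded in a truth table (position, ancestral
and derived base, class, derived count), so each pipeline stage can be
validated against the generator's own bookkeeping.

A gene is generated as: a random sense-codon ancestral sequence over the
configured exon layout; a coalescent genealogy per scenario; ingroup
mutations $\mathrm{Poisson}(\theta_{locus} T_{total}/2)$ placed on
branches by length; outgroup mutations
$\mathrm{Poisson}(\theta_{locus}\,t_{div})$ on a branch of length
$2\,t_{div}$ hanging off the ingroup root. Each mutation is mapped to a
sequence position honoring codon structure: synonymous and non-coding
changes are accepted, replacement changes with probability $\omega$, and
rejected proposals are re-drawn elsewhere. Re-proposal (rather than
discarding) means the configured $\theta$ is recovered exactly by
Watterson's estimator — a deliberate choice, since matching observed $S$
values is what the study conditions on — but it concentrates accepted
changes onto synonymous and non-coding sites. The resulting enrichment of
per-synonymous-site divergence is computed analytically
(`syn_divergence_factor`), and `table1_like_configs()` inverts it, along
with the Jukes–Cantor correction and the ingroup-side contribution
$E[T_{MRCA}] \approx 2(1 - 1/n)$, when calibrating divergence times to
the published per-gene $K_s$ values (0.033–0.079).

Two stop-safety rules make the generated data well-formed by
construction: every accepted change is itself sense-preserving, and at
most one mutation is placed per codon per side (ingroup/outgroup), so no
haplotype can combine individually-sense changes into a stop codon. The
one-per-codon cap is a mild thinning that only binds in extreme
configurations (it is counted and reported when it does).

Scenarios are genealogy-shaping approximations, not forward selection
simulations:

* **sweep**: a fraction (default 0.85) of lineages coalesces in a star at
  a recent time (default 0.05), the rest neutrally afterwards. Mutations
  on the star's parent branch segregate at high derived frequency,
  driving $H$ negative.
* **balanced**: two clades (default frequencies 0.5/0.5) coalesce
  internally and merge only beyond a deep split (default depth 3).
  Deep-branch mutations segregate at intermediate frequency, driving $D$
  positive.

With the default parameters, 100 replicate genes per scenario separate
the signatures by about 10 combined standard errors
(`scenario_signature_check()`); the defaults were chosen once, for
scientific plausibility (a just-completed hard sweep; an old balanced
polymorphism), not tuned to any test.

What the generator does *not* emulate: recombination (consistent with
the no-recombination null), gap/missing-data structure, base
composition bias, CpG effects, sequencing error, and linkage to flanking
genes. Passing tests on synthetic data therefore demonstrate internal
consistency of the statistics and calibration of the null machinery —
not robustness to alignment error or demographic misspecification in
real data.

## Study-shaped defaults and problem sizes

`table1_like_configs()` mirrors the eight published gene shapes
(haplotype counts 22–54, lengths 1035–3454 bp, 1–4 exons), with per-site
$\theta$ chosen so the expected $S$ matches each gene's published count
and divergence times calibrated as above; $\omega = 0.25$ reflects the
predominance of purifying selection on replacement sites. The analysis
drivers use $R = 2000$ gene-level null replicates and $R = 1000$ per
distinct window $S$ (the full design uses $10^4$); the calibration
driver uses $5\times10^4$ pair-coalescent replicates, $10^4$ Watterson
replicates, and 200 uniformity trials at $R = 999$. The test suite runs
the uniformity check at the documented calibration condition $n = 12$,
$S = 15$, 500 trials — small enough for the discrete null's ties to be
negligible against a continuous-uniform KS reference.

## Known limitations

* Fixed-$S$ conditioning is Hudson's, not the exact conditional
  $\theta$-model likelihood; for small $S$ the two differ measurably.
* The MK builder classifies polymorphisms against the ingroup consensus
  codon; when an outgroup-divergent codon also carries a majority-derived
  ingroup variant, the fixed-difference context can differ from the
  mutation's historical context. This mirrors what any
  sequence-only method can know.
* $-\log_{10}(NI)$ recomputed from rounded integer count tables can
  differ in the second decimal from values computed on fractional
  internal counts (one of the eight published rows shows exactly this).
* No recombination anywhere; gene-level tests are therefore conservative
  for $D$/$H$ outliers, as argued in the literature this follows.
* Reference-panel $K_a/K_s$ values are consumed as given; their
  sequences are not re-analyzed.
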