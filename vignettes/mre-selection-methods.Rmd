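---
title: "Quantifying and selecting condition-specific microRNA response elements"
author: "mreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and selecting condition-specific microRNA response elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(mreq))
```

# The problem

MicroRNAs repress mRNAs by pairing their seed region (positions 2--8 of the
mature microRNA) with short complementary sites -- microRNA response
elements (MREs) -- that sit mostly in 3'UTRs. Standard RNA-Seq differential
expression summarizes a gene as one number and discards where on the
transcript the reads fell. But reads covering a 3'UTR carry positional
information: how much sequencing support each individual MRE has, in each
sample. `mreq` turns UTR-restricted alignments into a per-sample matrix of
MRE read support, makes the values comparable across samples, and asks
which MREs are specific to one condition among several (for example, one
tumor subtype against other subtypes and all normal-adjacent tissue).
Because each MRE names both an mRNA and a microRNA family, a selected MRE
set decouples into two interacting partner lists, which is the biological
deliverable.

# Site catalog

For a microRNA with seed-derived match sequence $S$ (the DNA reverse
complement of positions 2--8), the four canonical site types are

| type | sequence | length |
|------|----------|--------|
| 8mer | $S$ + `A` | 8 |
| 7mer-m8 | $S$ | 7 |
| 7mer-A1 | $S[2..7]$ + `A` | 7 |
| 6mer | $S[2..7]$ | 6 |

The terminal `A` opposite microRNA position 1 is recognized directly, which
is why it is an `A` on the site regardless of the microRNA's first base.

The catalog enumerates every exact occurrence of every requested site
sequence on every gene's spliced, transcript-sense 3'UTR. Two rules matter:

* **Exact matching.** For motifs of 6--8 nt against a flat background, a
  motif-significance scan at conventional thresholds admits exactly the
  perfect matches, so exact string matching gives the same catalog while
  being deterministic and dependency-free. `N` bases never match.
* **Longest site wins.** An 8mer occurrence contains a 7mer-m8, a 7mer-A1
  and a 6mer occurrence of the same family at the same locus. Counting all
  four would count one binding site repeatedly, so within one
  (gene, family) the catalog suppresses any occurrence fully contained in a
  longer one; at identical intervals (possible for near-homopolymer seeds)
  the higher-priority type (8mer first) is kept. Overlapping but
  non-nested occurrences are all kept.

Offsets are 0-based on the spliced UTR; BED input is 0-based half-open;
minus-strand genes are spliced in genomic order and reverse-complemented.
Which site types make up a deployment's MRE universe is a setting
(`siteTypes`), defaulting to all four.

# Quantification

Reads are assigned to a gene when their aligned span overlaps any of its
UTR intervals by at least `minOverlap` (default 1 nt); a read overlapping
several genes' UTRs counts for each of them but once in the library size
$N_s$, which is defined as reads assigned to any UTR -- the only total that
is guaranteed to exist when the input is already UTR-restricted.

Two counting modes are provided because the two natural pictures of
"reads supporting an MRE" differ subtly:

* **sequence** (default): each assigned read's sequence is scanned for the
  family's catalogued site sequences; every motif occurrence counts, in
  both orientations by default (unstranded libraries), with a palindromic
  occurrence counted once. This is faithful to a pipeline that converts
  the UTR alignment back to FASTQ and scans motifs, which discards
  coordinates.
* **coordinate**: a fragment counts for a site when its aligned span fully
  contains the site's genomic interval, with paired mates deduplicated per
  site. This is the vertical-dotted-line picture of read-over-site
  counting.

On error-free reads that are exact substrings of the UTR the two agree,
and the test suite asserts this on simulated data. On real data sequence
mode can only over-count relative to coordinate mode (sequencing errors
destroy matches, but revcomp hits and soft-clipped bases can add them);
both are exposed, and `--stranded` restricts scanning to the sense
orientation. Counts are reported at the (gene, microRNA family) level --
`"gene|family"` keys -- the unit at which downstream statistics operate.

# Normalization

Raw support depends on sequencing depth, on how long the UTR is, and on a
sample-specific GC effect (library preparation and amplification favor
different GC ranges in different samples). Two stages:

1. **Depth and length** (per value):
   $y = \log_2(c + p) - \log_2(N_s/10^6) - \log_2(L_g/10^3)$, an RPKM-like
   log2 value with pseudocount $p = 0.5$ (the common log-CPM choice; it
   only matters near zero and keeps all values finite).
2. **GC** (fitted): rows are binned by their gene's GC fraction (20
   equal-width bins on $[0,1]$; bins with fewer than 50 rows are merged
   with a neighbor so medians are stable). For sample $s$ and bin $b$ the
   model records the within-bin median $m_{s,b}$ and the across-sample
   grand median $\bar m_b$; the correction subtracts
   $\delta_s(\mathrm{gc}) = \mathrm{interp}(m_{s,\cdot} - \bar m_\cdot)$,
   interpolated linearly between bin centers and held constant beyond the
   outer centers.

This binned-median offset is a deliberately simple stand-in for
spline-based conditional quantile normalization: it removes the same
systematic per-sample GC trend, is exactly reproducible, and has clean
invariants the tests exercise -- the correction is a pure shift within
(sample x bin), so in-bin ranks are untouched, and corrected bin medians
coincide across samples at bin centers to machine precision. What it does
not do is adjust higher quantiles separately from the median; a
full-quantile implementation can be slotted in behind the same
`fitGCCorrection()` / `applyGCCorrection()` interface. Covariates are
per-gene (one length and one GC value applied to every MRE row of that
gene): MRE rows of one gene share their UTR, and the normalization is not
meant to support between-gene abundance claims. A sample with all-identical
values carries no GC signal and gets zero offsets with a warning; a sample
with $N_s = 0$ cannot be normalized and must be excluded.

# Selection

Two complementary routes, intersected.

## Pairwise multiple comparisons (DTK route)

On normalized values, every pair among the $k$ groups is compared with
Dunnett's C -- the concrete procedure behind the Dunnett--Tukey--Kramer
test, chosen because group variances are visibly unequal between tumor
subtypes and it handles unequal $n_i$; with equal variances it reduces to
Tukey--Kramer, and with $k = 2$ to the two-sided $t$ test (an identity,
$q_{\alpha,2,\nu} = \sqrt 2\, t_{\alpha/2,\nu}$, that the tests verify
numerically). For pair $(i,j)$:

$$SE_{ij} = \sqrt{s_i^2/n_i + s_j^2/n_j}, \qquad
q^*_{ij} = \frac{q_{\alpha,k,\nu_i}\, s_i^2/n_i +
                 q_{\alpha,k,\nu_j}\, s_j^2/n_j}{s_i^2/n_i + s_j^2/n_j},$$

with $\nu_i = n_i - 1$ and $q$ the studentized-range quantile; the pair is
significant when $|\bar x_i - \bar x_j| > q^*_{ij} SE_{ij}/\sqrt 2$.
An MRE is **target-specific** when all $k-1$ pairs involving the target
group are significant *and* the target sits on the same side of every
other group. The sign-consistency requirement is the package's reading of
"unique to the target condition" -- without it, an MRE merely unusual in
both directions would pass -- and it is switchable
(`requireSignConsistency = FALSE`). Zero-variance degenerate pairs get a
zero half-width: equal constants are non-significant, unequal constants
are flagged `degenerate` but significant.

Monte-Carlo checks at the study design ($k = 6$, $n = 13$/group) show the
family-wise error held below $\alpha$ and essentially complete selection
power at a $5\sigma$ target shift (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`).

## Count-based differential test (DE route)

On raw counts of the target tumor group versus its matched normal group,
the package follows the classic exact-test structure for NB counts:

* **TMM factors**: doubly trimmed (30% on M, 5% on A), precision-weighted
  mean of log-ratios against the column whose 75th percentile is closest
  to the mean; factors rescaled to geometric mean 1. The implementation is
  cross-checked in the tests against an independent reference
  implementation to 1e-10.
* **Common dispersion** by method of moments:
  $\hat\phi = (\hat v - \hat\mu)/\hat\mu^2$ per row on factor-scaled
  counts, pooled across the two conditions, median across rows, floored at
  0. This deliberately omits empirical-Bayes tagwise shrinkage: a single
  common $\phi$ is what the conditional test below consumes.
* **Conditional NB exact test**: per-sample counts are rescaled to the
  geometric-mean effective library size, summed per condition and rounded
  to pseudo-counts $T$ and $N$; conditional on $z = T + N$, the null law
  of $T$ is proportional to
  $\mathrm{NB}(t;\, n_T/\phi,\, z\pi)\,\mathrm{NB}(z-t;\, n_N/\phi,\,
  z(1-\pi))$ with $\pi = n_T/(n_T+n_N)$, enumerated over $t = 0..z$; at
  $\phi = 0$ this is exactly the binomial law, and the implementation is
  verified against the exact binomial test by enumeration. The two-sided
  p-value sums outcomes no more likely than the observed one, the observed
  point mass counted once (ties included via a $1 + 10^{-7}$ relative
  guard, matching exact-test convention). $z = 0$ gives $p = 1$.
* **Fold change** $\log_2\frac{T/n_T + 0.5}{N/n_N + 0.5}$, and BH
  adjustment (`stats::p.adjust`). Thresholds default to FDR < 0.05 and
  $|\log_2 FC| \ge 2$.

Pairing of tumor and normal samples from the same case is *not* modeled
(the exact test treats samples as exchangeable within condition); this is
a known limitation of the classic-exact-test design and is stated here
rather than patched.

## Intersection and decoupling

The condition-specific set is the intersection of the two routes' key
sets: an MRE must stand apart from every group on normalized values *and*
show a large, well-supported tumor/normal fold change on raw counts.
Decoupling then yields the unique mRNA list, the unique microRNA family
list, the pair table, and per-gene multiplicity (genes hosting two or more
selected MREs are reported separately, since repeatedly used mRNAs are
candidate regulatory hubs). All outputs are lexicographically ordered and
the operation is idempotent.

# The synthetic-data generator

`simConfig()` defaults encode the study design the pipeline targets: six
groups (three subtypes x tumor/normal-adjacent) of 13 samples; 200 genes
with UTRs of 500--2000 nt and GC drawn from 0.30--0.70; 50 microRNA
families with 5 planted sites per gene (1000 (gene, family) rows); NB
counts with baseline mean 100 and dispersion 0.2 (typical bulk RNA-Seq
overdispersion); log-uniform per-sample depth factors in 0.75--1.35; 10%
of rows planted with a target-group multiplier of $2^{\pm 3}$
($|\log_2 FC| = 3$, direction random per row).

Design choices that make the truth *exact* rather than approximate:

* Seed regions are redrawn until no family's site sequence occurs inside
  another family's sites in either orientation, so planted sites are
  family-exclusive.
* Background sequence is iteratively repaired until the only site-motif
  occurrences on a UTR (either orientation) lie inside planted sites of
  their own family. The planted site list is then *exactly* the catalog
  the scanner recovers, and simulated reads carry no stochastic false
  support. With a degenerate GC range the repair swaps bases instead of
  resampling them, preserving exact base composition.
* Planted sites are spaced at least one read length apart, so no read can
  support two sites.
* Reads are error-free substrings covering their site (SAM coordinates
  correct, minus-strand genes stored reverse-complemented), which makes
  coordinate-mode quantification recover the count matrix identically and
  ties the two counting modes together.

Everything is driven by R's RNG under a single integer seed (stage
offsets seed, seed+1, seed+2), so outputs are byte-identical across runs.

What the generator does **not** emulate -- and hence what passing tests do
not certify about real data: sequencing errors and quality variation,
multi-mapping and soft-clipping, fragment-length and positional coverage
bias, correlated (paired) tumor/normal samples, isoform-level 3'UTR
shortening, and motif occurrences in flanking genomic context. The
generator validates the machinery, not the biology.

# Validation problem sizes

The test suite and the acceptance script
(`Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json`)
recompute: scanner agreement with a brute-force substring oracle over
1000 random cases; DTK family-wise error and $5\sigma$ selection power
over 2000 Gaussian replicates at $k = 6$, $n = 13$; NB-null calibration
over 2000 replicates ($\mu = 100$, $\phi = 0.2$) plus exact binomial
agreement at $\phi = 0$; a read-level round trip on a small
8-gene/6-family scenario; the full counts-level pipeline at the default
200-gene/1000-row design (planted-row sensitivity and false-discovery
proportion of the intersected set, and the decoupled set sizes); and GC
flatness of the normalization to machine precision. The end-to-end check
runs at the counts level -- the count matrix is the generator's NB truth
directly rather than re-derived from millions of simulated reads -- with
the read-level path exercised separately at the smaller scale above,
where exact recovery is asserted.

# Other numerical choices

* GC bins interpolate at bin centers (midpoints of merged bin edges);
  beyond the outer centers the offset is constant, so extreme-GC rows are
  corrected by their nearest fitted bin rather than extrapolated.
* `tmmFactors()` returns 1 (with a warning) for a sample sharing no
  positive row with the reference, and skips trimming when all M-values
  are numerically zero.
* Dispersion rows with zero mean in a condition contribute nothing;
  all-zero matrices give $\phi = 0$ with a warning.
* `dtkTest()` guards zero-variance pairs explicitly rather than letting
  the critical value become NaN.
* Aggregated pseudo-counts are rounded to the nearest integer before
  enumeration; at aggregate counts in the thousands the rounding error is
  negligible next to sampling noise.

# Limitations

Beyond those noted inline: no conserved-site or context scoring (all
catalog sites are treated alike), no non-canonical or 3'-supplementary
sites, no UMI handling or MAPQ reweighting, no GLM/quasi-likelihood DE
route, and no pathway or network analysis downstream of decoupling --
the decoupled lists are the hand-off point to those tools.
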