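---
title: "Calling sLADs from DamID-seq: model, parameters and design"
author: "DamLAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling sLADs from DamID-seq: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DamLAD)
```

# The model

DamID-seq measures nuclear-lamina contact by sequencing fragments methylated
by a Dam-LaminB1 fusion, against a free-Dam control library that captures
chromatin accessibility and amplification bias. LADs are broad (kilobases to
megabases), so the caller is an island method rather than a point-peak
method.

The genome (admitted chromosomes only) is tiled into non-overlapping 2 kb
windows. Under the null, reads fall uniformly on the *mappable* genome, so a
window's count is modelled as Poisson with rate

$$\lambda = \frac{N\,w}{f\,G}$$

for library size $N$, window size $w$, effective genome fraction $f$ and
total admitted genome length $G$. The model assumes reads are independent
after deduplication and that mappability is uniform at rate $f$; both are
idealizations — real coverage is locally autocorrelated (GC, GATC density)
— which is one reason the control library, not the Poisson model, carries
the final significance decision.

**Eligibility and scoring.** A window with count $k$ is *eligible* when
$P(\mathrm{Pois}(\lambda) \ge k) < p_0$, equivalently $k \ge l_0$ with
$l_0$ the smallest such count, and then scores
$-\log P(\mathrm{Pois}(\lambda) = k)$; ineligible windows score 0.

**Gap merging.** Eligible windows separated by at most $g/w$ consecutive
ineligible windows (gap $g = 6$ kb, i.e. up to three windows — a gap of
exactly 6 kb is allowed) merge into one island, compensating for
unsaturated sequencing. The island interval runs from its first to its last
eligible window; interior gap windows belong to the island interval but
contribute nothing to its score (the convention of the island-calling tools
this design follows; scoring gap windows is a noted alternative).

**E-value filter.** Islands whose score falls below $s^\*$ are discarded,
where $s^\*$ is the smallest score at which the expected number of
pure-background islands scoring $\ge s^\*$ is at most the E-value budget
(0.1 genome-wide).

**Control significance.** Both libraries are scaled to $10^6$ reads. For an
island with normalized treatment count $a$ and normalized control count
$b$, the enrichment p-value is $P(\mathrm{Pois}(\max(b, b_0)) \ge a)$,
where $b_0$ is the island-width background expectation at the normalized
library size. The floor prevents a zero-mean degeneracy when the control
has little or no signal on the island. P-values are Benjamini–Hochberg
corrected over all candidate islands (the multiple-testing procedure is our
choice; ranking ties are resolved in genomic order for determinism), and
islands with FDR ≤ 0.001 are the sLADs.

**Tracks and labels.** Windows with no read in either library, and each
chromosome's trailing sub-2 kb window, are *undetermined*; the remaining
windows are sLAD or non-sLAD (a window inside a called island is sLAD even
if empty, so the three coverage fractions sum to 1). Per-window association
is the scaled log2 seq ratio
$\log_2((\mathrm{LmnB1\ RPKM} + p)/(\mathrm{Dam\ RPKM} + p))$.

# Parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `windowSize` | 2000 | bp | Dam methylation spreads up to ~5 kb from a binding site; 2 kb windows resolve domains without fragmenting them |
| `gapSize` | 6000 | bp | absorbs drop-outs from unsaturated sequencing; must be a multiple of `windowSize` |
| `effectiveGenomeFraction` | 0.81 | — | uniquely mappable fraction of mm9 at 75 bp single-end reads; toy simulations use 1 (see below) |
| `eValue` | 0.1 | islands | expected background islands tolerated genome-wide |
| `fdrThreshold` | 0.001 | — | BH cutoff on control-corrected island p-values |
| `windowPvalue` | 0.20 | — | Poisson tail cutoff defining eligibility; the island-calling convention this design follows, exposed as a knob since it is rarely reported |
| `normalizationTarget` | 1e6 | reads | common library size for the control test |
| `minMapq` | 40 | — | operationalizes "uniquely mapped" |
| `redundancyThreshold` | 1 | reads | PCR-duplicate collapse per (chrom, 5′ position, strand); dedup is strand-aware — collapsing without strand is the stricter noted alternative |

# Numerical choices

* **E-value threshold.** Under the background, a window is eligible with
  probability $p_E$, an island continues past an eligible window with
  probability $c = p_E \sum_{j=0}^{g/w} (1-p_E)^j$, so island scores follow
  a geometric mixture of convolutions of the single-eligible-window score
  distribution. `islandExpectationThreshold()` evaluates this analytically
  on a discretized score axis (bin 0.01, natural-log scores; the
  single-window distribution is sparse, so convolution is done directly on
  its support) and stops when the residual mixture weight is three orders
  of magnitude below the required tail level, counting the residual as tail
  mass (conservative). The unit tests check it against a seeded Monte-Carlo
  background simulation with 5 % agreement.
* **Pseudo-count.** Nearest-rank 5th percentile of the pooled RPKM
  multiset; quantile conventions differ across software, and nearest-rank
  keeps the value a member of the data. Pooling uses determined windows
  only — the zeros of undetermined windows are missingness, not
  measurement (pooling all windows is the exposed alternative). A zero
  percentile falls back to the smallest positive pooled value; all-zero
  pooled input is an error.
* **Coordinates.** 0-based half-open internally and in BED outputs; window
  assignment uses the read's strand-aware 5′-most base, so every read lands
  in exactly one window. Peak centers use the floor of the 0-based
  midpoint.
* **Gene bodies.** TSS-to-TES genomic span; bp in undetermined windows stay
  in the denominator of the sLAD fraction (conservative). The sLAD-gene
  cutoff is strictly greater than 0.60.
* **Metagene orientation.** Profiles are transcription-oriented:
  minus-strand genes are reversed so "upstream" is always 5′. This is a
  design choice (`strandFlip = FALSE` restores genomic orientation for
  sensitivity checks); the asymmetry between TSS and TES profiles it
  produces is the behaviour we consider biologically meaningful.
* **Degenerate inputs.** Empty candidate lists, empty domain sets and empty
  full-depth sLAD sets are results, not errors (concordance against an
  empty lower-depth sLAD set is reported as undefined); empty libraries,
  out-of-bounds positions and malformed annotation rows are hard errors.

# The synthetic generator

`plantDomains()` places disjoint, window-aligned domains (sizes log-uniform
in 20 kb–1 Mb by default, spanning the size range real sLADs occupy) with
at least 20 kb separation — above the 6 kb gap allowance, so distinct
planted domains cannot merge. The size vector is redrawn if it would exceed
35 % of the toy genome, keeping placement feasible. `simulateDamidReads()`
draws per-window Poisson counts (background λ = 2 reads/window by default,
multiplied by the enrichment fold inside domains, and by a hotspot fold in
the control at designated accessibility hotspots such as open TSS-proximal
chromatin), then scatters reads uniformly within windows. Everything is
seeded and byte-reproducible.

The default toy genome is 2 chromosomes × 5 Mb — large enough for stable
island-score thresholds, small enough for seconds-scale calls. Simulated
runs set the effective genome fraction to 1 because every simulated
position is mappable; using the mm9 value there would deliberately
overestimate λ.

What the generator does *not* emulate: GATC-fragment structure and
methylation spreading (counts are drawn at window level, matching the
caller's own resolution), mappability holes, GC/amplification bias, and
long-range coverage autocorrelation. Passing tests therefore demonstrate
the algorithmic contract — recovery of Poisson-enriched domains, null
control, determinism — not robustness to every artefact of real libraries;
the control-library correction is the main guard against those in practice.

# Test bed and scale

The suite runs entirely on generated data: randomized toy genomes of at
most 200 windows are checked against a brute-force island enumeration;
background-only calls on the 2 × 5 Mb toy genome (20 seeds) verify that
called coverage stays below 1 %; planted-domain runs (10 domains per seed,
4-fold enrichment, 10 seeds) verify mean bp-level Jaccard ≥ 0.9; and a
deterministic minimal construction (uniform two-read background, one
40-read window) demonstrates the caller's 2 kb domain size floor. These
sizes keep the full suite under a minute while leaving the score-threshold
and FDR machinery in their realistic regimes.

# Known limitations

* Single-end reads only; the analysis the package implements used 75 bp
  single-end libraries.
* No HMM or per-GATC-fragment segmentation; domains are unions of 2 kb
  windows.
* The Poisson background ignores overdispersion; strongly overdispersed
  controls will surface as conservative (floored) island means rather than
  inflated significance.
* Array-era LAD sets can be compared (`partitionDomainSets()`,
  `mapProbeTrack()`) but not re-called from intensities.
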