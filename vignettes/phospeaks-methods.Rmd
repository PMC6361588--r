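---
title: "Models and methods behind phospeaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phospeaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phospeaks)
```

This vignette is the package's own account of its statistics: the
enrichment model, the motif and insulation machinery, what the
synthetic-data generator does and does not emulate, and the numerical
and design choices a maintainer would want spelled out.

## The window enrichment model

ChIP enrichment is tested per sliding window (1 kb wide, 200 bp step).
For a window with ChIP count $k$ and input count $k_{in}$, the null
mean is the library-scaled input,
$$\mu = (k_{in} + c)\,\frac{N_{chip}}{N_{input}},$$
with pseudocount $c = 0.5$ guarding windows with no input tags. The
null is a negative binomial with mean $\mu$ and size $r$ (variance
$\mu + \mu^2/r$), and the score is
$$z = \Phi^{-1}\!\bigl(1 - P(X \ge k)\bigr).$$

Two consequences of this definition are worth stating. First, $z$ is a
probability transform of the *exact* NB tail, not a moment
standardization; for heavy-tailed nulls the two differ by several units
at the calling threshold, and the probability transform is the one that
makes "$z \ge 6$" mean $P < 10^{-9}$ under the model. Second, the tail
is computed in log space (`pnbinom(..., log.p = TRUE)` into
`qnorm(..., log.p = TRUE)`), so precision holds far beyond the
threshold; only when even the log tail underflows does the code fall
back to the moment approximation $(k-\mu)/\sqrt{\mu + \mu^2/r}$, and
all scores are clamped to $[-38, 38]$ (the useful range of double
precision for $\Phi^{-1}$). A count of zero therefore lands exactly at
the negative clamp.

The size parameter $r$ is a data-analyst choice, not an estimated
quantity — in practice it is tuned until the peak calls look right.
The default is `nb_size = 10`, exposed in `caller_config()`. Windows
at $z \ge 6$ are merged into peaks when their gap is at most 1 kb; the
threshold is applied per window, and a merged peak keeps the maximum
member $z$. A gap of exactly 1 kb merges.

**Window tiling.** Full windows start at $0, s, 2s, \dots$ while they
fit; when the last full window stops short of the chromosome end, one
additional terminal window truncated at the end is appended. A 10 kb
chromosome at the defaults therefore yields 46 windows (starts 0
through 9000), and no base is ever left uncovered.

## Motif scanning with an exact tail threshold

Motifs are scored as log2 odds against the background. To make the
threshold machinery exact, scores are discretized on a fixed grid
(default $10^{-3}$ log2 units; matrix probabilities are floored at
$10^{-4}$ so zero entries stay finite). The null distribution of the
total score of a random background $w$-mer is then computed by exact
dynamic programming — a convolution over positions of the four-point
per-position score distributions — and the threshold for a target
p-value (default $3\times10^{-5}$, the conventional cutoff for
genome-wide motif tracks) is the smallest achieved score whose tail
probability is below the target. Because the scanner uses the same
discretized scores, "tail probability at the threshold" means the same
thing in theory and on sequence. For an 8-mer this agrees with
exhaustive enumeration of all $4^8$ words to below $10^{-12}$, which
the test suite asserts.

The bundled `ctcf_like_pwm()` is a synthetic 16-position matrix with a
GC-rich consensus resembling the CTCF core motif; it is constructed in
code and is not a database matrix. Real matrices load via `read_pwm()`
(JASPAR-style text).

## Peak features

Interval operations use ≥1 bp overlap semantics throughout:
`intersect_peaks()` reports each query peak once however many subject
peaks it touches (the `-u` convention), and `count_motifs_in_peaks()`
counts a motif for every peak it overlaps (the `-counts` convention).
Per-peak coverage counts tags with any overlap of the peak interval;
whether the original analyses required full containment is not
documented for this class of pipeline, and any-overlap is the common
default. R² between two signals over peaks is ordinary least squares
with intercept via `lm()`; a zero-variance response is flagged
undefined rather than scored 0 or 1.

Rank-sum comparisons use `wilcox.test()` underneath: the exact null
when the combined sample size is at most 20 and no ties are present,
otherwise the normal approximation with tie and continuity correction.
The returned tibble records which path ran. Identical samples give
$p = 1$ on either path.

Peak annotation assigns each peak, by midpoint, to exactly one category
with fixed priority promoter > 5'UTR > 3'UTR > exon > intron >
downstream > intergenic. The promoter is a symmetric ±`promoter_bp`
window around the TSS (default 1000 bp; the window also defines
"downstream" beyond the 3' end). Multi-category tools can report
percentages summing above 1; the midpoint-plus-priority rule trades
that resolution for a distribution that is exactly comparable to its
genome background, which is computed by classifying uniformly spaced
probe points with the same rule. Metagene profiles rescale each gene
body to a fixed number of bins, attach fixed-width flank bins, reverse
minus-strand genes, and skip (with a count) genes shorter than the bin
number.

## Capture Hi-C insulation and TAD score

Only read pairs with both ends inside the capture region are binned
(default 25 kb), because normalizing sparse, un-enriched off-target
rows is not meaningful for a capture design. Sqrt-coverage balancing
divides each entry by $\sqrt{r_i r_j}$ of its row/column sums, masks
zero-coverage bins, and rescales to preserve the mean of the unmasked
entries; the downstream insulation score is a log2 ratio to the
regional mean and is therefore invariant to that constant (and to any
global scaling of the matrix — asserted to $10^{-12}$ in the tests).

The insulation score at bin $i$ sums the square of contacts between the
$w$ bins upstream and the $w$ bins downstream of $i$ (excluding $i$
itself), $w = \mathrm{is}/\mathrm{resolution} = 125000/25000 = 5$ by
default, and reports $\log_2$ of the ratio to the mean square sum over
valid bins. Bins within $w$ of a region edge, or whose square is empty,
are masked. For cross-library comparison of the *raw* square sums,
`region_read_normalize()` scales by region reads per million — reads in
the capture region, not on the chromosome, since capture depth is what
varies between libraries.

Boundaries are minima of the insulation score where the delta vector
(mean over the next $d$ bins minus mean over the previous $d$,
$d = 75000/25000 = 3$) crosses from negative to positive. Boundary
strength is the mean of the two flanking maxima minus the value at the
minimum, floored at zero; boundaries weaker than 0.1 log2 units are
discarded by default (a detection knob, not a biological constant).
Near the masked edges both spans truncate to the available valid bins,
so a boundary two bins from the edge mask remains scoreable. The TAD
score of a domain is the mean of the boundary strengths evaluated at
its two (user-specified) boundary bins. The external scripts these
scores descend from do not publish their exact formulas, so this
definition is the package's own documented stand-in; its contract,
asserted by simulation, is monotonicity — weakening the simulated
boundary depletion strictly lowers the score — together with exact
boundary recovery on block-structured toy matrices.

## The synthetic-data generator

The generator exists so every stage of the pipeline runs at desk scale
against known truth. Its defaults are the package's study conditions:

* **Genome**: i.i.d. bases at a target GC (default 0.42, mammalian-
  like). No repeats, no mappability structure, no CpG methylation.
* **Sites**: 1 kb planted sites (window-scale, as real ChIP enrichment
  regions at kilobase callers are), affinities uniform on 8–16× over
  background, at least 5 kb apart so a 1 kb/200 bp caller with 1 kb
  merging resolves them individually. A `phospho_fraction` (default
  0.1) of sites — those at the top of the affinity draw — is flagged as
  the phospho-bound subset and receives at least the median motif count
  of the rest. This mirrors the *observed* structure in phospho-ChIP
  data (the modified factor sits at higher-affinity, multi-motif
  sites); the generator asserts it by construction and makes no causal
  claim.
* **Tags**: per-bp negative binomial, ChIP mean `depth_chip` (default
  0.02/bp, i.e. ~20 background tags per 1 kb window — the regime where
  kilobase window callers operate) scaled by affinity inside sites;
  input mean `depth_input` (default 5× deeper). Dispersion defaults to
  size 10 per bp; real libraries' dispersion is not published for this
  design, so it is an explicit free parameter, and ChIP and input may
  differ (`nb_size_input`). Reads are simulated as tag counts, not
  FASTQ: alignment is out of scope and the first in-scope quantity is
  the window tag count.
* **Contacts**: expected counts decay as $(|i-j|+1)^{-\alpha}$
  (default $\alpha = 1$), multiplied by `boundary_depletion` per
  boundary crossed, Poisson-sampled. Poisson (rather than NB) keeps
  the oracles analytic; capture Hi-C overdispersion is not
  characterized well enough to parameterize honestly. The default
  geometry — 59 bins of 25 kb with boundaries at bins 34 and 52 —
  matches a ~1.5 Mb capture region with an interior domain.
* **Codon reads**: a deterministic `round(fraction × n)` of reads
  carry the glutamate codon (GAG; GAA also counts as glutamate in the
  classifier), the rest the serine codon (TCC), with optional
  independent per-base miscalls. The demo pipeline uses fraction 0.14,
  mid-range for a modestly expressed phosphomimetic transgene.

Passing recovery tests on these simulations shows the *computations*
are correct and calibrated under the stated model; it does not show
that real chromatin obeys the model. Real data bring mappability
artifacts, copy-number structure, fragment-length effects and
overdispersion heterogeneity that the generator deliberately omits.

### Why the default depths and site widths look the way they do

With the caller's NB size fixed at $r = 10$, the window z saturates as
depth grows: for a site occupying fraction $f$ of a window at affinity
$a$, the moment z tends to $\sqrt{r}\,f(a-1)$ and the exact-tail z is
smaller still. A 200 bp site in a 1 kb window ($f = 0.2$) therefore
cannot clear $z = 6$ at affinity 8 no matter how deep the libraries —
the power analysis, run against the exact NB tail, gives $z \approx
4.5$. Window-scale sites ($f \approx 1$) at ~20 background tags per
window give $z \approx 8.8$ at affinity 8 and $z \approx 6.3$ even for
a worst-case 60% window offset, which is why the defaults are 1 kb
sites at `depth_chip = 0.02`.

### The null-calibration experiment

Calibration of the z-scores is checked on null simulations (no planted
sites, 10 Mb, 10 replicates). Two things must hold for the nominal
tail to be observable: the caller's $r$ must match the true windowed
dispersion, and the plug-in mean $\hat\mu$ from the input must be much
less noisy than the ChIP window counts. The experiment therefore
simulates ChIP at per-bp size 0.05 (window-level size 50), input
near-Poisson at 5× depth, and calls with `nb_size = 50`: the variance
inflation from estimating $\mu$ is then $\sqrt{1 + \sigma^2_{\hat\mu} /
\sigma^2_k} \approx 1.04$, and observed exceedance at $z \in \{2, 3\}$
sits within a factor ~1.5 of $\Phi(-z)$ (asserted within 10×). Had the
input instead been NB at the same size, $\sigma_{\hat\mu} \approx
\sigma_k$ and the inflation factor $\sqrt{2}$ would push the $z = 3$
exceedance outside a factor of 10 — a property of plug-in nulls worth
remembering when interpreting real calls. With the *default* mismatch
($r = 10$ against near-Poisson window sums) the caller is deliberately
conservative, which is the right failure direction for peak calling.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in memory and on disk
  (BED convention); Hi-C pair files carry 1-based positions.
* `gc_fraction = 1` is allowed (G/C-only genomes) as a degenerate test
  case; 0 is not, matching the lower-open interval.
* Empty ChIP libraries return empty peak sets rather than erroring;
  the NB test itself refuses zero library totals.
* An empty peak set makes the overlap fraction undefined (`NA` with a
  warning), never 0 or 1.
* A background-identical PWM has no attainable threshold; the
  threshold is `Inf`, flagged, and scanning at it returns no hits.
* Merging is idempotent, and accepts either `z` or `z_max` as the
  score column so peak sets can be re-merged.
* Insulation boundary ties (a cut exactly between two bins with
  identical squares) resolve to the lower-scoring bin; tests accept
  either bin of the tied pair.
* All simulation functions take explicit seeds and restore the RNG
  state afterwards; a fixed seed reproduces outputs byte for byte,
  which the pipeline manifest (md5 checksums) makes checkable.

## Problem sizes

The test and acceptance runs use 10 Mb null genomes (10 replicates),
5 Mb recovery genomes (5 seeds, 50 sites), a 20 Mb genome with 1000
sites for the ~1000-peak regression experiment, 59-bin contact
matrices at 25 kb, and 5000-read codon pileups — sizes chosen so each
experiment estimates its quantity with comfortable margin while the
whole suite runs in a few minutes on one CPU.

## Known limitations

* The caller tests each window independently; no genome-wide FDR or
  local background (input smoothing) is provided, and the z = 6
  threshold is a model-based tail bound, not an empirical FDR.
* The insulation/TAD formulas are documented stand-ins for external
  scripts whose internals are unpublished; cross-tool numeric equality
  is not a goal, rank behavior is.
* The annotation rule is midpoint-based: peaks spanning a feature
  boundary contribute only their midpoint category.
* DE analysis is consumed, never fitted: the package thresholds an
  existing table (adjusted p < 0.01) and tallies directions, keeping
  the boundary with model-fitting tools explicit.
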