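---
title: "Domain-level methylome analysis with pmdomains: models, parameters and design choices"
author: "pmdomains authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level methylome analysis with pmdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmdomains)
```

# The scientific problem

Cancer genomes lose DNA methylation unevenly: megabase-scale *partially
methylated domains* (PMDs) drift towards intermediate methylation while the
rest of the genome — *highly methylated domains* (HMDs) — stays high. PMDs
are heterochromatic (H3K9me3 or H3K27me3), gene-poor and late-replicating,
which has motivated the model that they arise from incomplete maintenance
methylation (DNMT1) in late S-phase. Studying maintenance loss directly —
for example in a DNMT1-deficient colorectal cancer line — requires a chain
of genome-scale computations: segmenting the methylome into domains,
attaching chromatin and replication-timing covariates to each domain,
finding the domains that *gain* methylation when maintenance is removed,
and modelling the decay kinetics that distinguish maintenance failure from
compensating *de novo* methyltransferase (DNMT3A/B) activity. `pmdomains`
implements that chain as a tested, deterministic pipeline.

# Domain segmentation

## Model

Window-level methylation (weighted mean % mCpG in 10 kb windows) in such
cell lines is bimodal: a low mode from PMDs and a high mode from HMDs, with
strong spatial persistence. We model the window series per chromosome as a
two-state hidden Markov chain with Gaussian emissions,

$$ v_t \mid s_t = k \sim \mathcal N(\mu_k, \sigma_k^2), \qquad
   P(s_{t+1} = l \mid s_t = k) = A_{kl}, $$

fitted by Baum–Welch (`fitTwoStateHMM()`) and decoded by Viterbi
(`viterbiDecode()`). State 1 is always the lower-mean state.

The choice of *Gaussian emissions on the window summary* (rather than
binomial emissions on read counts) is deliberate: at the 1–3x coverages
typical of domain-level whole-genome bisulfite data the window weighted
mean is the stable observable, the domain signal lives at window
resolution, and a window-level emission model makes every stage directly
testable against planted ground truth. The package makes no attempt to be
bit-compatible with count-level segmenters; the accuracy target is
recovery of planted domains, which the test suite measures as base-pair
Jaccard (≥ 0.95 required, ≈ 0.997 achieved on the default synthetic
genome).

Missing windows (no covered CpG) carry no emission term: the
forward–backward and Viterbi recursions propagate through them on
transitions alone, so a run of missing data inside a domain never splits
it. Only a decoded state change does.

## Fitting choices

* **Initialisation**: k-means (k = 2, 5 restarts, fixed seed) on the
  non-missing window values gives the state means; state variances start
  from the cluster variances; transitions start at 0.99 on the diagonal
  (domains are megabase-scale, i.e. tens of windows).
* **Convergence**: relative log-likelihood tolerance `1e-4`, at most 200
  iterations. The log-likelihood trace is stored in the fit
  (`@logLikTrace`) and asserted non-decreasing in the tests.
* **Degenerate inputs**: a track whose non-missing values are all equal has
  no two-state structure; the fit is flagged (`@degenerate`) instead of
  returning arbitrary parameters, and the segmentation caller then emits
  zero PMDs (one HMD per analysable block).

## Post-processing

`callPMDs()` applies, in order: low-state runs become raw PMDs; each PMD is
**trimmed** to the first and last CpG it contains (domain boundaries should
sit on observed CpGs, not on empty window edges); PMDs separated by a gap
smaller than twice the window size (< 20 kb at the 10 kb default) are
**bridged**; the complement of the PMDs within the analysable genome
becomes the HMDs; **exclusion regions** (assembly gaps, centromeres —
supplied as a BED and pre-merged across gaps of up to 10 Mb, so that a
fragmented centromeric annotation acts as one block) are subtracted from
both sets; domains shorter than **200 kb** are removed; adjacent same-kind
domains are then merged.

Two details are worth spelling out because the informal recipe above is
ambiguous about them:

* *Gap semantics.* "Closer than the threshold" is implemented inclusively
  (gap ≤ threshold merges), matching `bedtools merge -d`; the bridging rule
  is strict (< 2 windows). Both are covered by boundary-exact tests.
* *Removal of sub-200 kb domains.* Deleting a small domain outright would
  leave a hole covered by neither PMD nor HMD, breaking the invariant that
  the two sets partition the analysable genome — an invariant the rest of
  the pipeline (complement-based HMD definition, per-domain statistics)
  relies on. We therefore implement removal as *absorption*: the small
  domain is relabelled to the opposite kind and merged with its
  neighbours, iterated to a fixpoint. This realises "remove, then merge
  the now-adjacent neighbours" while keeping the partition exact. An
  isolated analysable block shorter than 200 kb (no neighbours to absorb
  it) is dropped entirely.

Because trimming moves PMD edges onto CpGs and absorption can move them
off again, the two steps alternate until both properties hold (in practice
one or two rounds). Analysable blocks are also clamped to the span of
their CpGs, so block-edge sequence with no data at all belongs to no
domain rather than to an arbitrary one.

Chromatin (H3K9me3/H3K27me3) domains are called by the same HMM on 25 kb
input-normalised ChIP ratio windows (`callChromatinDomains()`), keeping the
*high*-state runs; no bridging or length filter is applied there.

# ChIP-seq normalisation and replication timing

`normalizeChip()` computes, per window,
$(\mathrm{IP} + 0.5) \cdot 10^7 / N_\mathrm{IP} \;/\;
 (\mathrm{IN} + 0.5) \cdot 10^7 / N_\mathrm{IN}$ —
counts per 10 million with a 0.5 pseudocount added *before* scaling, so a
zero-input window can never normalise to infinity. Windows with zero
coverage in every sample are removed (set to missing). The offset makes
the ratio scale-dependent only at very low counts; the scale-invariance
property is tested.

`replicationTiming()` turns early/late repli-seq fraction counts into a
timing track: per replicate, reads-per-million scaling with the same 0.5
pseudocount, then $\log_2(\mathrm{early}/\mathrm{late})$. The log is taken
(although a plain ratio would carry the same ordering) so that early and
late shifts are symmetric around zero and replicate averaging behaves; the
sign convention *higher = earlier* is preserved everywhere. With several
replicates the ratio tracks are quantile-normalised across samples
(rank-wise means via the standard limma implementation) before smoothing;
normalising the derived ratio rather than the raw fraction counts is a
package choice, recorded in the output's `normalization` field, and both
orders give the same class-level conclusions on synthetic data. Finally
each chromosome is loess-smoothed (local linear fit on window midpoints,
default span 0.05 of the chromosome's windows, raised automatically when it
would cover fewer than 10 points; chromosomes with fewer than 10 points
pass through unsmoothed) and replicates are averaged.

# Domain classification and hypermethylation calls

`classifyPMDs()` clusters PMDs on their mean H3K9me3 and H3K27me3
enrichment with k-means (k = 2). Features are z-scored per mark first (the
two marks need not share a dynamic range) and 25 restarts under a fixed
seed make the partition deterministic; the cluster whose centroid has the
higher *raw* H3K9me3 mean is labelled K9-marked, so the labels depend on
the data, not on input order or the solver's arbitrary numbering.

`callHypermethylated()` compares per-domain weighted mean methylation
between conditions and calls a domain hypermethylated when the gain is at
least 5 *percentage points* (not a 5 % relative change), boundary
inclusive: a gain of exactly 5.0 pp qualifies. The threshold is a
parameter; monotonicity in it is a tested property.

`pileupMatrix()` reimplements the scale-regions summary matrix: each
domain body is resampled to 100 equal bins (1 Mb / 10 kb), flanked by 100
native 10 kb bins per side, every cell an overlap-width-weighted mean of
the track; rows are ranked by a caller-supplied key (typically parental
mean methylation) and never dropped. `decileAnalysis()`,
`fisherExact()`, `wilcoxonRankSum()` and `spearmanCor()` wrap the standard
R tests with the package's guard rails (deterministic decile tie-breaking
by genomic coordinate; p = 1 with a warning for information-free tables or
fully tied groups; errors for undefined cases). `fisherExact()` is
two-sided by default and exposes `alternative = "greater"` for directional
enrichment hypotheses. Gene-level comparisons use
`assignGenesToDomains()`, which assigns a gene only when *wholly
contained* in a domain — straddling genes are ambiguous and stay
unassigned.

# Decay kinetics under maintenance loss

When the maintenance methyltransferase is removed acutely, domain
methylation decays. We model a domain's methylation fraction $m(t)$ by

$$ \frac{dm}{dt} = -\lambda\, m + \nu\,(1 - m), $$

with $\lambda$ the per-day loss rate (maintenance failure at replication)
and $\nu$ the per-day *de novo* gain rate. This is the minimal linear
model with the two signatures that matter:

* $\nu = 0$: pure exponential decay, $m(t) = m_0 e^{-\lambda t}$ —
  log-linear with slope $-\lambda$ *regardless of the initial level*;
* $\nu > 0$: slower apparent loss and a plateau at
  $m_\infty = \nu / (\lambda + \nu)$, reached at combined rate
  $\lambda + \nu$.

`decayModel()` evaluates the closed form
$m(t) = m_\infty + (m_0 - m_\infty) e^{-(\lambda+\nu)t}$, which the test
suite verifies against an independent numerical ODE integration (lsoda) to
within 1e-8 on $t \in [0, 12]$ days.

Fitting deliberately does **not** estimate $(\lambda, \nu)$ jointly by
nonlinear regression — with a handful of noisy timepoints that problem is
poorly conditioned. Instead `fitDecay()` extracts the two robust
observables: the OLS slope of the *natural log* of weighted mean
methylation over days 0–6 (where the decay is still near log-linear; with
$\nu > 0$ the fitted $|\text{slope}|$ is strictly below $\lambda + \nu$
and shrinks with $\nu$) and the day-12 level as the plateau estimate
(falling back, with a message, to the last available day). Domains with a
non-positive value — where the log is undefined — are excluded and
reported. `compareClasses()` then compares slope and final level between
domain classes with two-sided rank-sum tests, ordering classes in a
locale-independent way so that reports are byte-identical across machines.

# The synthetic-data generator

Every stage is exercised against `simulationConfig()` defaults chosen once
to be realistic at desk scale:

* **Genome**: 2 chromosomes x 25 Mb, 10 kb windows, one 500 kb unmappable
  block mid-chromosome standing in for a centromere. Large enough for
  ~60-70 domains (roughly 15-20 per PMD class), small enough that the full
  pipeline runs in seconds.
* **Domains**: alternating HMD/PMD tiling with log-normal lengths (medians
  0.8 / 0.8 / 0.55 Mb for HMD / K9-PMD / K27-PMD, sdlog 0.35, truncated at
  0.3 Mb so every planted domain clears the 200 kb filter), snapped to the
  window grid — domains are defined at window resolution throughout the
  analysis, so sub-window boundary placement would only add unmeasurable
  jitter. A quarter of the K9 PMDs are planted as *hyper-convertible*.
* **Methylation**: per-CpG propensities are beta-distributed around the
  class mean (precision 60) and read counts beta-binomial (depth
  1 + Poisson(5), echoing low-coverage whole-genome bisulfite data); CpG
  density 2/kb in HMDs and 1/kb in PMDs (PMDs are CpG-poor). Class means:
  85 % (HMD), 50/55 % (K9/K27 PMDs) in the parental condition; under
  maintenance loss HMDs drop ~9 pp, PMDs ~15 pp, and hyper domains *gain*
  8 pp — comfortably above the 5 pp call threshold, so recovery failures
  indicate pipeline defects, not threshold grazing.
* **ChIP and repli-seq**: Poisson counts (depth 50/window) with class-level
  enrichment (3x for the defining mark of a PMD class; hyper domains lose
  H3K9me3 to background and gain H3K36me2 to HMD level under knockout —
  the magnitude of the H3K36me2 gain is an order-of-magnitude choice, as
  no quantitative effect size is established) and symmetric early/late
  expectations targeting log2 ratios of +0.8 (HMD) to −1.0 (K9 PMDs), with
  hyper domains staying late under knockout.
* **Kinetics**: per-class $(\lambda, \nu)$ — HMD (0.25, 0.15), K9-PMD
  (0.50, 0.02), K27-PMD (0.45, 0.04), hyper (0.50, 0.10) per day — so HMDs
  lose slowly and plateau high, and hyper domains behave like K9 PMDs with
  elevated de novo activity. Observation noise 0.3 pp; time grid
  {0, 1, 2, 3, 4, 6, 12} days (the slope window plus a plateau readout).

Randomness is organised as one stream per (seed, stage name), so adding a
stage never perturbs another stage's draws, and the parental and knockout
methylomes of one configuration share a single planted truth. Identical
configs give bit-identical output; `runPipeline()` is tested for
byte-identical reruns.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: sequence context (no solo-WCGW modelling, no
real CpG clustering or CpG islands), mappability structure beyond the one
planted gap, copy-number variation, between-replicate batch effects,
fragment-length effects in ChIP, or partially overlapping domain classes.
The generator validates the *machinery* (segmentation accuracy, exact
recovery of planted conversions, statistical plumbing); biological
conclusions on real data still require the usual caution.

# Numerical and degenerate-input policy

* Coordinates are 0-based half-open at every file boundary (BED
  convention) and converted exactly once, in the readers/writers.
  Chromosome order follows the supplied layout, never lexicographic sort.
* Window/domain means are read-count weighted; windows with no qualifying
  CpG are missing and excluded from downstream statistics, never imputed.
  The minimum-coverage filter defaults to 1 (every observed CpG counts)
  and is exposed for stricter use.
* Variance floors (1e-6) in the HMM prevent emission collapse when a
  k-means cluster is near-constant; transition rows with no mass fall back
  to 0.5/0.5.
* Decile ties are broken by genomic coordinate, k-means and HMM restarts
  by fixed seeds: every stochastic step is reproducible.
* Tests that need an independent numerical oracle (ODE integration,
  exhaustive Viterbi enumeration, per-base interval arithmetic,
  hypergeometric enumeration) construct it in the test code, not from the
  implementation under test.

# Problem sizes

The bundled tests and the acceptance script run the full pipeline on the
default 50 Mb synthetic genome (~75,000 CpGs, 5,000 windows, ~65 domains),
200 exhaustively-enumerated Viterbi tracks of up to 12 windows, and
kinetic fits over a 3 x 5 rate grid; the complete suite finishes in about
two minutes on a single CPU, and `runPipeline()` itself in roughly ten
seconds. These sizes were chosen so that planted-domain recovery is
measured on dozens of domains per class while the whole loop stays
interactive.

# Known limitations

* The Gaussian window-level HMM can misplace a boundary by a window or two
  when coverage is very sparse; boundary-accuracy requirements tighter
  than one window would need count-level emissions.
* `fitDecay()` reports slope and plateau, not $(\lambda, \nu)$; the
  mapping is monotone but not invertible from the slope alone.
* Quantile normalisation assumes replicates share a signal distribution;
  with strong global shifts between replicates it will remove real
  differences.
* `pileupMatrix()` resamples bodies by overlap-weighted means, which is
  exact for piecewise-constant tracks but slightly smooths sharp features
  at bin edges.
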