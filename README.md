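# pmdomains

Domain-level analysis of cancer methylomes: segmentation of whole-genome
bisulfite data into partially methylated domains (PMDs) and highly
methylated domains (HMDs), integration of ChIP-seq and repli-seq
covariates, detection of domains that *gain* methylation under
maintenance-methyltransferase (DNMT1) loss, and modelling of per-domain
methylation decay kinetics.

## Who this is for

Epigenomics groups working with low-coverage WGBS of cancer cell lines or
tumours who need reproducible, domain-level answers: where are the PMDs,
which chromatin mark dominates each one, which domains defy global
hypomethylation when DNMT1 is removed, and what do their decay kinetics
say about compensating de novo (DNMT3A/B) activity.

## The models at the core

**Segmentation.** Weighted mean methylation in 10 kb windows,
$v_t = 100 \cdot \sum m_i / \sum t_i$, is modelled per chromosome as a
two-state Gaussian hidden Markov chain
($v_t \mid s_t = k \sim \mathcal N(\mu_k, \sigma_k^2)$, near-diagonal
transitions), fitted with Baum–Welch and decoded with Viterbi. Low-state
runs become PMDs after trimming to the first/last contained CpG, bridging
of gaps < 2 windows, subtraction of gap/centromere exclusions, removal of
domains < 200 kb (absorbed so PMD ∪ HMD always partitions the analysable
genome), and merging of same-kind neighbours.

**Covariates.** ChIP windows are normalised as
$\frac{(\mathrm{IP}+0.5)\cdot 10^7/N_{IP}}{(\mathrm{IN}+0.5)\cdot 10^7/N_{IN}}$;
replication timing is the loess-smoothed, quantile-normalised
$\log_2(\mathrm{early}/\mathrm{late})$ of repli-seq fraction counts
(higher = earlier). PMDs are split into H3K9me3- vs H3K27me3-marked
classes by k-means (k = 2) on their mark means; a domain is
*hypermethylated* when its mean methylation gains ≥ 5 percentage points in
the knockout (boundary inclusive).

**Kinetics.** Domain methylation under acute DNMT1 removal follows
$dm/dt = -\lambda m + \nu(1-m)$: closed form
$m(t) = m_\infty + (m_0 - m_\infty)e^{-(\lambda+\nu)t}$ with plateau
$m_\infty = \nu/(\lambda+\nu)$. Fits report the log-linear slope over days
0–6 and the day-12 final level; classes are compared by rank-sum tests.

A synthetic-data generator (`simulationConfig()`, `simulateMethylome()`,
`simulateChip()`, `simulateRepliseq()`, `simulateTimecourse()`) plants a
ground-truth domain structure with all of these signals, so the entire
pipeline is testable offline.

## Worked example

```r
library(pmdomains)

cfg <- simulationConfig(seed = 7)   # 2 x 25 Mb synthetic genome
res <- runPipeline(cfg)             # simulate -> segment -> classify ->
                                    # hyper-call -> timing -> kinetics
rep <- res$report
```

This prints (exactly, given the seed):

```
PMDs: 28  HMDs: 28
K9-marked: 15  K27-marked: 13  hyper: 4
Fisher p (hyper in PMD vs HMD): 0.111
Wilcoxon p (PMD vs HMD methylation change): 1.12e-06
Spearman rho (meth change vs timing): 0.162
     class  n median_slope median_final
       HMD 28   -0.1170777    37.820272
   PMD-K27 13   -0.2731031     8.111229
    PMD-K9 11   -0.3600387     3.850467
 PMD-hyper  4   -0.1686015    16.531654
```

Reading it: the 50 Mb synthetic genome segments into 28 PMDs and 28 HMDs;
k-means splits the PMDs into 15 H3K9me3-marked and 13 H3K27me3-marked; 4
domains gain ≥ 5 pp methylation in the simulated knockout (exactly the
planted set — `res$hyper`). PMDs lose significantly more methylation than
HMDs (rank-sum p ≈ 1e-06), and the loss correlates with replication
timing. The kinetics table shows the expected ordering: HMDs lose
methylation slowly and plateau high (high de novo activity), K9-marked
PMDs fastest and lowest, and the hypermethylated subset sits in between —
the signature of elevated de novo activity in those domains.

Real data enter through `readMethylation()` (bismark coverage / bedGraph),
`readBed()`, `readChromSizes()` and `binCounts()`; the same functions the
pipeline uses on simulated input.

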