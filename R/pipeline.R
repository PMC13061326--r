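#' @include simulate.R segmentation.R chip-repli.R domain-analysis.R kinetics.R
NULL

#' Run the full domain-level analysis on a synthetic genome
#'
#' End-to-end composition of every stage, driven entirely by a
#' [SimulationConfig]: simulate parental (WT) and DNMT1-loss (KO)
#' methylomes, segment the WT methylome into PMDs/HMDs, normalise simulated
#' H3K9me3/H3K27me3 ChIP against input and classify PMDs by dominant mark,
#' compute smoothed replication timing from two simulated repli-seq
#' replicates, call hypermethylated PMDs from the WT/KO domain means, build
#' a scale-regions pileup of WT methylation over the PMDs, run the
#' domain-level statistics (rank-sum, Fisher, decile/Spearman), and fit the
#' per-domain decay kinetics of a simulated DNMT1-removal time course.
#'
#' Identical config (including seed) gives identical results; when `outdir`
#' is given, domain BEDs, tracks and a JSON-able run report are written
#' there.
#'
#' @param config A [SimulationConfig]; `simulationConfig()` by default.
#' @param outdir Optional output directory (created if missing).
#' @param hyper_threshold_pp Hypermethylation threshold in percentage points.
#' @return A list report: per-stage counts and key statistics, plus the
#'   main result objects (`domains`, `classification`, `hyper`, `timing`,
#'   `kinetics`, `truth`).
#' @export
runPipeline <- function(config = simulationConfig(), outdir = NULL,
                        hyper_threshold_pp = 5.0) {
  wt <- simulateMethylome(config, "WT")
  ko <- simulateMethylome(config, "KO")
  truth <- wt$truth

  domains <- callPMDs(wt$calls, config@layout, config@exclusions,
                      window = config@window, seed = config@seed)
  pmds <- domainSubset(domains, "PMD")
  hmds <- domainSubset(domains, "HMD")

  k9 <- simulateChip(config, "H3K9me3", "WT")
  k27 <- simulateChip(config, "H3K27me3", "WT")
  k9n <- normalizeChip(k9$ip, k9$input)
  k27n <- normalizeChip(k27$ip, k27$input)
  classification <- classifyPMDs(pmds, k9n, k27n, seed = config@seed)

  rep1 <- simulateRepliseq(config, "WT", replicate = 1L)
  rep2 <- simulateRepliseq(config, "WT", replicate = 2L)
  timing <- replicationTiming(list(rep1$early, rep2$early),
                              list(rep1$late, rep2$late))

  allDoms <- domainRanges(domains)
  methWT <- weightedMeanMethylation(wt$calls, allDoms)
  methKO <- weightedMeanMethylation(ko$calls, allDoms)
  hyper <- callHypermethylated(methWT, methKO, hyper_threshold_pp)
  hyper$kind <- domainKind(domains)

  isP <- hyper$kind == "PMD"
  hyperTab <- matrix(c(sum(hyper$hyper[isP]), sum(!hyper$hyper[isP]),
                       sum(hyper$hyper[!isP]), sum(!hyper$hyper[!isP])),
                     2, byrow = TRUE,
                     dimnames = list(c("PMD", "HMD"), c("hyper", "not")))
  fisherHyper <- if (all(rowSums(hyperTab) > 0) && all(colSums(hyperTab) > 0))
    fisherExact(hyperTab) else list(odds_ratio = NA_real_, p_value = NA_real_)
  deltaP <- hyper$delta[isP]; deltaH <- hyper$delta[!isP]
  wilcoxDelta <- wilcoxonRankSum(deltaP[!is.na(deltaP)],
                                 deltaH[!is.na(deltaH)])

  methTrack <- methylationTrack(wt$calls, config@layout, config@window)
  pmdMeanWT <- methWT[isP]
  pileup <- pileupMatrix(pmds, methTrack, rank_values = pmdMeanWT)

  koTrack <- methylationTrack(ko$calls, config@layout, config@window)
  deltaTrack <- binnedTrack(binWindows(methTrack),
                            binValues(koTrack) - binValues(methTrack),
                            binSize = config@window)
  deciles <- decileAnalysis(deltaTrack, timing@smoothed)

  tc <- simulateTimecourse(config)
  fits <- fitDecayByDomain(tc)
  byClass <- split(fits$fits, fits$class[names(fits$fits)])
  kinetics <- compareClasses(byClass)

  report <- list(
    seed = config@seed,
    n_cpgs_wt = length(wt$calls), n_cpgs_ko = length(ko$calls),
    n_pmds = length(pmds), n_hmds = length(hmds),
    n_k9_marked = sum(classification$class == "K9-marked"),
    n_k27_marked = sum(classification$class == "K27-marked"),
    n_hyper = sum(hyper$hyper),
    fisher_hyper_p = fisherHyper$p_value,
    wilcox_delta_p = wilcoxDelta$p_value,
    decile_rho = deciles$rho,
    kinetics_summary = kinetics$summary,
    pileup_dim = dim(pileup))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeBed(domains, file.path(outdir, "domains.bed"))
    writeBed(truthDomains(truth), file.path(outdir, "ground_truth.bed"))
    writeMethylation(wt$calls, file.path(outdir, "wt.cov.gz"))
    writeBedGraph(timing@smoothed, file.path(outdir, "timing.bedgraph.gz"))
    utils::write.table(
      data.frame(domain = seq_along(allDoms), kind = hyper$kind,
                 meth_wt = methWT, meth_ko = methKO, delta = hyper$delta,
                 hyper = hyper$hyper),
      file.path(outdir, "domain_table.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(report = report, domains = domains, classification = classification,
       hyper = hyper, timing = timing, kinetics = kinetics, truth = truth,
       pileup = pileup)
}
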