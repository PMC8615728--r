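#' Run the full basal-vs-carbachol synthetic study
#'
#' End-to-end orchestration of the analysis pipeline on synthetic data: a
#' basal and a carbachol-like spontaneous recording (matched mean firing
#' rate) are generated and analysed (band powers, multi-unit network
#' metrics, neural complexity), and a stimulation session per condition is
#' generated and analysed (PSTH areas, percent variation and channel
#' classification, spiking PCI). All sub-stage seeds derive from `seed`, so
#' the whole report is reproducible.
#'
#' @param seed master seed.
#' @param duration spontaneous recording duration per condition (s).
#' @param n_trials stimulation trials per condition.
#' @param segment_length neural-complexity segment length (s).
#' @param nc_samples bipartitions per partition size for NC.
#' @param n_boot bootstrap repetitions for the PCI threshold.
#' @param response_scale_cch evoked-response amplitude scaling under the
#'   carbachol-like regime.
#' @param include_lfp compute the LFP-proxy band powers (slowest stage).
#' @param sttc_dt STTC coincidence half-window (s).
#' @return object of class `mea_study_report`: nested list with elements
#'   `spontaneous` (per-condition `network_metrics`, NC, band powers and
#'   normalized band-power ratios), `evoked` (PSTH areas, `channel_change`,
#'   `pci_result` per condition), `stats` (test table) and `params`.
#' @export
run_study <- function(seed = 1, duration = 600, n_trials = 120,
                      segment_length = 300, nc_samples = 100,
                      n_boot = 500, response_scale_cch = 0.5,
                      include_lfp = TRUE, sttc_dt = 0.01) {
  cfg_bas <- regime_config("basal", duration = duration, seed = seed)
  cfg_cch <- regime_config("cch", duration = duration, seed = seed + 1L)
  sp_bas <- generate_spontaneous(cfg_bas)
  sp_cch <- generate_spontaneous(cfg_cch)

  metrics <- list(basal = network_metrics(sp_bas, sttc_dt = sttc_dt),
                  cch = network_metrics(sp_cch, sttc_dt = sttc_dt))
  nc <- list(
    basal = neural_complexity(sp_bas, segment_length = segment_length,
                              n_samples = nc_samples, seed = seed + 2L),
    cch = neural_complexity(sp_cch, segment_length = segment_length,
                            n_samples = nc_samples, seed = seed + 3L))

  bands <- NULL
  if (include_lfp) {
    set.seed(seed + 4L)
    lfp_bas <- generate_lfp_proxy(sp_bas)
    set.seed(seed + 5L)
    lfp_cch <- generate_lfp_proxy(sp_cch)
    bp_bas <- band_power_table(lfp_bas)
    bp_cch <- band_power_table(lfp_cch)
    bands <- list(basal = bp_bas, cch = bp_cch,
                  ratio = bp_cch$mean / bp_bas$mean)
  }

  ecfg <- evoked_config(n_trials = n_trials,
                        response_scale_cch = response_scale_cch,
                        seed = seed + 6L)
  ev_bas <- generate_evoked(ecfg, "basal")
  ev_cch <- generate_evoked(ecfg, "cch")
  psth_bas <- compute_psth(ev_bas$spikes, ev_bas$stim)
  psth_cch <- compute_psth(ev_cch$spikes, ev_cch$stim)
  active <- filter_active_channels(psth_bas)
  dpa <- delta_pa(psth_bas$area[match(active, psth_bas$channels)],
                  psth_cch$area[match(active, psth_cch$channels)])
  changes <- classify_channels(dpa, threshold = NULL, channels = active)
  pci_res <- list(
    basal = perturbational_complexity(ev_bas$spikes, ev_bas$stim,
                                      n_boot = n_boot, seed = seed + 7L),
    cch = perturbational_complexity(ev_cch$spikes, ev_cch$stim,
                                    n_boot = n_boot, seed = seed + 8L))

  stats <- rbind(
    compare_conditions(nc$basal$nc, nc$cch$nc, label = "NC"),
    compare_conditions(metrics$basal$mfr, metrics$cch$mfr, label = "MFR"))

  structure(list(
    spontaneous = list(metrics = metrics, nc = nc, bands = bands),
    evoked = list(psth = list(basal = psth_bas, cch = psth_cch),
                  active_channels = active, delta_pa = dpa,
                  changes = changes, pci = pci_res),
    stats = stats,
    params = list(seed = seed, duration = duration, n_trials = n_trials,
                  segment_length = segment_length, nc_samples = nc_samples,
                  n_boot = n_boot,
                  response_scale_cch = response_scale_cch)),
    class = "mea_study_report")
}

#' @export
print.mea_study_report <- function(x, ...) {
  m <- x$spontaneous$metrics
  cat("Synthetic basal-vs-CCh study (seed", x$params$seed, ")\n\n")
  cat("Spontaneous activity (basal | cch):\n")
  cat(sprintf("  MFR (sp/s):      %6.2f | %6.2f\n",
              m$basal$mfr_mean, m$cch$mfr_mean))
  cat(sprintf("  IBR (%%):         %6.1f | %6.1f\n", m$basal$ibr, m$cch$ibr))
  cat(sprintf("  BI:              %6.3f | %6.3f\n", m$basal$bi, m$cch$bi))
  cat(sprintf("  STTC:            %6.3f | %6.3f\n",
              m$basal$sttc_mean, m$cch$sttc_mean))
  cat(sprintf("  SPIKE-sync:      %6.3f | %6.3f\n",
              m$basal$spike_sync, m$cch$spike_sync))
  cat(sprintf("  CV(MFR):         %6.3f | %6.3f\n",
              m$basal$cv_mfr, m$cch$cv_mfr))
  cat(sprintf("  NC (bits):       %6.3f | %6.3f\n",
              mean(x$spontaneous$nc$basal$nc), mean(x$spontaneous$nc$cch$nc)))
  if (!is.null(x$spontaneous$bands)) {
    r <- x$spontaneous$bands$ratio
    cat(sprintf("  band power ratio (cch/basal): delta %.2f, theta %.2f, beta %.2f\n",
                r[["delta"]], r[["theta"]], r[["beta"]]))
  }
  s <- attr(x$evoked$changes, "summary")
  cat("\nEvoked activity:\n")
  cat(sprintf("  active channels: %d; %.0f%% decreased, median dPA %.1f%%\n",
              nrow(x$evoked$changes), s$pct_decreased, s$median_delta_pa))
  cat(sprintf("  PCI: basal %.3f | cch %.3f\n",
              x$evoked$pci$basal$pci, x$evoked$pci$cch$pci))
  invisible(x)
}

#' Two-group comparison with data-driven test selection
#'
#' Thin wrapper over the standard routines: normality of each group is
#' checked with a Kolmogorov-Smirnov test against a normal distribution
#' with the sample moments; if both groups look normal (p > 0.05) a t-test
#' is used, otherwise a Mann-Whitney (Wilcoxon rank-sum) test. With fewer
#' than 3 observations per group only descriptive output is returned.
#'
#' @param x,y numeric samples for the two conditions.
#' @param paired paired comparison.
#' @param label row label for the output table.
#' @return one-row data.frame: `label`, `test`, `statistic`, `p`,
#'   `mean_x`, `mean_y`.
#' @export
compare_conditions <- function(x, y, paired = FALSE, label = "") {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    return(data.frame(label = label, test = "descriptive",
                      statistic = NA_real_, p = NA_real_,
                      mean_x = mean(x), mean_y = mean(y)))
  }
  normal <- function(v) {
    if (stats::sd(v) == 0) return(FALSE)
    suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v))$p.value) > 0.05
  }
  if (normal(x) && normal(y)) {
    tt <- stats::t.test(x, y, paired = paired)
    data.frame(label = label, test = "t-test",
               statistic = unname(tt$statistic), p = tt$p.value,
               mean_x = mean(x), mean_y = mean(y))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = paired))
    data.frame(label = label, test = "mann-whitney",
               statistic = unname(wt$statistic), p = wt$p.value,
               mean_x = mean(x), mean_y = mean(y))
  }
}

#' Two-way ANOVA with a drug-treatment factor
#'
#' Group-level contrast used for NC, CV(MFR) and PCI: a two-way analysis of
#' variance of `value ~ treatment + experiment`, reporting the treatment
#' effect.
#'
#' @param df data.frame with numeric `value` and factors `treatment` and
#'   `experiment`.
#' @return one-row data.frame with the treatment F statistic and p value.
#' @export
anova_treatment <- function(df) {
  stopifnot(all(c("value", "treatment", "experiment") %in% names(df)))
  fit <- stats::aov(value ~ treatment + experiment, data = df)
  tab <- summary(fit)[[1]]
  i <- grep("treatment", rownames(tab))
  data.frame(test = "two-way ANOVA (treatment)",
             statistic = tab[i, "F value"], p = tab[i, "Pr(>F)"])
}
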