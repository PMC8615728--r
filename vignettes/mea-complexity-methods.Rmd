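---
title: "Quantifying synchrony, evoked responses and complexity in MEA cortical cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synchrony, evoked responses and complexity in MEA cortical cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meaculture)
```

## The scientific problem

Dissociated cortical neurons grown on a planar 60-channel micro-electrode
array (MEA) spontaneously settle into a synchronized, slow-oscillation-like
regime: most spikes occur inside network bursts that recruit nearly every
electrode, and the local field potential (LFP) is dominated by delta-band
power. Activating neuromodulation — modeled chemically with the cholinergic
agonist carbachol (CCh) — suppresses the slow oscillation and fragments the
bursts into heterogeneous tonic firing, without changing the overall firing
rate. Two complementary complexity measures quantify what this state change
does to network dynamics:

* **Neural complexity (NC)** is computed on spontaneous activity. For a
  bipartition size $n$, the network is split into complementary subsets of
  $n$ and $N - n$ electrodes; the electrode-averaged instantaneous firing
  rates of the two parts are discretized and their mutual information (MI)
  computed. NC is the sum over $n \in \{5, 10, \dots, 30\}$ of the mean MI
  over 100 random bipartitions per size:
  $\mathrm{NC} = \sum_n \langle \mathrm{MI}_n \rangle$.
* **The perturbational complexity index (PCI)** is computed on stimulus-evoked
  activity. Spiking is binned at 5 ms in a window of 1000 ms before to 500 ms
  after each of 120 electrical stimuli; a bootstrap null built from the
  pre-stimulus window yields a per-channel threshold for significant
  activation, giving a binary channel $\times$ time matrix $SS(x,t)$. After
  sorting channels by total activity, the matrix is compressed with the
  Lempel–Ziv (1976) production parsing and normalized:
  $\mathrm{PCI} = C \cdot \log_2 L \,/\, (L \cdot H_{src})$, with
  $L = 60 \times 100$ and $H_{src}$ the binary entropy of the fraction of
  significant entries.

The interesting phenomenon is a *dissociation*: desynchronization raises the
complexity of spontaneous dynamics (NC, and the dispersion of firing rates)
dramatically, while the complexity of the causal response to perturbation
(PCI) moves only moderately when the evoked response merely shrinks in
amplitude without changing its spatio-temporal structure.

## Pipeline stages and their parameters

### LFP

Raw 10 kHz traces are reduced to 1 kHz LFPs by zero-phase Butterworth
filtering into 1–300 Hz. The band-pass is realized as a cascade (4th-order
low-pass at 300 Hz at the native rate, decimation by 10, 4th-order high-pass
at 1 Hz) because a direct transfer-function band-pass spanning almost four
decades below Nyquist is numerically unstable; the low-pass doubles as the
anti-alias filter. Spectra use Welch's method, 5 s Hann windows with 50%
overlap for spontaneous activity and 200 ms windows (up to 100 Hz) for the
mean evoked response, whose 10 ms post-stimulus artifact interval is linearly
interpolated per trial rather than zero-filled, to avoid injecting broadband
step edges. Band powers are trapezoidal integrals over delta (1–4 Hz), theta
(4–11 Hz) and beta (11–30 Hz); adjacent bands share single edge points, so
power is additive over the three bands. The alternative edge convention
(theta 5–9, beta 10–30) is available as `lfp_bands("figure")`; the 4/11 Hz
convention is the default because it is the operative definition in this
analysis family. Gamma is deliberately out of scope.

### Multi-unit activity

Spikes are single over-threshold peaks of the >300 Hz band at $k = 7$ robust
noise SDs (`median(|x|)/0.6745`) with 1 ms dead time; bursts are maximal
spike runs with inter-spike intervals $\le$ 100 ms and at least 5 spikes.
These detector defaults are documented substitutes: the published pipelines
this package follows rely on lab-internal detectors whose exact parameters
are not recoverable, so both are exposed as arguments. Derived statistics
are the mean firing rate (MFR), the inverse burst ratio (IBR, % of spikes
outside bursts), the burstiness index (BI, excess fraction of spikes in the
15% fullest 1 s bins, normalized to [0, 1]), and CV(MFR), the SD/mean of
per-electrode rates. Pairwise synchrony uses the spike time tiling
coefficient (STTC) with $\Delta t$ = 10 ms (the coincidence window is not
standardized in this literature; 10 ms is half the NC rate bin and a common
choice, and it is a parameter). Empty-train pairs are excluded from the mean
STTC rather than zero-filled, which would bias the network mean downward.
The parameter-free SPIKE-synchronization measure (adaptive coincidence
window of half the minimum of the four surrounding inter-spike intervals) is
computed as an independent cross-check; both measures must agree in sign on
any regime contrast.

### Evoked responses

PSTHs use 4 ms bins over 400 ms post-stimulus; dividing counts by
(trials $\times$ bin width) gives spikes/s, and the PSTH area is the mean
number of evoked spikes per trial. Channels with area below 1 spike/trial
are removed before statistics (the boundary is retained). Response change is
the percent variation $\Delta PA = 100 (PA_{CCh} - PA_{BAS}) / PA_{BAS}$,
classified against a stability band estimated by splitting a basal
stimulation session into halves and pooling the per-channel percent
variation (mean $\pm$ SD); when no stability session is supplied the band
falls back to the $\pm 20\%$ constant that such stability analyses typically
produce. The 10 ms artifact blanking is applied to spiking as well as LFP
(configurable): blanking only one modality would let residual artifact
masquerade as ultra-short-latency "responses".

### Complexity

MI uses 6 discretization levels. Discretization is equipopulated (quantile)
by default for robustness to heavy-tailed rate distributions, with two
safeguards: signals with at most 6 distinct values are coded exactly, and if
the quantile grid degenerates (more than 5/6 of the mass on one value) the
fallback is equally spaced levels. Without these, a mostly-silent bursting
network collapses to a single level and its MI is spuriously zero. The
plug-in MI is bias-corrected with the Panzeri–Treves expected-occupancy
estimate, $(\hat R_{xy} - \hat R_x - \hat R_y + 1)/(2 N \ln 2)$; corrected
values are truncated at zero inside NC so the summed complexity stays
non-negative. NC is computed per 5-min segment.

For PCI, the bootstrap null resamples trials with replacement (500
repetitions) and records the maximum trial-mean count over the 200
pre-stimulus bins; the per-channel threshold is the 95th percentile of these
maxima. Using the max statistic controls the family-wise error across the
100 post-stimulus bins, and makes the test conservative (the realized
false-activation rate is below the nominal 5%). Channels silent before the
stimulus get a pooled-channel null and are flagged. The sorted binary matrix
is flattened time-major (successive 5 ms columns concatenated across
channels; row-major is an option recorded in the result) and parsed with the
Kaspar–Schuster procedure (compiled). The printed normalization in parts of
this literature mixes natural and base-2 logarithms; only
$C \log_2 L / (L H_{src})$ with $H_{src}$ in bits yields the intended [0, 1]
scale (i.i.d. Bernoulli(0.5) matrices calibrate to $\approx 1$), so base 2
is the default and the base is configurable. $\mathrm{PCI} = 0$ by
convention when $H_{src} = 0$. The LFP variant applies the identical
bootstrap/compression pipeline to per-bin mean absolute baseline-corrected
amplitudes of the 1–300 Hz signal.

## What the synthetic generator emulates

Because the recordings this methodology was developed on are not publicly
deposited, the package ships a generator whose defaults *are* the study
conditions, and every stage is validated against it.

* **Basal regime**: network-burst events arrive as a Poisson process
  (0.2 events/s). Each event has a mother spike train whose rate (80
  spikes/s per electrode equivalent) decays exponentially from a sharp onset
  (time constant 80 ms, duration 0.3 s); each electrode joins an event with
  probability 0.9, copying mother spikes with probability 0.6, 2 ms spike
  jitter and 10 ms onset jitter. The thinned-jittered-copy construction is
  the minimal mechanism that makes fine-time synchrony (STTC,
  SPIKE-synchronization) a real, tunable property rather than a rate
  artifact. Sparse homogeneous tonic firing (~0.5 spikes/s) completes the
  rate budget.
* **CCh-like regime**: bursts nearly abolished (0.02 events/s, recruitment
  0.3); firing dominated by heterogeneous tonic trains (log-normal across
  electrodes, sdlog 0.8) driven by a shared slow multiplicative modulation
  (log-Gaussian process, strength 1, correlation time 0.3 s). The common
  slow input is deliberate: fully independent tonic trains would carry
  (near) zero bipartition MI, and the observed *rise* of NC under
  desynchronization requires slow co-fluctuation to survive while fine-time
  synchrony is removed.
* **Matched rate**: the expected per-electrode burst contribution is
  subtracted from the 4.8 spikes/s target and the drawn tonic rates are
  rescaled to hit the remainder exactly, so no contrast is a rate confound.
* **LFP proxy**: spike trains convolved with a causal PSP-like
  double-exponential kernel (5 ms rise, 80 ms decay; ~0.3 s wide) plus
  approximately 1/f background noise (a three-pole AR cascade). The sharp
  burst onsets leave measurable theta-band power, so the basal-vs-CCh
  contrast is testable in all three bands.
* **Evoked sessions**: responsive channels (70%) emit an early single spike
  at a channel-specific 5–50 ms latency (3 ms jitter) with per-trial
  probability ~0.8, and a late reverberant burst (~8 spikes in 100–400 ms)
  with probability ~0.35, over 0.5 spikes/s background; 120 trials at 0.2 Hz.
  The CCh-like session multiplies the response *probabilities* by 0.5 and
  changes nothing else — an amplitude-only scaling with preserved
  spatio-temporal structure, which is exactly the regime in which PCI should
  move little while the response amplitude halves.

What the generator does **not** emulate: distance-dependent connectivity and
propagation delays across the array, bursting nonstationarities over tens of
minutes, electrode-specific noise and artifact statistics, and any real
pharmacodynamics of carbachol (the "regime" switch is instantaneous).
Passing the regime-contrast suite therefore shows that the *pipeline*
recovers planted directions of effect at realistic signal strengths — not
that the generator is a faithful culture model.

## Problem sizes and numerical choices

Tests use 600 s spontaneous recordings (60 electrodes) and 120-trial evoked
sessions across 10 seeds for the regime-contrast suite, 5-min segments for
NC, and 500-repetition bootstraps; the band-power stage runs on 20-electrode
subsets, which leaves the channel-averaged contrast unchanged. The
acceptance script uses 5 seeds per condition. Half-open bins `[t, t + dt)`
everywhere remove double-counting ambiguity; trial tensors require the
window to divide evenly into bins. STTC clips tiling windows at the
recording edges and returns missing values for empty trains. Ties in the
significant-source sorting are broken by channel id so the matrix is a
deterministic function of the input up to channel relabeling.

## Known limitations

* The ±20% stability fallback is an empirical constant of this preparation;
  for other preparations the self-calibrating path (supplying a basal
  stimulation session) should be preferred.
* PCI values depend on the flattening convention and on `L`; results record
  both, and only like-configured values should be compared.
* SPIKE-synchronization has a nonzero chance level for Poisson-like trains
  (~0.2 under these conditions); it supports direction-of-effect contrasts,
  not absolute statements about synchrony strength.
* The KS-normality-then-test-selection wrapper mirrors common practice in
  this literature; it is not a recommendation of that inferential strategy.

## A worked miniature study

```{r study, eval = FALSE}
report <- run_study(seed = 1, duration = 300, n_trials = 60,
                    segment_length = 300, nc_samples = 50, n_boot = 200)
print(report)
```

The report prints the per-condition MFR (matched by construction), IBR, BI,
STTC, SPIKE-synchronization, CV(MFR), NC, the normalized band-power ratios,
the fraction of decreased channels with the median percent PSTH-area change,
and the spiking PCI for both conditions.
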