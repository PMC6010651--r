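---
title: "Higher-order spectra for EEG epilepsy-state recognition: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order spectra for EEG epilepsy-state recognition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoseeg)
```

## The problem and the model

Power-spectral methods discard phase. EEG during epileptic activity is
neither Gaussian nor linear, and part of its structure lives precisely in
phase relations among frequency triples: when components at $f_1$, $f_2$ and
$f_1+f_2$ satisfy $\phi_3=\phi_1+\phi_2$ (quadratic phase coupling, QPC),
second-order statistics cannot see it but the third-order spectrum can. The
bispectrum of a zero-mean signal is

$$B(f_1,f_2) = E\left[X(f_1)\,X(f_2)\,X^*(f_1+f_2)\right],$$

estimated here by segment averaging of the FFT triple product (direct
method) or by tapering and transforming the third-order cumulant sequence
$c_3(m,n)$ (indirect method). The bicoherence normalizes the bispectrum:

$$b(f_1,f_2) = \frac{\left|\langle X_1 X_2 X_3^*\rangle\right|}
 {\sqrt{\langle |X_1X_2|^2\rangle\,\langle |X_3|^2\rangle}},$$

which the Cauchy–Schwarz inequality bounds in $[0,1]$; it measures the
phase-coupled fraction of energy at a frequency pair, independent of
amplitude scale. A perfectly coupled noise-free triple has $b=1$ at
$(f_1,f_2)$; independent phases drive the average toward
$1/\sqrt{K}$ for $K$ averaged segments.

On this foundation the package computes, per analysis window, a
47-dimensional feature vector: for each of 11 regions of the bi-frequency
plane the four sums $\Sigma|Bis|$, $\Sigma|Bis|^2$, $\Sigma|Bic|$,
$\Sigma|Bic|^2$, plus the three Hinich statistics ($\chi^2$ Gaussianity
statistic, linearity noncentrality $\lambda$, and the probability of false
alarm). Feature selection (a GA wrapper and Student-$t$ ranking at
$P<0.001$) feeds a least-squares SVM, binary or multiclass through
one-versus-one voting or error-correcting output codes.

## Geometry: principal domain and the twelve symmetries

$B(f_1,f_2)$ is invariant under the six permutations of the triple
$(f_1,f_2,-f_1-f_2)$ and conjugate-symmetric under negation — twelve
transforms in all. The package's principal domain is the inner triangle
$\{0\le f_2\le f_1,\ f_1+f_2\le f_s/2\}$. Its twelve images tile the
band-limited hexagon $\{|f_1|,|f_2|,|f_1+f_2|\le f_s/2\}$, i.e. the whole
plane that a properly sampled signal can populate; the remaining corner of
the square plane is the aliasing orbit, which carries no information for
band-limited inputs. `symmetry_coverage()` verifies the tiling exhaustively
on a discrete grid: full coverage, interior cells covered exactly once,
overlaps confined to the symmetry boundary lines.

## Windowing and estimation resolution

The corpus layout this package emulates stores ~4096-sample records at
173.61 Hz. Each record is cut into 16 non-overlapping 256-sample windows,
giving 1600 feature vectors per 100-record set — the bookkeeping all split
counts rest on. A single 256-sample window, however, cannot feed a
segment-averaged bicoherence (the normalization needs several segments and
the Hinich statistics need the averaging count $K$). Each window is
therefore subdivided into 64-sample sub-segments at 75% overlap (13
segments), and HOS estimates use `nfft = 64`, i.e. a bi-frequency
resolution of about 2.71 Hz. That resolution still separates the clinical
bands used for the region grid — delta $[0.53,4)$, theta $[4,8)$, alpha
$[8,13)$, beta $[13,30)$ Hz (edges config-exposed); with four bands there
are $\binom{4}{2}+4=10$ unordered pair regions plus the whole principal
domain. Region membership uses cell-centre frequencies and half-open
intervals, so no cell is counted twice; the whole-domain sums run over the
full principal triangle, including cells outside the named bands.

The estimator functions themselves are size-agnostic: any segment list and
any `nfft` at least the segment length are accepted, and `nfft` defaults to
the segment length.

## Hinich statistics

For Gaussian data $2K\,\hat b^2(f_1,f_2)$ is asymptotically central
$\chi^2_2$ per cell. The Gaussianity statistic sums it over the interior
principal-domain cells ($P$ of them) and refers the sum to $\chi^2_{2P}$;
its upper tail is the reported probability of false alarm. Cells on the
$f=0$ lines and the $f_1+f_2=f_s/2$ boundary are excluded: after mean
removal they are degenerate, and zero-denominator cells (flagged by the
bicoherence estimator) are likewise skipped — this keeps band-limited
synthetic inputs from contributing spurious infinities. The linearity check
estimates the noncentrality $\lambda=\max(\bar x - 2, 0)$ from the mean
cell statistic and compares the sample interquartile range of the cell
statistics with the IQR of $\chi^2_2(\lambda)$: a linear non-Gaussian
process has constant noncentrality, so a large discrepancy flags
nonlinearity.

The $\chi^2$ reference is asymptotic in $K$. The Monte-Carlo calibration in
the test suite therefore uses 64 non-overlapping 64-sample segments per
run (a 4096-sample record), where the measured type-I rate at
$\alpha=0.05$ is ~0.06 over 200 runs. At the pipeline's per-window $K=13$
the statistic remains usable as a *feature* (it needs only to differ
between classes), but its null calibration is not relied on there.

## The synthetic generator

`gen_qpc_signal()` builds three-component sinusoids with QPC switchable on
or off, and `gen_bonn_like_dataset()` arranges them in the corpus layout:
one-column ASCII integers, per-set directories, 4096 samples per record at
173.61 Hz, amplitudes scaled into roughly ±2000 before rounding. Phases are
redrawn every `block_len` samples (default 64, aligned with the analysis
sub-segments) because segment-averaged bicoherence estimation *requires*
phase diversity across segments: with one global phase draw, an uncoupled
triple would be indistinguishable from a coupled one. The default class
recipes place no coupling in the healthy sets, delta–theta coupling of
strength 0.5/0.8 in the interictal sets and full-strength alpha–beta
coupling in the ictal set, at band frequencies snapped to the analysis
grid. Coupling strength $s$ splits the third component between a coupled
and an independent-phase part, so bicoherence rises smoothly with $s$.

What the generator does *not* emulate: 1/f background spectra, artifacts,
nonstationarity, inter-subject variability — none of the physiological
texture of real EEG. Passing tests demonstrate that the estimators, the
feature geometry and the classifier chain behave as the theory predicts on
signals with *known* higher-order structure; they say nothing about
clinical accuracy on real recordings, which is why the published clinical
accuracies are not reproduction targets here.

## Selection and classification

The GA follows the published recipe: binary chromosomes over the 47
features, fitness = classification accuracy of the wrapped LS-SVM,
crossover probability 0.4, per-bit mutation 0.05, 100 generations.
Population size (50), tournament-of-2 parent selection and top-1 elitism
are unstated in the source material and fixed here as conventional
defaults; elitism makes best-ever fitness non-decreasing. Fitness is
evaluated on the validation partition only, never the test partition, and
repeated masks are served from a cache. The $t$-ranking is the pooled
two-sample Student $t$ (Welch optional) with a two-sided $P<0.001$ pass
rule; for more than two classes a feature's $p$-value is its minimum over
class pairs. How the two selectors combine is genuinely open; the default
is their intersection (falling back to the union when empty), with union
and GA-only as options.

The LS-SVM replaces the SVM's inequality constraints with equalities, so
training is one linear solve of the dual KKT system
$\left[\begin{smallmatrix}0&y^T\\ y&\Omega+I/\gamma\end{smallmatrix}\right]
\left[\begin{smallmatrix}b\\ \alpha\end{smallmatrix}\right]=
\left[\begin{smallmatrix}0\\ 1\end{smallmatrix}\right]$ with
$\Omega_{ij}=y_iy_jK(x_i,x_j)$. Kernels: Gaussian
$\exp(-\|x-z\|^2/\sigma^2)$ and polynomial $(x\cdot z + c)^d$. Defaults
$\gamma=10$ and $\sigma=\sqrt{d}$ (feature count $d$) are sensible on
z-scored features; both are config-exposed. Multiclass: one-versus-one
majority voting, or ECOC with the exhaustive three-column code for three
classes and Hamming decoding; ties break on the largest summed decision
margin. The printed total-accuracy formula in the source material is
typographically corrupted; the standard
$(TP+TN)/(TP+TN+FP+FN)$ is implemented, and metrics with empty
denominators are reported as `NA`, never 0.

## Pipeline hygiene and reproducibility

Normalization ($z$-scores) is fitted on the training partition only;
zero-variance features are dropped with a warning. Splits are stratified
60/5/35 per class with largest-remainder rounding, so 1600 vectors give
exactly 960/80/560. A single master seed derives every stage seed
(splitting, GA, ECOC codes, generation) through a documented hash, making
whole runs bit-reproducible; the package never touches the caller's RNG
state.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data at
desk scale: 10 records per class for the end-to-end three-class experiment
(480 feature vectors), 50 seeds for the coupled/uncoupled bicoherence
contrast, 200 Monte-Carlo runs for the Hinich calibration, and 20 seeded
GA runs at the full published GA settings for the planted-feature recovery
benchmark. These sizes were chosen as the smallest at which the asymptotic
references and Monte-Carlo bands are meaningful.

## Known limitations

- The indirect bispectrum's Parzen lag window trades variance for
  resolution; triples closer than the smoothing bandwidth (roughly
  `nfft/max_lag` bins) can merge. The direct method resolves them.
- The per-window Hinich statistics inherit small-$K$ bias; they are
  features, not calibrated tests, inside the pipeline.
- Filtering is applied to the full record before windowing (the
  alternative order is not implemented).
- No artifact model, no multichannel montages, no trispectrum.
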