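---
title: "Marking and morphometry of evoked-potential waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marking and morphometry of evoked-potential waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epwave)
```

## The problem

Clinical evoked-potential analysis — brainstem responses (waves I, III, V
within ~10 ms of the stimulus) and cortical responses (P1, N1, P2) — rests
on marking peaks and troughs on a sampled voltage trace and deriving
measures from the marks: latencies (ms), amplitudes (µV), interpeak
intervals, the area between a peak and its following trough, and the slope
of the peak-to-trough descent. Latency and amplitude alone often miss
morphological detail; area, slope and the frequency content of the trace
carry additional diagnostic information. `epwave` implements this analysis
chain as a library plus command line, together with the apparatus needed to
*validate* it: a synthetic-signal generator whose ground truth is known in
closed form, and a descriptive agreement harness.

## Validation model: sinusoids with analytic landmarks

The desk validation uses pure tones
$y(t) = A \sin(2\pi f t)$ because every quantity the toolkit measures has a
closed form there. For the first peak--trough pair:

* $t_{peak} = 1/(4f)$, $t_{zero} = 1/(2f)$, $t_{trough} = 3/(4f)$;
* peak amplitude $A$, trough amplitude $-A$, peak-to-trough $2A$;
* absolute area $\int_{t_{peak}}^{t_{trough}} |y|\,dt = A/(\pi f)$
  (equivalently $1000\,A/(\pi f)$ µV·ms with $f$ in Hz);
* two-triangle approximation
  $(t_{zero}-t_{peak})\frac{A}{2} + (t_{trough}-t_{zero})\frac{A}{2}
  = 1000\,A/(4f)$ µV·ms;
* slope $2A/(t_{trough}-t_{peak}) = 4Af/1000$ µV/ms.

Note the fixed ratio: the two-triangle area is exactly $\pi/4 \approx 0.785$
of the absolute area for *every* sinusoid, which is why the two methods must
differ systematically — the triangle construction inscribes straight edges
under a convex arch. The test suite asserts the ratio analytically and the
inequality numerically on every fixture.

A subtlety worth making explicit: the signed integral
$\int_{t_{peak}}^{t_{trough}} y\,dt$ of a sinusoid is **zero** — the lobe
above the baseline cancels the lobe below. The meaningful area measure is
the integral of the *absolute* signal, and that is what `absolute_area()`
computes: a composite trapezoid on $|y - \text{baseline}|$ with the
integration interval subdivided at interpolated baseline crossings, so the
cusp of $|y|$ is integrated exactly rather than smeared across a sample
step. A property test verifies that the signed integral vanishes while the
absolute one does not.

The standard fixture set is three tones (0.5, 1, 2 kHz, each ±10 µV) and
their pointwise sum, sampled on the default grid below.

## The sampling grid

`sampling_grid()` defaults to 3072 samples spanning a 10 ms sweep from 0,
with the **half-open** convention $t_k = k \cdot 10/3072$ ms. This choice is
deliberate:

* the sweep holds an integer number of cycles for all three fixture tones,
* the spectral bin width is exactly $100$ Hz
  ($f_s/N = 307200/3072$), so each stimulus frequency falls exactly on a
  bin, and
* automatic spectral marking therefore reads 500/1000/2000 Hz exactly.

The endpoint-inclusive convention ($t_k = k \cdot 10/3071$, final sample at
10 ms) is available via `endpoint_mode = "inclusive"` for data exported
that way; none of the package's contracts depend on it. Phase is fixed at
zero in `sine_spec()` — the generator models stimulus-locked averages, not
arbitrary phases.

## Display conventions

Reports in this field quote two decimals. Two rules coexist, and the
package keeps both deliberately, always alongside the full-precision value:

* **Marked (measured) values** — latencies and amplitudes read off the
  trace — are rounded half-up (`display_round()`): a grid-snapped trough
  at 0.748698 ms reports as 0.75 ms.
* **Derived values** — areas, slopes, and analytic landmark tables — are
  truncated toward zero (`display_trunc()`): the analytic 2 kHz peak
  latency 0.125 ms reports as 0.12, the 500 Hz absolute area 6.3662 µV·ms
  as 6.36, and a slope of 40.8163 µV/ms as 40.81.

No single rounding rule reproduces all of those conventional printed
values; the split above does, and it is the one the agreement fixtures
assume. Internally nothing is ever computed from rounded numbers.

## The automatic detector

The original analysis systems do not document their detectors, so the
design here is the package's own, chosen to be deterministic and
reproducible:

1. interior local extrema by first-difference sign change; a plateau
   counts at its first sample;
2. each peak is scored by **prominence**: its height above the higher of
   the two flanking troughs (a single flank is used alone at the window
   edges);
3. the `n_pairs` most prominent peaks are selected; each is paired with
   the most prominent trough before the next selected peak (or the window
   end);
4. ties break toward the earlier time.

Step 4 needs care on sampled periodic signals. Successive crests of a
sampled sinusoid differ by ~$10^{-4}$ relative amplitude purely through
grid alignment (a crest that happens to sit on a sample beats one that
falls between samples), which would make "most prominent" an accident of
the grid. Prominence comparisons therefore treat candidates within a
relative tolerance `tie_tol` (default $10^{-3}$) as tied, and the earliest
wins — on the fixtures this selects the *first* crest, which is the
clinically meaningful P1. Real components differ by far more than 0.1 %,
so the tolerance is inert on genuine data. The detector is checked against
an independently written naive scan oracle on randomized multi-tone
traces, and against plain argmax/argmin within windows that isolate a
single cycle.

Zero-crossings are located by linear interpolation between the two samples
that bracket the sign change of $y - \text{baseline}$; the baseline
defaults to 0 µV and is configurable for tracings with offset.

## Frequency domain

`amplitude_spectrum()` applies a rectangular-taper FFT and single-sided
amplitude scaling $2|Y_k|/N$ (with $|Y_k|/N$ at DC and, for even $N$,
Nyquist), so a bin-aligned sinusoid of peak amplitude $A$ — i.e.
peak-to-peak $2A$ — reads $A$ at its frequency. The scaling is validated
through Parseval's identity reconstructed from the single-sided amplitudes.
Peak frequencies are reported as exact bin frequencies, without
interpolation; interval selection snaps to whole samples (floor at the
start, ceiling at the end); zero padding is available but off by default.
Power spectral density and non-rectangular tapers are out of scope.

## Agreement harness

`build_phase1_report()` compares observed measurement vectors (examiners or
the automatic pipeline) against expected values per label group:

* **MAD** — mean absolute deviation;
* **MAPE** — mean of $|obs-exp|/|exp|$, stored as a dimensionless
  *fraction*. Published tables in this area sometimes print the fraction
  with a percent sign; the report exposes both the fraction and
  fraction×100 so neither reading is ambiguous;
* **Pearson r** via `stats::cor()`;
* **ICC**, fixed to the two-way, absolute-agreement, single-measure form
  ICC(A,1), computed from the mean-squares decomposition (subjects =
  labels, raters = columns). Absolute agreement penalizes constant offsets
  between raters; the suite checks the identity case, the offset case, and
  equality with an independent `aov()`-based oracle.

The bundled reference tables (`phase1_reference_tables()`) are the printed
readings of a three-examiner validation session on the standard fixtures —
two trained humans and an automatic marker treated as examiner 3. The
row-per-printed-value convention matters: the time-domain table has 11
marking rows (amplitude rows stated once for "all frequencies" count once)
and 9 calculation rows; with that convention the harness reproduces the
session's summary statistics (marking MAD 0.0009 for the human examiners;
calculation MAD 0.1111 / MAPE 0.0094 for the humans and 0.0100 / 0.0037
for the automatic marker) from the raw table values. The corresponding
published FFT-group summary (MAD 1.04) is *not* derivable from the printed
frequency-domain table under any row-counting convention we tried, so it is
not asserted anywhere.

## The end-to-end run

`run_phase1_validation()` chains everything: generate the three tones and
their sum → auto-mark each tone's first pair and zero-crossing → compute
the full measure set → transform all four channels and mark spectral peaks
→ compare observed display values to analytic expectations with the
harness, alongside the bundled reference readings. Tolerance checks use
full-precision values and bound the *grid-snapping* error of the default
sweep, not examiner variability: 0.005 ms for latencies and zero-crossings,
0.01 µV for amplitudes, 0.05 µV·ms for areas, 0.5 µV/ms for slopes, 0.5 Hz
and 0.01 µV for spectral peaks. A failed stage raises a classed condition
naming the stage (e.g. a grid whose sampling rate cannot resolve the
highest stimulus frequency fails in `detect`); a failed tolerance only
clears `passed`. The pipeline has no stochastic stage; repeated runs are
byte-identical, and the configuration's `seed` field is reserved.

```{r, eval = FALSE}
res <- run_phase1_validation(phase1_config(out_dir = "phase1_out"))
res$passed
print(res)
```

## What the synthetic fixtures do and do not show

The generator emulates ideal, noise-free, stimulus-locked sinusoids on a
uniform grid. It does not emulate background EEG noise, component overlap,
latency jitter across sweeps, filter ringing, or asymmetric clinical
morphologies. Passing the desk validation therefore demonstrates that the
*computational chain* is correct to within grid resolution — not that the
detector's prominence ranking is optimal on noisy clinical tracings, where
search windows and baseline configuration remain the operator's
responsibility. Inferential statistics on clinical recordings
(repeated-measures ANOVA, paired comparisons, effect sizes) are outside the
package's scope; the harness is descriptive only.

## Numerical and I/O choices

* Test and validation problem sizes: 3072-sample fixtures throughout; the
  area-convergence checks refine to $10^5$ samples in the unit tests and
  $10^6$ in the acceptance script, where the trapezoid error is orders of
  magnitude below the $10^{-4}$ relative criterion.
* Waveform text output writes channels at 7 significant digits and the
  time axis at 15, so a write/read round trip preserves values to 1e-6
  relative and keeps the uniform-spacing invariant intact. Output is
  byte-stable and locale-independent unless a dialect requests decimal
  commas.
* Dialect sniffing prefers semicolon and tab over comma (decimal commas
  only occur with the former), infers the decimal mark from the fields,
  and treats a non-numeric first row as a header. `#` lines are comments.
* Markers persist in a fixed-order comma/period sidecar regardless of the
  waveform dialect; the reader does not judge marker validity — range
  checks happen downstream against a concrete waveform.
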