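---
title: "Methods: quantifying alpha entrainment by rhythmic TMS with simultaneous EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying alpha entrainment by rhythmic TMS with simultaneous EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, what the
synthetic generator does and does not emulate, the numerical conventions,
and the design choices made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The measurement model

A rhythmic rTMS burst is a train of `n` pulses at the individual alpha
frequency `f` (IAF, 8–12 Hz). The burst duration follows the `n/f`
convention — each pulse owns a full cycle — so a 20-pulse burst lasts
2.5 s at 8 Hz and 1.67 s at 12 Hz. A session interleaves blocks of
rhythmic bursts with **arrhythmic** control bursts: the same pulse count,
approximately the same duration, but inter-pulse instantaneous
frequencies (`1/Δt`) constrained to avoid the alpha band, its first
harmonic and its subharmonic (`[f_lo/2, f_hi/2] ∪ [f_lo, f_hi] ∪
[2 f_lo, 2 f_hi]`; for 8–12 Hz: 4–6, 8–12, 16–24 Hz). This removes
frequency-specific drive while matching pulse energy and acoustics.

Entrainment is quantified by the phase locking value between each EEG
channel and a deterministic reference wave at the IAF, phase-aligned to
the burst offset:

$$\mathrm{PLV}(c, f, t) \;=\; \frac{1}{N}\,\Bigl|\sum_{n=1}^{N}
e^{\,i\,(\Phi_{\mathrm{ong}}(c,f,t,n)-\Phi_{\mathrm{IAF}}(t))}\Bigr|
\;\in\;[0,1],$$

with `N` trials, `Φ_ong` from a complex Morlet decomposition (5 cycles,
Gaussian envelope truncated at ±3 SD) and `Φ_IAF(t) = 2π f (t − t_off)`.
Because the reference is identical across trials, the PLV against it
equals the inter-trial phase coherence of the signal up to a fixed
rotation per time point; the reference's own frequency therefore does not
restrict the frequency axis, and maps over 5–30 Hz are meaningful.
Time courses are normalized by the mean PLV in the baseline window
(−3.0, −2.5) s before burst offset (relative normalization: 1 = no
change, 0.5 = −50 %, 1.5 = +50 %).

*Statistical inference.* Per-unit (subject or synthetic replicate)
electrode maps of stimulation-window mean normalized PLV are compared by
a two-tailed cluster-based permutation test: per-electrode t (dependent
for rhythmic-vs-arrhythmic within session, independent vs. sham),
cluster-forming threshold at the parametric `t` critical value for
α = 0.05, clusters formed over the sensor neighbor graph among
same-signed suprathreshold electrodes, cluster mass = Σt, and a
max-|mass| null from 1000 sign flips (paired) or label shuffles
(independent); `p = (r+1)/(n_perm+1)`.

## 2. The artifact-removal cascade

The fixed order is: segment → ringing excision → decay ICA → gap
interpolation → common-average re-reference → downsample → statistical
rejection → ocular ICA. Key constants (all `run_config()` defaults):

| Parameter | Default | Meaning |
|---|---|---|
| trial window | −3.5 … +5.0 s re offset | 8.5 s, offset = last pulse |
| ringing excision | −4 … +9 ms per pulse | endpoints inclusive |
| decay criterion | 30 µV | peak of trial/pulse-averaged component in (9, 50] ms |
| power outliers | 1.5 × IQR | per trial × channel broadband power |
| trial rejection | ≥ 20 % bad channels | else neighbor interpolation |
| channel STD rule | > 30 µV | computed before cell interpolation |
| neighbor correlation | < 0.4 | mean Pearson r with graph neighbors |
| downsampling | 1250 Hz | zero-phase windowed-sinc anti-alias at 0.8 × new Nyquist |
| Morlet | 5 cycles, ±3 SD | phase from complex coefficients |
| baseline | (−3.0, −2.5) s | relative normalization |
| permutations | 1000 | two-tailed, max-mass correction |

Conventions that needed a decision:

* **Excision endpoints** are inclusive; at 2500 Hz a single pulse masks
  exactly 33 samples (tested against brute-force enumeration).
* **"Amplitude exceeded 30 µV"** is read as the *peak* of the averaged
  component time course (not its mean), over the window (9, 50] ms so the
  excised ringing cannot leak into the criterion. ICA component scale is
  fixed by normalizing each mixing column to unit maximum gain, which
  makes the microvolt criterion well defined despite ICA's inherent scale
  indeterminacy.
* **Channel-level STD and correlation rules** operate on data *before*
  per-trial cell interpolation: a persistently bad channel should be
  removed and logged, not silently patched trial by trial.
* **pchip** = Fritsch–Carlson shape-preserving monotone cubic Hermite
  interpolation (`stats::splinefun(method = "monoH.FC")`), applied locally
  with 8 context samples per side; exact on linear data, < 5 % error on
  an alpha-band sinusoid across a 13 ms gap. Gaps at a trial edge fall
  back to nearest-value extension and are logged.
* **Ocular component selection** is visual in practice; it is automated
  here as: |correlation| > 0.7 with a virtual EOG (mean of the
  frontopolar/AF rows) **or** frontal-to-posterior topography ratio > 3
  with super-Gaussian time course (kurtosis > 5) and dominant power below
  5 Hz. The kurtosis requirement protects near-Gaussian background
  components from false rejection. This is a stand-in for the original
  manual step, not a reconstruction of it.
* **FastICA** is the symmetric fixed-point iteration with tanh contrast
  (tol 1e-4, ≤100 iterations, 2 seeded restarts, fit on ≤20 000 strided
  samples). When the input is largely Gaussian — true for the synthetic
  background by construction — the rotation within the Gaussian subspace
  is unidentifiable and the global convergence criterion may never
  trigger; since reconstruction is exact under any orthogonal rotation
  and the non-Gaussian components of interest stabilize early, the final
  rotation is then used with a logged warning rather than failing the
  pipeline.
* **Neighbor interpolation** uses inverse-distance weights over immediate
  graph neighbors, normalized to sum 1.

## 3. The synthetic world

`generate_session()` realizes the stated acquisition: 64 channels (32 for
phantom runs) on an idealized spherical 10-10 montage, 2.5 kHz, an alpha
oscillator with posterior Gaussian topography (peak gain at POz) over a
correlated background of 20 spatially smooth 1/f sources (slope 1) plus
30 % sensor noise — the source mixture is what gives realistic
between-channel correlations, without which the neighbor-correlation
rejection rule would condemn every channel.

**Entrainment model.** The oscillator phase performs Brownian drift
(`phase_diffusion` = 4 rad²/s, giving a phase-memory of roughly half a
second, a realistic resting-alpha coherence time). During rhythmic bursts
with coupling `κ > 0`, the phase is reset at each pulse to the
pulse-train phase plus a von Mises perturbation of concentration `κ`.
Consequences, all tested: at `κ = 0` the oscillator is untouched and
statistically independent of the pulse train; for large `κ` the
across-trial resultant approaches `I₁(κ)/I₀(κ)` (≈ 0.95 at κ = 10); the
stimulation-window PLV is monotone in `κ`; and after the last pulse the
PLV relaxes to baseline at the diffusion rate — reproducing the
rapid-rise/plateau/return phenomenology. The "low / medium / high"
stimulation-intensity conditions are emulated by κ = 1 / 3 / 10; a
monotone map is the only assumption, not a biophysical calibration.

**Artifacts.** Ringing: a 1 kHz damped transient strictly confined to
−4…+9 ms around each pulse (500 µV at the coil site, gain decaying with
angular distance from PO3). Decay: `A·exp(−t/τ)` after each pulse with a
fixed smooth topography; defaults A = 80 µV, τ = 30 ms — a clearly
present decay source (at 40 µV the averaged component would sit exactly
on the 30 µV criterion boundary, a degenerate default). Blinks: 400 ms
biphasic frontal template, 10/min, 120 µV. Sham bursts carry no scalp
artifact but an onset-locked theta-range transient over temporal sites
decaying within five pulses (amplitude 8 µV — the real effect size is
unknown; it is a free parameter chosen to be detectable). The alpha
waveform carries a phase-locked second harmonic (ratio 0.2, arc-shaped
alpha), so entrained sessions also lock at 2×IAF.

**What the generator does not emulate** — and hence what a green test
does not establish: no neural-mass dynamics or Arnold-tongue frequency
detuning (coupling is at the stimulation frequency by construction), no
somatosensory or auditory co-stimulation pathways, no inter-subject
anatomy, no recharge/line artifacts, no electrode drift. Green tests
establish that the *analysis* recovers known ground truth under the
stated noise model, not that the biology behaves this way.

## 4. IAF estimation

2 s epochs with 50 % overlap → common average → per-epoch detrend/demean
→ zero-phase Butterworth band-pass 0.1–40 Hz (order 4 high- plus low-pass
biquad cascades) → automatic epoch rejection (variance > Q3 + 1.5 IQR;
the original criterion was visual) → multitaper spectrum with DPSS tapers
(NW = 2, 3 tapers) on the 1–20 Hz grid in 0.5 Hz steps → average over
epochs and posterior channels → peak search in 8–12 Hz. A peak is
accepted if it is a local maximum exceeding a fitted log–log 1/f trend by
a factor 1.5 (the acceptance factor is a stand-in for visual inspection).
If eyes-open data yield no acceptable peak the eyes-closed block is used;
failing both, the result is "none". The multitaper stage runs at 250 Hz
(recordings sampled faster are subsampled after the 40 Hz low-pass —
alias-free by construction, and a dense-grid eigendecomposition at
2.5 kHz would be intractable); the 1–20 Hz grid is unaffected.

## 5. Numerical and scale choices

* **Percentiles** (electric-field summaries): linear interpolation
  between order statistics (type 7), because a "99.9th percentile" on a
  finite mesh is method-sensitive; tested against an independent
  sort-and-interpolate oracle.
* **Arrhythmic sampling**: instantaneous frequencies drawn uniformly from
  [3, 30] Hz minus the forbidden bands (segment-width-weighted), with the
  whole burst redrawn until its duration matches the rhythmic burst
  within ±10 % (bounded retries). Whether the original bursts were
  duration-matched is unstated; only pulse-count matching is asserted, so
  the duration match is this package's choice.
* **Reference phase** φ₀ = 0 (cosine peak) at burst offset; PLV magnitude
  is invariant to φ₀.
* **Pulse-locked PLV** evaluates the IAF phase at each of the 20
  pulse-aligned time points plus `pre`/`post` points one IAF cycle before
  the first and after the last pulse (window length at these points is
  one cycle; the original figure does not state it).
* **Marker dialect**: BrainVision markers are free text, so a fixed
  numeric dialect is shipped (pulse 1 / burst on 10 / off 20 / block
  30–40, plus a condition offset 0–3; burst index in the marker channel
  field; fractional data-point positions so off-grid pulse times
  round-trip). EDF events ride in an EDF+ annotation signal; recordings
  are zero-padded to whole data records with the true sample count in the
  reserved header field. Both are conventions, not reconstructions of the
  original lab's scheme.
* **Desk scale.** Tests and the acceptance script reduce sampling rate,
  channel count and burst counts wherever the measured quantity is
  invariant to them (trial counts, rule arithmetic) or is a property with
  Monte-Carlo tolerance (type-I error, monotonicity). The type-I-error
  criterion generates null data at the unit level (spatially smooth
  Gaussian electrode maps), which is the quantity the cluster test
  consumes; running 1000 full EEG pipelines is not a desk-scale
  operation. The "identity on clean data" property compares the full
  cascade against plain re-reference + downsampling, since common-average
  referencing is itself a (linear, intended) signal transformation.
* **Exchangeability caveat**: sign flips are drawn per unit index, so
  permuting unit order leaves the t statistics exactly invariant but the
  Monte-Carlo p only up to permutation noise.

## 6. Known limitations

The generator's phase-reset mechanism makes entrainment detectable *by
construction*; it cannot adjudicate between entrainment and superposition
of evoked responses — the central interpretive debate in this literature.
The shipped montage is an idealized sphere, not digitized positions. The
ocular and peak-acceptance criteria replace human judgment and were tuned
for the synthetic world's signal-to-noise regime. EF dose helpers perform
no field computation; they consume externally computed per-element field
tables and a linear EF-per-%MSO slope.
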