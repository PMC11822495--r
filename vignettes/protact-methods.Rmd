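---
title: "Methods: chaotic drives, the composite-response surrogate, and the analysis suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chaotic drives, the composite-response surrogate, and the analysis suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protact)
```

# The system and what this package models

Proteinoid microspheres (thermal proteins of l-Glu:l-Phe:l-Asp) bridged by
actin filaments form a bio-hybrid composite that exhibits spontaneous
electrical oscillations and transforms applied voltage stimuli in
characteristic ways: it suppresses input amplitude 5-30 fold, bounds the
output to a narrow voltage range, approximately preserves the dominant
spectral mode, and adds small-amplitude noise. Experiments on such
composites drive them with *quasi-chaotic* voltage waveforms - trajectories
of well-understood chaotic systems - and compare input and output
statistics to quantify what kind of signal processor the material is.

`protact` re-implements that computational workflow end to end, replacing
the laboratory recordings with a synthetic-data stage:

1. **chaotic drives** (`generate_logistic()`, `generate_baker()`,
   `generate_lorenz()`, `generate_rossler()`, `generate_fhn()`,
   `generate_pulse_train()`),
2. a **response surrogate** for the composite (`apply_surrogate()`,
   `apply_sigmoid_coupling()`, `recover_surrogate_params()`),
3. the **analysis suite** (`trace_stats()`, `peaks_per_second()`,
   `trace_spectrum()`, `cross_correlate()`, `pca_input_output()`,
   `smooth_savgol()`, `lyapunov_wolf()`),
4. **Oscillatory Threshold Logic** (`threshold_bits()`, `gate_or()`,
   `gate_and()`, `half_adder()`, `otl_pipeline()`), and
5. **SEM fiber morphometry** (`binarize()`, `label_components()`,
   `canny_compare()`, `morphometry_summary()`, `generate_phantom()`).

Everything flows through one container, the `voltage_trace`: a tibble of
`time` (s) and `voltage` (V) with a uniform sampling interval.

# Drive generators

## Logistic map

The map $x_{n+1} = \mu x_n (1 - x_n)$ is iterated 10,000 times (default)
and linearly rescaled to $-0.5\ldots+0.5$ V. The default growth rate
$\mu = 3.8$ sits in the fully developed chaotic band; $\mu = 4$ is the
analytically tractable case whose Lyapunov exponent is $\ln 2$ per
iteration, which the test suite uses as an oracle. Initial values are
drawn uniformly on $(0.01, 0.99)$ under a mandatory seed, avoiding the
absorbing endpoints. Iterates with $\mu > 4$ can escape $[0,1]$, so those
parameters are rejected.

The fixed point $x^* = 1 - 1/\mu$ exists but is unstable for $\mu > 3$
($|f'| = \mu - 2$), so a trace started exactly there stays constant only
until floating-point rounding is amplified out of it - about 20
iterations at $\mu = 3.8$.

Map-based drives have no intrinsic time base. One iterate is one sample
and the playback interval defaults to `dt = 0.01` s, a choice made once
so that spectral quantities (Hz) are well defined; it is configurable.

## Baker transformation

The standard area-preserving stretch-and-fold map on the unit square,
with fold parameter $\alpha$ (default 0.5):
$$ (x, y) \mapsto \begin{cases}
  (x/\alpha,\ \alpha y) & x < \alpha \\
  ((x-\alpha)/(1-\alpha),\ \alpha + (1-\alpha) y) & x \ge \alpha.
\end{cases} $$

A numerical property worth knowing: at $\alpha = 0.5$ the $x$-dynamics is
the binary shift, which is *exact* in IEEE floating point - each iterate
consumes one mantissa bit, so every orbit collapses to $x = 0$ within
about 53 iterations and the emitted voltage settles at `v_lo`. A long
$x$-component trace therefore has mean and median essentially at `v_lo`
with small dispersion. We keep the map exact rather than noise-kicking
it, for two reasons: the short-orbit oracle tests require bit-exact
iteration, and the collapsed statistics reproduce the shape actually
reported for baker-driven stimulation (mean and median pinned at the
lower encoding limit), suggesting the original drive was generated the
same way. Users who want sustained mixing can use the $y$-component or
$\alpha \ne 0.5$.

## Lorenz, Rossler: fixed-step RK4

$$\dot x = \sigma(y - x),\quad \dot y = x(\rho - z) - y,\quad
  \dot z = xy - \beta z$$
with $\sigma = 10$, $\rho = 28$, $\beta = 8/3$, $y_0 = (0, 1, 1.05)$,
and
$$\dot x = -y - z,\quad \dot y = x + ay,\quad \dot z = b + z(x - c)$$
with $a = b = 0.2$, $c = 5.7$, are integrated with the classic
*fixed-step* fourth-order Runge-Kutta scheme (step 0.01 s over 100 s by
default, giving 10,001 samples). No adaptive step-size control is used,
deliberately: the study conditions are a fixed-step solver, and a fixed
step keeps the sample grid uniform for the spectral analyses. The
integrator is delegated to `deSolve` (`method = "rk4"`); tests verify it
reproduces $e^{-t}$ to $10^{-8}$ relative error and tracks a tight-
tolerance adaptive reference to better than $10^{-2}$ state-units over
10 s of chaotic Lorenz/Rossler dynamics (trajectory-level agreement
beyond that horizon is not expected for chaotic systems - that is what
chaos means).

The emitted component (default $x$) is scaled by `scale` volts per
state-unit, default 1. Reported input statistics for the composite
experiments (e.g. a Lorenz input maximum above 10 V) imply some unstated
laboratory scale factor; reproducing a specific input table requires
fitting `scale` to it, which we do not attempt.

## FitzHugh-Nagumo

The two-variable excitability model is implemented as
$$\dot v = \frac{v (v - a)(1 - v)}{\gamma} - w + c, \qquad
  \dot w = \epsilon (v + a - \gamma w),$$
with $a = \epsilon = \gamma = 0.1$ and drive $c$. The *form* of the
equations was a genuinely open design choice: with these parameter
values the common textbook parameterisations (cubic $v - v^3/3$ with any
natural linear recovery) place the rest state on the unstable middle
branch for every moderate drive, so they oscillate at both $c = 1$ and
$c = 2$ and cannot express the documented transition from quiescence to
spiking above a critical input current. We therefore use the
excitability-threshold cubic $v(v-a)(1-v)$ with gain $1/\gamma$, under
which the stated parameters verifiably produce the intended dichotomy
from a resting start $(0,0)$: at $c = 1$ the trajectory settles to a
fixed point; at $c = 2$ it sustains a relaxation limit cycle (period
74.5 s, step-size robust to $10^{-5}$ relative between `dt` 0.01 and
0.001). `a` is the excitation threshold, $\epsilon$ the recovery time
scale, $\gamma$ the recovery leak.

## Binary pulse trains

Seeded uniform bits at 1 ms resolution, encoded as 100 ms holds at
+500 mV (bit 1) or -500 mV (bit 0). Identical seeds give byte-identical
traces; the bit stream and its voltage encoding are returned together.

# The response surrogate

The composite's input-to-output transformation is emulated
*phenomenologically*:
$$y(t) = \mathrm{clamp}\big(g \cdot \mathrm{LP}(x)(t) + b,\ v_{min},\
  v_{max}\big) + \varepsilon(t),$$
a zero-phase moving-average low-pass (cutoff in Hz, reflect-padded so
the kernel stays symmetric and the map commutes with time reversal),
attenuation $g$, offset $b$, hard clamp, and seeded Gaussian noise. An
optional dominant-mode frequency shift (time-axis resampling) is off by
default: the observed output-frequency changes (a ~0.05 Hz reduction
under map drives, a ~2.16x multiplication under the Rossler drive) are
observations without an established mechanism, so the surrogate does not
assert one. There is deliberately *no* electrochemical or mechanochemical
model here - the surrogate encodes measured transfer signatures only, so
that every downstream analysis is testable against known ground truth.
Passing tests on surrogate data therefore validate the analysis code,
not any claim about the material's physics.

Per-system presets (`surrogate_preset()`) ship as JSON. Their
gain/offset/clamp values were fixed once from the reported output-row
statistics divided by the default drives' input scales; they approximate
the reported output rows to within a factor of two and are documented as
presets, never as ground truth.

`recover_surrogate_params()` is a one-shot closed-form estimator: clamp
bounds from the output extrema (exact whenever the clamp is active),
gain as the covariance slope $\widehat g = \mathrm{cov}(y,x)/
\mathrm{var}(x)$ over non-clamped samples, offset as the mean residual.
The covariance slope is preferred over the naive standard-deviation
ratio because the ratio is biased upward by additive noise (by a factor
$\sqrt{1 + (\sigma_\varepsilon/\sigma_{signal})^2}$, already ~8% at
$g = 0.04$, noise 5 mV), while the slope is unbiased under output noise
and identical to the ratio when noise is absent. No iterative fitting is
performed, and the low-pass stage is not deconvolved: with smoothing
active the recovered gain is the effective pass-band gain.

The sigmoid spiking coupling is the pointwise logistic transform
$V_{out} = (1 + e^{-m (V_{in} - c)})^{-1}$ with midpoint $c = 0.5$ V;
large $m$ approaches the all-or-none step.

# Analysis suite conventions

* **Peaks per second** (the tables' "frequency"): count of local maxima
  whose topographic prominence exceeds `prominence_factor` (default 0.5)
  times the standard deviation of the linearly detrended trace, divided
  by the record duration. The default makes the count robust to
  recording noise while reducing to cycle counting for clean periodic
  signals. Peaks whose prominence is truncated by the record boundary do
  not count; the definition is a rate over the observed window.
* **Spectra**: $20 \log_{10}(|\mathrm{FFT}(v)|/n)$, floored at -200 dB.
  The mean is retained so DC-dominated records report their dominant
  mode at 0 Hz; `mean_db`/`sd_db` summarise the positive-frequency bins.
  Absolute dB levels depend on this normalisation convention, so only
  *differences* (input vs output attenuation) are comparable across
  conventions.
* **Cross-correlation**: mean-removed, normalised by
  $n\,\sigma_a \sigma_b$ so the self-pair attains exactly 1 at lag 0.
  Positive lag means the second trace trails the first; ties on the
  maximum break toward the smallest $|$lag$|$.
* **PCA**: eigen-decomposition of the 2x2 covariance of the paired
  samples (correlation with `standardize = TRUE`). Covariance is the
  default because the input/output pair have wildly different scales
  and the dimensional-collapse readings are covariance statements;
  reported PC1 fractions in the high-90s arise naturally in this mode.
  A constant channel yields fractions (1, 0) with a `degenerate` flag.
* **Savitzky-Golay**: order 2, frame 15 defaults (the Lyapunov
  conditioning settings), delegated to `signal::sgolayfilt`; tests pin
  the impulse response to the normal-equations kernel.

## The Lyapunov estimator

The largest Lyapunov exponent is estimated from a scalar series in the
spirit of Wolf's algorithm: after optional Savitzky-Golay smoothing,
each point $i$ is paired with its nearest neighbour *in value* $j$
subject to (a) a temporal exclusion $|i - j| \ge$ `step_offset` (50
samples by default - a Theiler-style window that keeps trivially
correlated neighbours out) and (b) a noise floor
$|v_i - v_j| \ge$ `min_separation` (1 mV). The exponent is
$$\lambda = \left\langle \ln \frac{|v_{i+1} - v_{j+1}| + \epsilon}
  {|v_i - v_j| + \epsilon} \right\rangle, \qquad \epsilon = 10^{-5},$$
per sample step. Positive $\lambda$ means divergence (chaos), negative
means convergence.

Why nearest-neighbour pairing is the reference interpretation: if pairs
are instead taken at a *fixed* temporal offset, their separations are
order-one draws from the stationary separation distribution, and by
stationarity the expected one-step log-ratio is zero regardless of the
dynamics - the estimator degenerates. With nearest-neighbour pairing the
separations are small enough for the local linearisation to hold, and on
the $\mu = 4$ logistic map the estimator lands within a fraction of a
percent of the analytic $\ln 2$. The literal fixed-offset rule remains
available (`pairing = "offset"`) and the degeneracy is itself asserted
by a test. Two caveats: no delay embedding is performed (the estimator
is scalar and pairwise by design), so for smooth continuous-time signals
value-neighbours can lie on opposite-slope branches and the absolute
scale of $\lambda$ is convention-dependent; and reported magnitudes are
per sample step, not per second. Sign comparisons (input vs output,
chaotic vs contracting) are the robust use.

# Oscillatory Threshold Logic

`threshold_bits()` maps a trace to bits: HIGH where the voltage
*strictly* exceeds $\theta$ (a value exactly at $\theta$ is LOW - the
threshold must be surpassed) and the suprathreshold run lasts at least
$\tau_{min}$ (100 ms default), the minimum duration for a stable
conformational change; shorter excursions are transient fluctuations
and are filtered out. With $\tau_{min} = 0$ this is a plain comparison.
Increasing $\tau_{min}$ is monotone: it can only clear bits.

Two thresholds ship (`otl_theta_presets()`): the stated operating value
$\theta = 0.5$ V (the default) and the statistically derived
$0.0212 + 2 \times 0.0176 = 0.0564$ V. The two derivations are mutually
inconsistent as reported; we default to the explicitly
stated value and expose both.

The half adder follows the printed gate semantics - sum as OR, carry as
AND - which is nonstandard (a true half adder sums with XOR, and the
(1,1) input distinguishes them). We implement the printed semantics as
the default and provide `sum_gate = "xor"`.

`otl_pipeline()` composes the four recorded channels. The output gates
are defined as the AND of the duration-constrained thresholded bit with
a companion bit; since ANDing a bit with an analog voltage is undefined,
the companion is interpreted as the plain ($\tau_{min} = 0$) comparison
bit of the same channel. The overall OTL gate is the OR of the two
output gates, so a suprathreshold event in either output channel
registers a positive OTL result; the matrix is constructed so that its
OTL column always equals the OR of its own output columns, and a test
asserts exactly that identity. Note that the printed truth-table
analysis lists OTL = 0 at steps where an output gate is 1, which
contradicts the OR composition; `truth_table_report()` reproduces the
layout from the computed matrix rather than matching that column.

# Morphometry

The micrograph pipeline is binarize (Otsu by default, the level recorded
for provenance) -> connected components (8-connectivity by default,
4 available) -> per-component measures -> summary. Areas are pixel
counts times `pixel_size`$^2$; the "length" of a component is its
major-axis extent - the range of its pixel coordinates projected on the
principal axis, plus one pixel of width, times `pixel_size` - so a
single pixel has length one pixel and all reported quantities scale
exactly (lengths by $k$, areas by $k^2$) under a pixel-size change.
Reported fiber statistics for such composites mix nm (length) units
with "cross-sectional area" language; we report both quantities
explicitly and treat the printed 14,732.6 nm figure as a length
statistic. The standard-deviation convention is population ($/n$) by
default, sample ($/(n-1)$) by flag.

The Canny comparison smooths with a Gaussian, takes Sobel gradients,
applies non-maximum suppression along the quantised gradient direction
and two-level hysteresis (quantile thresholds), then reports the
fraction of mask-boundary pixels with an edge pixel within 1 px
(Chebyshev). A blank edge map reports overlap 0 with an `undefined`
flag.

`generate_phantom()` renders thick random-walk fiber strokes and filled
discs (emulating ~20 um microspheres and ~10 um protrusions at the
default 20 nm/px calibration) on a darker background with optional
Gaussian noise, and returns the exact ground-truth segmentation. Objects
are placed with a 2 px clearance so zero-noise phantoms segment exactly;
an overcrowded request raises a placement error rather than silently
merging objects. What the phantom does *not* emulate: SEM texture and
charging artifacts, uneven illumination, out-of-focus blur, and
touching/overlapping fibers - so passing the exactness tests validates
the measurement code, not robustness to those real-data complications.

# Orchestration and reproducibility

`experiment_config()` requires an explicit integer seed (wall-clock
seeding is not available anywhere in the package) and
`run_experiment()` chains generate -> surrogate -> analyse -> (optional)
OTL deterministically: identical configurations produce identical
reports, asserted via a content hash in the provenance block, which also
records every stated parameter ($\mu$; $\sigma, \rho, \beta$; $a, b, c$;
$\theta$, $\tau_{min}$; the Lyapunov settings) so a run is auditable.
Traces round-trip through a two-column CSV dialect
(`time_s,voltage_V`, `#`-prefixed JSON metadata header, Unicode minus
normalised on read, headerless TSV autodetected); gate matrices and
reports serialise to CSV/JSON.

# Problem sizes and test design

The suite validates each operation against independent oracles: frozen
hand iterations for the maps, tight-tolerance adaptive integration for
the RK4 trajectories, the analytic $\ln 2$ for the Lyapunov estimator,
normal-equations kernels for the smoother, constructed shift/phantom
fixtures elsewhere. Simulation sizes were chosen as the smallest that
make each statistical check sharp: 5,000-sample series over 20 seeds for
the Lyapunov battery, 10,000 samples x 100 noise replicates for
surrogate recovery, 10,000-step fixtures for the OTL identities, a
512x512, 50-fiber phantom for the morphometry exactness check, and
10-second windows for integrator cross-validation.

# Known limitations

* The Lyapunov estimator is scalar and pairwise; no embedding, no
  spectrum of exponents, and absolute magnitudes for continuous-time
  signals are convention-dependent (signs and relative comparisons are
  the supported use).
* The surrogate is a transfer-signature model; it cannot answer
  mechanistic questions, and its frequency-shift mode is a crude
  resampling, not a model of the composite's frequency multiplication.
* Reproducing the laboratory input tables exactly requires the deposited
  recordings and their (unstated) amplitude and sampling conventions;
  the package reads such deposits through `read_trace()` but does not
  download them.
* The baker $x$-drive at $\alpha = 0.5$ is degenerate in floating point
  by construction (see above); use the $y$-component for a sustained
  mixing drive.
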