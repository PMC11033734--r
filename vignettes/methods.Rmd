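---
title: "Measurement design and two-step reconstruction: models, numerics, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measurement design and two-step reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cspat)
```

This vignette is the package's own account of its science: the measurement
model and its assumptions, the quantities it optimizes, the numerical
schemes behind the forward and inverse operators, and the design choices
made where more than one reasonable option existed. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement family

The instrument has 64 line detectors on a circle, wired in 16 blocks of 4
sensors sharing one multiplexing switch; four neighboring blocks are summed
into one recording channel, so measurements act independently on four
groups of 16 sensors. A feasible binary measurement row activates **at most
one sensor per block** ("at most" — a block may also be switched off
entirely). `cs_structure()` captures the three integers behind this family
(block size, blocks per group, number of groups) plus `m0`, the rows per
group; the matrix on the full ring is block diagonal
(`assemble_block_diagonal()`).

**Sampling distribution.** The family itself does not prescribe a sampling
law. `sample_feasible_matrix()` draws each (row, block) cell independently
and uniformly over the `block_size + 1` states {off, sensor 1, ...,
sensor `block_size`}: the maximum-entropy choice under which every feasible
matrix — including rows with inactive blocks — has positive probability.
Duplicate rows are permitted; they waste a measurement and depress the
design score, which the search then avoids on its own.

## The s-sparse injectivity number and its two scales

For `M` with `n0` columns and sparsity level `s`,
`sparse_injectivity(M, s)` returns

$$\Theta_s(M) = \inf\Big\{ \tfrac{\|M x_1 - M x_2\|_2}{\|x_1 - x_2\|_2} :
x_1 \neq x_2 \ s\text{-sparse} \Big\},$$

computed exactly as the minimum over all $\binom{n_0}{2s}$ column subsets
of the smallest singular value of the submatrix (a difference of two
s-sparse vectors is 2s-sparse). Positivity of $\Theta_s$ is equivalent to
unique identifiability of every s-sparse signal from exact data, which
`decode_sparse()` (exhaustive-support least squares) turns into an
operational certificate.

Two scale conventions coexist for this quantity: the singular-value scale
$\Theta_s$ (the package API) and the squared scale $\Theta_s^2$, the
smallest eigenvalue of the submatrix Gram matrices, on which design-quality
figures such as the 0.1 usability bound are quoted in this package's
acceptance outputs. `glance()` on a search result reports both
(`best_sin`, `best_sin_sq`), plus `best_sin / ‖M‖₂` as a scale-free
diagnostic. The two scales order designs identically; only reported
magnitudes differ.

**Numerical rank floor.** The subset enumeration runs in compiled code
(RcppArmadillo) on the 2s×2s Gram matrices. Eigenvalues below
$10^{-12}\times\mathrm{tr}(G_S)$ are treated as exact zeros: for binary
matrices, any genuinely nonzero Gram eigenvalue is bounded well away from
zero (an integer matrix with unit determinant bound), while symmetric
eigensolver round-off otherwise surfaces as $\sqrt{10^{-15}}\approx
3\times10^{-8}$ — right at the non-singularity threshold a user would set.
With the floor in place, the package's default non-singularity threshold is
$10^{-6}$ on the singular-value scale (configurable in
`compression_sweep()`), and search results are reproducible down to exact
zeros.

## Random-search design

`search_design()` implements the simple strategy that works for this small,
non-asymptotic regime: draw feasible matrices, keep the strictly best
(ties keep the earlier matrix, so the incumbent is the *first* optimum
found). Two exact shortcuts keep long searches cheap: a candidate with an
all-zero column, or with fewer than 2s nonzero columns, has
$\Theta_s = 0$ by definition and is rejected without enumeration; and the
enumeration of a surviving candidate aborts once its running minimum can no
longer beat the incumbent. Both are exact, so the result is identical to
scoring every draw fully (a property the test suite checks against an
unpruned reference search).

**The compression frontier.** At block size 4 and group size 16 with
`s = 2`, 100-iteration searches reliably find designs at `m0 = 12`
(compression 4/3); `m0 = 11` designs exist but need longer searches. At
`m0 = 10` nonsingular designs are *rare but present* in the uniform family:
an extended chunked search (up to $10^5$ draws, `scripts/acceptance.R`)
does locate matrices with all 1820 four-column submatrices of full rank —
verifiable by exact rank computation — so the frontier under exhaustive
random search extends to 10 measurements per group, even though searches of
modest effort will not find them. The block-size-2 variant (eight blocks
per group, same group size) reaches `m0 = 10` easily (compression 8/5), at
the hardware cost of twice the phase switches.

## Wave model

The source `u` (supported strictly inside the detection circle of radius
`R`; sound speed rescaled to 1) generates a 2D pressure field whose value
at a detector is the time derivative of an Abel-type transform of the
circular means:

$$p(s,t) = \partial_t \int_0^t \frac{r\, m(s,r)}{\sqrt{t^2-r^2}}\,dr,
\qquad m(s,r) = \text{mean of } u \text{ over the circle of radius } r
\text{ at } s.$$

The wave equation is never time-stepped; this solution representation is
exact, and circular means of disk phantoms are available in closed form
(uniform profile: arc fractions) or by dedicated quadrature (tapered and
flat-means profiles), which makes every downstream operator testable
against analytic pairs.

**Grids.** Time and radius grids are identified: `q` uniform samples on
`[0, 2R]` (`time_grid()`), the default experiment scale being `R = 1`,
`n = 64` detectors, `q = 1024`, and a 128² image raster — deliberately
*below* the full-sampling detector count `round(π·128/2) = 201`
(`nyquist_sensor_count()`), since operating in the spatially undersampled
regime is the reason for compressed acquisition. Test and example runs use
reduced sizes (`q` = 256–512, raster 32–64) chosen so the full suite runs
in minutes; the convergence-sensitive checks (Abel round trip, image
self-consistency, adjoint identity) run at `q = 1024`.

**Abel transform numerics.** `abel_matrix()` discretizes the weakly
singular integral by *product integration*: the means are interpolated
linearly between grid nodes and the kernel $r/\sqrt{t^2-r^2}$ is
integrated against each linear piece in closed form. This handles the
singular end panel exactly and — unlike quadrature-plus-interpolation
schemes, which make the triangular system's diagonal artificially small —
keeps the forward-substitution inverse (`abel_inverse()`) stable. The
`r = 0` node carries no information (the kernel weight vanishes); the
inverse closes the system with the constant extrapolation `m(0) = m(dt)`,
exact for locally constant means and irrelevant in practice because
detectors sit outside the support, so physical means vanish at radius 0.
Round-trip accuracy is tested on smooth origin-vanishing signals at
`q ∈ {256, 512, 1024}` with a monotone-decrease assertion.

**Image reconstruction.** `fbp_from_means()` uses the exact inversion of
the circular-mean transform in two dimensions,

$$u(x) = \frac{1}{2\pi R} \oint_{\partial B_R} \int_0^{2R}
\big(\partial_r\, r\, \partial_r m\big)(s, r)\,
\log\big|r^2 - d^2\big|\, dr\, dC(s), \quad d = |x - s|,$$

with the log kernel product-integrated exactly against piecewise-linear
integrands (split $\log|r-d| + \log(r+d)$, closed-form antiderivatives).
`fbp()` composes this with the temporal filter `apply_phi()` (trapezoidal
time integration enforcing `g(0) = 0`, then Abel inversion); the filter
acts per channel in time only, so it commutes *exactly* with any
sensor-mixing matrix — the property that lets the two-step method filter
compressed channels before recovery. `fbp_from_means()` inverts the means
directly rather than via the pressure, avoiding one derivative/integration
round trip; the pressure path agrees within that round trip's
discretization error (a tolerance-based test, not a bit-identity).

**Adjoint versus inverse.** The exact inverse above is *not* proportional
to the $L^2$ adjoint of the forward map (numerically, $\langle Wu_1, Wu_2
\rangle / \langle u_1, u_2\rangle$ varies by tens of percent across phantom
pairs, so $W^*W \neq c\,I$). The package therefore provides both:
`fbp()` inverts, `forward_adjoint()` implements the true discrete adjoint.
Because 2D waves have no Huygens principle — the pressure has a persistent
tail — a record truncated at `t = 2R` ends on nonzero values, and the
adjoint of the *truncated* forward operator acquires a time-boundary term
$p(s, 2R)/\sqrt{4R^2 - d^2}$ alongside the interior term
$-\int_d^{2R} (\partial_t p)/\sqrt{t^2-d^2}\,dt$. Without the boundary
term the inner-product identity plateaus at a few percent error
independently of `q`; with it, the identity holds to the accuracy the test
suite asserts.

## Two-step recovery

**TV problem.** Each radius sample of the filtered data is recovered by

$$\min_h \tfrac12 \|A h - y\|_2^2 + \mu \|D h\|_1,$$

with `D` the cyclic first difference around the full 64-sensor ring (the
physical ring is closed; a per-group cyclic variant is available through
`ring_difference(n, groups)` for ablation). The squared-fidelity form is
used because it admits a robust splitting solver; an unsquared fidelity
would need a weight convention of its own and offers no advantage at these
scales. The solver is ADMM with the ℓ1 term split out: the `h`-update is a
single Cholesky-factorized solve shared by all `q` radius samples (solved
as one multi-column system), the `z`-update a soft threshold. The returned
iterate is the best-objective iterate visited, so the reported objective
trace is nonincreasing by construction (the same device monotone-FISTA
variants use); termination is on relative iterate change below `tol`
(default $10^{-8}$) or `max_iter` (default 2000). An independent
projected-subgradient oracle cross-checks the attained objective in the
tests.

**Choosing `μ`.** The model offers no canonical weight.
`select_reg_weight()` picks it on a *held-out* synthetic instance of the
strictly gradient-sparse class: measure, optionally add noise at the target
level, scan a logarithmic grid, keep the weight with the smallest
recovery-domain error. Because the objective's optimal weight scales
linearly with signal amplitude, the held-out instance is rescaled to the
root-mean-square of the data actually being solved (`match_data`); without
this the selection transfers poorly between unit-scale synthetic signals
and phantom means of amplitude a few hundredths.

**What positive SIN does and does not certify.** $\Theta_2 > 0$ certifies
exact decodability of entry-2-sparse signals by exhaustive support
enumeration. It does *not* certify that TV minimization recovers every
gradient-2-sparse signal: a minority of random gradient-sparse instances
(roughly one in seven under the default generator) are not exact TV
minimizers and recover with errors around $10^{-1}$ instead of $10^{-4}$.
Pipeline-level claims are therefore asserted on the median over a fixed
batch of instances, not on a single draw.

## Synthetic data

`make_group_sparse_signals()` draws the strict signal classes: per group
and sample either exactly `s` nonzero entries, or exactly `s` nonzero
cyclic differences (jump values sum to zero around the group; `s = 1` is
impossible cyclically). Amplitudes are uniform on [0.5, 1.5] with random
sign — bounded away from zero so near-cancellation does not blur the
exact-recovery criterion, signed so sign recovery is exercised.

`make_disk_phantom()` provides two object classes. `"piecewise"` draws 3–6
disks of mixed radii, amplitudes and profiles inside `0.8R` — a
piecewise-smooth object whose detector data are only approximately
gradient-sparse. `"sparse"` draws 1–2 small disks with the `"flat_means"`
profile $A\,(1-\rho^2/a^2)^{-1/2}$, whose integral along any straight chord
is the constant $\pi a A$: for disks small against the ring, every circle
crossing the disk picks up nearly the same integral, so the detector-domain
means form an indicator-like plateau across sensors — two jumps per
crossing, the structure TV recovery handles exactly. A plain uniform disk,
by contrast, produces a smooth bump across a contiguous arc of sensors
(never 2-sparse in gradient at 64 sensors), which is why the profile
matters. Because even flat-means plateaus have ramp sensors at the arc
edges, strict jump-counting is unattainable for any physical disk; the
generator contract is instead `audit_gradient_concentration()`: per group,
the top-2 jumps must carry ≥ 65% of the cyclic-gradient ℓ1 mass (small
flat-means disks measure ≈ 0.7–0.97 on this statistic, piecewise phantoms
≈ 0.5), and the generator redraws until the audit passes. The audits are
exported so tests bind to the same definitions.

`add_noise()` rescales a Gaussian draw so the realized relative ℓ2 error
equals the target exactly — experiments then report the realized level by
construction, and noise comparisons are never confounded by sampling
variance in the noise norm.

**The experiment driver** (`run_experiment()`) mirrors the full study
grid — {optimized, first-nonsingular-random} × {sparse, piecewise} ×
{exact, 9% noise} — and reports, per run, the realized data error, the
recovery-domain error against the true means, and the image error against
the *full-data FBP reconstruction* (not the phantom raster): the goal of
compressed acquisition is to match what the uncompressed array would have
produced. The random baseline is the first uniform draw whose injectivity
number clears the threshold (`sample_nonsingular_matrix()`); under uniform
sampling such draws are themselves fairly strong designs, so optimized and
baseline errors can tie on easy instances — the decisive comparison is
against unoptimized feasible draws, which typically have zero injectivity
number and fail outright.

## Known limitations

- The forward model is 2D, constant-sound-speed, full-ring, with ideal
  point-like (in angle) detectors: no impulse response, bandwidth,
  or finite-aperture effects, and no 3D reconstruction by rotation.
- The TV recovery guarantee is empirical, not certified by the injectivity
  number (see above); image-domain errors inherit both TV bias and the
  temporal filter's discretization error.
- Passing tests on the synthetic generators show the pipeline recovers the
  *assumed* signal classes; real detector data deviate from them (detector
  noise correlations, model mismatch), and only the 9%-noise runs probe
  robustness.
- The sampling distribution over the feasible family is a modeling choice;
  frontier statements ("rare but present at `m0 = 10`") are relative to it.
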