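---
title: "Methods: dynamics analysis of a memristive Hindmarsh-Rose neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamics analysis of a memristive Hindmarsh-Rose neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memhr)
```

## The model

`memhr` simulates and analyzes a three-variable Hindmarsh-Rose (HR)
neuron in which the usual slow adaptation current is replaced by
electromagnetic-induction feedback through a flux-controlled memristor,
with up to two sinusoidal current injections:

$$
\begin{aligned}
\dot x &= y + a x^2 - b x^3 + k\,W(\varphi)\,x
          + A_1 \sin(2\pi f_1 t) + A_2 \sin(2\pi f_2 t),\\
\dot y &= c - d x^2 - y,\\
\dot\varphi &= x - \varphi,
\end{aligned}
\qquad W(\varphi) = \alpha + \beta\varphi^2 .
$$

Here $x$ is the membrane potential, $y$ the recovery variable, and
$\varphi$ the magnetic flux across the membrane; $W$ is the memductance
and $k$ scales the induced current $k W(\varphi) x$.  All quantities are
dimensionless.  The canonical constants are $a=3$, $b=1$, $c=1$, $d=5$,
$\alpha=0$, $\beta=0.01$; they are symbolic throughout the package so
the classical two-variable HR equations are recovered as the $k=0$,
$A_1=A_2=0$ special case.  Time is an explicit argument of the
non-autonomous vector field; no auxiliary time state is introduced.

Depending on $k$, the initial condition, and the drive, the model
produces quiescence, tonic (spiking) firing, burst firing, chaos, and —
the property the toolkit is organized around — *coexisting* firing
patterns: different attractors reached from different initial
conditions at identical parameters.

## Equilibria of the forced system

Because the system is periodically forced it has no fixed points in the
strict sense.  Equilibria are defined by freezing the total injected
current at its instantaneous value $I$; this is the convention used
throughout (`solve_equilibria(k, I_total)`), and every "stability"
statement refers to the frozen-drive system at one instant.  The
reduction gives $y = c - d\eta^2$, $\varphi = \eta$, and the cubic

$$
P(\eta) = (k\beta - b)\,\eta^3 + (a-d)\,\eta^2 + k\alpha\,\eta + c + I
        = 0 ,
$$

which is $(0.01k-1)\eta^3 - 2\eta^2 + 1 + I$ at the canonical
constants.  Roots are computed by Cardano's method.  Numerical choices:

* the three-real-root branch ($\Delta < 0$) uses the trigonometric
  form, which avoids the branch-cut ambiguity of complex cube roots;
* every closed-form root is polished by three Newton steps, so accuracy
  does not rest on the closed form (the test suite checks all roots
  against a grid-plus-`uniroot` bisection oracle at $10^{-8}$);
* the double-root boundary is declared at
  $|\Delta| \le 10^{-12}\max(1, q^2)$ so the two-root case is reachable
  in floating point;
* the degenerate leading coefficient ($k\beta = b$, i.e. $k = 100$ at
  defaults) falls back to the explicit quadratic.

The equilibrium Jacobian always carries the eigenvalue $-1$ (rows 2 and
3 of $J + \mathbb{1}$ are multiples of $e_1$), equivalently the
characteristic coefficients obey $m_2 = m_1 + m_3 - 1$; both facts are
exercised as properties.  An equilibrium is labeled *stable* only when
every eigenvalue real part is below $-10^{-9}$; mixed-sign (saddle) and
marginal spectra are labeled *unstable*, and the eigenvalues themselves
are returned so a finer taxonomy can be derived by the caller.
`equilibrium_track()` repeats the analysis along a time grid; with
$A_1=A_2=1$, $f_1=f_2=0.05$ the tracked stability flips near
$t \approx 11.7$ and $18.3$ in the window $(5, 25)$, with a
three-root window around each flip.

## Integration

Trajectories come from deSolve's `ode45` (Dormand-Prince 4(5),
adaptive, dense output); the right-hand side, the 12-dimensional
variational system, and a paired two-trajectory system are compiled C.
Defaults: `rtol = 1e-8`, `atol = 1e-10`, output step `sample_dt =
0.01`, and an internal step cap `min(1/(20 f1), 1/(20 f2), 0.1)`
(active drives only) so the forcing is always resolved.  These defaults
hold periodic-orbit peak amplitudes to four decimals; halving the
tolerances moves the $A_1=5.5$ periodic orbit by less than $10^{-3}$ at
$t=100$.  Integration is fully deterministic — re-running reproduces
trajectories bit for bit.  Statistics are computed after discarding a
transient ($t < 500$ by default); convergence-time analyses keep the
trajectory from $t = 0$.  Typical horizons are $t_{\mathrm{end}} = 2000$
for statistics and 500 for phase portraits.

## Lyapunov spectra

`lyapunov_spectrum()` integrates the variational (tangent) system along
the trajectory and reorthonormalizes the frame by QR every
`renorm_dt = 1` time unit, accumulating the log diagonal growth rates.
Only the three state directions contribute; explicit time adds no
exponent, and the forced system has no structurally zero exponent.
Defaults `t_transient = 1000`, `t_horizon = 10000` stabilize the second
decimal.  The result stores a running-estimate trace; if the final 10%
of the trace moves by more than 0.05 the result is flagged unconverged.
Cross-checks built into the package and suite:

* the engine (`lyapunov_qr()`) accepts arbitrary steppers and is tested
  on a linear flow with known rates $(-1,-2,-3)$ to $10^{-3}$;
* the model's own exactly solvable linear limit ($a=b=d=k=0$) has
  spectrum $(0,-1,-1)$ — note the $-1$ pair is a Jordan block, so
  finite-horizon estimates carry a $\log t / t$ correction;
* a two-trajectory Benettin estimate of the leading exponent
  (`max_lyapunov(..., method = "benettin")`) agrees with the tangent
  route to 0.02 on the standard scenarios;
* `le_sum_check()` compares the exponent sum with the time-averaged
  divergence $2ax - 3bx^2 + kW(\varphi) - 2$.  The gate of 0.1 holds
  when the horizon covers many drive cycles; the $f_2 = 0.002$ drive
  fits only four slow cycles into 2000 time units, and its window
  averages genuinely fluctuate at the 0.1-0.2 level.

Downstream classification calls a trajectory chaotic when
$\mathrm{LE}_1 > 0.005$, regular when $\mathrm{LE}_1 < -0.005$, and
indeterminate in between.

## Spike detection, bursts, and the firing taxonomy

No quantitative spike or burst definition is inherent to the model, so
all thresholds are configuration with the following defaults, chosen
from the attractor geometry:

* **Spikes** are local maxima of $x$ with topographic prominence at
  least 0.5 and height at least *half the trace maximum*.  Full action
  potentials reach $x \approx 2$-$3$ while the ripples imprinted by the
  fast drive stay near $0.3$-$1.1$, so half-maximum separates the two
  robustly; on subthreshold traces (maximum below zero) it excludes
  everything, which is the intended quiescent reading.  A fixed
  absolute threshold near zero instead counts every drive ripple as a
  spike and, e.g., inflates three-spike bursts to five.  Minimum spike
  separation is 0.5 time units.
* **Bursts.**  Two signatures are recognized.  (1) A bimodal ISI
  distribution: a multiplicative gap $\ge 3$ between short and long ISI
  modes; an ISI above $3\times$ the short-mode median opens a new
  burst.  (2) A drive-locked ISI *ladder*: under a fast drive, spikes
  lock to drive cycles and ISIs are integer multiples of the drive
  period, which defeats any multiplicative gap test.  When the base ISI
  is at burst scale ($\le 3$ time units, i.e. consecutive-cycle firing,
  comparable to the spike width) and the ISI range spans at least three
  base intervals, the same $3\times$ rule applies to the base.  Either
  way a train is only *called* bursting if at least half of its spikes
  sit in multi-spike runs; sparse single spikes separated by irregular
  gaps are tonic.
* **Labels.**  `classify_firing()` combines this structure with
  $\mathrm{LE}_1$: quiescent (spike rate below $10^{-3}$; a
  `subthreshold` flag separates a genuine fixed point from a small
  forced oscillation, using a tail-variance cut of $10^{-4}$), then
  {periodic, chaotic} x {spiking, bursting}.  Periodic spiking carries
  a period count from peak-amplitude clustering (gap tolerance
  $10^{-2}$); bursting labels carry the modal spikes-per-burst over
  multi-spike bursts and the within-burst ISI coefficient of variation
  as an irregularity descriptor.  The "periodic bursting with
  chaotic intra-burst spiking" regime at $f_2 = 0.002$ is labeled
  periodic bursting (its leading exponent is negative) with that
  descriptor, not with a chaotic label.

Under the high-low-frequency drive ($k=1$, $A_1=A_2=3$, $f_1=0.5$,
initial condition $(-5,0,0)$) this machinery yields: periodic bursting
with many irregular spikes per burst at $f_2=0.002$; periodic bursting
with three spikes per burst at $f_2=0.02$; period-2 spiking at
$f_2=0.04$; chaotic spiking (positive leading exponent) at $f_2=0.07$ —
with full spectra computed alongside.

## Sweeps and coexistence

`bifurcation_sweep()` sweeps $A_1$, $f_1$, $f_2$, or $k$; the ordinate
is the multiset of post-transient $x$ peaks (peak sampling; a
stroboscopic option samples once per drive period as a cross-check).
Every grid point restarts from the declared initial condition, so
branches keep their initial-condition identity, and per-point
integration failures are recorded without aborting the sweep.

Whether two initial conditions reach different attractors is decided by
comparing *fingerprints* (`attractor_fingerprint()`): leading exponent,
mean and standard deviation of $x$, a normalized ISI histogram on fixed
0.5-wide bins, the spike rate, and the peak-cluster count.  The
distance is a weighted sum of component differences; the spike-rate
term is essential because the spike-conditional ISI histogram alone
cannot tell a quiescent window from a firing one.  Windows of one
ergodic run score around 0.1-0.2, distinct attractors score above 1, so
`detect_coexistence()` uses 0.35 as its default tolerance on the final
half of two runs.

`convergence_time()` handles the regimes where multistability is
eliminated: it slides a 50-time-unit window (stride 5) over the run
that starts on the transient orbit and reports the earliest window
start whose fingerprint matches the reference run's asymptotic
fingerprint and stays matched.  Matching uses hysteresis: the entry
tolerance is the 95th percentile of the reference run's own windowed
self-distances (a window must look statistically like an attractor
window), and persistence only requires staying below twice that, so
chaotic window-to-window variability does not postpone detection.
Windows that straddle the transition bias the estimate earlier by a
fraction of the window width; the window is kept at 50 time units
because much shorter windows make the ISI histogram too noisy to
calibrate.

`elimination_threshold()` sweeps $k$ (default $-8$ to $-6$, step 0.1),
runs the coexistence test at each point, and returns the largest grid
$k$ at which the two runs have merged, refined by half a grid step.  A
coarse grid plus one bisection level is deliberate: chaotic transients
make the boundary fuzzy, and the answer also depends on the run length
(longer horizons allow more orbits to merge), so the protocol — horizon
3000, fingerprints on the final half — is part of the definition.

## Analog-circuit mapping

`map_to_circuit()` translates the dimensionless constants into
component values for an op-amp integrator realization with multipliers
of gain 0.1 (the origin of the factors of 10 in the identities).  With
the anchor choices $R_7 = 300$, $R_{11} = R_{14} = R_{15} = 100$ kOhm,
$C = 50$ nF and time-scaling factor $\tau_0 = 1/(RC) = 10^4\,
\mathrm{s}^{-1}$:

$$
a = \frac{R_7}{10 R_1},\quad b = \frac{R_7}{100 R_3},\quad
k = \frac{R_7}{10 R_4},\quad c = \frac{R_{11}}{R_9},\quad
d = \frac{R_{11}}{10 R_8},\quad \beta = \frac{R_o}{10 R_{15}},
$$

unit gains $R_2 = R_5 = R_6 = R_7$, $R_{10} = R_{11}$,
$R_{12} = R_{13} = R_{14}$, and base resistance $R = 1/(\tau_0 C)$
(2 kOhm).  Where several anchor splits are algebraically possible
(e.g. $\beta$ between $R_o$ and $R_{15}$), $R_{15}$ is fixed and $R_o$
solved, matching the canonical component table.  The inverse
`circuit_to_params()` restores the constants exactly (round-trip tested
to $10^{-12}$); `scale_frequency()` maps dimensionless frequencies to
hardware Hz via $f \cdot \tau_0$ (0.5 to 5 kHz, 0.002 to 20 Hz, ...).
The mapping requires $\alpha = 0$ and positive solved resistances —
negative $k$ is reported as not realizable with these anchors rather
than silently producing a negative resistor.  Component tolerances,
op-amp saturation, and transient circuit simulation are out of scope.

## Problem sizes

The defaults above are the analysis-grade settings.  The shipped test
suite and the acceptance script use these sizes: Lyapunov horizons of
2000-5000 (tests) and 10000 (acceptance, which reproduces the chaotic
leading exponent to the required 0.02), trajectory horizons of 2000,
elimination sweeps of 11-21 grid points with horizons of 2000-3000, and
1000 random draws for the root-finding oracle.

## Known limitations

* The frozen-drive equilibrium analysis is instantaneous bookkeeping,
  not averaging theory; its labels say nothing about the attractors of
  the forced flow.
* Transition/convergence times of runs that leave a transient orbit are
  reported by the windowed-fingerprint estimator, which is quantized by
  the window stride and biased early by partial windows; the underlying
  first-spike transition itself is robust to integrator settings, so
  disagreements with eyeball readings of published time series at the
  tens-of-time-units level are expected.
* The elimination threshold is horizon-dependent by construction; the
  reported value is tied to the declared protocol.
* Spike/burst thresholds are geometry-based heuristics; they are exposed
  as configuration and the headline classifications tolerate moderate
  (tens of percent) perturbations, but pathological parameter sets may
  need retuning.
* No continuation of equilibria or periodic orbits, no
  basin-of-attraction maps, and no estimation of exponents from scalar
  time series.
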