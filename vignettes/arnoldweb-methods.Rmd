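---
title: "Phase-space methods for a model unimolecular dissociation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-space methods for a model unimolecular dissociation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arnoldweb)
```

## The model

The package studies a three-degree-of-freedom local-mode model of a
dissociating bent triatomic (Bunker's model 6, loosely representing ozone):
two Morse stretches and a harmonic bend coupled through the off-diagonal
momentum terms of the equilibrium Wilson G-matrix,

$$H(\mathbf q,\mathbf p)=\sum_{i=1}^{3}\Big[\tfrac12 G^{(0)}_{ii}p_i^2
 + V_i(q_i)\Big] + \epsilon\sum_{i<j}G^{(0)}_{ij}p_ip_j,$$

with $V_{1,2}$ Morse ($D = 24$ kcal/mol each) and $V_3$ harmonic. The
dimensionless factor $\epsilon\in[0,1]$ scales the kinetic coupling: at
$\epsilon=0$ the modes are uncoupled (no intramolecular energy flow), at
$\epsilon=1$ the full model is recovered. All ensembles live on the energy
shell $E = 34$ kcal/mol, above the single-bond threshold, and a trajectory
counts as dissociated when a stretch coordinate exceeds 7.5 bohr.

In action-angle variables the zeroth-order part is
$H_0(\mathbf J)=\sum_{k=1,2}\omega_k J_k(1-\omega_k J_k/4D_k)+\omega_3J_3$,
giving nonlinear frequencies $\Omega_k=\omega_k(1-\omega_kJ_k/2D_k)$ for
the stretches and the constant $\Omega_3=\omega_3$ for the bend. Resonances
$l\Omega_1+m\Omega_2+n\Omega_3=0$ are therefore straight lines in the
$(J_1,J_2)$ plane, and junctions (intersections of two independent
resonances, the maximum multiplicity at three degrees of freedom) are
points computable in closed form — `resonance_lines()` and `junctions()`.
The prominent $1{:}1$ stretch-bend junction sits at
$(J_1,J_2)\approx(6.52,\,6.33)\,\hbar$, and the bound Morse domain ends at
$J_{\max,k}=2D_k/\omega_k\approx 15\,\hbar$.

## Parameters and units

Internally everything is propagated in atomic units ($\hbar=1$);
user-facing energies are cm$^{-1}$ (kcal/mol in configuration files,
1 kcal/mol = 349.755 cm$^{-1}$), times are ps (1 ps = 41341.37 a.u.),
lengths bohr, actions $\hbar$.

The literature description of Bunker's model 6 fixes $D$, the harmonic frequencies
$(\omega_1,\omega_2,\omega_3)=(1112,1040,632)$ cm$^{-1}$, $E$, and the
dissociation threshold; it does not pin down the G-matrix, Morse range
parameters or equilibrium geometry. `bunker_params()` therefore builds
$G^{(0)}$ from the Wilson formulas for a bent symmetric triatomic with
ozone masses (15.995 u), bond length 2.4052 bohr and angle 116.8°, and then
*calibrates* $\alpha_k$ from
$\omega_k=\sqrt{2D_k\alpha_k^2G^{(0)}_{kk}}$ so the printed frequencies are
reproduced exactly. Every constant can be overridden explicitly (or through
a YAML file, `bunker_params_from_config()`), so an exact parameter table
can be dropped in verbatim. Headline results — junction locations, bound
domain, frequency ratios — depend only on $(D,\omega)$ and are insensitive
to this choice; absolute coupling amplitudes (and hence the overlap
threshold below) inherit an $O(1)$ geometric factor from it, which is one
reason that threshold is quoted only to a factor of ~2.

## Trajectories, events, and the FLI

`propagate()` integrates Hamilton's equations with an adaptive
Dormand–Prince 8(5,3) method (relative tolerance $10^{-11}$ by default)
and audits every run against a relative energy-drift threshold of
$10^{-8}$ over 40 ps; a violating trajectory is flagged and warned about,
never silently returned. Dissociation events are detected at step
boundaries and bisection-refined to below 1 fs. Undissociated trajectories
carry the sentinel lifetime `Inf`, so the downstream discard rule is
unambiguous.

The fast Lyapunov indicator is computed by co-integrating the variational
equations: $\mathrm{FLI}(t)=\sup_{s\le t}\log_{10}\lVert v(s)\rVert$ from
the generic initial tangent $(1,\dots,1)/\sqrt6$, with renormalisation
whenever $\lVert v\rVert>10^6$ and the accumulated log added back, so
overflow cannot occur on 40 ps chaotic runs. Regular cells grow
logarithmically in time (anharmonic shear), chaotic cells linearly;
resonant (librating) cells grow more slowly than the shear baseline. The
absolute FLI offset depends on the tangent convention, so all comparisons
in the package are relative, never against external colour-scale values.

## Ensembles

Two constructions generate the initial conditions used throughout:

* `sample_energy_shell()` — microcanonical-style samples of
  $H(\mathbf p_0,\mathbf q_0)=E$: coordinates uniform in the classically
  allowed region by rejection, momentum direction uniform on the sphere
  mapped onto the kinetic-energy ellipsoid, magnitude scaled onto the
  shell ($|H-E|/E<10^{-10}$ by construction). The density on the shell is
  a declared modelling choice and is isolated in one function so
  alternatives can be swapped.
* `angle_slice_grid()` — the fixed-angle slice
  $(\theta_1,\theta_2,\theta_3)=(\pi/2,\pi/2,0)$ on a uniform
  $(J_1,J_2)$ grid, solving the *full coupled* $H(\mathbf J,\theta^*)=E$
  for $J_3\ge0$ by a vectorised bracket-and-bisect (the coupling term
  shifts the shell whenever $\epsilon>0$); infeasible cells are data, not
  errors, and where several roots exist the smallest non-negative one is
  taken, continuous with the $\epsilon=0$ closed form. Default grid ranges
  stop at $0.99\,J_{\max}$: above that the Morse outer turning point
  already crosses the 7.5 bohr threshold, which would create spurious
  zero-lifetime cells.

Default map resolution is $100\times100$; web structure is
resolution-stable (an invariant the tests check at $50^2$ versus
$100^2$), and $500^2$ maps sharpen the picture without moving the
geometry.

## Survival analysis

`survival_curve()` is the empirical survival function over retained
(dissociating) trajectories — the discard rule only rescales $S$, which is
tested as an invariant — with binomial standard errors;
`lifetime_density()` is the histogram estimate of $P(t)=-dS/dt$
(Freedman–Diaconis bins by default, avoiding double smoothing of an
already-empirical curve). `fit_survival()` fits
$S(t)=\sum_i a_ie^{-k_it}$, $\sum a_i=1$, with rates log-parametrised,
amplitudes through a softmax, multi-start over log-spaced rate seeds, and
weights $1/\max(\mathrm{se},\mathrm{floor})$ where the floor is the
binomial error of a half-count — tail points with $S$ near 0 or 1
otherwise acquire unbounded weight. Model order is compared by
small-sample-corrected AIC, mirroring the usual single- versus
multi-exponential comparison for statistical versus nonstatistical decay.

## Arnold-web maps and classification

`compute_fli_map()` integrates every feasible slice cell with tangent
dynamics to the horizon (default 40 ps; `quick = TRUE` gives the standard
cheap 4 ps look). At dissociating cells the FLI is frozen at the event
time and the lifetime recorded — cells are kept, so FLI and lifetime maps
share one grid. The module is RNG-free and maps are bit-reproducible.

`classify_map()` labels cells regular / resonant / chaotic. Because the
absolute FLI scale is conventional, thresholds are *calibrated* from two
reference ensembles at the same horizon, as follows: the integrable
baseline is the per-cell $\epsilon=0$ FLI (with the median
$\epsilon=0$ curve supplying its time dependence), and the chaotic
exemplar is the median frozen-FLI-versus-dissociation-time curve of an
$\epsilon=1$ calibration ensemble. Every cell is compared at its own
frozen time: chaotic if it exceeds the integrable baseline by 1 log-unit
or lies closer to the chaotic exemplar, resonant if it falls 0.15
log-units below the baseline (libration suppresses shear), else regular.
At the 40 ps horizon this classifies ~91% of $\epsilon=1$ cells chaotic;
cells that dissociate within a few bend periods are genuinely
indeterminate to any FLI rule, which is why the quick-look fraction is
lower.

## Chirikov overlap estimate

`chirikov_threshold()` applies the pendulum approximation to the dominant
$(1,0,-1)$ stretch-bend resonance: half-width
$\Delta J=2\sqrt{\epsilon|V_{\rm res}|/|\partial^2H_0/\partial J^2|}$ with
$|\partial^2H_0/\partial J_1^2|=\omega_1^2/2D_1$ and $V_{\rm res}$ the
resonant Fourier amplitude of the coupling, computed numerically
(`fourier_table()`, a 2-D FFT over the unperturbed torus, exactly
testable against direct evaluation of $H-H_0$ — preferable to deriving
closed forms for the coefficients). The neighbour defaults to
$(2,0,-1)$ — the nearest stretch-bend line with a non-vanishing
first-order coefficient, since the harmonic bend momentum carries only
first harmonics. Evaluation tori sit on each line at $E$, the remaining
energy split equally between the other two modes. $\epsilon^*$ solves
"sum of half-widths = line separation", giving $\epsilon^*\approx0.14$,
consistent with the ~0.2 order-of-magnitude estimate for widespread chaos;
the quantity is meaningful only to such a factor, as both the torus choice
and the geometric $O(1)$ factors in $V_{\rm res}$ move it.

## Wavelet frequency analysis and locking

`wavelet_frequencies()` extracts $\Omega_k(t)$ as the ridge of a
continuous Morlet transform (centre parameter 6, 32 voices/octave over
300–1400 cm$^{-1}$, FFT-based) of $z_k=\sqrt{2J_k}e^{i\theta_k}$, with
log-parabolic refinement across scales. The transform uses L1
normalisation so a pure tone's ridge sits exactly at its frequency (the
L2 convention biases ridges low by $\sim1/2\omega_0^2\approx1.4\%$). The
bend frequency is taken from its own ridge rather than assumed equal to
$\omega_3$, so the method would carry over to anharmonic bends. Because
the total energy exceeds $D$, a bound trajectory can transiently push one
stretch's instantaneous mode energy above $D$, where the Morse
action-angle inverse is undefined; such samples are clamped to the
bound-domain boundary for signal construction only.

Ridges are regularised by a running median (default window 0.1 ps; the
locking analyses use 0.5 ps, about one pendulum libration period of the
$1{:}1$ junction at $\epsilon=0.1$). The rationale: ratio locking is a
property of the libration-averaged frequency — the raw ridge oscillates
*with* the resonant libration itself, so an unsmoothed ratio leaves the
tolerance band every half-period even for a cleanly trapped trajectory.

`detect_locking()` segments intervals where both ratios
$(f_1,f_2)=(\Omega_1/\Omega_3,\Omega_2/\Omega_3)$ stay within 0.02 of a
junction's rational point for at least 0.25 ps (~5 bend periods);
overlapping claims go to the junction with the smaller residual. The
default junction list is the four formed by the
$(1,0,-1)/(0,1,-1)$ and $(2,0,-3)/(0,2,-3)$ stretch-bend resonances
($\mathcal M^{1,0,-1}_{0,1,-1}$, $\mathcal M^{2,0,-3}_{0,2,-3}$ and the
two mixed ones) — the junctions that dominate the trapping in this model;
tolerances, dwell and junction set are exposed arguments because no
community-standard locking convention exists. `locking_mode()`
summarises per-trajectory totals with 1 ps bins (a few times the minimum
dwell — stable counts at a few hundred tracks). Enlarging the tolerance
can only grow total locking time; this nesting property is tested.

## What the generators emulate — and what they do not

The synthetic ensembles reproduce the *construction* of the initial
conditions (the energy shell, the angle slice, the seeds), not any
particular realisation: the shell-sampling density and the locking
criteria are conventions, so distributional character — not bit-level
values — is the meaningful comparison surface. Passing tests therefore
show that the pipeline reproduces the mechanism (resonance-line geometry,
stable-chaos trapping near junctions, the kinetics of delayed
dissociation) under faithfully re-stated conditions; they do not certify
bit-level agreement with any particular historical computation, and
multi-exponential fit *coefficients* are sensitive to the ensemble
construction by nature.

## Numerical choices and problem sizes

Tolerances: integrator $10^{-11}$ relative (maps $10^{-10}$ — the FLI is
a coarse indicator), drift audit $10^{-8}$, slice-shell accuracy
$10^{-10}$, event refinement 1 fs. Wavelet signals are sampled at 2 fs.
Degenerate inputs are handled as data where the physics says so
(infeasible cells, zero-locking tracks) and as errors where it does not
(all-undissociated survival input, unbound action-angle inversion,
non-coprime resonance pairs).

The shipped tests and the acceptance script run at desk scale, chosen as
the sizes at which each statistic stabilises: $32^2$ slice grids
(~600 trajectories) for the full-coupling kinetics, $50^2$–$100^2$
quick-look maps for web geometry, $33^2$ maps at 40 ps for the
junction-lifetime contrast, and ensembles of ~2500 shell samples
(retaining ≥200 survivors) for the $\epsilon=0.1$ locking statistics.
$500\times500$ maps at 40 ps are cluster-scale and not part of the test
surface.

## Known limitations

* The absolute coupling amplitudes inherit the reconstructed geometry;
  quantities built from them (the overlap $\epsilon^*$) are
  order-of-magnitude by nature.
* FLI classification is indeterminate for cells that dissociate within a
  few bend periods; they are labelled by the calibrated rule but carry
  little dynamical information either way.
* Locking statistics depend on the tolerance convention;
  under the package defaults the total-locking mode for $\epsilon=0.1$
  survivors sits near 1–2 ps, and a looser
  ratio tolerance comparable to the junction libration amplitude (~0.05)
  roughly doubles dwell times. The defaults are fixed once and swept only
  as explicit arguments.
* The zero-momentum-surface analysis, coordinate-dependent G-matrix
  variant, other Bunker parameter sets and energies other than
  34 kcal/mol are out of scope (the configuration does not preclude them,
  but nothing is validated there).
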