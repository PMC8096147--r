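---
title: "Models and methods behind deazaRNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind deazaRNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deazaRNA)
```

## Scientific scope

3-deazapurine nucleosides (c3A, c3G) replace the purine N3 nitrogen by a
CH group; their 7-deaza isomers (c7A, c7G) do the same at N7. Both keep
the Watson-Crick face intact, so a c3G still pairs with C and a c3A with
U, yet the substitution removes a minor-groove (N3) or major-groove (N7)
hydrogen-bond acceptor and raises the nucleobase pKa by one to three
units. These are the work-horse probes of RNA atomic mutagenesis, and
quantifying how much they destabilize a double helix -- and why -- takes
four independent biophysical measurements. `deazaRNA` implements the
analysis side of each: two-state UV-melting thermodynamics, CLEANEX-PM
imino-proton/water exchange kinetics, pKa titration by chemical shift,
and crystal-structure superposition with minor-groove hydration reports,
plus generators that simulate each raw-data type from the corresponding
forward model.

## Two-state melting thermodynamics

A strand is assumed to exist only fully folded or fully unfolded, with
equilibrium constant

$$K(T) = \exp\!\left(-\frac{\Delta H^\circ - T\,\Delta S^\circ}{RT}\right),$$

with $\Delta H^\circ$ in kcal/mol, $\Delta S^\circ$ in cal/(mol K) and
$R = 1.987$ cal/(mol K). The mass-action link between $K$ and the folded
fraction $\theta$ depends on molecularity, which the analysis always
takes as an explicit argument (a palindromic self-dimer and a hairpin
cannot be told apart from a single melting curve):

* unimolecular hairpin: $K = \theta/(1-\theta)$, so $T_m = 1000\,\Delta H/\Delta S$ (K);
* self-complementary duplex at total strand concentration $c_T$:
  $K = \theta / (2 c_T (1-\theta)^2)$, giving
  $1/T_m = (R/\Delta H)\ln c_T + \Delta S/\Delta H$;
* non-self-complementary duplex mixed 1:1 (each strand at $c_T/2$):
  $K = 2\theta / (c_T (1-\theta)^2)$ and the same line in $\ln(c_T/4)$.

The bimolecular $\theta(T)$ is the root of a quadratic; we evaluate it in
the cancellation-free conjugate form ($\theta = 2a/(2a+1+\sqrt{4a+1})$
with $a = 2c_T K$ for the palindromic case), which is exact from
$K \to 0$ to $K \to \infty$ in double precision.

**Derivative melting temperature.** `tm_first_derivative()` reports the
temperature of the maximum of dA/dT, smoothed with a Savitzky-Golay
filter (defaults: window 11 points, polynomial order 3 -- a standard
choice for 0.5 degC-step melting data; both are arguments). The discrete
peak is refined by quadratic interpolation, and a profile whose
derivative peak is absent, indistinct relative to the flank derivative
level, or within one filter window of the range edge raises a
no-transition error rather than returning a number. The derivative is
taken on raw absorbance by default (`on = "theta"` switches to the
baseline-corrected folded fraction). Note one property of the model
itself: for bimolecular transitions the derivative maximum sits slightly
below the $\theta = 1/2$ temperature because the transition is
asymmetric; the two agree for hairpins. Fitted parameters, not the raw
derivative peak, are therefore the right thing to compare across
molecularities.

**Baselines and the van't Hoff fit.** Folded and unfolded absorbance
baselines are linear in temperature; pairing is hypochromic, so the
unfolded baseline lies above the folded one and
$\theta(T) = (A_u - A)/(A_u - A_f)$, clipped to [0, 1]. Baseline windows
default to the coolest and hottest 15% of points and are overridable per
curve. Fixed windows, however, always absorb some transition tail -- for
a hairpin melting at 72 degC on a 20-90 degC grid the folded fraction is
still 0.10-0.16 at 80 degC -- and that bias propagates into
$\Delta H^\circ$. `van_t_hoff_fit()` therefore uses the window estimate
only for start values and then refines all six parameters (two baselines
plus $\Delta H^\circ$, $\Delta S^\circ$) against the raw profile
$A(T) = A_f(T)\theta + A_u(T)(1-\theta)$ by Levenberg-Marquardt least
squares. With this refinement the fit is an exact inverse of the forward
model on noise-free data, which the test suite asserts for all three
molecularities. $\Delta G^\circ_{298}$ is evaluated at 298.15 K
(the "298" subscript read as 25 degC), and all standard errors come from
the fit covariance (delta method for $\Delta G$ and $T_m$).

**Concentration dependence.** `tm_concentration_fit()` regresses
$1/T_m$ on $\ln c_T$ (palindromes) or $\ln(c_T/4)$ (heteroduplexes):
slope $= R/(1000\,\Delta H)$, intercept $= \Delta S/(1000\,\Delta H)$. It
is an independent estimation path from the single-curve fit, and reports
flag which path produced each number. A non-negative slope implies
$\Delta H \ge 0$ and is flagged non-two-state instead of being reported
silently.

**Replicates.** Published tables of this kind quote "standard deviation
of three (duplex) or five (hairpin) measurements for a confidence
interval of 95%", which conflates two conventions. We read it as a 95%
interval and use mean $\pm\, t_{0.975,\,n-1}\, s/\sqrt{n}$; the plain
replicate standard deviation is available via `interval = "sd"`.
Replicates aggregated together should share a concentration, since the
bimolecular $T_m$ varies legitimately across $c_T$.

## CLEANEX-PM exchange kinetics

CLEANEX-PM transfers magnetization from bulk water to exchanging imino
protons; over the mixing time $\tau$ the relative intensity follows the
two-site transfer build-up

$$I/I_0 = \frac{k}{R_{1A} + k - R_{1w}}
 \left(e^{-R_{1w}\tau} - e^{-(R_{1A}+k)\tau}\right),$$

where $k$ is the imino-proton/water exchange rate, $R_{1A}$ the apparent
(mixed longitudinal/transverse) relaxation rate of the imino resonance
during the spin-lock, and $R_{1w}$ the water longitudinal rate. (Typeset
renderings of this equation elsewhere sometimes scramble the second
exponent's grouping; the form above is the one consistent with the
symbol definitions and with the physics: the initial slope is exactly
$k$, and the curve decays to zero at long mixing times.) The removable
singularity at $R_{1A}+k = R_{1w}$ is evaluated by its limit
$k\tau e^{-R_{1w}\tau}$. $R_{1w}$ is measured independently by
saturation recovery (`fit_t1_saturation_recovery()`; water $T_1$ is
around 3.0-3.1 s for these samples) and held fixed during fitting,
because floating it trades off directly against $R_{1A}$.

`fit_exchange()` runs bounded Levenberg-Marquardt over
$(k, R_{1A})$ with $k \in [0, 100]$ s$^{-1}$ and
$R_{1A} \in (0, 200]$ s$^{-1}$; solutions pinned at a bound are flagged.
The default mixing schedule is the twelve-point series 5-500 ms with
duplicated 50, 100 and 400 ms points treated as independent repeats.

**Monte-Carlo errors.** The error model is parametric residual
resampling: synthetic datasets are drawn as model$(\tau) + N(0,
\hat\sigma^2)$, with $\hat\sigma$ the residual standard error (degrees
of freedom corrected for the two fitted parameters) and refitted; the
reported error is the standard deviation of the refitted parameters,
deterministic for a fixed seed, with a nonparametric residual bootstrap
as an option. The default is 1000 runs; the calibration experiments in
the test suite use 150 runs per replicate (the standard error of an
MC standard deviation scales as $1/\sqrt{2n}$, so 150 runs determine the
error to about 6%, enough to score interval coverage across 200
replicates).

**What precision is attainable.** The information the twelve-point
schedule carries about $k$ falls off steeply with $R_{1A}$: propagating
the model Jacobian at noise 0.005 on $I/I_0$ gives a lower bound on the
relative standard error of $k \approx 1\ \mathrm{s}^{-1}$ of about 4% at
$R_{1A} = 5$ s$^{-1}$, 14% at 20 s$^{-1}$ and 36% at 40 s$^{-1}$ -- no
estimator can beat this. The suite checks both that the fit attains the
bound's order (near-efficiency) and that the Monte-Carlo 95% intervals
cover the truth at their nominal rate, which holds at any $R_{1A}$.
Single-digit-percent rate errors, when quoted, therefore imply either
slow imino relaxation or noise well below 0.005.

## pKa titration and base-pair pKa gaps

A single protonation site shifts a reporter resonance between its
protonated and deprotonated end points:

$$\delta_{obs} =
  \frac{\delta_{deprot}\,10^{pH - pK_a} + \delta_{prot}}
       {1 + 10^{pH - pK_a}}.$$

`fit_titration()` estimates $(pK_a, \delta_{prot}, \delta_{deprot})$ by
least squares with covariance standard errors. Only single-site curves
are in scope; flat series are rejected as unidentifiable, and a fitted
$pK_a$ more than one unit outside the sampled pH window is flagged
"extrapolated" rather than suppressed -- relevant for c3G, whose
$pK_a$ of 12.3 sits at the edge of what aqueous titration can bracket.
Different reporter nuclei (e.g. C2 and C6) are fitted separately by
default; a shared-pKa joint fit is a deliberate non-default because
discrepant per-nucleus fits are themselves diagnostic of multi-site
behaviour.

The package carries the reference pKa table for the Watson-Crick-facing
sites -- protonated purine N1 / cytosine N3 on the acceptor side, U N3-H
and (deaza)guanine N1-H on the donor side: A 3.7, c3A 6.8, c7A 5.3,
U 9.2, G 9.5, c3G 12.3, c7G 10.3, C 4.1 -- and `base_pair_gaps()` reports
the donor-acceptor gap of each pair. The natural pairs sit at gaps of
5.5 (A-U) and 5.4 (G-C); 3-deaza substitution collapses the A-U gap to
2.4 and overshoots the G-C gap to 8.2, while the 7-deaza gaps (3.9, 6.2)
move only moderately -- mirroring the ranking of thermodynamic
destabilization. `protonated_fraction()` adds the Henderson-Hasselbalch
bookkeeping; c3A ($pK_a$ 6.8) is ~39% protonated at pH 7.

## Structure superposition and hydration

`read_structure()` parses PDB or mmCIF through bio3d, retaining
alternate locations and occupancies. Superposition is a proper-rotation
Kabsch fit (SVD with determinant correction); by default the paired set
is every shared non-hydrogen, non-water atom matched by residue number
and atom name, and a 3-deazapurine's C3 is matched positionally to the
parent purine's N3 (the replacement is isosteric), configurable off. The
tests pin the implementation against a brute-force rotation-grid oracle
on small toys.

`minor_groove_waters()` reports ordered waters within a cutoff (default
3.6 A, a generous hydrogen-bond distance) of the minor-groove face
atoms: purine N3 or its deaza C3, pyrimidine O2, and both 2'-OH oxygens.
Altlocs resolve to the highest-occupancy conformer (ties to "A", the
convention matching deposited SRL structures where residues 2647-2650
have alternates), waters under 0.5 occupancy are excluded by default,
and distances print at 0.1 A. Residue numbers are taken verbatim from
the input (23S rRNA numbering for sarcin-ricin loop constructs); the
module deliberately does not guess which residues form the pair of
interest. The deposited SRL structures themselves (PDB IDs 7L3R and
3DVZ) are not redistributed with the package; the corresponding
comparison in the acceptance suite runs when those files are placed
under `inst/extdata/`, and is otherwise reported as unavailable.

## Synthetic data: what it does and does not emulate

Every generator is the exact forward model of its fitting module plus
optional Gaussian noise, and each is deterministic for a fixed seed.
That gives the package its central self-consistency property -- at zero
noise, fit-then-generate recovers the generator truth to solver
tolerance -- and makes recovery experiments meaningful: the melting
curves carry sloping linear baselines (folded +0.0003 AU/degC from
0.95 AU, unfolded +0.0005 AU/degC with 20% hyperchromicity, typical of
RNA UV melts at 260 nm), five log-spaced concentrations from 1 to 100
uM, and a 20-90 degC grid in 0.5 degC steps; the exchange build-ups use
the twelve-point mixing schedule with water $R_{1w} = 1/3.03$ s$^{-1}$
and default $R_{1A} = 20$ s$^{-1}$; the titrations use ten points
spanning $pK_a \pm 2$ (clipped to pH 0-14) at 0.05 ppm shift noise; the
toy base pairs place waters at exact requested distances from named
anchors.

Gaussian, homoscedastic noise is the least-structured choice consistent
with least-squares fitting, and it is the generators' only distortion.
Real melting data additionally carry lamp drift, temperature lag and
cell-to-cell offsets; real CLEANEX intensities inherit correlated
spectral noise and imperfect water suppression; real titrations carry
electrode calibration error in pH itself, which the model treats as
exact. Passing recovery tests therefore demonstrate correctness of the
estimators under the stated statistical model, not robustness to
instrument systematics. Multi-state melting, heat-capacity corrections,
NOE/ROE contamination of build-ups, and multi-site titrations are out of
scope by design and are rejected, not approximated.

**Problem sizes.** The recovery and calibration experiments run at 50
seeds x 3 molecularities x 5 concentrations (melting), 200 simulated
experiments for interval coverage with 150 Monte-Carlo runs each, 50
seeds for pKa recovery, and 4x50 simulations for exchange-rate recovery;
these sizes determine each median or coverage estimate to within a few
percent, which matches the width of the acceptance bands they are
compared against.

## Workflow runners

`run_melt()`, `run_cleanex()`, `run_pka()`, `run_structure()` and
`run_simulate()` tie the stages into scripted runs driven by plain
configuration lists or YAML files, write JSON reports plus the resolved
configuration next to them, and log nothing into the report stream.
They are ordinary exported functions, so the same surface serves
interactive sessions, Rscript one-liners and pipeline managers.

## Known limitations

* The two-state assumption is structural: nothing in a single curve
  flags a populated intermediate, and $\Delta H$ errors from
  non-infinite cooperativity (typically 10-15% on real data) are not
  modelled by the reported statistical errors.
* $\Delta C_p$ is assumed zero, so free energies extrapolated far from
  the transition inherit the usual van't Hoff bias.
* The exchange model is the fast-transfer two-site form; radiation
  damping and cross-relaxation pathways are not represented.
* pH is treated as error-free in titration fits.
* The hydration report is purely geometric (distance to face atoms); it
  does not score hydrogen-bond angles or water networks.
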