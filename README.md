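# deazaRNA

Biophysics of deazapurine-modified RNA, as an R package. 3-deazaadenosine
(c3A), 3-deazaguanosine (c3G) and their 7-deaza isomers are the standard
probes of RNA atomic mutagenesis: they delete a single ring nitrogen
while keeping the Watson–Crick face intact. The price is thermodynamic —
3-deazapurines in particular can destabilize a double helix by more than
10 °C in Tm — and understanding that price takes melting thermodynamics,
imino-proton exchange kinetics, nucleobase pKa values and minor-groove
hydration structure together. `deazaRNA` implements the complete analysis
chain for all four measurements, for people who design or interpret
deaza-substitution experiments.

## What it computes

**Two-state UV melting.** With K(T) = exp(−(ΔH° − TΔS°)/RT) and the
molecularity-specific mass-action link (hairpin K = θ/(1−θ);
palindromic dimer K = θ/(2c_T(1−θ)²); 1:1 heteroduplex
K = 2θ/(c_T(1−θ)²)), the package extracts Tm from the smoothed first
derivative, fits ΔH°/ΔS°/ΔG°₂₉₈ per curve (linear baselines refined
jointly with the thermodynamics), fits the 1/Tm-versus-ln c_T line as an
independent route, aggregates replicates with t-based 95% intervals, and
reports ΔTm/ΔΔG against a reference strand.

**CLEANEX-PM exchange.** Build-up curves
I/I₀ = k/(R₁A+k−R₁w)·(e^(−R₁w τ) − e^(−(R₁A+k)τ)) are fitted for the
imino-proton/water exchange rate k with the water rate R₁w fixed from a
saturation-recovery T₁ fit, and errors come from seeded Monte-Carlo
resampling (default 1000 runs).

**pKa titration.** Chemical-shift titrations are fitted to
δ_obs = (δ_deprot·10^(pH−pKa) + δ_prot)/(1 + 10^(pH−pKa)); a built-in
reference table of Watson–Crick-site pKa values (A 3.7, c3A 6.8, c7A 5.3,
U 9.2, G 9.5, c3G 12.3, c7G 10.3, C 4.1) yields the donor–acceptor ΔpKa
gap of every natural and deaza base pair.

**Structures.** PDB/mmCIF models are superposed by a proper-rotation
Kabsch fit (a 3-deaza C3 matches the parent purine N3 isosterically) and
ordered minor-groove waters are reported with nearest-contact distances.

**Synthetic data.** Every raw-data type above can be generated from its
exact forward model with seeded Gaussian noise, so the whole pipeline
runs and tests itself without any instrument data.

## Worked example

Measure how a central c3G destabilizes the palindromic 8-mer GGUCc3GACC
relative to its unmodified parent, from simulated triplicate melts at
10 µM:

```r
library(deazaRNA)

seq_mod <- parse_rna("GGUCc3GACC")
is_self_complementary(seq_mod)   # TRUE: pairs as GGUCGACC at parent level

mk3 <- function(dH, dS, seed0) lapply(1:3, function(s)
  van_t_hoff_fit(gen_melting_curve(dH, dS, "bimolecular_self_complementary",
                                   c_T = 1e-5, sigma_frac = 0.003,
                                   seed = seed0 + s)[[1]]))
fit_ref <- aggregate_replicates(mk3(-64.6, -172, 100))  # unmodified truth
fit_mod <- aggregate_replicates(mk3(-74.7, -213, 200))  # c3G-modified truth

fit_ref$mean
#> <thermo_params> [replicate_mean(n=3,ci95), bimolecular_self_complementary]
#>   dH    = -64.5 +/- 0.8 kcal/mol
#>   dS    = -171.7 +/- 2.3 cal/(mol K)
#>   dG298 = -13.3 +/- 0.1 kcal/mol
#>   Tm    = 58.3 +/- 0.1 degC

round(compare_to_reference(fit_mod$mean, fit_ref$mean), 2)
#>  dTm_C ddG298
#> -14.76   2.08
```

The unmodified duplex melts at 58.3 °C with ΔG°₂₉₈ = −13.3 kcal/mol; the
single c3G–C pair (doubled by the palindrome) costs ~15 °C in Tm and
~2 kcal/mol in folding free energy. The pKa rationale is one call away:

```r
base_pair_gaps()
#>    pair donor acceptor pKa_donor pKa_acceptor gap
#> 1   A-U     U        A       9.2          3.7 5.5
#> 2 c3A-U     U      c3A       9.2          6.8 2.4
#> 3 c7A-U     U      c7A       9.2          5.3 3.9
#> 4   G-C     G        C       9.5          4.1 5.4
#> 5 c3G-C   c3G        C      12.3          4.1 8.2
#> 6 c7G-C   c7G        C      10.3          4.1 6.2
```

Natural pairs sit near the apparently optimal gap of ~5.5; 3-deaza
substitution pushes the gap far off in either direction, 7-deaza only
moderately — the same ordering as the measured destabilization.

An exchange-rate fit with Monte-Carlo errors:

```r
ser <- gen_cleanex_series(1.68, R1A = 20, R1_water = 1/3.03,
                          sigma = 0.005, seed = 7, residue_label = "U3 imino")
monte_carlo_errors(fit_exchange(ser), n = 1000, seed = 8)
#> <exchange_fit> U3 imino: k = 1.344 +/- 0.136 1/s, R1A = 14.75 +/- 1.81 1/s (n_mc = 1000)
```

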