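# xbnmr

Solution-NMR characterisation of very weak intramolecular interactions,
demonstrated on an iodine–ether halogen bond embedded in a cooperatively
folding β-hairpin peptide.

Interactions worth only a fraction of a kJ/mol are invisible to direct
chemical-shift detection. The strategy implemented here measures them
indirectly, through their effect on a folding equilibrium, and
reconciles three independent estimates of the folded population:

1. **Two-state melting analysis** of variable-temperature chemical
   shifts: per-proton and global fits of
   δ(T) = δ_U + (δ_F − δ_U)/(1 + exp(−ΔH_m/R·(1/T − 1/T_m))),
   folding free energies ΔG° = −RT·ln k_F and ΔG° = ΔH_m − T·ΔS_m,
   relative stabilities of a halogen-bonding compound vs its
   non-bonding reference (K = k_F¹/k_F², ΔΔG = −R·T_m2·ln K), and
   amide temperature coefficients with hydrogen-bonding classification.
2. **NAMFIS-style ensemble deconvolution**: NOESY build-ups →
   initial-rate cross-relaxation rates → r⁻⁶-calibrated distances,
   plus Karplus-predicted ³J(HN,Hα) couplings, deconvoluted into
   populations over a rigid conformer pool by tolerance-weighted
   constrained least squares on the probability simplex.
3. **RDC alignment-tensor analysis**: ¹D_CH = (¹T − ¹J)/n_H extraction,
   Saupe-tensor fitting by SVD with Cornilescu Q and condition-number
   diagnostics, shared-tensor ensemble fits by alternating linear
   solves, and χ²-penalised sub-ensemble selection.

Conformers are classified as folded β-hairpins (type II′ turn windows,
interstrand Cα–Cα distance, cross-strand H-bond proxies) and as
halogen-bonded (I···O below the van der Waals sum 3.50 Å, C–I···O angle
≥ 140°). A synthetic-data module generates every input with known
ground truth — conformer pools built by internal-coordinate chain
construction, melt tables, NOE build-ups, coupling and RDC tables — so
the full pipeline is testable end to end without any external data.

## Worked example

```r
library(xbnmr)

rc <- run_config(seed = 9, outdir = tempfile(), noise_shift = 0,
                 noise_intensity = 0, noise_rdc = 0, kappa = 0)
report <- run_pipeline(rc)
report
```

```
xbnmr report (xbnmr-report/1)
  folded fraction at 274 K: melt 0.500 | NAMFIS 0.500 | RDC 0.500
  halogen-bond population (RDC): 0.300
  halogen-bond geometry: I...O 3.20 A, C-I...O 145.0 deg
```

The run simulates a noise-free dataset whose ground truth is 50%
folded and 30% halogen-bonded at 274 K (the melting temperature, so
populations and melt are thermodynamically consistent), then recovers
that truth by all three routes: the global melt fit (T_m = 274.0 K,
ΔH_m = 23.9 kJ/mol recovered), the NOE/J deconvolution and the RDC
sub-ensemble fit agree on the folded population, the RDC analysis
finds the halogen-bonded share, and the selected conformers carry the
built 3.2 Å / 145° I···O geometry. The same report contains the
relative-stability comparison against the reference compound
(T_m = 267.6 K): `report$relative` gives K_ratio ≈ 1.32 and
ΔΔG ≈ −0.61 kJ/mol.

Individual stages are available as plain functions
(`fit_two_state()`, `global_melt_fit()`, `relative_folding()`,
`fit_initial_rate()`, `calibrate_distances()`, `fit_populations()`,
`svd_fit()`, `ensemble_rdc_fit()`, `model_select()`, ...) and through
a thin command-line wrapper (`inst/scripts/xbnmr`) with subcommands
`simulate`, `melt`, `noe`, `namfis`, `rdc`, `report`, `pipeline`.

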