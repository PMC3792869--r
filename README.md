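# bridgestab

Salt-bridge hallmarks and thermal stability of bacterial lipolytic enzymes.

Thermostable carboxylesterases and monoacylglycerol lipases of the
α/β-hydrolase fold (the *Geobacillus*-type "N′ subfamily" of family XV)
carry a distinctive inventory of conserved salt bridges — five exclusive
side-chain ion pairs plus a diagnostic "interloop" bridge tethering the two
catalytic loops — and their thermal stability responds strongly to removing
the basic partners of those bridges. `bridgestab` implements the complete
computational workflow for studying this kind of system:

* **Geometric salt-bridge detection** in PDB structures: a bridge is an
  acidic carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2) within a cutoff
  (default 4 Å, inclusive after rounding) of a basic side-chain nitrogen
  (Arg NH1/NH2/NE, Lys NZ, His ND1/NE2), scored per residue pair by the
  minimum atom-pair distance.
* **Shrake–Rupley solvent accessibility** with a deterministic golden-spiral
  lattice, relative accessibility against extended Gly-X-Gly reference
  areas, and burial classification of bridges.
* **Hallmark profiling and subfamily assignment**: catalogs of the five
  N′-exclusive pairs, the two shared His pairs and the six N-pattern
  (Est30-type) pairs; the interloop (i−2, i−4) rule locating the bridge at
  two residues before the catalytic Asp and four before the catalytic His,
  with acid→base polarity in N′ and base→acid in N; and a documented
  decision rule returning N′ (family XV), N (family XIII), LipS-like or
  unassigned.
* **Phylogeny**: global-alignment percent identity (BLOSUM62, gap 10/0.5),
  Poisson-corrected distances d = −ln(1 − p) with pairwise gap deletion, and
  a Saitou–Nei neighbor-joining implementation with deterministic
  tie-breaking and Newick output.
* **Two-state denaturation thermodynamics**: with sloping linear baselines
  y_F(T), y_U(T),

      f_U = (y_F − y)/(y_F − y_U),  K = f_U/(1 − f_U),  ΔG = −RT ln K,

  T_m is the zero crossing of ΔG(T), ΔS_m = −dΔG/dT and ΔH_m = T_m ΔS_m
  (van't Hoff); stability away from T_m follows Gibbs–Helmholtz,
  ΔG(T) = ΔH_m(1 − T/T_m) − ΔC_p[(T_m − T) + T ln(T/T_m)]. A direct
  6-parameter nonlinear fit, linear-extrapolation chemical-denaturation
  midpoints (C_m, m-value), and variant bookkeeping (ΔT_m, ΔΔG) round out
  the module.
* **Seeded synthetic-data generators** for every stage: structures with
  planted bridge geometries, melting and GuHCl curves with known
  parameters, hallmark-knockout sequence families, and additive
  tree-structured distances — so the whole pipeline is testable against
  ground truth without external downloads.

The packaged reference table `estgta2_variants()` carries the published
melting temperatures of wild-type EstGtA2 and its 14 combinatorial
alanine-shaving mutants (pH 8 and pH 10 rows), the reported ΔG(25 °C)
values and GuHCl midpoints, and drives the reproduction scripts below.

## Worked example

```r
library(bridgestab)

# synthetic wild-type and quadruple-mutant melting curves at published Tm
wt  <- synth_melting_curve(Tm_C = 64.2, dHm = 120, noise_sd = 0.02, seed = 1)
m4b <- synth_melting_curve(Tm_C = 49.9, dHm = 120, noise_sd = 0.02, seed = 2)
fit_wt  <- linearized_stability(wt)$fit
fit_m4b <- linearized_stability(m4b)$fit
print(fit_wt)
#> <two_state_fit> Tm = 64.43 C, dHm = 128.3 kcal/mol, dSm = 0.3802 kcal/(mol K) [linearized]
print(fit_m4b)
#> <two_state_fit> Tm = 50.55 C, dHm = 94.3 kcal/mol, dSm = 0.2913 kcal/(mol K) [linearized]
compare_variants(fit_wt, fit_m4b, temp_C = 25)
#> $dTm_C
#> [1] -13.87687
#> $ddG_kcal_mol
#> [1] -7.545699
#> $temp_C
#> [1] 25
```

At 2 % signal noise the fitted midpoints land within a few tenths of a
degree of the planted 64.2 / 49.9 °C, and the mutant is reported as
destabilized by ~14 °C and ~7.5 kcal/mol at 25 °C. Salt-bridge detection on
a structure with two planted pairs:

```r
s <- synth_structure(data.frame(acid = c("GLU", "ASP"), base = c("ARG", "LYS"),
                                dist_A = c(3.3, 3.6)), decoys = 3, seed = 1)
detect_salt_bridges(s, cutoff = 4.0)
#>   acid_resid acid_resno base_resid base_resno min_dist_A
#> 1        GLU          1        ARG          2        3.3
#> 2        ASP          3        LYS          4        3.6
```

`run_pipeline()` chains the stages from a YAML config and writes a single
JSON report (bridges with burial labels, subfamily calls, a Newick tree,
thermal/chemical fits and a ΔT_m/ΔΔG comparison); see `?run_pipeline`.

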