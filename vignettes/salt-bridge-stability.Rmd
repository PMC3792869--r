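---
title: "Salt-bridge hallmarks and two-state stability analysis with bridgestab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salt-bridge hallmarks and two-state stability analysis with bridgestab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bridgestab)
```

`bridgestab` analyses the relationship between conserved salt bridges and
thermal stability in bacterial lipolytic enzymes of the α/β-hydrolase fold.
This vignette is the package's methods account: the models it implements,
the assumptions behind them, the parameters that matter and their defaults,
what the synthetic-data generators do and do not emulate, and the numerical
and design decisions taken where the choice was genuinely open.

## The biological setting

Thermostable *Geobacillus*-type carboxylesterases and monoacylglycerol
lipases (~250 residues, Ser-Asp-His catalytic triad, α/β cap domain over
the active site) form a tight cluster — the N′ subfamily of bacterial
lipolytic enzyme family XV — distinguished from the Est30-like family XIII
(the N subfamily) by sequence hallmarks rather than by overall fold:

* five salt bridges exclusive to N′, at EstGtA2/MGL numbering
  E3–R54, E12–R37, E66–R140, D124–K178 and D205–R220;
* two His-containing bridges (E78–H110, D148–H197) shared more widely;
* a six-bridge pattern exclusive to the N group, at Est30 numbering
  R37–E40, E124–K165, K139–E152, E142–K144, R191–E219 and K216–D237;
* an "interloop" bridge joining the two catalytic loops, located two
  residues before the catalytic Asp and four before the catalytic His.
  Its polarity is diagnostic: acid→base (e.g. D194–H222 or D194–R222) in
  N′, base→acid (e.g. R191–E219) in N.

Disrupting the basic partners of the five exclusive bridges by alanine
shaving destabilizes the enzyme by 5–14 °C of melting temperature, and one
particular quadruple combination abolishes folding altogether; replacing
the interloop His by Arg raises the melting temperature under alkaline
conditions, where a His partner is largely deprotonated. The package
reproduces the computational side of that analysis end to end.

## Salt-bridge detection

A salt bridge is a close electrostatic contact between an acidic side-chain
carboxylate and a basic side-chain group. The detector
(`detect_salt_bridges()`) scores every acidic/basic residue pair by the
*minimum* distance over all charged-atom pairs — Asp OD1/OD2 and Glu
OE1/OE2 against Arg NH1/NH2/NE, Lys NZ and (by default) His ND1/NE2 — not
by a centroid distance, which is the convention under which per-bridge
distances such as "3.3 Å" are reported in the structural literature.

Decisions worth stating explicitly:

* **Cutoff 4.0 Å, inclusive, applied after rounding to 1 decimal.** A pair
  reported at exactly 4.0 Å is a bridge. Rounding first means the printed
  distance and the detection decision can never disagree.
* **Histidine** is treated as basic by default. His pK_a is near 6, so at
  the alkaline pH range where these enzymes are typically studied
  (pH 8–10) His-mediated bridges are largely absent; `include_his = FALSE`
  is the pH-aware mode.
* **Termini are excluded by default**; only side-chain bridges are
  inventoried. Backbone N/OXT termini can be added with
  `include_termini = TRUE`.
* **Hydrogens are ignored** throughout the geometry; the crystal structures
  this workflow targets do not resolve them.
* Charged residues whose side-chain charged atoms are all missing
  (truncated models) are skipped with a warning rather than an error.

`conserved_bridges()` compares two inventories through a residue-number
mapping and distinguishes `identical` pairs, `conserved_substitution`
(identity changed within the charge class, as in the His222↔Arg222 switch
between close homologs), `absent` and `unalignable`.

## Solvent accessibility and burial

`compute_sasa()` implements the Shrake–Rupley method directly: each heavy
atom's van der Waals sphere (C 1.70, N 1.55, O 1.52, S 1.80 Å; 1.70 for
anything else) is expanded by the probe radius (default 1.4 Å) and covered
with a golden-spiral lattice of `n_points` (default 960) directions; the
accessible fraction is the fraction of lattice points outside every
neighbouring expanded sphere. The deterministic lattice makes results
bit-reproducible without a seed, and at 960 points an isolated atom matches
the analytic sphere area to well under 0.5 %.

Relative accessibility divides each residue's area by its theoretical
maximum in an extended Gly-X-Gly tripeptide (the Tien et al. reference
table), so values are comparable across residue types; extended termini can
slightly exceed 1. `bridge_burial()` averages the two partners' relative
accessibilities and labels a bridge `buried` below 0.10 and `exposed` above
0.35. These two thresholds are this package's own calibration — the
qualitative targets are that deeply encased pairs rank most buried and
surface pairs (the interloop bridge in particular) label exposed — and both
are exposed as arguments.

## Hallmark profiling and classification

`hallmark_profile()` scores a target row of an alignment against a bridge
catalog through the reference row's column mapping
(`map_reference_positions()`): a pair is `present` when both positions
carry the catalog identities, `substituted` when both preserve their charge
class (D↔E; R↔K↔H — the tolerance observed at the interloop position,
where His and Arg interchange between close homologs), `absent` otherwise,
including gaps.

`interloop_bridge()` applies the (i−2, i−4) rule: from a catalytic triad
(ser, asp, his) it inspects positions asp−2 and his−4 and reports
acid→base, base→acid or absent polarity. Triad positions are supplied, not
discovered: these enzymes' triads are identified by homology, and motif
scanning (GXSXG) is error-prone enough that silent misidentification would
be worse than requiring an annotation. For enzymes whose triad is not
annotated but whose interloop positions are known directly (the Est30 case),
the two positions can be given verbatim via `positions =`.

`classify_subfamily()` turns the qualitative hallmark observations into an
explicit, configurable decision rule, applied in order:

1. ≥ 4 of the 5 N′-exclusive pairs present-or-substituted *and* acid→base
   interloop polarity → `Nprime_familyXV`;
2. ≥ 5 of the 6 N-pattern pairs *and* base→acid polarity → `N_familyXIII`;
3. base→acid polarity *and* an α/β cap *and* fewer than 2 hits in either
   catalog → `LipS_like`;
4. otherwise `unassigned`.

The thresholds (4/5, 5/6, < 2) are the package's own quantification of
hallmarks that are only stated qualitatively in the literature; they are
chosen so that a single knocked-out or unresolved pair does not flip a
call, and they are arguments, not constants. Cap architecture cannot be
derived from sequence alone, so it enters as metadata
(`alpha_beta`/`alpha`/`unknown`, default `unknown`), and rule 3 simply
cannot fire without it. The classifier is a pure function: identical
evidence always yields an identical call.

## Phylogeny

`pairwise_identity()` uses a Needleman–Wunsch global alignment (BLOSUM62,
gap open 10, extend 0.5, via Biostrings) and defines identity as identical
aligned pairs over aligned (both non-gap) pairs with *terminal* gap columns
excluded — so a His-tag or other expression overhang aligns as terminal
gaps and does not depress identity; the mismatch count covers
substitutions only.

`poisson_distance()` computes p-distances with *pairwise* deletion of
gap-containing columns (complete deletion discards signal on ragged
alignments; nothing in the underlying methodology requires it) and applies
the Poisson correction d = −ln(1 − p), the classical correction for
multiple amino-acid substitutions at one site; it is undefined at p = 1 and
the package raises an error naming the offending pair rather than
truncating.

`nj_tree()` is an in-package Saitou–Nei neighbor-joining implementation:
the standard Q criterion, deterministic tie-breaking toward the lowest
(row, column) pair, negative branch lengths clamped to zero with a warning
(standard practice; they arise from non-additivity, and tiny negative
internal branches also appear on near-identical sequences). On additive
matrices it reproduces leaf-to-leaf path lengths to numerical precision
(the suite checks 1e−9), and the independent cross-check in the tests is
`ape::nj`. The result is an `ape` `phylo`, so Newick round-tripping and
plotting come for free.

## Two-state denaturation thermodynamics

The thermal model assumes a reversible two-state equilibrium F ⇌ U
monitored by a linear-in-temperature spectroscopic signal in each state
(sloping baselines y_F(T) = a_F + b_F·T, y_U(T) = a_U + b_U·T):

* f_U = (y_F − y)/(y_F − y_U), f_F = 1 − f_U;
* K = f_U/f_F;
* ΔG = −RT ln K, with R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹ (energies are
  reported in kcal/mol throughout);
* at the midpoint ΔG(T_m) = 0 = ΔH_m − T_m ΔS_m (van't Hoff);
* away from T_m, ΔG(T) = ΔH_m(1 − T/T_m) − ΔC_p[(T_m − T) + T ln(T/T_m)]
  (Gibbs–Helmholtz; with ΔC_p = 0 this is the van't Hoff line).

`linearized_stability()` is the classical graphical pipeline: least-squares
baselines on pre-/post-transition windows, Eqs above on the transition
points, a linear fit of ΔG against T, T_m at the zero crossing,
ΔS_m = −slope, ΔH_m = T_m ΔS_m. Numerical choices:

* **Transition mask f_U ∈ [0.15, 0.85].** Outside this band the ΔG values
  blow up logarithmically and are dominated by baseline error; the band is
  an argument.
* **Baseline windows default to the first/last 15 %** of the temperature
  range when not given; explicit windows should be preferred whenever the
  transition is not roughly centred.
* **Kelvin inside, Celsius at the interface** (conversion constant 273.15);
  baselines are linear in Celsius, which only relabels their intercepts.
* Degenerate inputs fail loudly: crossing baselines, fewer than 3 window
  points, fewer than 3 masked transition points, or ΔG increasing with
  temperature all raise descriptive errors.

`fit_two_state()` fits all six parameters (T_m, ΔH_m, two baselines)
directly to y(T) = [y_F + y_U K]/[1 + K] with
K = exp[(ΔH_m/R)(1/T_m − 1/T)] by Levenberg–Marquardt least squares,
initialized from the linearized fit; on non-convergence the raised
condition carries the linearized fallback. On clean curves the two routes
agree in T_m to well under 0.2 °C, and ΔG evaluated at either fitted T_m
is zero to 1e−9 by construction.

`chem_midpoint()` fits the linear-extrapolation model for chemical
denaturation, ΔG(c) = m(C_m − c), i.e.
f_U(c) = 1/(1 + exp[m(C_m − c)/RT]) mixed between linear baselines, at
fixed temperature (default 298.15 K). Flat or purely linear signals are
rejected before fitting. ΔC_p defaults to 0 everywhere — the workflow's
source data do not constrain it — and `gibbs_helmholtz()` takes it as an
explicit argument instead of hiding an assumed value.

`compare_variants()` reports ΔT_m = T_m(mut) − T_m(ref) in °C and
ΔΔG = ΔG(mut, T) − ΔG(ref, T) at a stated common temperature; numeric
inputs are taken as already-extrapolated ΔG values. Fits carry an optional
pH tag and a mismatch warns: stability differences across pH are not
comparable. The packaged `estgta2_variants()` table keeps the published
per-variant ΔT_m column for reference but the package always computes
shifts from fitted midpoints, because a reported-difference column can be
internally inconsistent with its own T_m columns (the K178A/R220A row is an
example); computed differences are the single source of truth here.
Heating/cooling hysteresis is deliberately not modelled: the package
reports the two scans' fits side by side and defines no hysteresis
statistic.

## Synthetic data: what it emulates, and what it does not

The generators (`synth_structure()`, `synth_melting_curve()`,
`synth_chem_curve()`, `synth_msa_family()`, `synth_tree_data()`) are
first-class, tested code. Their defaults are the study conditions the
reproduction scripts run under: melting curves on a 25–90 °C grid at
0.5 °C steps with ΔH_m = 120 kcal/mol (a typical van't Hoff enthalpy for a
~250-residue globular domain) and distinct baseline slopes; GuHCl curves
on 0–3 M at 0.1 M steps with m = 3 kcal mol⁻¹ M⁻¹ (a typical m-value at
this chain length); Gaussian, homoscedastic noise scaled to the
folded-to-unfolded signal span (2 % in the replicate studies) — the
underlying experiments publish no noise model, and homoscedastic Gaussian
is the neutral choice; hallmark knockout probability 0.1 per bridge,
mimicking alanine shaving of the basic partner.

Planted structures use minimal side chains (the charged atoms plus short
stubs), each pair rigidly rotated at random: sufficient for every contract
of the detector (exact planted minimum distances, rotation invariance,
decoy rejection), but deliberately not rotamer-realistic, not sterically
packed and not polymeric — a detector validated here is validated for its
geometry, not against crystallographic artefacts such as alternate
conformations of real side chains (those are exercised separately through
the PDB reader's altloc policies). Likewise the sequence evolver draws each
substitution uniformly from the 19 alternatives, which makes the
Poisson-corrected distance estimator consistent up to a small back-
substitution bias (order p²/19, far below sampling error at the branch
lengths used), but it does not emulate rate heterogeneity or exchangeability
structure. Melting curves are generated by the same two-state signal
equation the direct fitter assumes; the *linearized* route therefore serves
as the independent recovery path on clean curves, and passing tests show
parameter recovery under the model's assumptions, not robustness to
aggregation, irreversibility or three-state behaviour — all of which are
explicitly out of scope.

Burial fixtures in the test suite encase selected planted pairs in solid
carbon shells to create a known burial ordering; these structures are
labelled synthetic stand-ins wherever they appear, including the stand-in
carrying the eight-bridge inventory of the EstGtA2/MGL system at the
published residue numbers and distances, which the suite uses for
structure-dependent checks in place of a crystal-structure download.

## Problem sizes and determinism

The test suite runs the detector–oracle equivalence on 100 random
structures of ~10 charged residues, SASA convergence on three-pair
structures (~90 heavy atoms, 960 vs 1920 points), NJ recovery on trees of
up to 8 taxa, 100 noisy melting-curve replicates and 1000-site sequence
evolution — sizes chosen so the whole suite completes in well under a
minute while every stochastic assertion retains comfortable margins. All
generators are seeded and platform-stable; the SASA lattice and the NJ
tie-break are deterministic by construction, so every reported number in
the reproduction script is either bit-reproducible (noiseless inputs) or
an average over seeds derived from the single `--seed` argument.

## Known limitations

* PDB input only (fixed-column ATOM/HETATM; first model of multi-model
  files; mmCIF is not supported). Assemblies, symmetry mates and ligand
  chemistry are out of scope.
* Salt-bridge energetics are purely geometric; no continuum electrostatics,
  pK_a prediction or hydrogen-bond geometry beyond heavy-atom distances.
* Cap-domain architecture is consumed as metadata, never derived from
  coordinates.
* The two-state machinery does not model irreversible or multi-state
  unfolding, aggregation at high temperature, or baseline curvature.
* Neighbor joining is the only tree method; no bootstrap supports, no
  likelihood models.
* Relative SASA can exceed 1 for fragmentary synthetic side chains; the
  reference areas assume complete residues.
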