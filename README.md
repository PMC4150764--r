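# tetrdna

Structural and thermodynamic analysis of how TetR-family transcriptional
regulators read their operator DNA.

TetR-family regulators (TetR, QacR, CprB, and relatives) repress
transcription by inserting a helix–turn–helix recognition helix into the
major groove of a short, often semi-palindromic operator. Establishing *how*
a given family member binds requires a set of quantitative readouts that
usually live in four or five separate tools: the DNA's base-pair step
parameters and groove geometry, the inventory of protein–DNA and
protein–protein polar contacts and how the dimeric interface restructures
between the apo and DNA-bound states, the geometry and torsional strain of
inter-monomer disulfides, quaternary dimer-of-dimers metrics and solvent
accessibility, cooperative binding thermodynamics from isothermal titration
calorimetry (ITC), and a genome scan for further operator copies. `tetrdna`
implements that whole tool chain as one tidyverse-style R package, and —
because crystal structures and calorimeter files cannot ship with a package
— pairs every analysis stage with a synthetic-data generator so the full
pipeline is exercisable (and tested) without any download.

## The models at the core

**DNA geometry.** Base reference frames are obtained by least-squares
superposition of standard-geometry bases onto the observed ring atoms (the
standard reference frame used by the 3DNA family of tools); base-pair frames
average the two base frames after flipping the complementary strand, and the
six rigid-body step parameters (shift, slide, rise, tilt τ, roll ρ, twist ω)
come from the mid-step-triad decomposition of the relative rotation
*T* = R_z(ω/2−φ)·R_y(Γ)·R_z(ω/2+φ) with Γ = √(ρ²+τ²), φ = atan2(τ, ρ).
The same algebra run forward is the duplex builder, so
`step_parameters(build_ideal_bdna(...))` is the identity on the requested
helical parameters. Groove widths follow the direct phosphate convention —
minimal cross-strand P–P distance over a fixed offset window, minus 5.8 Å
for two phosphate-group radii — calibrated so an ideal fiber duplex (twist
36.0°, rise 3.38 Å) reports the canonical ideal-B values, 11.7 Å (major) and
5.7 Å (minor).

**ITC.** Injection heats follow the Wiseman isotherm. With total titrant X_t
and macromolecule M_t updated per injection by the displacement-dilution
factor (1 − v/V₀), the free titrant X_f solves the mass balance
X_t = X_f + M_t Σⱼ nⱼ Kⱼ X_f/(1 + Kⱼ X_f) (closed-form quadratic for one set
of sites, bracketed root solve for two), the cumulative heat is
Q_i = V₀ M_i Σⱼ nⱼ ΔHⱼ θ_ij, and the injection heat is
Q_i − Q_{i−1} + (v_i/V₀)(Q_i+Q_{i−1})/2, normalized per mole of injectant.
Fitting minimizes least squares over (log nⱼ, log Kⱼ, ΔHⱼ) by
Levenberg–Marquardt from seeded, dispersed multi-starts; derived quantities
use ΔG = −RT ln K and TΔS = ΔH − ΔG. Concentrations are carried on the
repressor-dimer basis, so n ≈ 0.5 reads "one duplex per two dimers" — the
signature of a dimer-of-dimers ("clamp and click") binding mode, which the
two-sets-of-sites model captures as a weak first and strong second site
class.

**Disulfide strain.** For a cystine bridge the five side-chain dihedrals
(χ1, χ2, χ3, χ2′, χ1′) are measured, handedness is the sign of χ3,
spiral/hook/staple classification follows the sign pattern of (χ2, χ2′)
against χ3, and the torsional strain is
E = 2.0[1+cos 3χ1] + 2.0[1+cos 3χ1′] + 1.0[1+cos 3χ2] + 1.0[1+cos 3χ2′] +
3.5[1+cos 2χ3] + 0.6[1+cos 3χ3] kcal/mol (constants configurable).

**Motif scanning.** Ungapped IUPAC-aware Hamming similarity of a fixed
22-bp operator consensus against every window of both genome strands, with
1-based plus-strand coordinates and Fig.-style `*`/`:`/space conservation
annotation of aligned candidate sites.

## Worked example

```r
library(tetrdna)

## 1. DNA geometry of an ideal operator duplex
dup <- build_ideal_bdna(consensus_cs())       # 22-bp consensus, fiber B-DNA
average_params(step_parameters(dup, "A", "B"))
#>   parameter   mean
#>   rise        3.38      (Å)
#>   twist      36.0       (degrees; shift/slide/tilt/roll ~ 0)
gw <- groove_widths(dup, "A", "B")
mean(gw$major_width, na.rm = TRUE)
#> [1] 11.7                                    # canonical ideal-B major groove
global_bend(build_ideal_bdna(consensus_cs(), roll_profile = 5), "A", "B")
#> [1] 3.58                                    # degrees, end-to-end axis angle

## 2. ITC: simulate a noisy titration and refit it
proto <- titration_protocol()                 # 25 x 1.5 ul, 120 uM into 10 uM
gen <- binding_params(n = 0.52, dh = -10.1, kd_nM = 200)
iso <- simulate_itc(gen, proto, noise_sd = 0.3, seed = 42)
tidy(fit_isotherm(iso, "one-site", n_starts = 10, seed = 1))
#>   site     n  n_se kd_nM  dh_kcal dh_se dg_kcal tds_kcal ds_cal_per_mol_K
#>      1 0.516 0.012  157.    -9.78 0.307   -9.28   -0.502            -1.68
autoplot(fit_isotherm(iso, "one-site"))       # isotherm + fitted curve

## 3. Genome scan for a planted, degenerate operator copy
g <- generate_genome(10000, gc_fraction = 0.72,
       plants = tibble::tibble(motif = consensus_cs(), position = 4321,
                               strand = "+", mismatches = 2), seed = 11)
scan_motif(g, consensus_cs(), min_score = 18)
#>   record start  end strand score subsequence
#>   seq     4321 4342 +         20 ACATACGAGACGCCCCGTTTTT
```

The fitted table reads: roughly half a duplex bound per repressor dimer
(n ≈ 0.52), dissociation constant of order 200 nM recovered within the
noise, binding driven by a large negative enthalpy, and ΔG/TΔS derived at
the protocol temperature. The scan returns the planted window with a score
of exactly 22 − 2 mismatches = 20.

Interface work runs the same way: `find_polar_contacts()`,
`classify_dna_contacts()` (base vs phosphate-backbone), `diff_interface()`
(disrupted / formed / retained ledger between apo and bound states),
`disulfide_geometry()`, `sasa()`, `dimer_dna_angle()`, and
`run_full_report()` bundles every stage into one deterministic JSON + TSV
report.

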