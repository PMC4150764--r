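---
title: "Methods: operator recognition analysis with tetrdna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: operator recognition analysis with tetrdna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetrdna)
```

`tetrdna` analyzes how a TetR-family repressor engages its operator DNA. A
typical study of such a system produces a moderate-resolution crystal
structure of the protein–DNA complex, an apo structure for comparison, ITC
titrations against one or more operator candidates, and a genome scan for
further binding sites. This vignette is the package's own account of the
models behind each stage, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate, and
the numerical choices and limitations a careful user should know about.

## 1. Structures and the atom-table model

Structures are tibbles with one row per atom (chain, residue number and
name, atom name in PDB convention, element, coordinates in ångström,
occupancy, B-factor, water flag), in file order. PDB parsing and writing go
through `bio3d`; the package resolves alternate locations to the
highest-occupancy conformer (ties by file order), retains waters but flags
them, and accepts both `DA/DC/DG/DT` and bare `A/C/G/T` nucleotide names.
Hydrogens are kept when present but ignored by every geometric operator —
the structures this package targets are solved at resolutions where
hydrogens are not observed, which is also why hydrogen-bond detection below
is heavy-atom-only. All user-facing residue numbering is 1-based (PDB
convention).

Watson–Crick pairing (`pair_duplex()`) uses three criteria: base
complementarity, C1′–C1′ distance within 8.9–11.9 Å, and the glycosidic-face
heavy-atom distance (purine N1 to pyrimidine N3) at most 3.5 Å. Candidate
pairs are accepted greedily by hydrogen-bond distance, each residue pairing
at most once; unpaired terminal nucleotides are reported as overhangs, which
mirrors how disordered terminal bases in real structures drop out of
helical-parameter averages.

## 2. The fiber builder and base-pair geometry

### Base templates and frames

Base heavy atoms are stored in the standard nucleic-acid base-pair reference
frame: pair origin on the pseudo-dyad, x into the major groove, y along the
long base-pair axis toward the strand-I backbone, z along the helix advance.
A complementary base generated by the flip (x, y, z) → (x, −y, −z) forms an
ideal Watson–Crick pair (glycosidic N1–N3 2.96–3.00 Å, C1′–C1′ 10.7 Å). A
base frame for an observed residue is the Kabsch least-squares superposition
of the standard base onto the observed ring atoms, with the fit RMSD
reported; a base-pair frame averages the two base frames (complementary
frame flipped first, rotation average by orthogonal projection).

### Step parameters

The six step parameters come from the mid-step-triad (CEHS) construction:
the relative rotation between consecutive pair frames is decomposed as
`Rz(ω/2−φ) Ry(Γ) Rz(ω/2+φ)` with bend magnitude Γ and phase φ, giving
roll = Γ cos φ (about y), tilt = Γ sin φ (about x) and twist ω (about z);
the displacement is expressed in the mid-step triad to give shift, slide and
rise. The duplex builder (`build_ideal_bdna()`) runs exactly this algebra
forward, so the analyzer applied to a built duplex returns the requested
parameters to numerical precision — the central generator/analyzer
round-trip property the test suite asserts for roll in ±8°, and the reason
synthetic duplexes are trustworthy fixtures for everything downstream. Two
consequences of the shared convention are worth knowing: reversing the two
strands negates tilt (and shift) while preserving twist, rise and roll, and
every quantity is rigid-body invariant.

The backbone of a built nucleotide is deliberately schematic: correct atom
names, a phosphorus placed at a calibrated position in the pair frame, and
the remaining sugar atoms interpolated. That is sufficient for every P-based
metric and for contact-classification fixtures, and is not intended for
refinement-grade stereochemistry or force-field work.

### Groove widths and the 11.7 Å anchor

Groove widths use the direct phosphate convention: at each base-pair level
the minimal cross-strand P–P distance over a fixed window of partner-strand
levels, minus 5.8 Å for two phosphate-group radii. The windows (major:
partner levels l−1…l+3; minor: l−6…l−3) and the template phosphorus position
were calibrated once so that the default fiber duplex (twist 36.0°, rise
3.38 Å) reports 11.7 Å for the major groove and 5.7 Å for the minor groove —
the canonical ideal-B values — with the window minima interior, not at a
window edge. Levels whose window leaves the duplex (or that lack a
phosphate, e.g. 5′ termini in deposited structures) are flagged not
measurable rather than extrapolated. Because the convention is anchored to
the ideal-B reference rather than to any particular program's refined
definition, absolute widths on real, strongly deformed DNA may differ from
spline-based conventions by a few tenths of an ångström; *changes* in width
(widening at the recognition site, compensatory narrowing next door) are
robust.

### Global bend

Two bend definitions are exposed. The default, end-to-end definition takes
the local helical-axis direction of the first three and last three base
pairs — the normalized mean of their frame z-axes — and reports the angle
between them. The alternative (`method = "cumulative"`) sums per-step bend
magnitudes √(roll²+tilt²). They answer different questions: a uniform 5°
roll on every step of a 22-mer coils the duplex into a superhelix whose
end-to-end axis angle is ≈3.6° even though the cumulative bend is 105°; a
single 10° kink gives 10° under both. Both are provided because an
"overall bend" quoted for a crystal structure can be computed either way,
and the difference matters exactly in the smoothly-curved regime.

## 3. Interface analysis

Polar contacts are heavy-atom donor–acceptor pairs within a cutoff
(default 3.5 Å), using fixed chemical dictionaries for the 20 amino acids
and 4 deoxynucleotides. With no hydrogens there is no angular criterion, and
histidine/amide nitrogens that are ambiguous at such resolutions are listed
as both donor and acceptor. Three cutoffs appear in the package and are kept
strictly separate: 3.5 Å for hydrogen-bond-quality polar contacts; 3.9 Å for
the loose all-heavy-atom "contact" inventory (`find_close_contacts()`) used
for base-vs-backbone totals that mix hydrogen bonds with van der Waals
packing — such counts are reported separately and never called hydrogen
bonds; and 5.5 Å ring-centroid distance for aromatic stacking flags
(`detect_stacking()`), likewise excluded from polar counts. DNA atoms are
classified as backbone when primed or in the phosphate group, base
otherwise, matching the base/phosphate dichotomy used in contact maps.

`diff_interface()` keys contacts by (chain, residue, atom-name) pairs after
applying a chain correspondence map, and partitions the union into
disrupted (apo only), formed (bound only) and retained (both), always
reporting the distance in *both* states — including beyond the cutoff, so a
broken bond shows its new separation. Two identities hold by construction
and are property-tested across random fixtures: disrupted ∪ retained equals
the apo contact set, and formed ∪ retained equals the bound set.

`make_toy_complex()` generates paired apo/bound structures with a prescribed
ledger (counts of retained/disrupted/formed pairs, jittered bond distances,
broken pairs separated beyond the cutoff by construction) so the diff can be
validated against exact ground truth at any size.

## 4. Disulfide geometry, quaternary metrics and surface area

A cystine bridge yields the five dihedrals χ1, χ2, χ3, χ2′, χ1′; handedness
is the sign of χ3 (left-handed when negative); the spiral/hook/staple class
follows whether the signs of χ2 and χ2′ agree with χ3 (both: spiral;
neither: staple; mixed: hook). Torsional strain is the standard six-term
cosine expression with constants (2.0, 2.0, 1.0, 1.0, 3.5, 0.6) kcal/mol,
exposed via `disulfide_energy_constants()` because published server
implementations differ slightly in their constant sets; a ±15% band is the
right way to compare against values computed elsewhere.
`build_disulfide_model()` constructs a cystine with exact requested
dihedrals (internal-coordinate chain extension), which is how the
classification and the closed-form energy are tested.

The dimer-of-dimers angle takes the centroid of all DNA heavy atoms as the
pivot and measures the angle between rays to the Cα centroid of each dimer.
Published figures of this kind rarely state whether centroids are Cα-only,
all-atom, or DNA-binding-domain-only, so the angle is reported as a
descriptive quantity and not asserted against any particular published
value.

Solvent-accessible surface area is Shrake–Rupley quadrature with a
deterministic Fibonacci-spiral point set (default 960 points/atom), probe
1.4 Å, and a fixed radius table (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å).
Determinism makes totals exactly reproducible; the price is that rigid-body
rotation changes which quadrature points are buried, so totals are invariant
only to quadrature accuracy (≈1% at 960 points — the tests budget for
this). Exact agreement with areas from other programs (different radii,
different point sets) is explicitly not promised; inequalities and
differences are the robust quantities.

## 5. ITC: one and two sets of sites

The Wiseman-isotherm model and its conventions are described in the README;
three design choices deserve explanation.

*Dimer basis.* The cell concentration default is 10 µM of repressor
*dimer* — half of a 20 µM monomer preparation — so a fitted n of ≈0.5 reads
"one duplex per two dimers", the natural number for a dimer-of-dimers
binder. Because simulation and fitting share the convention, parameter
recovery is basis-independent.

*Injection schedule.* Instrument methods files rarely survive into
publications; the default protocol (25 × 1.5 µl from a 120 µM syringe into
a 200 µl cell at 298.15 K) reaches a molar ratio of ≈2.5 per dimer, which
spans the equivalence point of every parameter set the package targets. It
is fully configurable, and a first-injection drop flag is deliberately *not*
hard-wired: discard injection 1 yourself if your instrument warrants it.

*Fitting.* Optimization runs over (log n, log K, ΔH) so positivity is
structural; multi-starts draw Kd log-uniformly in 1 nM–10 µM, n log-uniformly
in 0.1–2 and ΔH uniformly in ±30 kcal/mol; Levenberg–Marquardt polishes each
start and the best optimum wins, with site classes reordered weakest-first
(Kd₁ > Kd₂) for the two-site model. The loop stops early once a fit reaches
RSS < 1e−18 — a machine-precision optimum that no further start can improve —
which matters only for noise-free data. Standard errors are asymptotic
(J'J)⁻¹ values delta-transformed to the natural scale; for noise-free
recovery they are numerically zero and meaningless, for noisy data the
log-scale 95% interval on K covers the generating value at close to nominal
rate (the suite checks ≥90% over 50 replicates at 0.3 kcal/mol noise).
Model choice between one and two site classes is reported via a
small-sample-corrected information criterion in `glance()`; the package
never auto-selects.

The free-ligand mass balance is solved in closed form (one site) or by a
bracketed monotone root solve (two sites) to a relative residual of 1e−10,
property-tested over random parameter draws. Two identities pin the model
down: heats are linear in each ΔH, and a two-site model with equal K and ΔH
is indistinguishable from a one-site model with n = n₁+n₂ (asserted at
1e−9).

*A note on published entropy values.* ΔS is derived (ΔS = (ΔH − ΔG)/T, ΔG =
−RT ln K), not fitted. Published captions sometimes quote a (Kd, ΔH, ΔS)
triple that is not exactly self-consistent after rounding; the package
always reports the self-consistent derived value, and its tests assert
recovery of the entropy implied by the generating (Kd, ΔH) pair.

## 6. Genome scanning

Scoring is ungapped match counting with IUPAC degeneracy on the consensus
side — the search a fixed-length operator consensus calls for, with no
alignment gaps. Both strands are scanned by matching the
reverse-complemented consensus against the same plus-strand windows;
coordinates are always 1-based inclusive on the plus strand, with the hit
subsequence reported as read on its own strand (stated this explicitly to
avoid off-by-one drift). No similarity threshold is endorsed: `min_score`
is a required argument, because the right threshold depends on genome size
and GC content. `annotate_conservation()` renders the `*` (all agree),
`:` (two agree) and space annotation used in published alignments of
candidate sites. A position-weight-matrix mode is out of scope by design —
with a single consensus and a handful of confirmed sites there is nothing
to train.

`generate_genome()` plants motif copies with an exact mismatch count at
chosen positions/strands into an i.i.d. background of chosen GC content.
Real intergenic sequence is not i.i.d. — it has repeats, skews and
composition structure that inflate high-scoring background windows — so a
passing scan test shows coordinate/strand/score correctness, not a
false-positive rate for real genomes.

## 7. What the synthetic generators do and do not establish

Every generator is a pure function of its parameters and seed (seeds are
consumed locally; the global RNG stream is untouched). The fiber duplex has
exact standard-geometry bases, no sequence-dependent geometry, no solvent;
the toy complexes have idealized isolated donor/acceptor pairs; the ITC
simulator adds i.i.d. Gaussian noise with no baseline drift or
first-injection artifact. Green tests on these fixtures therefore establish
that the *algorithms* are correct against closed-form and brute-force
oracles, and that the analysis inverts the generator exactly. They do not
certify behavior on refinement artifacts, alternate conformations,
correlated calorimeter noise or repetitive genomes. Assertions that require
the deposited reference structures (center-to-center distance, mean
twist/roll of the bound operator, disulfide strain of the apo bridge, SASA
inequality, specific disrupted interface pairs) are implemented in the
acceptance tests but run only when the user supplies the coordinate files —
they are reference data, not package fixtures.

## 8. Problem sizes and numerical choices

The shipped tests run on a 22-bp duplex (the operator consensus length),
toy complexes up to ~20 bonded pairs, 100-complex and 50-genome property
sweeps (genomes of 200–10 000 bp), 25-injection titrations with 50-draw
recovery sweeps, and 960-point SASA quadrature (reduced to 120–480 points
inside report tests). These sizes were chosen so every oracle is exactly
checkable; all operations scale to structure-sized inputs (the SASA loop is
O(N·k) in atoms times neighbors, the scanner is vectorized per consensus
position). Ties and degenerate inputs are handled explicitly: altloc ties go
to file order, near-parallel frame averaging falls back cleanly, Γ→0 steps
take φ=0, unpaired overhangs are skipped, and every domain error names the
offending chain/residue/atom.

## 9. Known limitations

- The schematic backbone means built duplexes are not inputs for
  refinement, docking or force-field scoring.
- Groove widths on strongly deformed real DNA follow the direct-P
  convention, not spline-fit conventions; compare trends, not third
  decimals.
- SASA totals depend on the radius table and point count; only differences
  and inequalities are convention-free.
- Polar-contact detection is distance-only by design at moderate
  resolution; at atomic resolution with hydrogens an angular term would be
  appropriate and is not provided.
- The two-site fitter recovers noise-free parameters exactly, but with
  realistic noise the (n₁, n₂, K₁, K₂) posterior is strongly correlated;
  treat single-experiment two-site standard errors with caution.
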