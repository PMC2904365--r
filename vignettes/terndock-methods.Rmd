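---
title: "Modelling TCR-peptide-MHC ternary complexes by docking and filtering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling TCR-peptide-MHC ternary complexes by docking and filtering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terndock)
```

## The modelling problem

A T-cell receptor (TCR) recognizes a peptide presented in the groove of
an MHC molecule.  When no crystal structure of a particular ternary
complex exists, a working model can be built by rigid-body docking of
the TCR variable domain onto the peptide/MHC complex, followed by
aggressive filtering of the candidate poses with biochemical knowledge,
and ranking of the survivors.  `terndock` implements that pipeline as
reusable, tested components:

1. **FFT shape-complementarity docking** (`dock()`): the receptor is
   held fixed, the probe domain is rotated through a deterministic
   angular sweep and, for each rotation, all grid translations are
   scored at once by a fast Fourier transform correlation.
2. **Coulombic binary filter** (`electrostatic_screen()`): poses with
   net repulsive screened electrostatics are discarded.
3. **Distance-constraint filter** (`apply_constraints()`): the
   two-step model of TCR binding says CDR1/CDR2 loops engage the MHC
   helices first and the CDR3 loop then folds over the central peptide.
   Constraints written in a compact notation (`"30D:A 50D:B
   (97-98)D:P"`: residue 30 of probe chain D within the cutoff of MHC
   chain A, and so on) encode this.
4. **Register filter** (`apply_register_filter()`): a pose survives
   only if the peptide residue nearest the CDR3 apex centroid carries
   one of the allowed register labels (typically the central P5/P6
   positions).  This operationalizes what is otherwise a visual
   inspection step, and is flagged as such in reports.
5. **Ranking** (`rank_survivors()`): survivors are rescored with a
   pairwise 6-12 Lennard-Jones + screened-Coulomb interaction energy
   and with the buried interface area; the selected model maximizes
   both (with a rank-sum fallback when no pose dominates).

Interface characterization (`interface_report()`, `vdw_contacts()`,
`hbonds()`, `frame_rmsd()`/`frame_rmsf()`) and a simplified
computational alanine scan (`scan_interface()`) analyse the final
model, including multi-model PDB trajectories.

## The docking grid model

Both molecules are digitized onto an $N^3$ grid (default $N = 64$,
1.0 Å per cell; published applications of this class of method use
finer settings such as $246^3$ at 0.69 Å — the parameters are exposed
in `dock_params()` and the algorithm is identical at any size).  A
cell is occupied when its centre lies within an atom's radius.  For
the *static* molecule, occupied cells within `surface_thickness`
(default 1.3 Å) of an unoccupied cell form the surface layer (value
1); the remaining interior takes the penalty value $\rho$ (default
$-15$).  The *mobile* molecule is 1 on all occupied cells.  The score
of a relative translation $\mathbf{t}$ is the correlation

$$S(\mathbf{t}) = \sum_{\mathbf{c}} A(\mathbf{c} + \mathbf{t})\,
  B(\mathbf{c}),$$

evaluated for all $N^3$ translations simultaneously via forward and
inverse FFTs and rounded to integers.  Large positive scores mean good
surface-surface complementarity; penetration of the static core is
penalized by $\rho$; zero means no contact.  Grids are sized so that
the combined extents never wrap around the periodic FFT box; `dock()`
refuses configurations that would.

Rotations are swept deterministically: axis directions on a
golden-section spiral whose mean spacing equals `rotation_step`
(default 15°), each combined with twist angles in `rotation_step`
increments.  The identity rotation is always the first element, and
the whole sweep is seed-independent, which makes docking runs
bit-for-bit reproducible.  Per rotation the best `best_per_rotation`
(default 3) translations are pooled; the top `n_poses_kept` (default
10,000, matching common practice for this method family) are returned.

Two implementation details are worth noting.  First, two rotations are
evaluated per complex FFT by packing their real-valued grids into the
real and imaginary parts of one array; because the correlation of real
grids is real, the two score lattices separate exactly into the real
and (negated) imaginary parts of the inverse transform.  This is an
exact identity, not an approximation, and it halves the transform
count.  Second, ties in shape score are broken by lower rotation
index, then lexicographic translation, so pose ranks are reproducible.

## Energies, surfaces, hydrogen bonds

**Parameterization.** Radii are a NACCESS-style united-atom set keyed
by element (C 1.87, N 1.65, O 1.40, S 1.85, H 1.00 Å).  Charges are
residue-level formal charges (Asp/Glu $-0.5$ per carboxylate oxygen,
Lys $+1$, Arg $+0.5$ per terminal nitrogen, His neutral).
Lennard-Jones well depths and minimum-energy distances are a compact
element-level set with Lorentz-Berthelot combination.  These choices
are recorded in `inst/extdata/` and are deliberately simple: absolute
energies are comparable only *within* this parameterization, which is
sufficient for ranking poses of the same pair of molecules.  They are
not expected to reproduce the output of any particular molecular
mechanics package.

**Electrostatics** use a distance-dependent dielectric
$\varepsilon(r) = 4r$, a standard implicit-screening choice for
structures lacking explicit solvent, giving
$E = 332.0637\, q_i q_j / (4 r^2)$ kcal/mol.

**Accessible surface area** is computed by Shrake-Rupley sampling with
a deterministic golden-section spiral of `n_points` (default 960)
points per atom and probe radius 1.4 Å.  Being seed-free, ASA values
are bit-for-bit reproducible at fixed `n_points`; 960 points give
isolated-atom areas within 0.5 % of $4\pi(r+p)^2$ and two-sphere
burial within 1 % of the closed-form cap formula, while 4,000+ points
are available when tighter convergence is wanted.  The buried
interface area is reported as the total over both sides,
$\mathrm{ASA}(A) + \mathrm{ASA}(B) - \mathrm{ASA}(AB)$, which for a
TCR-Vβ/pMHC-sized interface is on the order of 850-1,700 Å².

**Hydrogen bonds** follow the trajectory-analysis convention: donor to
acceptor at most 0.35 nm and hydrogen-donor-acceptor angle at most
30°.  Occupancy is the percentage of frames (reported to 0.01 %) in
which a bond is present.  When a donor has no hydrogen, a heavy-atom
fallback (donor-acceptor ≤ 0.35 nm and antecedent-donor-acceptor angle
≥ 120°) is used and the row is marked `inferred`.

**Alanine scanning** (`scan_interface()`) truncates each interface
residue of the probe side beyond Cβ, recomputes the interaction
energy, and reports $\Delta\Delta G_\mathrm{proxy} = E_\mathrm{mut} -
E_\mathrm{wt}$ with hotspots called at ≥ 1 kcal/mol.  This is an
explicit simplified stand-in for trained alanine-scanning energy
functions: no side-chain repacking is performed (keeping the proxy
deterministic and oracle-testable) and the per-residue values carry
the package's own energy model, so only the hotspot concept and the
threshold semantics — not published per-residue values — should be
compared.  Gly and Pro are excluded as not scannable, per the standard
convention; mutations are restricted to one designated side of the
interface so that a salt bridge is attributed to the residue being
scanned.

## The synthetic benchmark

Because real modelling studies of this kind start from coordinates
that are not redistributable (homology models, private trajectories),
every stage here is exercised on a generated benchmark
(`make_benchmark()`) with planted ground truth:

* a **receptor** with MHC-II-like architecture: two groove-flanking
  helices (chains A and B, with two-layer floor slabs so that the
  docking grid has a genuine core), and an extended 13-residue
  **peptide** (chain P, residues 261-273) with register labels
  P-2..P11, P1 at residue 263;
* a **probe** domain (chain D): three short helices, a CDR3-like loop
  (residues 96-102) dipping into the groove, CDR1/CDR2 contact
  residues 30 and 50 facing the two helices;
* planted, exactly constructed features: a Lys97(D)-Glu266(P) salt
  bridge (the unique energetic hotspot), a Ser100(D) OG → Gln267(P)
  OE1 hydrogen bond with ideal geometry, and contacts satisfying the
  constraint set `"30D:A 50D:B (97-98)D:P"` at 4.5 Å.

The probe's binding face is *molded* onto the receptor: glycine filler
residues are placed programmatically on the receptor's 3.5 Å offset
surface across the interface window.  This constructs what evolution
constructs in real complexes — a binding face complementary to the
target — and it is what makes the planted pose the shape-complementarity
optimum that docking is expected to find.  The native pose is the
identity transform (redocking convention), so the deterministic
rotational sweep contains the native rotation exactly and recovery is
limited only by the 1 Å translation lattice.

What the benchmark does **not** emulate: real side-chain packing and
rotamer flexibility, solvent, backbone strain (filler and side-chain
placements prioritize exact planted distances over ideal covalent
geometry, and bond lengths within planted side chains can deviate
from ideal values), and the conformational changes that docking of
separately modelled structures has to absorb.  Passing the planted
recovery tests therefore demonstrates the correctness of the machinery
— grids, transforms, filters, scores, bookkeeping — not docking
accuracy on real unbound structures.

`make_decoys()` produces clash-free random placements (minimum
inter-part distance between 1.5 and 3.6 Å), with a manifest recording
which planted filters each decoy violates, computed by direct distance
loops.  `make_trajectory()` produces multi-frame structures with
Gaussian coordinate noise (default σ = 0.3 Å, chosen to stay below
the hydrogen-bond criteria margins so planted occupancies are not
corrupted) and enforces the planted hydrogen bond in exactly
`round(n_frames × occupancy)` frames.

## Numerical and design choices

* **Problem sizes.** Shipped tests and the acceptance script dock on a
  64³ grid at 1.0 Å with a 15° sweep (≈ 5,000 rotations), evaluate 20
  decoy seeds of 50 decoys each, and use 960-point ASA sampling;
  these sizes were chosen so a complete verification runs on a single
  CPU in minutes while leaving every algorithmic path identical to a
  full-resolution run.
* **Constraint semantics.** "Distance between a residue and a chain"
  is the minimum over all atom pairs, hydrogens included when present
  (a heavy-atom-only flag exists); the inequality is strict (< cutoff),
  so boundary equality fails.
* **Filter staging** (`mode = "staged"`) applies MHC-facing
  constraints before peptide-facing ones and reports per-stage
  survivor counts; the final survivor set is provably identical to
  unstaged filtering — staging only affects reporting.
* **"Largest binding energy"** is interpreted as largest magnitude,
  i.e. most negative interaction energy, consistent with how docking
  studies tabulate it.  The joint ranking rule prefers a pose that is
  maximal in both energy magnitude and interface ASA; when no such
  double maximizer exists the rank-sum fallback is used and the
  rationale string says so.
* **No pose minimization.** Published pipelines of this type
  energy-minimize survivors before ranking; `terndock` rescores
  rigidly instead, because minimization belongs to an external engine
  and is out of scope.  The ranking interface is unchanged, so a
  minimization step can be inserted between filtering and ranking by
  the caller.
* **Electrostatic filter placement.** The Coulombic screen is applied
  to the pose list after truncation to `n_poses_kept`
  (config-switchable), since the method description leaves the order
  ambiguous.
* **Residue numbering** is treated as opaque: constraint and register
  specifications take residue numbers verbatim from the caller, and
  no renumbering between schemes is attempted.
* **Degenerate inputs.** Empty structures, missing chains/residues in
  constraints, frame/atom mismatches, and over-extent grids raise
  errors; an empty survivor set at any pipeline stage is reported
  (with the emptying stage named), not thrown.

## Known limitations

* Rigid-body only: no soft docking, side-chain flexibility, or pose
  refinement.
* The energy model is intentionally minimal; its absolute values are
  not transferable outside the package.
* The register filter assumes the caller supplies the register map
  (e.g. which peptide residue is P1); it is never inferred from
  sequence.
* PDB support covers ATOM/HETATM/MODEL records with altloc 'A' or
  blank; mmCIF is out of scope.
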