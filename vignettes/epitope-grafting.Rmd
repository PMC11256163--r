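---
title: "Stacked epitope grafting onto beta-solenoid scaffolds: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked epitope grafting onto beta-solenoid scaffolds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigraft)
```

## The problem

Amyloid fibrils of alpha-synuclein — the pathological species in
Parkinson's disease, dementia with Lewy bodies and multiple system
atrophy — display *conformational* surface epitopes: residues that are
far apart in sequence but adjacent on the fibril surface, where identical
chains stack in a parallel in-register cross-beta arrangement spaced
~4.8 Å along the fibril axis. Antibodies raised against linear peptides
cannot distinguish this surface from the natively unfolded monomer, which
is why an immunogen must *present the fibrillar surface geometry itself*
while being otherwise innocuous.

The engineering route implemented here grafts such a surface patch onto
the prion-forming domain HET-s(218–289) of *Podospora anserina*. That
domain folds into a left-handed, two-rung beta-solenoid: each rung is one
helical turn of four beta-strands, successive rungs are ~4.8 Å apart, and
in the fibril every molecule stacks with the same register. Because rung
geometry mimics cross-beta stacking, placing a donor residue on *both*
rungs of the solenoid (positions $p$ and $p + \Delta$, where $\Delta$ is
the rung pseudo-repeat offset) makes the self-assembled scaffold fibril
display an uninterrupted column of that residue — exactly what two
stacked donor molecules would display. We call this the **stacked
graft** rule; dropping substitutions whose target already carries the
donor residue (**identity-dropping**) is its natural complement and
explains why published substitution lists can be asymmetric between
rungs.

## The procedure

For a scaffold structure and a donor fibril structure the pipeline is:

1. **Geometry** (`estimate_fibril_frame`, `segment_strands`,
   `check_in_register`): fit the screw transformation (axis, rise, twist)
   relating consecutive repeats by least squares over all corresponding
   C-alpha pairs; segment strands from backbone dihedrals; verify the
   donor is parallel and in register.
2. **Rung register** (`detect_rung_offset`): scan candidate offsets
   $\Delta$, superposing C-alpha($i$) onto C-alpha($i+\Delta$) over the
   maximal overlapping window; the lowest-RMSD offset below the solenoid
   threshold wins, ties toward smaller $\Delta$.
3. **Surface** (`compute_sasa`, `classify_exposure`,
   `fibril_context_exposure`): Shrake–Rupley solvent accessibility with a
   deterministic golden-spiral point set; graftable sites must not be
   buried, and exposure is scored in fibrillar context by stacking copies
   of the repeating unit and scoring the middle one.
4. **Design** (`extract_epitope`, `site_mapping`, `superpose_epitope`,
   `design_stacked_graft`, `validate_design`): donor residues are
   assigned to rung-1 positions only; rung-2 positions always derive
   through $\Delta$. Each donor residue $x$ mapped to $p$ emits
   substitutions $(p, \mathrm{wt}(p) \to x)$ and
   $(p+\Delta, \mathrm{wt}(p+\Delta) \to x)$ unless identity-dropped.
   Geometric acceptance is backbone-level only: C-alpha RMSD of the
   epitope superposition (Kabsch, proper rotations only), exposure
   fraction, and face parity.
5. **Constructs** (`apply_design`, `render_report`, `load_preset`): the
   edited sequence (never an indel), plus JSON/FASTA/TSV reports. The
   four published vaccine candidates α-SC3, α-SC6, α-SC8 and α-SC9 ship
   as verbatim presets.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| probe radius | 1.4 | Å | water-sized probe, the universal SASA convention |
| sphere points | 960 | — | <2 % error on an isolated atom; deterministic golden spiral, no RNG |
| relative-SASA reference | Gly-X-Gly maxima | — | frozen table (Tien et al. 2013 theoretical values) |
| exposed / buried thresholds | 0.25 / 0.05 | rel. SASA | common practice; the design rule only excludes *buried* sites |
| rung RMSD threshold | 3.0 | Å | the solenoid pseudo-repeat is approximate, not exact |
| minimum aligned window | 15 | residues | roughly half a rung; prevents spurious short-window fits |
| register tolerance | 2.4 | Å | half the canonical 4.8 Å rise; separates a one-residue shift cleanly |
| strand windows | φ ∈ [−180°, −45°], ψ ∈ [45°, 225°] | deg | dihedral-based assignment works on backbone-only models, no H-bond inference |
| min strand length | 3 | residues | shorter runs are turns, not strands |

All are exposed as function arguments; the defaults are the package's
study conditions.

## Scaffold sequence and the published designs

The scaffold sequence (72 residues, author numbering 218–289) is bundled
with the package and is the source of truth for wild-type letters. The
four preset substitution lists constrain 18 of those letters and agree
with the bundled sequence at every position except one: the α-SC3 rung-2
entry **K269G**. Under the stacked-graft rule the rung-2 partner of
E234G is position 270 (and the scaffold has K270, G269), so the
published entry is internally inconsistent with the other three designs;
whether it is a typo for K270G cannot be decided from the published
lists alone. The preset therefore stores K269G verbatim and
`validate_design` flags both the wild-type conflict at 269 and the rung
asymmetry — the package reports such conflicts, it never silently
corrects them.

Donor provenance is recorded where published (α-SC3 from the ssNMR
fibril structure, α-SC6 from the cryo-EM structure) and `"unknown"`
otherwise; the donor residue numbering behind each design is not
published, so presets are regenerated from donor residue *identities*
read off the lists, via `epitope_patch()`.

## What the synthetic generators emulate — and what they do not

`make_ideal_solenoid` and `make_in_register_fibril` build idealized
coordinates from canonical bond lengths/angles and two frozen torsion
basins (strand: φ = −139°, ψ = +135°; turn: φ = +80°, ψ = +60°, the
left-handed basin typical of tight turns, chosen once so that a rung
stays flat enough to stack without steric overlap at a 4.8 Å rise). Rung
$k$ (or chain $k$) is rung 0 rotated by $k\,\cdot$ twist and translated
$k\,\cdot$ rise, so the generator parameters are *exact* ground truth
for every geometry operation. Generation is pure arithmetic: there are
no random seeds anywhere in the package.

`scaffold_structure()` is a synthetic stand-in for the experimental
two-rung solenoid: it carries the real HET-s(218–289) sequence on an
idealized 36-residue-per-rung lattice (offset 36, four strands per
rung), with the grafted surface sites placed on one long strand per
rung. `donor_fibril_structure()` likewise stacks idealized extended
copies of the real alpha-synuclein sequence. These stand-ins reproduce
the *architectural* facts the design procedure uses — rise, twist,
register, rung offset, strand parity, relative exposure — but not the
experimental fold of either protein: loop conformations, side chains
beyond C-beta, and the donor's Greek-key core are absent. Passing tests
therefore demonstrate that the procedure recovers known architecture and
reproduces the published sequence-level designs; they do not re-measure
the experimental structures.

## Numerical choices

* **Superposition** is Kabsch via SVD with the determinant correction,
  so reflections are never admitted; fewer than three pairs is an error.
* **Screw decomposition**: the rotation angle comes from the fitted
  rotation matrix, the rise is the translation component along the
  rotation axis; for twist → 0 the axis is taken along the translation
  (the rotation eigenvector is numerically undefined there). The axis is
  oriented so the rise is positive, and the twist sign follows it
  (negative = left-handed).
* **Register deviation** is the full 3-D deviation of each residue's
  chain-to-chain C-alpha displacement from the ideal screw step. A
  purely axial criterion cannot see a *lateral* register slip (a chain
  shifted by two residues along its own strand moves sideways, not
  axially), so the 3-D form is what "residue i sits directly above
  residue i" actually requires.
* **Rung-offset ties** within 0.01 Å (above coordinate-precision
  noise) go to the smaller offset, which
  keeps exact multiples of the repeat (2Δ, 3Δ, …) from winning on
  floating-point noise.
* **Fibril-context SASA** stacks five copies (`rise_multiple = 2` for a
  two-rung solenoid, since one molecule spans two rungs) and scores the
  middle copy while all copies occlude. With a nonzero twist the
  golden-spiral lattice samples rotated copies slightly differently
  (≲1 Å² per residue); the middle-versus-end occlusion inequality is
  exact for untwisted stacks.
* **Degenerate inputs** error loudly: truncated coordinate records,
  empty selections, chains without shared numbering, non-standard donor
  residues ('X'), out-of-range positions, wild-type conflicts in strict
  mode.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on the
72-residue scaffold model (350 heavy atoms; 1750 when stacked five-fold
for context scoring), a 140-residue five-chain donor model, and a
3 × 3 × 3 generator parameter grid (rise 4.6–5.0 Å, twist ±5°, two to
five rungs) — sizes at which every computation, including all SASA
scoring, completes in well under a minute on one CPU. These sizes were
chosen because the procedure's outputs (offsets, substitution lists,
register verdicts) are discrete and already fully exercised at them.

## Known limitations

* No side-chain repacking, clash scoring, electrostatics or stability
  prediction — the published screen for fold integrity was experimental
  (circular dichroism), and anything beyond backbone-level geometric
  acceptance would be invention.
* No automated epitope discovery: the user (or a preset) names the donor
  residues.
* Assembly beyond the chains/models present in the input is limited to
  helical stacking of rigid copies; no protofilament-interface analysis.
* mmCIF support covers the `atom_site` loop (the coordinate payload),
  not the full dictionary.
* The synthetic stand-ins cannot validate claims that depend on the
  experimental folds, as discussed above.
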