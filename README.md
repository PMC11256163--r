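# epigraft

Structure-based design of conformation-specific immunogens by **stacked
epitope grafting** onto beta-solenoid scaffolds.

Amyloid fibrils of alpha-synuclein (Parkinson's disease, dementia with
Lewy bodies, multiple system atrophy) stack identical chains in a
parallel in-register cross-beta arrangement, residue *i* directly above
residue *i*, spaced ~4.8 Å along the fibril axis. The epitopes that
distinguish this pathological surface from the harmless monomer are
*conformational*: columns of identical residues built by the stacking
itself. `epigraft` implements the engineering procedure that transplants
such a surface patch onto the innocuous two-rung beta-solenoid
HET-s(218–289): because rung *k* and rung *k*+1 of the solenoid are
related exactly like successive chains of the donor fibril, writing each
donor residue *x* at rung-1 position *p* **and** at its rung-2 partner
*p* + Δ (Δ = rung pseudo-repeat offset, here 36) makes the self-stacking
scaffold display the donor's in-register residue columns:

    substitutions(x → p) = { (p, wt(p) → x), (p+Δ, wt(p+Δ) → x) },
    dropped when wt(·) = x   ("identity-dropping")

The package is aimed at structural bioinformaticians and protein
engineers. It provides

* cross-beta geometry: screw-fit of fibril axis, rise and twist;
  dihedral-based strand segmentation; parallel/in-register verification
  (`estimate_fibril_frame`, `segment_strands`, `check_in_register`);
* rung-register detection on beta-solenoids (`detect_rung_offset`);
* deterministic Shrake–Rupley solvent accessibility with fibril-context
  scoring and strand face parity (`compute_sasa`,
  `fibril_context_exposure`, `strand_face_parity`);
* the stacked-graft designer and its validator (`design_stacked_graft`,
  `validate_design`), Kabsch superposition scoring
  (`superpose_epitope`);
* construct building and reporting (`apply_design`, `render_report`),
  with the four published vaccine candidates **α-SC3, α-SC6, α-SC8,
  α-SC9** shipped as verbatim presets (`load_preset`);
* synthetic generators of idealized solenoids and in-register fibrils
  with exact ground-truth rise/twist/offset (`make_ideal_solenoid`,
  `make_in_register_fibril`) — all structural examples in the package
  are such synthetic stand-ins; no downloads are needed anywhere;
* PDB/mmCIF reading, FASTA output, and a CLI
  (`inst/cli/epigraft.R` with subcommands `fixtures`, `analyze`,
  `design`, `preset`).

## Worked example: regenerate α-SC9 from its donor residues

```r
library(epigraft)

sca  <- scaffold_structure()      # synthetic two-rung HET-s(218-289) model
seq  <- scaffold_sequence()       # 72 aa, author numbering 218-289
rmap <- detect_rung_offset(sca, "A")
rmap
#> <rung_map> offset 36 (rung1 218-253 <-> rung2 254-289), 36 pairs, rmsd 0.000 A

estimate_fibril_frame(sca, list(kind = "intra_chain_rung", chain = "A",
                                range1 = c(218, 253), range2 = c(254, 289)))
#> <helical_parameters> intra_chain_rung: rise 4.800 A, twist -3.000 deg,
#>   superposition rmsd 0.000 A (36 Ca pairs)

# donor residues K, V, E, A assigned to rung-1 positions 227/229/230/232
patch   <- epitope_patch(c("K", "V", "E", "A"), donor_id = "printed-list")
mapping <- site_mapping(patch$residues$resno, c(227, 229, 230, 232), rmap)
design  <- design_stacked_graft(seq, rmap, patch, mapping, "alpha-SC9")
design
#> <construct_design> alpha-SC9 on HET-s_218-289: 8 substitutions
#>   rung 1: S227K, K229V, D230E, R232A
#>   rung 2: S263K, E265V, T266E, V268A

identical(substitution_ids(design), substitution_ids(load_preset("alpha-SC9")))
#> [1] TRUE

diff_sequences(seq, apply_design(seq, design))
#>   position wt new
#> 1      227  S   K
#> 2      229  K   V
#> ...                      # exactly the 8 designed positions
```

The detected offset 36 is the same constant obtained by subtracting the
published rung-1 positions from their rung-2 partners (261−225 = 263−227
= … = 36), and the rung-2 list falls out of the rung-1 assignment through
the stacked-graft rule — including asymmetric cases such as α-SC6's
rung-2-only `G271E` (its rung-1 partner is identity-dropped) and the
published α-SC3 entry `K269G`, which `validate_design` flags as
inconsistent with the rule (the expected partner position is 270).

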