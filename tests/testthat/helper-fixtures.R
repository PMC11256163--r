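# Shared in-code fixtures. Everything is generated deterministically; no
# files are read other than ones the tests write themselves.

# hand-written minimal 3-atom PDB (one ALA CA/N/C in chain A, model 1)
minimal_pdb_lines <- function() {
  c("ATOM      1  N   ALA A  10       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A  10       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A  10       1.969   1.427   0.000  1.00  0.00           C",
    "END")
}

write_minimal_pdb <- function(path) {
  writeLines(minimal_pdb_lines(), path)
  path
}

# atom-table row builder for synthetic point structures
atom_row <- function(serial, x, y, z, name = "CA", element = "C",
                     resname = "ALA", resno = serial, chain = "A",
                     model = 1L) {
  data.frame(serial = serial, name = name, element = element,
             x = x, y = y, z = z, resname = resname, resno = resno,
             ins = "", chain = chain, model = model, occ = 1, b = 0,
             stringsAsFactors = FALSE)
}

# a rigid chiral point set (no symmetry) for superposition tests
chiral_points <- function() {
  matrix(c(0, 0, 0,
           3.8, 0, 0,
           5.1, 3.2, 0,
           4.0, 4.1, 2.9,
           0.5, 6.0, 3.5), ncol = 3, byrow = TRUE)
}

# deterministic rigid motion (rotation angle deg about axis + shift)
rigid_motion <- function(xyz, angle = 37, axis = c(1, 2, 3),
                         shift = c(5, -3, 11)) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(xyz %*% t(R), 2, shift, "+")
}

# scaffold objects reused by several test files (computed once)
scaffold_env <- new.env()
get_scaffold <- function() {
  if (is.null(scaffold_env$structure)) {
    scaffold_env$structure <- scaffold_structure()
    scaffold_env$sequence <- scaffold_sequence()
    scaffold_env$rung_map <- detect_rung_offset(scaffold_env$structure, "A")
  }
  scaffold_env
}

# rebuild a preset design from donor residues read off its printed lists
design_from_printed <- function(name, codes, rung1_positions, seq, rmap) {
  patch <- epitope_patch(codes, donor_id = "printed-list")
  mapping <- site_mapping(patch$residues$resno, rung1_positions, rmap)
  design_stacked_graft(seq, rmap, patch, mapping, name)
}
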