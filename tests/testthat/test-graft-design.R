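test_that("epitope extraction reads donor residue identities at author numbers", {
  fib <- donor_fibril_structure(n_chains = 2)
  patch <- extract_epitope(fib, "A", 61:95)
  expect_equal(nrow(patch$residues), 35)
  donor_seq <- donor_sequence()
  expect_equal(paste(patch$residues$code, collapse = ""),
               substr(donor_seq$sequence, 61, 95))
  expect_error(extract_epitope(fib, "A", c(139, 141)), "absent: 141")
})

test_that("strict exposure mode rejects buried donor residues by name", {
  fib <- donor_fibril_structure(n_chains = 3)
  prof <- compute_sasa(select_structure(fib), subset_chains = "B")
  prof$residues$class <- "exposed"
  prof$residues$class[prof$residues$resno == 80] <- "buried"
  expect_error(extract_epitope(fib, "B", c(78, 80, 82),
                               require_exposed = TRUE, profile = prof),
               "buried.*80")
  patch <- extract_epitope(fib, "B", c(78, 82), require_exposed = TRUE,
                           profile = prof)
  expect_equal(patch$residues$resno, c(78, 82))
})

test_that("epitope superposition is exact on translated copies and rigid-motion invariant", {
  env <- get_scaffold()
  sca <- env$structure
  # donor = an exact translated copy of the scaffold rung-1 sites
  positions <- c(224L, 226L, 228L, 230L, 232L)
  ca <- atom_coords(sca, "A", "CA", positions)
  donor_atoms <- do.call(rbind, lapply(seq_along(positions), function(i) {
    atom_row(i, ca[i, 1] + 10, ca[i, 2] - 4, ca[i, 3] + 2,
             resno = positions[i])
  }))
  donor <- new_structure(donor_atoms, "copy")
  patch <- extract_epitope(donor, "A", positions)
  mapping <- site_mapping(positions, positions, env$rung_map)
  sc <- superpose_epitope(patch, donor, sca, mapping)
  expect_lt(sc$ca_rmsd, 1e-6)
  expect_true(sc$parity_consistent)

  moved_atoms <- donor_atoms
  xyz <- rigid_motion(as.matrix(donor_atoms[, c("x", "y", "z")]))
  moved_atoms$x <- xyz[, 1]; moved_atoms$y <- xyz[, 2]
  moved_atoms$z <- xyz[, 3]
  moved <- new_structure(moved_atoms, "moved")
  sc2 <- superpose_epitope(patch, moved, sca, mapping)
  expect_equal(sc2$ca_rmsd, sc$ca_rmsd, tolerance = 1e-6)
  expect_error(superpose_epitope(
    extract_epitope(donor, "A", positions[1:2]),
    donor, sca, site_mapping(positions[1:2], positions[1:2],
                             env$rung_map)),
    "underdetermined")
})

test_that("stacked grafts write each donor residue on both rungs with identity-dropping", {
  env <- get_scaffold()
  d6 <- design_from_printed("alpha-SC6", c("K", "V", "E", "G"),
                            c(232, 234, 235, 236), env$sequence,
                            env$rung_map)
  expect_equal(substitution_ids(d6),
               c("R232K", "E234V", "R236G",
                 "V268K", "K270V", "G271E", "E272G"))
  expect_equal(d6$score$n_identity_skipped, 1)

  # donor identical to wild type on both rungs: nothing to substitute
  # (226/227/238 carry the same letter one rung offset apart)
  id_pos <- c(226, 227, 238)
  expect_equal(seq_letter(env$sequence, id_pos),
               seq_letter(env$sequence, id_pos + env$rung_map$offset))
  d_id <- design_from_printed("identity",
                              seq_letter(env$sequence, id_pos),
                              id_pos, env$sequence, env$rung_map)
  expect_equal(nrow(d_id$substitutions), 0)
  expect_equal(d_id$score$n_identity_skipped, 2 * 3)

  patch_x <- epitope_patch(c("K", "Q"), c(1, 2))
  patch_x$residues$code[2] <- "X"
  mapping <- site_mapping(c(1, 2), c(225, 227), env$rung_map)
  expect_error(design_stacked_graft(env$sequence, env$rung_map, patch_x,
                                    mapping, "bad"), "non-standard")
})

test_that("stack-mimicry closure: grafted positions carry equal letters one offset apart", {
  env <- get_scaffold()
  offset <- env$rung_map$offset
  cases <- list(
    list(codes = c("K", "Q", "T"), pos = c(225, 227, 229)),
    list(codes = c("Q", "V", "N", "G", "G"),
         pos = c(229, 230, 232, 234, 235)),
    list(codes = c("W", "W", "W"), pos = c(240, 242, 244)),
    list(codes = c("A", "H", "P", "M"), pos = c(226, 231, 237, 245)))
  for (cs in cases) {
    d <- design_from_printed("closure", cs$codes, cs$pos, env$sequence,
                             env$rung_map)
    mutant <- apply_design(env$sequence, d)
    for (p in cs$pos) {
      expect_equal(seq_letter(mutant, p), seq_letter(mutant, p + offset))
    }
    # idempotence: designing again from the mutated scaffold is a no-op
    d2 <- design_from_printed("again", cs$codes, cs$pos, mutant,
                              env$rung_map)
    expect_equal(nrow(d2$substitutions), 0)
  }
})

test_that("rung-2 positions always derive from rung 1 through the offset", {
  env <- get_scaffold()
  d9 <- design_from_printed("alpha-SC9", c("K", "V", "E", "A"),
                            c(227, 229, 230, 232), env$sequence,
                            env$rung_map)
  s <- d9$substitutions
  r1 <- s[s$rung == 1, ]; r2 <- s[s$rung == 2, ]
  expect_equal(r2$position, r1$position + env$rung_map$offset)
  expect_equal(r2$new, r1$new)
  expect_error(site_mapping(1:3, c(225, 227, 300), env$rung_map),
               "outside rung-1 range")
})

test_that("validation reports wild-type conflicts and rung asymmetries without mutating", {
  env <- get_scaffold()
  d8 <- load_preset("alpha-SC8")
  expect_equal(nrow(validate_design(d8, env$sequence, env$rung_map)), 0)

  d3 <- load_preset("alpha-SC3")
  before <- d3$substitutions
  report <- validate_design(d3, env$sequence, env$rung_map)
  expect_identical(d3$substitutions, before)
  expect_true(269 %in% report$position[report$flag == "wt_mismatch"])
  expect_true(all(c(234, 269) %in%
                    report$position[report$flag == "asymmetry"]))

  empty <- new_construct_design("empty", "x",
                                data.frame(position = integer(0),
                                           wt = character(0),
                                           new = character(0),
                                           rung = integer(0)))
  expect_equal(nrow(validate_design(empty, env$sequence, env$rung_map)), 0)
})
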