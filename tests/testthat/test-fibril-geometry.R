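test_that("kabsch matches an independent superposition implementation", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(5:40, 1)
    x <- matrix(rnorm(3 * n, sd = 5), ncol = 3)
    y <- rigid_motion(x, angle = rep * 23, shift = rnorm(3)) +
      matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
    fit <- kabsch(x, y)
    # oracle: bio3d's least-squares fit of the same pairing
    xyz_fit <- suppressWarnings(bio3d::fit.xyz(
      fixed = as.vector(t(y)), mobile = as.vector(t(x))))
    oracle_rmsd <- sqrt(mean(colSums(
      (matrix(xyz_fit, nrow = 3) - t(y))^2)))
    expect_equal(fit$rmsd, oracle_rmsd, tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition of a translated copy is exact and rigid-motion invariant", {
  x <- chiral_points()
  expect_lt(kabsch(x, sweep(x, 2, c(3, -7, 2), "+"))$rmsd, 1e-9)
  y <- rigid_motion(x) + matrix(rnorm(15, sd = 0.2), ncol = 3)
  r0 <- kabsch(x, y)$rmsd
  expect_equal(kabsch(rigid_motion(x, 61, c(3, 1, 2), c(-4, 8, 0)), y)$rmsd,
               r0, tolerance = 1e-6)
  expect_equal(kabsch(x, rigid_motion(y, 13, c(1, 0, 1), c(9, 9, 9)))$rmsd,
               r0, tolerance = 1e-6)
})

test_that("no-reflection constraint: a mirror image superposes worse than allowed by an improper fit", {
  x <- chiral_points()
  mirror <- x %*% diag(c(-1, 1, 1))
  proper <- kabsch(x, mirror)$rmsd
  # brute-force improper optimum: reflect first, then proper rotation
  improper <- kabsch(x %*% diag(c(-1, 1, 1)), mirror)$rmsd
  expect_gt(proper, 1e-3)
  expect_lt(improper, 1e-9)
})

test_that("frame estimation recovers generator rise and twist over the parameter grid", {
  for (rise in c(4.6, 4.8, 5.0)) {
    for (twist in c(-5, 0, 5)) {
      for (n_rungs in c(2L, 3L, 5L)) {
        sol <- make_ideal_solenoid(solenoid_spec(
          n_rungs = n_rungs, residues_per_rung = 36, rise = rise,
          twist = twist))
        rpr <- 36L
        fr <- estimate_fibril_frame(sol, list(
          kind = "intra_chain_rung", chain = "A",
          range1 = c(1, rpr), range2 = c(rpr + 1, 2 * rpr)))
        expect_equal(fr$rise, rise, tolerance = 0.01)
        expect_equal(fr$twist, twist, tolerance = 0.1)
        expect_lt(fr$rmsd, 0.05)
        rm <- detect_rung_offset(sol, "A")
        expect_equal(rm$offset, rpr)
      }
    }
  }
})

test_that("frame estimation is invariant under global rigid motion", {
  fib <- make_in_register_fibril(fibril_spec(4, rise = 4.8, twist = -2,
                                             sequence = strrep("A", 20)))
  fr0 <- estimate_fibril_frame(fib, list(kind = "inter_chain",
                                         chains = c("A", "B", "C", "D")))
  moved <- fib
  xyz <- rigid_motion(as.matrix(fib$atoms[, c("x", "y", "z")]))
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  fr1 <- estimate_fibril_frame(moved, list(kind = "inter_chain",
                                           chains = c("A", "B", "C", "D")))
  expect_equal(fr1$rise, fr0$rise, tolerance = 1e-6)
  expect_equal(fr1$twist, fr0$twist, tolerance = 1e-6)
})

test_that("frame estimation rejects degenerate repeat specifications", {
  sol <- make_ideal_solenoid(solenoid_spec(2, 12, strand_layout =
                                             list(c(4, 2), c(4, 2))))
  expect_error(estimate_fibril_frame(sol, list(kind = "inter_chain",
                                               chains = "A")),
               ">= 2 chains")
  expect_error(estimate_fibril_frame(sol, list(
    kind = "intra_chain_rung", chain = "A",
    range1 = c(1, 12), range2 = c(13, 20))), "unequal length")
})

test_that("strand segmentation finds strands in extended chains and none in helices", {
  ext <- new_structure(
    epigraft:::build_backbone(rep(-139, 10), rep(135, 10),
                              strrep("A", 10)), "ext")
  segs <- segment_strands(ext, "A")
  expect_equal(nrow(segs), 1)
  expect_gte(segs$end_residue[1] - segs$start_residue[1] + 1, 8)

  helix <- new_structure(
    epigraft:::build_backbone(rep(-57, 12), rep(-47, 12),
                              strrep("A", 12)), "helix")
  expect_equal(nrow(segment_strands(helix, "A")), 0)
})

test_that("a four-strand rung layout segments into four strands per rung", {
  sol <- make_ideal_solenoid(solenoid_spec(2, 36, 4.8, -3))
  expect_equal(nrow(segment_strands(sol, "A", residue_range = c(1, 36))), 4)
  expect_equal(nrow(segment_strands(sol, "A", residue_range = c(37, 72))), 4)
})

test_that("strand count never increases with min_strand_len", {
  sol <- make_ideal_solenoid(solenoid_spec(2, 36, 4.8, -3))
  counts <- vapply(2:8, function(L) {
    nrow(segment_strands(sol, "A", min_strand_len = L))
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("rung offset detection matches a brute-force scan with an independent fit", {
  sol <- make_ideal_solenoid(solenoid_spec(2, 18, 4.8, -2,
                                           strand_layout = list(c(5, 4),
                                                                c(5, 4))))
  rm <- detect_rung_offset(sol, "A", min_window = 10)
  ca <- atom_coords(sol, "A", "CA")
  resnos <- as.integer(rownames(ca))
  brute <- vapply(4:(length(resnos) - 10), function(d) {
    i1 <- resnos[(resnos + d) %in% resnos]
    if (length(i1) < 10) return(NA_real_)
    fit <- suppressWarnings(bio3d::fit.xyz(
      fixed = as.vector(t(ca[as.character(i1 + d), ])),
      mobile = as.vector(t(ca[as.character(i1), ]))))
    sqrt(mean(colSums((matrix(fit, nrow = 3) -
                         t(ca[as.character(i1 + d), ]))^2)))
  }, 0)
  expect_equal(rm$offset, (4:(length(resnos) - 10))[which.min(brute)])
  expect_equal(rm$offset, 18)
})

test_that("rung offset detection honors the search range and solenoid threshold", {
  sol <- make_ideal_solenoid(solenoid_spec(2, 36, 4.8, -3))
  expect_error(detect_rung_offset(sol, "A", search_range = c(4, 20)),
               "no solenoid repeat")
  rm <- detect_rung_offset(sol, "A", search_range = c(20, 50))
  expect_equal(rm$offset, 36)
  expect_true(all(rm$pairs[, "rung2"] == rm$pairs[, "rung1"] + 36))
})

test_that("register check passes in-register fibrils and fails shifted or antiparallel ones", {
  base <- fibril_spec(4, rise = 4.8, twist = -1, sequence = strrep("A", 20))
  reg <- check_in_register(make_in_register_fibril(base),
                           c("A", "B", "C", "D"))
  expect_true(reg$in_register)
  expect_equal(reg$orientation, "parallel")
  expect_lt(reg$max_offset, 0.1)

  shifted <- fibril_spec(4, rise = 4.8, twist = -1,
                         sequence = strrep("A", 20), register_shift = 2L)
  reg2 <- check_in_register(make_in_register_fibril(shifted),
                            c("A", "B", "C", "D"))
  expect_false(reg2$in_register)

  anti <- fibril_spec(4, rise = 4.8, twist = -1,
                      sequence = strrep("A", 20),
                      orientation = "antiparallel")
  reg3 <- check_in_register(make_in_register_fibril(anti),
                            c("A", "B", "C", "D"))
  expect_equal(reg3$orientation, "antiparallel")
  expect_false(reg3$in_register)
})

test_that("register check requires shared residue numbering", {
  fib <- make_in_register_fibril(fibril_spec(2, sequence = strrep("A", 10)))
  a <- fib$atoms
  a$resno[a$chain == "B"] <- a$resno[a$chain == "B"] + 1000L
  expect_error(check_in_register(new_structure(a, "x"), c("A", "B")),
               "no residue numbers")
})
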