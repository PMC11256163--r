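## Deterministic synthetic coordinate generators: idealized beta-solenoids
## and parallel in-register fibrils with known rise/twist/offset ground
## truth. Pure arithmetic from frozen constants; no RNG anywhere.

# canonical backbone geometry (Engh-Huber-type values)
BB <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  b_ca_cb = 1.521,
  a_c_n_ca = 121.7, a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_ca_c_o = 120.8,
  a_n_ca_cb = 110.4, t_c_n_ca_cb = -122.6,
  omega = 180)

# torsion basins used by the generators
TORSION_BETA <- c(phi = -139, psi = 135)
TORSION_TURN <- c(phi = 80, psi = 60)  # left-handed (turn) basin, keeps rungs flat

# NeRF atom placement: D such that |C-D| = bond, angle(B,C,D) = angle,
# torsion(A,B,C,D) = torsion (degrees).
place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- -torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               bond * sin(ang) * sin(tor))
  C + d_local[1] * bc + d_local[2] * m2 + d_local[3] * n
}

# Build one continuous backbone (N, CA, C, O, CB) from per-residue phi/psi.
# phi[1] and the final psi are unused (termini). Returns a list of per-atom
# rows; sequence gives residue identities (Gly gets no CB).
build_backbone <- function(phi, psi, sequence, start_number = 1L,
                           chain = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n, nchar(sequence) == n)
  letters1 <- strsplit(sequence, "")[[1]]
  N <- CA <- C <- vector("list", n)
  N[[1]] <- c(0, 0, 0)
  CA[[1]] <- c(BB$b_n_ca, 0, 0)
  a <- BB$a_n_ca_c * pi / 180
  C[[1]] <- CA[[1]] + BB$b_ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(n)[-1]) {
    N[[i]] <- place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                         BB$b_c_n, BB$a_ca_c_n, psi[i - 1])
    CA[[i]] <- place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                          BB$b_n_ca, BB$a_c_n_ca, BB$omega)
    C[[i]] <- place_atom(C[[i - 1]], N[[i]], CA[[i]],
                         BB$b_ca_c, BB$a_n_ca_c, phi[i])
  }
  rows <- list()
  serial <- 0L
  add <- function(rows, name, element, xyz, resname, resno) {
    serial <<- serial + 1L
    rows[[length(rows) + 1]] <- data.frame(
      serial = serial, name = name, element = element,
      x = xyz[1], y = xyz[2], z = xyz[3],
      resname = resname, resno = resno, ins = "", chain = chain,
      model = 1L, occ = 1, b = 0, stringsAsFactors = FALSE)
    rows
  }
  for (i in seq_len(n)) {
    resno <- start_number + i - 1L
    resname <- AA1TO3[letters1[i]]
    if (is.na(resname)) resname <- "UNK"
    psi_i <- if (i < n) psi[i] else TORSION_BETA[["psi"]]
    O <- place_atom(N[[i]], CA[[i]], C[[i]], BB$b_c_o, BB$a_ca_c_o,
                    psi_i + 180)
    rows <- add(rows, "N", "N", N[[i]], resname, resno)
    rows <- add(rows, "CA", "C", CA[[i]], resname, resno)
    rows <- add(rows, "C", "C", C[[i]], resname, resno)
    rows <- add(rows, "O", "O", O, resname, resno)
    if (letters1[i] != "G") {
      CBx <- place_atom(C[[i]], N[[i]], CA[[i]], BB$b_ca_cb, BB$a_n_ca_cb,
                        BB$t_c_n_ca_cb)
      rows <- add(rows, "CB", "C", CBx, resname, resno)
    }
  }
  do.call(rbind, rows)
}

# torsion schedule for one rung from a strand layout
rung_torsions <- function(strand_layout) {
  phi <- psi <- numeric(0)
  for (seg in strand_layout) {
    phi <- c(phi, rep(TORSION_BETA[["phi"]], seg[1]),
             rep(TORSION_TURN[["phi"]], seg[2]))
    psi <- c(psi, rep(TORSION_BETA[["psi"]], seg[1]),
             rep(TORSION_TURN[["psi"]], seg[2]))
  }
  list(phi = phi, psi = psi)
}

# transform placing the point cloud's thinnest direction along +z with the
# centroid at the origin (returned so several copies can share it)
flatten_transform <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  pc <- prcomp(sweep(xyz, 2, ctr), center = FALSE)
  R <- pc$rotation  # columns: decreasing variance; 3rd = thinnest
  if (det(R) < 0) R[, 3] <- -R[, 3]
  list(center = ctr, rotation = R)
}

apply_flatten <- function(atoms, tf) {
  xyz <- sweep(as.matrix(atoms[, c("x", "y", "z")]), 2, tf$center) %*%
    tf$rotation
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

flatten_to_xy <- function(atoms) apply_flatten(atoms, flatten_transform(atoms))

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

apply_rot <- function(atoms, R) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

#' Specification for an idealized beta-solenoid
#'
#' @param n_rungs number of rungs (>= 2).
#' @param residues_per_rung residues in one rung.
#' @param rise axial rise per rung in Angstrom (default 4.8, the canonical
#'   cross-beta spacing).
#' @param twist twist per rung in degrees (negative = left-handed).
#' @param strand_layout list of `c(strand_len, turn_len)` pairs summing to
#'   `residues_per_rung`; default four 6-residue strands with 3-residue
#'   turns for a 36-residue rung.
#' @param sequence optional one-letter sequence of length
#'   `n_rungs * residues_per_rung` (default poly-Ala).
#' @param start_number author number of the first residue.
#' @return a `solenoid_spec` list.
#' @export
solenoid_spec <- function(n_rungs = 2L, residues_per_rung = 36L,
                          rise = 4.8, twist = -3,
                          strand_layout = NULL, sequence = NULL,
                          start_number = 1L) {
  if (n_rungs < 2) stop("need n_rungs >= 2")
  if (rise <= 0) stop("rise must be positive")
  if (is.null(strand_layout)) {
    per_strand <- residues_per_rung / 4
    if (per_strand != round(per_strand)) {
      stop("give an explicit strand_layout for residues_per_rung not ",
           "divisible by 4")
    }
    s <- ceiling(per_strand * 2 / 3); t <- per_strand - s
    if (t < 1) { s <- per_strand - 1; t <- 1 }
    strand_layout <- rep(list(c(s, t)), 4)
  }
  tot <- sum(vapply(strand_layout, sum, 0))
  if (tot != residues_per_rung) {
    stop("strand_layout sums to ", tot, ", expected ", residues_per_rung)
  }
  if (any(vapply(strand_layout, `[`, 0, 1) < 1)) {
    stop("strand lengths must be >= 1")
  }
  if (is.null(sequence)) {
    sequence <- strrep("A", n_rungs * residues_per_rung)
  }
  if (nchar(sequence) != n_rungs * residues_per_rung) {
    stop("sequence length ", nchar(sequence), " != n_rungs * ",
         "residues_per_rung = ", n_rungs * residues_per_rung)
  }
  list(n_rungs = as.integer(n_rungs),
       residues_per_rung = as.integer(residues_per_rung),
       rise = rise, twist = twist, strand_layout = strand_layout,
       sequence = sequence, start_number = as.integer(start_number))
}

#' Generate an idealized beta-solenoid structure
#'
#' Rung 0 is a continuous backbone laid out from the strand/turn torsion
#' schedule and flattened onto the xy-plane; rung k is rung 0 rotated by
#' `k * twist` about the z axis and translated `k * rise` along it, so the
#' generator parameters are the exact ground truth for frame estimation and
#' rung-offset detection. Fully deterministic.
#'
#' @param spec a [solenoid_spec].
#' @return an [epigraft_structure] (chain "A", heavy backbone + CB atoms).
#' @export
make_ideal_solenoid <- function(spec) {
  tor <- rung_torsions(spec$strand_layout)
  rpr <- spec$residues_per_rung
  # identical torsions give every rung an identical backbone; each rung is
  # built from its own sub-sequence so CB presence tracks its residues
  seqs <- vapply(seq_len(spec$n_rungs) - 1L, function(k) {
    substr(spec$sequence, k * rpr + 1, (k + 1) * rpr)
  }, "")
  tf <- flatten_transform(
    build_backbone(tor$phi, tor$psi, seqs[1],
                   start_number = spec$start_number))
  rungs <- vector("list", spec$n_rungs)
  serial0 <- 0L
  for (k in seq_len(spec$n_rungs) - 1L) {
    rk <- build_backbone(tor$phi, tor$psi, seqs[k + 1L],
                         start_number = spec$start_number + k * rpr)
    rk <- apply_flatten(rk, tf)
    rk <- apply_rot(rk, rot_z(k * spec$twist))
    rk$z <- rk$z + k * spec$rise
    rk$serial <- rk$serial + serial0
    serial0 <- serial0 + nrow(rk)
    rungs[[k + 1L]] <- rk
  }
  new_structure(do.call(rbind, rungs), id = "ideal_solenoid",
                source_format = "synthetic")
}

#' Specification for an idealized parallel in-register fibril
#'
#' @param n_chains number of stacked chains (>= 2).
#' @param rise axial rise per chain in Angstrom (default 4.8).
#' @param twist twist per chain in degrees.
#' @param sequence one-letter sequence of the chain template.
#' @param register_shift author-numbering offset applied to every second
#'   chain (0 = in-register ground truth).
#' @param orientation `"parallel"` or `"antiparallel"` (alternate chains
#'   flipped 180 degrees about the fibril axis).
#' @param start_number author number of the first residue.
#' @return a `fibril_spec` list.
#' @export
fibril_spec <- function(n_chains = 5L, rise = 4.8, twist = -1,
                        sequence = strrep("A", 20), register_shift = 0L,
                        orientation = c("parallel", "antiparallel"),
                        start_number = 1L) {
  if (n_chains < 2) stop("need n_chains >= 2")
  if (rise <= 0) stop("rise must be positive")
  list(n_chains = as.integer(n_chains), rise = rise, twist = twist,
       sequence = sequence, register_shift = as.integer(register_shift),
       orientation = match.arg(orientation),
       start_number = as.integer(start_number))
}

#' Generate an idealized parallel in-register fibril
#'
#' The chain template is an extended beta strand laid flat in the xy-plane;
#' chain k is the template rotated by `k * twist` about the fibril (z) axis
#' and translated `k * rise` along it, placing residue i of every chain
#' directly above residue i of the chain below — the parallel in-register
#' cross-beta architecture with its ~4.8 Angstrom spacing. Chains are
#' labelled "A", "B", ... in stacking order.
#'
#' @param spec a [fibril_spec].
#' @return an [epigraft_structure].
#' @export
make_in_register_fibril <- function(spec) {
  n_res <- nchar(spec$sequence)
  template <- build_backbone(rep(TORSION_BETA[["phi"]], n_res),
                             rep(TORSION_BETA[["psi"]], n_res),
                             spec$sequence,
                             start_number = spec$start_number)
  template <- flatten_to_xy(template)
  template <- template[!(template$name == "CB" &
                           template$resname == "GLY"), , drop = FALSE]
  chains <- vector("list", spec$n_chains)
  ids <- make.unique(rep(LETTERS, length.out = spec$n_chains), sep = "")
  n_atoms0 <- nrow(template)
  for (k in seq_len(spec$n_chains) - 1L) {
    ck <- template
    if (spec$orientation == "antiparallel" && k %% 2 == 1) {
      ck <- apply_rot(ck, rot_z(180))
    }
    ck <- apply_rot(ck, rot_z(k * spec$twist))
    ck$z <- ck$z + k * spec$rise
    if (k %% 2 == 1) ck$resno <- ck$resno + spec$register_shift
    ck$chain <- ids[k + 1L]
    ck$serial <- ck$serial + k * n_atoms0
    chains[[k + 1L]] <- ck
  }
  new_structure(do.call(rbind, chains), id = "ideal_fibril",
                source_format = "synthetic")
}
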