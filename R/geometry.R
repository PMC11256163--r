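#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares fit of `mobile` onto `target` over paired rows, constrained
#' to a proper rotation (determinant +1, no reflection).
#'
#' @param mobile,target n x 3 coordinate matrices with matched rows (n >= 3).
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   map is `x %*% t(rotation) + translation`), `rmsd` (Angstrom) and
#'   `fitted` (the transformed mobile coordinates).
#' @export
kabsch <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  stopifnot(ncol(mobile) == 3, ncol(target) == 3,
            nrow(mobile) == nrow(target))
  if (nrow(mobile) < 3) stop("superposition underdetermined: need >= 3 pairs")
  cm <- colMeans(mobile); ct <- colMeans(target)
  P <- sweep(mobile, 2, cm); Q <- sweep(target, 2, ct)
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  fitted <- sweep(P %*% t(R), 2, ct, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(rotation = R, translation = ct - as.vector(R %*% cm),
       rmsd = rmsd, fitted = fitted)
}

#' Dihedral angle of four points
#' @param p1,p2,p3,p4 length-3 coordinate vectors.
#' @return angle in degrees in (-180, 180].
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Screw parameters (axis, rise, twist) from a rigid transform y = R x + t.
screw_from_transform <- function(R, t, theta_tol = 1e-6) {
  cos_theta <- (sum(diag(R)) - 1) / 2
  cos_theta <- max(-1, min(1, cos_theta))
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  sin_theta <- sqrt(sum(v^2))
  if (sin_theta < theta_tol && cos_theta > 0) {
    # (near-)pure translation: axis along t
    axis <- t / sqrt(sum(t^2))
    return(list(axis = axis, twist = 0, rise = sqrt(sum(t^2)),
                axis_point = c(0, 0, 0)))
  }
  axis <- v / sin_theta
  theta <- atan2(sin_theta, cos_theta) * 180 / pi
  rise <- sum(t * axis)
  # orient so rise is positive; twist sign follows the axis flip
  if (rise < 0) { axis <- -axis; rise <- -rise; theta <- -theta }
  # point on axis: solve (I - R) p = t_perp
  t_perp <- t - sum(t * axis) * axis
  A <- diag(3) - R
  p <- tryCatch(qr.solve(A + tcrossprod(axis), t_perp),
                error = function(e) c(0, 0, 0))
  list(axis = axis, twist = theta, rise = rise, axis_point = p)
}

#' Estimate the helical frame of a fibril or solenoid
#'
#' Fits the single screw transformation (rotation `twist` about an axis plus
#' translation `rise` along it) that best maps each repeat onto the next, by
#' least squares over all corresponding C-alpha pairs of all consecutive
#' repeat pairs. Cross-beta stacks place repeats ~4.8 Angstrom apart along
#' the axis.
#'
#' @param structure an [epigraft_structure] (single model).
#' @param repeat_spec either `list(kind = "inter_chain", chains = c(...))`
#'   (ordered chains along the fibril; corresponding residues share author
#'   numbers) or `list(kind = "intra_chain_rung", range1 = c(a,b),
#'   range2 = c(c,d), chain = id)` (two equal-length author-number intervals
#'   of one chain, e.g. the two rungs of a beta-solenoid).
#' @return list of class `helical_parameters`: `axis_direction` (unit
#'   vector), `axis_point`, `rise` (Angstrom per repeat), `twist` (degrees
#'   per repeat, in (-180, 180]), `repeat_kind`, `rmsd` of the repeat
#'   superposition, `n_pairs`.
#' @export
estimate_fibril_frame <- function(structure, repeat_spec) {
  kind <- match.arg(repeat_spec$kind, c("inter_chain", "intra_chain_rung"))
  if (kind == "inter_chain") {
    chains <- repeat_spec$chains
    if (length(chains) < 2) stop("need >= 2 chains (repeats)")
    coords <- lapply(chains, function(ch) atom_coords(structure, ch, "CA"))
    common <- Reduce(intersect, lapply(coords, rownames))
    if (length(common) == 0) stop("chains share no residue numbers")
    reps <- lapply(coords, function(m) m[common, , drop = FALSE])
  } else {
    r1 <- repeat_spec$range1; r2 <- repeat_spec$range2
    if (is.null(r1) || is.null(r2)) stop("need range1 and range2")
    if (diff(r1) != diff(r2)) {
      stop("repeats of unequal length: ", r1[1], "-", r1[2], " vs ",
           r2[1], "-", r2[2])
    }
    ch <- repeat_spec$chain
    if (is.null(ch)) ch <- structure$atoms$chain[1]
    ca <- atom_coords(structure, ch, "CA")
    have <- as.integer(rownames(ca))
    n1 <- seq(r1[1], r1[2]); n2 <- seq(r2[1], r2[2])
    keep <- n1 %in% have & n2 %in% have
    miss <- c(setdiff(n1, have), setdiff(n2, have))
    if (sum(keep) < 3) {
      stop("too few matched residues between rungs; missing: ",
           paste(miss, collapse = ", "))
    }
    reps <- list(ca[as.character(n1[keep]), , drop = FALSE],
                 ca[as.character(n2[keep]), , drop = FALSE])
  }
  # single transform fitted to all consecutive repeat pairs at once
  mob <- do.call(rbind, reps[-length(reps)])
  tar <- do.call(rbind, reps[-1])
  fit <- kabsch(mob, tar)
  sc <- screw_from_transform(fit$rotation, fit$translation)
  structure(list(axis_direction = sc$axis, axis_point = sc$axis_point,
                 rise = sc$rise, twist = sc$twist, repeat_kind = kind,
                 rmsd = fit$rmsd, n_pairs = nrow(mob)),
            class = "helical_parameters")
}

#' @export
print.helical_parameters <- function(x, ...) {
  cat(sprintf(paste0("<helical_parameters> %s: rise %.3f A, twist %.3f deg, ",
                     "superposition rmsd %.3f A (%d Ca pairs)\n"),
              x$repeat_kind, x$rise, x$twist, x$rmsd, x$n_pairs))
  invisible(x)
}

#' Backbone dihedrals of a chain
#'
#' @param structure an [epigraft_structure] (single model).
#' @param chain chain id.
#' @param residue_range optional inclusive author-number interval.
#' @return data frame with resno, phi, psi (degrees; NA at termini).
#' @export
backbone_dihedrals <- function(structure, chain, residue_range = NULL) {
  a <- structure$atoms
  a <- a[a$chain == chain & a$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (nrow(a) == 0) stop("no backbone atoms in chain ", chain)
  resnos <- sort(unique(a$resno))
  if (!is.null(residue_range)) {
    resnos <- resnos[resnos >= residue_range[1] & resnos <= residue_range[2]]
  }
  get <- function(resno, name) {
    row <- a[a$resno == resno & a$name == name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  missing_bb <- resnos[vapply(resnos, function(r) {
    is.null(get(r, "N")) || is.null(get(r, "CA")) || is.null(get(r, "C"))
  }, TRUE)]
  if (length(missing_bb) > 0) {
    stop("missing backbone atoms for residue(s): ",
         paste(missing_bb, collapse = ", "))
  }
  phi <- psi <- rep(NA_real_, length(resnos))
  for (i in seq_along(resnos)) {
    r <- resnos[i]
    # sequence neighbours must be consecutive author numbers
    if ((r - 1) %in% resnos) {
      phi[i] <- dihedral(get(r - 1, "C"), get(r, "N"), get(r, "CA"),
                         get(r, "C"))
    }
    if ((r + 1) %in% resnos) {
      psi[i] <- dihedral(get(r, "N"), get(r, "CA"), get(r, "C"),
                         get(r + 1, "N"))
    }
  }
  data.frame(resno = resnos, phi = phi, psi = psi)
}

#' Beta-strand segmentation from backbone dihedrals
#'
#' A residue is in extended (beta) conformation when phi lies in
#' `phi_range` and psi lies in `psi_range` (interpreted modulo 360, so the
#' default 45..225 covers the canonical beta basin around +135 including
#' its wrap past 180). Runs of at least `min_strand_len` consecutive beta
#' residues become strand segments. Deterministic; no hydrogen-bond
#' inference, so it works on backbone-only synthetic fixtures.
#'
#' @param structure an [epigraft_structure] (single model).
#' @param chain chain id.
#' @param residue_range optional inclusive author-number interval.
#' @param min_strand_len minimum strand length (default 3).
#' @param phi_range,psi_range acceptance windows in degrees.
#' @return data frame with chain, start_residue, end_residue (author
#'   numbering), one row per strand, sorted and non-overlapping.
#' @export
segment_strands <- function(structure, chain, residue_range = NULL,
                            min_strand_len = 3,
                            phi_range = c(-180, -45),
                            psi_range = c(45, 225)) {
  di <- backbone_dihedrals(structure, chain, residue_range)
  in_window <- function(x, w) {
    x360 <- x %% 360; lo <- w[1] %% 360; hi <- w[2] %% 360
    if (lo <= hi) x360 >= lo & x360 <= hi else x360 >= lo | x360 <= hi
  }
  is_beta <- !is.na(di$phi) & !is.na(di$psi) &
    in_window(di$phi, phi_range) & in_window(di$psi, psi_range)
  # break runs at author-number gaps
  segs <- list()
  run_start <- NULL
  prev <- NULL
  for (i in seq_len(nrow(di))) {
    contiguous <- !is.null(prev) && di$resno[i] == prev + 1
    if (is_beta[i] && (is.null(run_start) || !contiguous)) {
      if (!is.null(run_start)) segs[[length(segs) + 1]] <- c(run_start, prev)
      run_start <- di$resno[i]
    } else if (!is_beta[i] && !is.null(run_start)) {
      segs[[length(segs) + 1]] <- c(run_start, prev)
      run_start <- NULL
    }
    prev <- di$resno[i]
  }
  if (!is.null(run_start)) segs[[length(segs) + 1]] <- c(run_start, prev)
  segs <- Filter(function(s) s[2] - s[1] + 1 >= min_strand_len, segs)
  if (length(segs) == 0) {
    return(data.frame(chain = character(0), start_residue = integer(0),
                      end_residue = integer(0)))
  }
  out <- data.frame(chain = chain,
                    start_residue = vapply(segs, `[`, 0, 1),
                    end_residue = vapply(segs, `[`, 0, 2))
  out[order(out$start_residue), , drop = FALSE]
}

#' Detect the beta-solenoid rung pseudo-repeat offset
#'
#' Scans candidate residue-number offsets Delta and superposes C-alpha(i)
#' onto C-alpha(i + Delta) over the maximal overlapping window; the offset
#' with the lowest superposition RMSD below `rmsd_threshold` wins, ties
#' going to the smaller Delta. For HET-s(218-289) the printed two-rung
#' substitution pairs (e.g. 225/261, 227/263, 229/265) all differ by one
#' constant, which this detection recovers from coordinates alone.
#'
#' @param structure an [epigraft_structure] (single model).
#' @param chain chain id.
#' @param search_range inclusive integer interval of candidate offsets
#'   (default 4 to chain length - 4).
#' @param rmsd_threshold solenoid acceptance threshold in Angstrom
#'   (default 3.0; the pseudo-repeat is approximate, not exact).
#' @param min_window minimum number of aligned C-alpha pairs (default 15).
#' @param tie_tolerance RMSD margin (Angstrom, default 0.01) within which
#'   two offsets count as tied and the smaller wins; keeps exact multiples
#'   of the repeat from beating it on coordinate-precision noise.
#' @return list of class `rung_map`: `offset`, `pairs` (two-column matrix
#'   rung1/rung2 author numbers), `rung1_range`, `rung2_range`,
#'   `alignment_rmsd`, and `profile` (RMSD per candidate offset).
#' @export
detect_rung_offset <- function(structure, chain, search_range = NULL,
                               rmsd_threshold = 3.0, min_window = 15,
                               tie_tolerance = 0.01) {
  ca <- atom_coords(structure, chain, "CA")
  resnos <- as.integer(rownames(ca))
  n <- length(resnos)
  if (is.null(search_range)) search_range <- c(4L, n - 4L)
  deltas <- seq(max(4L, search_range[1]), min(n - 4L, search_range[2]))
  if (length(deltas) == 0) stop("empty offset search range")
  prof <- data.frame(offset = deltas, rmsd = NA_real_, n_pairs = 0L)
  best <- NULL
  for (k in seq_along(deltas)) {
    d <- deltas[k]
    i1 <- resnos[(resnos + d) %in% resnos]
    if (length(i1) < min_window) next
    fit <- kabsch(ca[as.character(i1), , drop = FALSE],
                  ca[as.character(i1 + d), , drop = FALSE])
    prof$rmsd[k] <- fit$rmsd
    prof$n_pairs[k] <- length(i1)
    # ties (within coordinate-precision noise) go to the smaller offset
    if (fit$rmsd <= rmsd_threshold &&
        (is.null(best) || fit$rmsd < best$rmsd - tie_tolerance)) {
      best <- list(offset = d, rmsd = fit$rmsd, i1 = i1)
    }
  }
  if (is.null(best)) {
    stop("no solenoid repeat detected: no offset in [",
         min(deltas), ", ", max(deltas), "] superposes below ",
         rmsd_threshold, " A over >= ", min_window, " residues")
  }
  pairs <- cbind(rung1 = best$i1, rung2 = best$i1 + best$offset)
  structure(list(offset = best$offset, pairs = pairs,
                 rung1_range = range(best$i1),
                 rung2_range = range(best$i1 + best$offset),
                 alignment_rmsd = best$rmsd, profile = prof),
            class = "rung_map")
}

#' @export
print.rung_map <- function(x, ...) {
  cat(sprintf(paste0("<rung_map> offset %d (rung1 %d-%d <-> rung2 %d-%d), ",
                     "%d pairs, rmsd %.3f A\n"),
              x$offset, x$rung1_range[1], x$rung1_range[2],
              x$rung2_range[1], x$rung2_range[2], nrow(x$pairs),
              x$alignment_rmsd))
  invisible(x)
}

#' Check that stacked chains are parallel and in register
#'
#' In a parallel in-register cross-beta fibril, residue i of chain k sits
#' directly below residue i of chain k+1, one helical step (~4.8 Angstrom
#' rise plus twist) away. For every shared residue number, the deviation of
#' the observed chain-to-chain C-alpha displacement from that ideal screw
#' step is measured (full 3-D deviation, so both axial slips and lateral
#' register shifts are caught). Orientation comes from agreement of the
#' chains' N-to-C end vectors.
#'
#' @param structure an [epigraft_structure] (single model).
#' @param chains ordered chain ids along the fibril axis.
#' @param tolerance maximum residue deviation (Angstrom) still counted as
#'   in-register; default 2.4, half the canonical 4.8 rise, which cleanly
#'   separates one-residue register shifts.
#' @param frame optional [estimate_fibril_frame] result to use as the ideal
#'   step; default fitted from the chains themselves.
#' @return list of class `register_report`: `per_residue_offset` (named
#'   vector, Angstrom, max over adjacent chain pairs), `max_offset`,
#'   `orientation` ("parallel"/"antiparallel"/"mixed"), `in_register`.
#' @export
check_in_register <- function(structure, chains, tolerance = 2.4,
                              frame = NULL) {
  if (length(chains) < 2) stop("need >= 2 chains")
  coords <- lapply(chains, function(ch) atom_coords(structure, ch, "CA"))
  common <- Reduce(intersect, lapply(coords, rownames))
  if (length(common) == 0) stop("chains share no residue numbers")
  common <- as.character(sort(as.integer(common)))
  reps <- lapply(coords, function(m) m[common, , drop = FALSE])

  # orientation from end-to-end vectors
  dirs <- vapply(reps, function(m) {
    v <- m[nrow(m), ] - m[1, ]; v / sqrt(sum(v^2))
  }, numeric(3))
  dots <- vapply(seq_len(ncol(dirs) - 1),
                 function(k) sum(dirs[, k] * dirs[, k + 1]), 0)
  orientation <- if (all(dots > 0)) "parallel"
                 else if (all(dots < 0)) "antiparallel" else "mixed"

  if (is.null(frame)) {
    frame <- estimate_fibril_frame(
      structure, list(kind = "inter_chain", chains = chains))
  }
  # ideal screw step: rotate by twist about the fitted axis, advance by rise
  axis <- frame$axis_direction
  theta <- frame$twist * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
  step <- function(m) {
    p0 <- matrix(frame$axis_point, nrow(m), 3, byrow = TRUE)
    sweep((m - p0) %*% t(R) + p0, 2, axis * frame$rise, "+")
  }
  dev <- matrix(0, length(common), length(chains) - 1)
  for (k in seq_len(length(chains) - 1)) {
    dev[, k] <- sqrt(rowSums((reps[[k + 1]] - step(reps[[k]]))^2))
  }
  per_res <- apply(dev, 1, max)
  names(per_res) <- common
  max_offset <- max(per_res)
  structure(list(per_residue_offset = per_res, max_offset = max_offset,
                 orientation = orientation,
                 in_register = orientation == "parallel" &&
                   max_offset <= tolerance,
                 tolerance = tolerance, frame = frame),
            class = "register_report")
}

#' @export
print.register_report <- function(x, ...) {
  cat(sprintf("<register_report> %s, max deviation %.3f A (tol %.2f): %s\n",
              x$orientation, x$max_offset, x$tolerance,
              if (x$in_register) "in register" else "NOT in register"))
  invisible(x)
}

#' Stack rigid copies of a structure along a helical axis
#'
#' Copy k is the input rotated by `k * twist` about the axis and translated
#' `k * rise` along it; chains are relabelled `<chain><k>` to keep copies
#' distinct. Used to rebuild the fibrillar context of a repeating unit
#' (e.g. scoring surface exposure of a solenoid inside a fibril).
#'
#' @param structure an [epigraft_structure] (single model).
#' @param frame a `helical_parameters` object, or list with
#'   `axis_direction`, `axis_point`, `rise`, `twist`.
#' @param n_copies total number of copies (>= 1).
#' @param rise_multiple multiply the frame's rise/twist per copy (e.g. 2 for
#'   a two-rung solenoid whose molecules repeat every second rung).
#' @return the stacked [epigraft_structure].
#' @export
stack_repeats <- function(structure, frame, n_copies, rise_multiple = 1) {
  stopifnot(n_copies >= 1)
  a0 <- structure$atoms
  axis <- frame$axis_direction
  p0 <- frame$axis_point
  out <- vector("list", n_copies)
  for (k in seq_len(n_copies) - 1L) {
    theta <- k * rise_multiple * frame$twist * pi / 180
    K <- matrix(c(0, -axis[3], axis[2],
                  axis[3], 0, -axis[1],
                  -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
    R <- diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
    xyz <- as.matrix(a0[, c("x", "y", "z")])
    xyz <- sweep(xyz, 2, p0)
    xyz <- xyz %*% t(R)
    xyz <- sweep(xyz, 2, p0 + axis * k * rise_multiple * frame$rise, "+")
    ak <- a0
    ak$x <- xyz[, 1]; ak$y <- xyz[, 2]; ak$z <- xyz[, 3]
    ak$chain <- paste0(a0$chain, k)
    ak$serial <- a0$serial + k * (max(a0$serial) + 1L)
    out[[k + 1L]] <- ak
  }
  new_structure(do.call(rbind, out),
                id = paste0(structure$id, "_stack", n_copies),
                source_format = "synthetic")
}
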