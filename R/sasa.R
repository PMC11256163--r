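## Solvent-accessible surface area (Shrake-Rupley sphere sampling) and
## surface classification of graftable scaffold positions.

# Bondi-type van der Waals radii (Angstrom), heavy atoms; frozen so SASA is
# bit-stable across machines. Config-replaceable via compute_sasa(radii=).
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)
VDW_DEFAULT <- 1.80

# Theoretical maximum accessible areas (Angstrom^2) of residue X in an
# extended Gly-X-Gly tripeptide (Tien et al. 2013), used as the relative
# SASA denominator.
MAX_SASA_GXG <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
                  E = 223, Q = 225, G = 104, H = 224, I = 197,
                  L = 201, K = 236, M = 224, F = 240, P = 159,
                  S = 155, T = 172, W = 285, Y = 263, V = 174)

#' Deterministic near-uniform points on the unit sphere (golden spiral)
#'
#' @param n number of points (>= 1).
#' @return n x 3 matrix of unit vectors. No RNG: the same lattice is
#'   produced on every call and platform.
#' @export
golden_spiral_points <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  theta <- acos(1 - 2 * i / n)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = sin(theta) * cos(phi),
        y = sin(theta) * sin(phi),
        z = cos(theta))
}

#' Per-residue solvent-accessible surface area (Shrake-Rupley)
#'
#' Test points are distributed on each atom's solvent-expanded sphere
#' (radius = vdW + probe) and counted accessible when outside every
#' neighbouring expanded sphere; the accessible fraction times the sphere
#' area gives the atom's SASA, summed per residue. The golden-spiral point
#' set makes the result deterministic.
#'
#' @param structure an [epigraft_structure] (single model; heavy atoms).
#' @param probe_radius probe sphere radius in Angstrom (default 1.4, a
#'   water molecule).
#' @param n_sphere_points test points per atom (default 960; >= 92).
#' @param radii named vector of per-element vdW radii to override the
#'   packaged Bondi-type table.
#' @param subset_chains restrict *scored* atoms to these chains while all
#'   atoms still occlude (used for fibril-context exposure of one repeat).
#' @return list of class `exposure_profile`: `residues` data frame (chain,
#'   resno, resname, sasa, relative, class), `atom_sasa`, `probe_radius`,
#'   `n_sphere_points`. Classes are filled by [classify_exposure] (all
#'   `NA` here).
#' @export
compute_sasa <- function(structure, probe_radius = 1.4,
                         n_sphere_points = 960, radii = NULL,
                         subset_chains = NULL) {
  if (probe_radius <= 0) stop("probe_radius must be positive")
  if (n_sphere_points < 92) stop("need n_sphere_points >= 92")
  a <- structure$atoms
  if (length(unique(a$model)) > 1) {
    stop("multiple models present; use select_structure() first")
  }
  rad_table <- VDW_RADII
  if (!is.null(radii)) rad_table[names(radii)] <- radii
  r <- rad_table[toupper(a$element)]
  r[is.na(r)] <- VDW_DEFAULT
  r_exp <- r + probe_radius
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pts <- golden_spiral_points(n_sphere_points)
  score_idx <- if (is.null(subset_chains)) seq_len(nrow(a)) else
    which(a$chain %in% subset_chains)
  if (length(score_idx) == 0) stop("subset_chains matches no atoms")

  # neighbour candidates via a coarse cell hash
  cell <- max(r_exp) * 2
  key <- paste(floor(xyz[, 1] / cell), floor(xyz[, 2] / cell),
               floor(xyz[, 3] / cell))
  cells <- split(seq_len(nrow(a)), key)
  cell_of <- match(key, names(cells))
  neighbour_cells <- function(i) {
    cx <- floor(xyz[i, ] / cell)
    keys <- apply(expand.grid(cx[1] + (-1:1), cx[2] + (-1:1),
                              cx[3] + (-1:1)), 1, paste, collapse = " ")
    unlist(cells[intersect(keys, names(cells))], use.names = FALSE)
  }

  atom_sasa <- rep(NA_real_, nrow(a))
  for (i in score_idx) {
    cand <- neighbour_cells(i)
    cand <- cand[cand != i]
    if (length(cand) > 0) {
      d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
      cand <- cand[d2 < (r_exp[i] + r_exp[cand])^2]
    }
    sp <- sweep(pts * r_exp[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in cand) {
      if (!any(acc)) break
      dj <- rowSums(sweep(sp[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dj >= r_exp[j]^2
    }
    atom_sasa[i] <- 4 * pi * r_exp[i]^2 * sum(acc) / n_sphere_points
  }

  sub <- a[score_idx, , drop = FALSE]
  sub$atom_sasa <- atom_sasa[score_idx]
  keyr <- paste(sub$chain, sub$resno)
  agg <- aggregate(sub$atom_sasa, by = list(key = keyr), FUN = sum)
  first <- sub[!duplicated(keyr), , drop = FALSE]
  ord <- match(paste(first$chain, first$resno), agg$key)
  res <- data.frame(chain = first$chain, resno = first$resno,
                    resname = first$resname, sasa = agg$x[ord],
                    stringsAsFactors = FALSE)
  res <- res[order(res$chain, res$resno), , drop = FALSE]
  rownames(res) <- NULL
  res$relative <- res$sasa / MAX_SASA_GXG[aa321(res$resname)]
  res$class <- NA_character_
  structure(list(residues = res, atom_sasa = atom_sasa,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "exposure_profile")
}

#' @export
print.exposure_profile <- function(x, ...) {
  cat(sprintf(paste0("<exposure_profile> %d residues, probe %.2f A, ",
                     "%d points; classes: %s\n"),
              nrow(x$residues), x$probe_radius, x$n_sphere_points,
              if (all(is.na(x$residues$class))) "unset" else
                paste(names(table(x$residues$class)),
                      table(x$residues$class), collapse = " ")))
  invisible(x)
}

#' Classify residues as exposed / intermediate / buried
#'
#' Relative SASA (fraction of the Gly-X-Gly extended maximum) at or above
#' `exposed_threshold` is exposed; at or below `buried_threshold` buried;
#' in between intermediate. Only exposed or intermediate positions are
#' eligible graft sites: the design procedure substitutes residues onto the
#' *surface* of the scaffold.
#'
#' @param profile an `exposure_profile` from [compute_sasa].
#' @param exposed_threshold default 0.25.
#' @param buried_threshold default 0.05; must be below `exposed_threshold`.
#' @return the profile with the `class` column filled.
#' @export
classify_exposure <- function(profile, exposed_threshold = 0.25,
                              buried_threshold = 0.05) {
  if (buried_threshold >= exposed_threshold) {
    stop("buried_threshold must be below exposed_threshold")
  }
  rel <- profile$residues$relative
  profile$residues$class <- ifelse(rel >= exposed_threshold, "exposed",
                                   ifelse(rel <= buried_threshold, "buried",
                                          "intermediate"))
  profile
}

#' Surface exposure of a repeating unit inside its fibril
#'
#' A lone two-rung solenoid (or a single fibril layer) overstates exposure
#' at the stacking interfaces, so exposure is scored in fibrillar context:
#' `n_repeats` copies are stacked with the measured helical step and the
#' middle repeat is scored while all copies occlude.
#'
#' @param structure repeating unit, an [epigraft_structure] (single model).
#' @param frame `helical_parameters` of the repeat (e.g. molecule-on-
#'   molecule stacking: for a two-rung solenoid use `rise_multiple = 2`).
#' @param n_repeats number of stacked copies (default 5; odd, >= 3).
#' @param rise_multiple rise/twist units per molecular repeat (default 2:
#'   one molecule spans two rungs).
#' @param ... passed to [compute_sasa].
#' @return `exposure_profile` of the middle repeat; `resno`/`chain` refer
#'   to the original unit.
#' @export
fibril_context_exposure <- function(structure, frame, n_repeats = 5,
                                    rise_multiple = 2, ...) {
  if (n_repeats < 3 || n_repeats %% 2 == 0) {
    stop("n_repeats must be odd and >= 3")
  }
  stacked <- stack_repeats(structure, frame, n_repeats,
                           rise_multiple = rise_multiple)
  mid <- (n_repeats - 1) %/% 2
  mid_chains <- paste0(unique(structure$atoms$chain), mid)
  prof <- compute_sasa(stacked, subset_chains = mid_chains, ...)
  # map middle-copy chain labels back to the original unit's labels
  prof$residues$chain <- sub(paste0(mid, "$"), "", prof$residues$chain)
  prof
}

#' Assign strand residues to alternating faces of a beta-strand
#'
#' In a beta-strand consecutive side chains point to opposite faces of the
#' sheet, so residues spaced two apart share a face — the geometry that
#' makes a parallel in-register fibril display `i, i+2, i+4, ...` on one
#' surface. The side-chain direction (C-alpha to C-beta; a pseudo-C-beta
#' reconstructed from the backbone for glycine) is projected perpendicular
#' to the strand axis and classified by the sign of its component along the
#' first residue's direction.
#'
#' @param structure an [epigraft_structure] (single model).
#' @param chain chain id.
#' @param segment length-2 vector `c(start, end)` in author numbering
#'   (a strand from [segment_strands]).
#' @return data frame with resno and face (`"A"` / `"B"`).
#' @export
strand_face_parity <- function(structure, chain, segment) {
  resnos <- seq(segment[1], segment[2])
  ca <- atom_coords(structure, chain, "CA", resnos)
  a <- structure$atoms
  cb_dir <- matrix(NA_real_, length(resnos), 3)
  for (i in seq_along(resnos)) {
    rsel <- a$chain == chain & a$resno == resnos[i]
    cb <- a[rsel & a$name == "CB", c("x", "y", "z")]
    if (nrow(cb) == 1) {
      cb_dir[i, ] <- as.numeric(cb) - ca[i, ]
    } else {
      # pseudo-CB from backbone (glycine or missing CB)
      N <- a[rsel & a$name == "N", c("x", "y", "z")]
      C <- a[rsel & a$name == "C", c("x", "y", "z")]
      if (nrow(N) == 0 || nrow(C) == 0) {
        stop("cannot build pseudo-CB for residue ", resnos[i],
             ": missing backbone atoms")
      }
      pcb <- place_atom(as.numeric(C[1, ]), as.numeric(N[1, ]), ca[i, ],
                        BB$b_ca_cb, BB$a_n_ca_cb, BB$t_c_n_ca_cb)
      cb_dir[i, ] <- pcb - ca[i, ]
    }
  }
  # strand axis: dominant direction of the CA trace
  axis <- prcomp(ca)$rotation[, 1]
  perp <- cb_dir - outer(as.vector(cb_dir %*% axis), axis)
  ref <- perp[1, ]
  face <- ifelse(as.vector(perp %*% ref) > 0, "A", "B")
  data.frame(resno = resnos, face = face)
}
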