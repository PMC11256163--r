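## The stacked-graft design procedure: map a surface epitope of a donor
## parallel in-register fibril onto both rungs of a beta-solenoid scaffold.
## One donor molecule maps onto rung 1; because the donor fibril stacks
## identical molecules in register, the second stacked molecule contributes
## the same residues again, one rung (offset Delta) further along the
## scaffold -- so each donor residue is written at position p and p + Delta.

#' Extract an epitope patch from a donor fibril structure
#'
#' @param donor an [epigraft_structure] (single model).
#' @param chain donor chain id.
#' @param residue_numbers author numbers of the epitope residues
#'   (ascending).
#' @param require_exposed reject buried donor residues (default FALSE).
#' @param profile an `exposure_profile` with classes filled (required when
#'   `require_exposed`); fibril-context exposure is the appropriate input.
#' @return list of class `epitope_patch`: `donor_id`, `source_chain`,
#'   `residues` data frame (resno, code).
#' @export
extract_epitope <- function(donor, chain, residue_numbers,
                            require_exposed = FALSE, profile = NULL) {
  if (length(residue_numbers) == 0) stop("empty epitope")
  residue_numbers <- as.integer(residue_numbers)
  if (is.unsorted(residue_numbers, strictly = TRUE)) {
    stop("epitope residue numbers must be strictly increasing")
  }
  a <- donor$atoms
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", chain, " not present in donor")
  absent <- setdiff(residue_numbers, unique(a$resno))
  if (length(absent) > 0) {
    stop("donor residue(s) absent: ", paste(absent, collapse = ", "))
  }
  first <- a[!duplicated(a$resno), , drop = FALSE]
  codes <- aa321(first$resname[match(residue_numbers, first$resno)])
  if (require_exposed) {
    if (is.null(profile) || all(is.na(profile$residues$class))) {
      stop("require_exposed needs a classified exposure profile")
    }
    pr <- profile$residues[profile$residues$chain == chain, , drop = FALSE]
    cls <- pr$class[match(residue_numbers, pr$resno)]
    if (any(is.na(cls))) {
      stop("exposure profile does not cover residue(s): ",
           paste(residue_numbers[is.na(cls)], collapse = ", "))
    }
    if (any(cls == "buried")) {
      stop("buried donor residue(s) rejected: ",
           paste(residue_numbers[cls == "buried"], collapse = ", "))
    }
  }
  structure(list(donor_id = donor$id, source_chain = chain,
                 residues = data.frame(resno = residue_numbers,
                                       code = codes)),
            class = "epitope_patch")
}

#' Construct an epitope patch from residue codes
#'
#' For donors whose structure (or exact residue numbering) is not at hand
#' — e.g. reconstructing a published design from its substitution list,
#' where only the grafted residue identities are known — a patch can be
#' written down directly. Provenance accepts `"unknown"`.
#'
#' @param codes one-letter residue codes (standard 20).
#' @param resnos donor author numbers (ascending); defaults to
#'   `seq_along(codes)` when the true numbering is unknown.
#' @param donor_id donor identifier (default `"unknown"`).
#' @param chain donor chain label (default `"?"`).
#' @return an `epitope_patch`.
#' @export
epitope_patch <- function(codes, resnos = seq_along(codes),
                          donor_id = "unknown", chain = "?") {
  codes <- as.character(codes)
  bad <- setdiff(unique(codes), names(AA1TO3))
  if (length(bad) > 0) {
    stop("non-standard residue code(s): ", paste(bad, collapse = ", "))
  }
  if (length(resnos) != length(codes)) {
    stop("codes and resnos differ in length")
  }
  if (is.unsorted(resnos, strictly = TRUE)) {
    stop("resnos must be strictly increasing")
  }
  structure(list(donor_id = donor_id, source_chain = chain,
                 residues = data.frame(resno = as.integer(resnos),
                                       code = codes)),
            class = "epitope_patch")
}

#' @export
print.epitope_patch <- function(x, ...) {
  cat(sprintf("<epitope_patch> %s chain %s: %s\n", x$donor_id,
              x$source_chain,
              paste0(x$residues$code, x$residues$resno, collapse = " ")))
  invisible(x)
}

#' Build a donor-to-scaffold site mapping
#'
#' Donor residues are always assigned to rung-1 positions; rung-2 positions
#' are derived through the rung offset, never specified independently
#' (this enforces the two-molecules-per-two-rungs stack mimicry).
#'
#' @param donor_resnos donor author numbers (ascending).
#' @param scaffold_positions rung-1 scaffold author numbers (ascending,
#'   unique, same length).
#' @param rung_map a `rung_map` from [detect_rung_offset]; rung-1 positions
#'   must fall inside its rung-1 range.
#' @return list of class `site_mapping`.
#' @export
site_mapping <- function(donor_resnos, scaffold_positions, rung_map) {
  donor_resnos <- as.integer(donor_resnos)
  scaffold_positions <- as.integer(scaffold_positions)
  if (length(donor_resnos) != length(scaffold_positions)) {
    stop("donor and scaffold position lists differ in length")
  }
  if (anyDuplicated(scaffold_positions)) {
    stop("scaffold positions must be unique")
  }
  if (is.unsorted(scaffold_positions, strictly = TRUE)) {
    stop("scaffold positions must be strictly increasing")
  }
  out <- scaffold_positions < rung_map$rung1_range[1] |
    scaffold_positions > rung_map$rung1_range[2]
  if (any(out)) {
    stop("scaffold position(s) outside rung-1 range ",
         rung_map$rung1_range[1], "-", rung_map$rung1_range[2], ": ",
         paste(scaffold_positions[out], collapse = ", "))
  }
  structure(list(assignments = data.frame(donor = donor_resnos,
                                          scaffold = scaffold_positions),
                 rung_map = rung_map),
            class = "site_mapping")
}

#' Superpose a donor epitope onto its scaffold acceptor site
#'
#' Rigid-body (Kabsch, proper rotation only) superposition of the donor
#' epitope C-alphas onto the mapped scaffold rung-1 C-alphas, reporting the
#' geometric compatibility of the graft.
#'
#' @param patch an `epitope_patch`.
#' @param donor,scaffold [epigraft_structure]s (single model).
#' @param mapping a `site_mapping` covering the patch residues.
#' @param scaffold_chain scaffold chain id (default first chain).
#' @param profile optional classified `exposure_profile` of the scaffold;
#'   fills `exposure_fraction` (fraction of target sites exposed).
#' @return list of class `graft_score`: `ca_rmsd`, `exposure_fraction`,
#'   `parity_consistent` (do mapped scaffold positions preserve the donor
#'   residues' two-residue spacing parity?), `n_identity_skipped` (0 here;
#'   filled by [design_stacked_graft]).
#' @export
superpose_epitope <- function(patch, donor, scaffold, mapping,
                              scaffold_chain = NULL, profile = NULL) {
  asg <- mapping$assignments
  idx <- match(patch$residues$resno, asg$donor)
  if (any(is.na(idx))) {
    stop("mapping does not cover donor residue(s): ",
         paste(patch$residues$resno[is.na(idx)], collapse = ", "))
  }
  if (nrow(patch$residues) < 3) {
    stop("superposition underdetermined: need >= 3 mapped positions")
  }
  if (is.null(scaffold_chain)) scaffold_chain <- scaffold$atoms$chain[1]
  don_ca <- atom_coords(donor, patch$source_chain, "CA",
                        patch$residues$resno)
  sca_ca <- atom_coords(scaffold, scaffold_chain, "CA",
                        asg$scaffold[idx])
  fit <- kabsch(don_ca, sca_ca)
  exposure_fraction <- NA_real_
  if (!is.null(profile) && !all(is.na(profile$residues$class))) {
    pr <- profile$residues[profile$residues$chain == scaffold_chain, ,
                           drop = FALSE]
    cls <- pr$class[match(asg$scaffold[idx], pr$resno)]
    exposure_fraction <- mean(cls == "exposed", na.rm = TRUE)
  }
  d_par <- diff(patch$residues$resno) %% 2
  s_par <- diff(asg$scaffold[idx]) %% 2
  structure(list(ca_rmsd = fit$rmsd,
                 exposure_fraction = exposure_fraction,
                 parity_consistent = all(d_par == s_par),
                 n_identity_skipped = 0L),
            class = "graft_score")
}

#' @export
print.graft_score <- function(x, ...) {
  cat(sprintf(paste0("<graft_score> Ca rmsd %.3f A, exposure %.2f, ",
                     "parity %s, %d identity-skipped\n"),
              x$ca_rmsd, x$exposure_fraction,
              ifelse(isTRUE(x$parity_consistent), "ok", "violated"),
              x$n_identity_skipped))
  invisible(x)
}

#' Design a two-rung stacked graft
#'
#' For every donor residue `x` assigned to rung-1 position `p`, the design
#' substitutes `x` at `p` and at its rung-2 partner `p + Delta`, so that
#' when the engineered solenoid self-stacks every rung carries the same
#' substitutions — mimicking two donor molecules stacked in register.
#' A substitution whose target already equals the scaffold wild type is
#' dropped (identity-dropping) and counted; this is what produces
#' asymmetric lists such as a rung-2-only edit.
#'
#' @param scaffold_seq [seq_record] of the scaffold (author numbering).
#' @param rung_map `rung_map` giving the offset Delta.
#' @param patch `epitope_patch` of donor residues.
#' @param mapping `site_mapping` of donor residues to rung-1 positions.
#' @param name construct name.
#' @param score optional `graft_score` to attach.
#' @return list of class `construct_design`: `name`, `scaffold_id`,
#'   `substitutions` data frame (position, wt, new, rung; sorted by
#'   position), `provenance`, `score`.
#' @export
design_stacked_graft <- function(scaffold_seq, rung_map, patch, mapping,
                                 name, score = NULL) {
  asg <- mapping$assignments
  idx <- match(patch$residues$resno, asg$donor)
  if (any(is.na(idx))) {
    stop("mapping does not cover donor residue(s): ",
         paste(patch$residues$resno[is.na(idx)], collapse = ", "))
  }
  offset <- rung_map$offset
  subs <- list()
  n_skip <- 0L
  for (k in seq_len(nrow(patch$residues))) {
    x <- patch$residues$code[k]
    if (x == "X") {
      stop("donor residue ", patch$residues$resno[k],
           " is non-standard ('X'); cannot graft")
    }
    p <- asg$scaffold[idx[k]]
    for (rung in 1:2) {
      pos <- p + (rung - 1L) * offset
      wt <- seq_letter(scaffold_seq, pos)  # errors if outside sequence
      if (wt == x) {
        n_skip <- n_skip + 1L
      } else {
        subs[[length(subs) + 1]] <- data.frame(
          position = pos, wt = wt, new = x, rung = rung)
      }
    }
  }
  subs <- if (length(subs) > 0) do.call(rbind, subs) else
    data.frame(position = integer(0), wt = character(0),
               new = character(0), rung = integer(0))
  subs <- subs[order(subs$position), , drop = FALSE]
  rownames(subs) <- NULL
  if (is.null(score)) {
    score <- structure(list(ca_rmsd = NA_real_,
                            exposure_fraction = NA_real_,
                            parity_consistent = NA,
                            n_identity_skipped = n_skip),
                       class = "graft_score")
  } else {
    score$n_identity_skipped <- n_skip
  }
  new_construct_design(
    name = name, scaffold_id = scaffold_seq$id, substitutions = subs,
    provenance = list(donor_id = patch$donor_id,
                      donor_chain = patch$source_chain,
                      epitope = paste0(patch$residues$code,
                                       patch$residues$resno),
                      rung_offset = offset,
                      mapping = asg),
    score = score)
}

#' Construct-design container
#'
#' @param name construct name.
#' @param scaffold_id scaffold identifier.
#' @param substitutions data frame with position, wt, new, rung.
#' @param provenance list (donor id, epitope, mapping, citation, ...);
#'   `"unknown"` entries are allowed.
#' @param score optional `graft_score`.
#' @return list of class `construct_design`.
#' @export
new_construct_design <- function(name, scaffold_id, substitutions,
                                 provenance = list(), score = NULL) {
  stopifnot(all(c("position", "wt", "new", "rung") %in%
                  names(substitutions)))
  if (anyDuplicated(substitutions$position)) {
    stop("duplicate substitution positions")
  }
  if (any(substitutions$wt == substitutions$new)) {
    stop("identity substitutions (wt == new) must be dropped, not stored")
  }
  substitutions <- substitutions[order(substitutions$position), ,
                                 drop = FALSE]
  rownames(substitutions) <- NULL
  structure(list(name = name, scaffold_id = scaffold_id,
                 substitutions = substitutions, provenance = provenance,
                 score = score),
            class = "construct_design")
}

#' @export
print.construct_design <- function(x, ...) {
  cat(sprintf("<construct_design> %s on %s: %d substitutions\n",
              x$name, x$scaffold_id, nrow(x$substitutions)))
  s <- x$substitutions
  for (r in 1:2) {
    sr <- s[s$rung == r, , drop = FALSE]
    if (nrow(sr) > 0) {
      cat(sprintf("  rung %d: %s\n", r,
                  paste0(sr$wt, sr$position, sr$new, collapse = ", ")))
    }
  }
  invisible(x)
}

#' Substitution identifiers ("K229Q") of a design
#' @param design a `construct_design`.
#' @return character vector in position order.
#' @export
substitution_ids <- function(design) {
  s <- design$substitutions
  paste0(s$wt, s$position, s$new)
}

#' Validate a design against the scaffold sequence and rung map
#'
#' Report-only (never mutates the design). Flags:
#' \describe{
#'   \item{wt_mismatch}{stored wild-type letter disagrees with the scaffold
#'     sequence at that position}
#'   \item{asymmetry}{a substitution whose rung partner at `position +/-
#'     Delta` neither appears in the design with the same new residue nor
#'     is explainable by identity-dropping (partner wild type already equal
#'     to the new residue)}
#'   \item{outside_rung_range}{position outside the rung map's ranges}
#' }
#'
#' @param design a `construct_design`.
#' @param scaffold_seq [seq_record] of the scaffold.
#' @param rung_map `rung_map` with offset Delta.
#' @return data frame with columns position, flag, detail (zero rows for a
#'   clean design).
#' @export
validate_design <- function(design, scaffold_seq, rung_map) {
  s <- design$substitutions
  flags <- list()
  add <- function(position, flag, detail) {
    flags[[length(flags) + 1]] <<- data.frame(position = position,
                                              flag = flag, detail = detail)
  }
  offset <- rung_map$offset
  seq_last <- scaffold_seq$start_number + nchar(scaffold_seq$sequence) - 1L
  in_seq <- function(p) p >= scaffold_seq$start_number & p <= seq_last
  for (k in seq_len(nrow(s))) {
    p <- s$position[k]
    if (!in_seq(p)) {
      add(p, "outside_sequence", sprintf("position %d outside %d-%d", p,
                                         scaffold_seq$start_number,
                                         seq_last))
      next
    }
    wt_seq <- seq_letter(scaffold_seq, p)
    if (wt_seq != s$wt[k]) {
      add(p, "wt_mismatch",
          sprintf("stored wt %s but scaffold has %s at %d", s$wt[k],
                  wt_seq, p))
    }
    rng <- if (s$rung[k] == 1) rung_map$rung1_range else
      rung_map$rung2_range
    if (p < rng[1] || p > rng[2]) {
      add(p, "outside_rung_range",
          sprintf("position %d outside rung-%d range %d-%d", p, s$rung[k],
                  rng[1], rng[2]))
    }
    partner <- if (s$rung[k] == 1) p + offset else p - offset
    if (!in_seq(partner)) {
      add(p, "asymmetry",
          sprintf("rung partner %d outside the scaffold sequence", partner))
      next
    }
    partner_sub <- s[s$position == partner, , drop = FALSE]
    if (nrow(partner_sub) == 1 && partner_sub$new == s$new[k]) next
    if (seq_letter(scaffold_seq, partner) == s$new[k]) next  # identity-drop
    add(p, "asymmetry",
        sprintf("%s%d%s has no rung partner at %d carrying %s", s$wt[k], p,
                s$new[k], partner, s$new[k]))
  }
  if (length(flags) == 0) {
    return(data.frame(position = integer(0), flag = character(0),
                      detail = character(0)))
  }
  out <- do.call(rbind, flags)
  rownames(out) <- NULL
  out
}
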