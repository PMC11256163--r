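#' @title Atomic structure container
#'
#' @description An `epigraft_structure` is a light container around a
#' data frame of heavy atoms. Author residue numbering is preserved verbatim
#' (HET-s(218-289) runs 218-289) and is the only numbering used anywhere in
#' the package: every substitution identifier such as "K229Q" refers to it.
#'
#' Columns of the atom table:
#' \describe{
#'   \item{serial}{atom serial number (integer)}
#'   \item{name}{atom name, e.g. "CA"}
#'   \item{element}{element symbol}
#'   \item{x, y, z}{coordinates in Angstrom}
#'   \item{resname}{3-letter residue code}
#'   \item{resno}{author residue number (any integer)}
#'   \item{ins}{insertion code ("" when absent)}
#'   \item{chain}{chain identifier}
#'   \item{model}{model number (integer, >= 1)}
#'   \item{occ, b}{occupancy and B-factor}
#' }
#' @name epigraft_structure
NULL

ATOM_COLS <- c("serial", "name", "element", "x", "y", "z",
               "resname", "resno", "ins", "chain", "model", "occ", "b")

#' Create a structure object from an atom table
#'
#' @param atoms data frame with the columns described in
#'   [epigraft_structure].
#' @param id free-text identifier.
#' @param source_format one of `"pdb"`, `"mmcif"`, `"synthetic"`.
#' @return An object of class `epigraft_structure`.
#' @export
new_structure <- function(atoms, id = "structure", source_format = "synthetic") {
  stopifnot(is.data.frame(atoms))
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in atom table")
  }
  source_format <- match.arg(source_format, c("pdb", "mmcif", "synthetic"))
  atoms <- atoms[order(atoms$model, atoms$chain, atoms$resno, atoms$serial), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, id = id, source_format = source_format),
            class = "epigraft_structure")
}

#' @export
print.epigraft_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("<epigraft_structure> %s [%s]\n", x$id, x$source_format))
  cat(sprintf("  %d atoms, %d model(s), chains: %s\n",
              nrow(a), length(unique(a$model)),
              paste(sort(unique(a$chain)), collapse = " ")))
  rng <- range(a$resno)
  cat(sprintf("  residues %d-%d\n", rng[1], rng[2]))
  invisible(x)
}

#' Number of atoms in a structure
#' @param structure an [epigraft_structure].
#' @return integer atom count.
#' @export
n_atoms <- function(structure) nrow(structure$atoms)

#' Subset a structure by model, chains and residue range
#'
#' All bounds are inclusive and use author residue numbering.
#'
#' @param structure an [epigraft_structure].
#' @param model model number to keep (default 1; NMR ensembles default to the
#'   first model).
#' @param chains character vector of chain ids, or NULL for all chains.
#' @param residue_range length-2 integer vector `c(first, last)` in author
#'   numbering, or NULL for all residues.
#' @return the filtered `epigraft_structure`.
#' @export
select_structure <- function(structure, model = 1L, chains = NULL,
                             residue_range = NULL) {
  a <- structure$atoms
  if (!model %in% a$model) {
    stop("model ", model, " not present (available: ",
         paste(sort(unique(a$model)), collapse = ", "), ")")
  }
  keep <- a$model == model
  if (!is.null(chains)) {
    absent <- setdiff(chains, unique(a$chain[keep]))
    if (length(absent) > 0) {
      stop("chain(s) not present: ", paste(absent, collapse = ", "))
    }
    keep <- keep & a$chain %in% chains
  }
  if (!is.null(residue_range)) {
    stopifnot(length(residue_range) == 2)
    keep <- keep & a$resno >= residue_range[1] & a$resno <= residue_range[2]
  }
  if (!any(keep)) stop("empty selection")
  new_structure(a[keep, , drop = FALSE], id = structure$id,
                source_format = structure$source_format)
}

#' Coordinates of one named atom per residue
#'
#' @param structure an [epigraft_structure] (single model assumed; pre-filter
#'   with [select_structure]).
#' @param chain chain id.
#' @param atom_name atom name, default `"CA"`.
#' @param resnos optional author residue numbers; default all that carry the
#'   atom, in ascending order.
#' @return matrix with one row per residue (rownames = residue numbers) and
#'   columns x, y, z.
#' @export
atom_coords <- function(structure, chain, atom_name = "CA", resnos = NULL) {
  a <- structure$atoms
  sel <- a$chain == chain & a$name == atom_name
  if (!any(sel)) stop("no '", atom_name, "' atoms in chain ", chain)
  a <- a[sel, , drop = FALSE]
  if (anyDuplicated(a$resno)) {
    a <- a[!duplicated(a$resno), , drop = FALSE]
  }
  if (is.null(resnos)) {
    resnos <- sort(a$resno)
  } else {
    absent <- setdiff(resnos, a$resno)
    if (length(absent) > 0) {
      stop("residue(s) lacking ", atom_name, " in chain ", chain, ": ",
           paste(absent, collapse = ", "))
    }
  }
  idx <- match(resnos, a$resno)
  m <- as.matrix(a[idx, c("x", "y", "z")])
  rownames(m) <- resnos
  m
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLU = "E", GLN = "Q", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

AA1TO3 <- setNames(names(AA3TO1), unname(AA3TO1))

#' One-letter code for a 3-letter residue name
#'
#' Non-standard residues (e.g. MSE) map to "X"; such positions are never
#' offered as design sites.
#' @param resname character vector of 3-letter codes.
#' @return character vector of one-letter codes.
#' @export
aa321 <- function(resname) {
  out <- AA3TO1[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}
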