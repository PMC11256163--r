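#' @importFrom bio3d read.pdb
NULL

# Strict pre-scan of coordinate records so malformed files fail loudly
# instead of being silently skipped by a lenient parser.
validate_pdb_lines <- function(lines, path) {
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) stop("no ATOM/HETATM records in ", path)
  bad <- which(is_coord & nchar(lines) < 54)
  if (length(bad) > 0) {
    stop("truncated ATOM/HETATM record at line ", bad[1], " of ", path)
  }
  for (i in which(is_coord)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz))) {
      stop("unparseable coordinates at line ", i, " of ", path)
    }
  }
  invisible(TRUE)
}

read_structure_pdb <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  n_models <- nrow(pdb$xyz)
  one <- function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    data.frame(serial = at$eleno, name = at$elety,
               element = ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(gsub("[0-9]", "", at$elety), 1, 1),
                                at$elesy),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               resname = at$resid, resno = at$resno,
               ins = ifelse(is.na(at$insert), "", at$insert),
               chain = ifelse(is.na(at$chain), "A", at$chain),
               model = m,
               occ = ifelse(is.na(at$o), 1, at$o),
               b = ifelse(is.na(at$b), 0, at$b),
               stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, lapply(seq_len(n_models), one))
  atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  new_structure(atoms, id = id, source_format = "pdb")
}

# Minimal mmCIF atom_site reader (loop_ category only). No installed R
# package parses mmCIF, so this covers exactly the fields the package needs.
read_structure_mmcif <- function(path, id) {
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^_atom_site\\.", lines)
  if (length(hdr_idx) == 0) stop("no _atom_site category in ", path)
  fields <- sub("^_atom_site\\.", "", trimws(lines[hdr_idx]))
  body_start <- max(hdr_idx) + 1
  rows <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0) stop("empty atom_site loop in ", path)
  toks <- strsplit(rows, "[[:space:]]+")
  nf <- length(fields)
  bad <- which(vapply(toks, length, 1L) != nf)
  if (length(bad) > 0) {
    stop("malformed atom_site row ", bad[1], " in ", path,
         " (expected ", nf, " fields)")
  }
  m <- do.call(rbind, toks)
  colnames(m) <- fields
  pick <- function(primary, fallback = NULL, default = NA_character_) {
    if (primary %in% fields) return(m[, primary])
    if (!is.null(fallback) && fallback %in% fields) return(m[, fallback])
    rep(default, nrow(m))
  }
  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out))) stop("non-numeric ", what, " in atom_site of ", path)
    out
  }
  ins <- pick("pdbx_PDB_ins_code", default = "")
  ins[ins %in% c("?", ".")] <- ""
  model <- pick("pdbx_PDB_model_num", default = "1")
  occ <- suppressWarnings(as.numeric(pick("occupancy", default = "1")))
  b <- suppressWarnings(as.numeric(pick("B_iso_or_equiv", default = "0")))
  atoms <- data.frame(
    serial = as.integer(num(pick("id"), "id")),
    name = pick("auth_atom_id", "label_atom_id"),
    element = pick("type_symbol", default = ""),
    x = num(pick("Cartn_x"), "Cartn_x"),
    y = num(pick("Cartn_y"), "Cartn_y"),
    z = num(pick("Cartn_z"), "Cartn_z"),
    resname = pick("auth_comp_id", "label_comp_id"),
    resno = as.integer(num(pick("auth_seq_id", "label_seq_id"), "seq_id")),
    ins = ins,
    chain = pick("auth_asym_id", "label_asym_id", default = "A"),
    model = as.integer(num(model, "model number")),
    occ = ifelse(is.na(occ), 1, occ),
    b = ifelse(is.na(b), 0, b),
    stringsAsFactors = FALSE)
  atoms$name <- gsub('"', "", atoms$name)
  atoms <- atoms[!(toupper(atoms$element) %in% c("H", "D")), , drop = FALSE]
  new_structure(atoms, id = id, source_format = "mmcif")
}

#' Read a protein structure from PDB or mmCIF
#'
#' Hydrogens are dropped on read (heavy-atom convention used by standard
#' solvent-accessibility implementations). Author residue numbers and
#' insertion codes are preserved unchanged; all models are returned.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or NULL to auto-detect from the file
#'   extension (falling back to content sniffing).
#' @param id identifier for the returned structure; defaults to the file
#'   base name.
#' @return an [epigraft_structure].
#' @export
read_structure <- function(path, format = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", cif = "mmcif",
                     mmcif = "mmcif", NA_character_)
    if (is.na(format)) {
      head_lines <- readLines(path, n = 50, warn = FALSE)
      format <- if (any(grepl("^(data_|_atom_site\\.)", head_lines)))
        "mmcif" else "pdb"
    }
  }
  switch(match.arg(format, c("pdb", "mmcif")),
         pdb = read_structure_pdb(path, id),
         mmcif = read_structure_mmcif(path, id))
}

#' Write a structure to a PDB or mmCIF file
#'
#' @param structure an [epigraft_structure].
#' @param path output path; the extension picks the format unless `format`
#'   is given.
#' @param format `"pdb"`, `"mmcif"` or NULL (from extension).
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  format <- match.arg(format, c("pdb", "mmcif"))
  a <- structure$atoms
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "pdb") {
    models <- sort(unique(a$model))
    multi <- length(models) > 1
    for (m in models) {
      if (multi) writeLines(sprintf("MODEL     %4d", m), con)
      am <- a[a$model == m, , drop = FALSE]
      nm <- ifelse(nchar(am$name) < 4, sprintf(" %-3s", am$name),
                   sprintf("%-4s", am$name))
      writeLines(sprintf(
        "ATOM  %5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        am$serial %% 100000L, nm, "", am$resname, am$chain, am$resno,
        ifelse(am$ins == "", " ", am$ins), am$x, am$y, am$z, am$occ, am$b,
        toupper(am$element)), con)
      if (multi) writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    writeLines(c(sprintf("data_%s", gsub("[^A-Za-z0-9_]", "_", structure$id)),
                 "loop_",
                 "_atom_site.group_PDB", "_atom_site.id",
                 "_atom_site.type_symbol", "_atom_site.auth_atom_id",
                 "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
                 "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
                 "_atom_site.Cartn_x", "_atom_site.Cartn_y",
                 "_atom_site.Cartn_z", "_atom_site.occupancy",
                 "_atom_site.B_iso_or_equiv",
                 "_atom_site.pdbx_PDB_model_num"), con)
    writeLines(sprintf(
      "ATOM %d %s %s %s %s %d %s %.3f %.3f %.3f %.2f %.2f %d",
      a$serial, toupper(a$element), a$name, a$resname, a$chain, a$resno,
      ifelse(a$ins == "", "?", a$ins), a$x, a$y, a$z, a$occ, a$b, a$model),
      con)
    writeLines("#", con)
  }
  invisible(path)
}

#' Create a sequence record
#'
#' @param id record identifier.
#' @param sequence one-letter amino-acid string (standard 20 letters plus
#'   "X" for non-standard residues).
#' @param start_number author number of the first residue, so that position
#'   arithmetic (`start_number + nchar(sequence) - 1` = last residue) holds.
#' @return an object of class `seq_record`.
#' @export
seq_record <- function(id, sequence, start_number = 1L) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (nchar(sequence) == 0) stop("empty sequence")
  letters_used <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(letters_used), c(names(AA1TO3), "X"))
  if (length(bad) > 0) {
    stop("invalid sequence letter(s): ", paste(bad, collapse = ", "))
  }
  structure(list(id = id, sequence = sequence,
                 start_number = as.integer(start_number)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d aa, residues %d-%d)\n", x$id,
              nchar(x$sequence), x$start_number,
              x$start_number + nchar(x$sequence) - 1L))
  invisible(x)
}

#' Letter at an author-numbered position of a sequence record
#' @param record a [seq_record].
#' @param position author residue number(s).
#' @return one-letter code(s).
#' @export
seq_letter <- function(record, position) {
  idx <- position - record$start_number + 1L
  if (any(idx < 1 | idx > nchar(record$sequence))) {
    stop("position(s) outside sequence range ",
         record$start_number, "-",
         record$start_number + nchar(record$sequence) - 1L, ": ",
         paste(position[idx < 1 | idx > nchar(record$sequence)],
               collapse = ", "))
  }
  vapply(idx, function(i) substr(record$sequence, i, i), "")
}

#' Extract the one-letter sequence of a chain
#'
#' Residues are taken in author-number order; non-standard residues map to
#' "X", as do any numbering gaps (keeping position arithmetic valid).
#'
#' @param structure an [epigraft_structure], filtered to one model.
#' @param chain chain id.
#' @return a [seq_record] whose `start_number` is the chain's first author
#'   residue number.
#' @export
extract_sequence <- function(structure, chain) {
  a <- structure$atoms
  if (length(unique(a$model)) > 1) {
    stop("multiple models present; use select_structure() first")
  }
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("chain ", chain, " not present")
  a <- a[!duplicated(a$resno), , drop = FALSE]
  a <- a[order(a$resno), , drop = FALSE]
  codes <- aa321(a$resname)
  if (all(codes == "X")) stop("chain ", chain, " has no amino-acid residues")
  first <- min(a$resno); last <- max(a$resno)
  seq_full <- rep("X", last - first + 1L)
  seq_full[a$resno - first + 1L] <- codes
  seq_record(id = paste0(structure$id, "_", chain),
             sequence = paste(seq_full, collapse = ""),
             start_number = first)
}

#' Write sequence records as FASTA
#'
#' @param records a list of [seq_record] objects (or a single one).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (length(records) == 0) stop("no records to write")
  ok <- vapply(records, inherits, TRUE, what = "seq_record")
  if (!all(ok)) stop("all records must be seq_record objects")
  seqinr::write.fasta(
    sequences = lapply(records, function(r) strsplit(r$sequence, "")[[1]]),
    names = vapply(records, function(r) r$id, ""),
    file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a FASTA file into sequence records
#'
#' @param path FASTA file.
#' @param start_number author number of the first residue (applied to every
#'   record; default 1).
#' @return list of [seq_record].
#' @export
read_fasta <- function(path, start_number = 1L) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  lapply(names(seqs), function(nm) {
    seq_record(nm, toupper(as.character(seqs[[nm]])), start_number)
  })
}
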