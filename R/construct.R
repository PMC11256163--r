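## Turning designs into deliverable sequences and reports, and the four
## published HET-s(218-289) alpha-synuclein vaccine-candidate presets.

PRESET_SOURCE <- paste("published stacked-graft vaccine-candidate designs",
                       "on the HET-s(218-289) beta-solenoid scaffold,",
                       "stored verbatim (rung labels included)")

#' Reference sequence of the HET-s(218-289) scaffold
#'
#' The 72-residue prion domain of the fungal HET-s protein (author
#' numbering 218-289), bundled with the package; all substitution
#' identifiers (e.g. "K229Q") refer to this numbering. The 18 wild-type
#' letters named across the four preset substitution lists agree with this
#' sequence, except the known alpha-SC3 "K269G" entry that
#' [validate_design] flags (the sequence has G269/K270).
#'
#' @return a [seq_record] with `start_number` 218.
#' @export
scaffold_sequence <- function() {
  path <- system.file("extdata", "hets218_289_scaffold.fasta",
                      package = "epigraft", mustWork = TRUE)
  read_fasta(path, start_number = 218L)[[1]]
}

#' Reference sequence of human alpha-synuclein
#'
#' 140 residues; the fibril core (residues 61-95) is the key determinant
#' of aggregation and the source of surface epitopes.
#'
#' @return a [seq_record] with `start_number` 1.
#' @export
donor_sequence <- function() {
  path <- system.file("extdata", "alpha_synuclein.fasta",
                      package = "epigraft", mustWork = TRUE)
  read_fasta(path, start_number = 1L)[[1]]
}

#' Synthetic stand-in for the HET-s(218-289) scaffold structure
#'
#' An idealized two-rung beta-solenoid (four strands per rung, 36 residues
#' per rung, offset 36) carrying the bundled HET-s(218-289) sequence.
#' This is a generated idealization of the solenoid architecture, not
#' experimental coordinates: rise and twist are exactly the requested
#' values and the rung repeat is exact. The strand layout places the
#' grafted surface sites (225-236 and their rung-2 partners 261-272) on
#' one long strand per rung.
#'
#' @param rise rise per rung in Angstrom (default 4.8, the canonical
#'   cross-beta spacing).
#' @param twist twist per rung in degrees (default -3, left-handed).
#' @return an [epigraft_structure] (chain "A", residues 218-289).
#' @export
scaffold_structure <- function(rise = 4.8, twist = -3) {
  seq <- scaffold_sequence()
  spec <- solenoid_spec(
    n_rungs = 2L, residues_per_rung = 36L, rise = rise, twist = twist,
    strand_layout = list(c(4, 2), c(14, 3), c(6, 2), c(3, 2)),
    sequence = seq$sequence, start_number = 218L)
  s <- make_ideal_solenoid(spec)
  s$id <- "hets218_289_synthetic"
  s
}

#' Synthetic stand-in for an alpha-synuclein fibril structure
#'
#' An idealized parallel in-register fibril: stacked copies of the full
#' 140-residue alpha-synuclein chain in extended conformation, successive
#' chains one helical step apart. A generated idealization of the
#' cross-beta stacking (residue i above residue i), not the experimental
#' fold of the monomer.
#'
#' @param n_chains stacked chains (default 5).
#' @param rise rise per chain in Angstrom (default 4.8).
#' @param twist twist per chain in degrees (default -1).
#' @return an [epigraft_structure] (chains "A", "B", ..., residues 1-140).
#' @export
donor_fibril_structure <- function(n_chains = 5L, rise = 4.8, twist = -1) {
  seq <- donor_sequence()
  s <- make_in_register_fibril(fibril_spec(
    n_chains = n_chains, rise = rise, twist = twist,
    sequence = seq$sequence, start_number = 1L))
  s$id <- "asyn_fibril_synthetic"
  s
}

normalize_preset_name <- function(name) {
  n <- tolower(name)
  n <- gsub("α", "alpha", n)   # Greek alpha aliasing
  n <- gsub("[^a-z0-9]+", "-", n)
  sub("^alpha-?sc", "alpha-SC", n)
}

#' The packaged preset registry
#'
#' @return list with `entries` (named list of `construct_design`) and
#'   `source` (provenance string).
#' @export
preset_registry <- function() {
  path <- system.file("extdata", "presets.tsv", package = "epigraft",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  entries <- lapply(split(tab, tab$name), function(d) {
    new_construct_design(
      name = d$name[1], scaffold_id = "HET-s_218-289",
      substitutions = d[, c("position", "wt", "new", "rung")],
      provenance = list(donor_id = switch(
        d$name[1],
        "alpha-SC3" = "alpha-synuclein fibril, ssNMR structure",
        "alpha-SC6" = "alpha-synuclein fibril, cryo-EM structure",
        "unknown"),
        citation = PRESET_SOURCE, stored = "verbatim published lists"))
  })
  list(entries = entries, source = PRESET_SOURCE)
}

#' Load a published vaccine-candidate preset
#'
#' The four published designs are available as `"alpha-SC3"`,
#' `"alpha-SC6"`, `"alpha-SC8"` and `"alpha-SC9"` (case- and
#' Greek-letter-insensitive: "α-SC9" works). Substitution lists are stored
#' exactly as published, including alpha-SC3's anomalous rung-2 entry
#' K269G (see [validate_design]).
#'
#' @param name preset name.
#' @return a fresh `construct_design` copy.
#' @export
load_preset <- function(name) {
  reg <- preset_registry()
  key <- normalize_preset_name(name)
  hit <- match(key, vapply(names(reg$entries), normalize_preset_name, ""))
  if (is.na(hit)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(reg$entries), collapse = ", "))
  }
  reg$entries[[hit]]
}

#' Apply a design's substitutions to a sequence
#'
#' @param seq a [seq_record] (author numbering).
#' @param design a `construct_design`.
#' @param strict when TRUE (default), any stored wild-type letter that
#'   disagrees with the sequence is an error; when FALSE the new letters
#'   are applied regardless and mismatches attached as a
#'   `"mismatch_warnings"` attribute.
#' @return a new [seq_record] of identical length and numbering (the
#'   procedure never inserts or deletes).
#' @export
apply_design <- function(seq, design, strict = TRUE) {
  s <- design$substitutions
  letters1 <- strsplit(seq$sequence, "")[[1]]
  last <- seq$start_number + length(letters1) - 1L
  warnings <- character(0)
  for (k in seq_len(nrow(s))) {
    p <- s$position[k]
    if (p < seq$start_number || p > last) {
      stop("substitution position ", p, " outside sequence range ",
           seq$start_number, "-", last)
    }
    i <- p - seq$start_number + 1L
    if (letters1[i] != s$wt[k]) {
      msg <- sprintf("position %d: expected wt %s, found %s", p, s$wt[k],
                     letters1[i])
      if (strict) {
        stop("wild-type mismatch in strict mode: ", msg)
      }
      warnings <- c(warnings, msg)
    }
    letters1[i] <- s$new[k]
  }
  out <- seq_record(paste0(seq$id, "_", design$name),
                    paste(letters1, collapse = ""), seq$start_number)
  if (length(warnings) > 0) attr(out, "mismatch_warnings") <- warnings
  out
}

#' Recover a substitution list by diffing two equal-length sequences
#'
#' Inverse of [apply_design]: positions where the sequences differ, as a
#' (position, wt, new) data frame in author numbering.
#'
#' @param wt,mutant [seq_record]s of equal length and start number.
#' @return data frame with position, wt, new.
#' @export
diff_sequences <- function(wt, mutant) {
  if (nchar(wt$sequence) != nchar(mutant$sequence) ||
      wt$start_number != mutant$start_number) {
    stop("sequences differ in length or numbering")
  }
  a <- strsplit(wt$sequence, "")[[1]]
  b <- strsplit(mutant$sequence, "")[[1]]
  idx <- which(a != b)
  data.frame(position = wt$start_number + idx - 1L, wt = a[idx],
             new = b[idx])
}

# small polynomial rolling hash for byte-stable design checksums
design_checksum <- function(design) {
  s <- design$substitutions
  txt <- paste(design$name, paste(s$wt, s$position, s$new, s$rung,
                                  collapse = ";"), sep = "|")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write the full design report
#'
#' Emits three byte-stable files: `<path>.json` (design, provenance,
#' score, validation flags, geometry summary), `<path>.fasta` (wild-type
#' and mutant sequences; headers carry name, scaffold id, substitution
#' count and design checksum) and `<path>.tsv` (substitution table:
#' position, wt, new, rung).
#'
#' @param design a `construct_design`.
#' @param scaffold_seq [seq_record] the design applies to.
#' @param path output path prefix.
#' @param geometry optional `helical_parameters` to include.
#' @param exposure optional classified `exposure_profile`; per-site
#'   classes of the substituted positions are included.
#' @param rung_map optional `rung_map`; when given, validation flags are
#'   recomputed and included.
#' @param strict passed to [apply_design] (default FALSE so that flagged
#'   presets can still be rendered; mismatches are reported in the JSON).
#' @return invisibly, the named vector of file paths written.
#' @export
render_report <- function(design, scaffold_seq, path, geometry = NULL,
                          exposure = NULL, rung_map = NULL,
                          strict = FALSE) {
  mutant <- apply_design(scaffold_seq, design, strict = strict)
  checksum <- design_checksum(design)
  s <- design$substitutions

  json_path <- paste0(path, ".json")
  fasta_path <- paste0(path, ".fasta")
  tsv_path <- paste0(path, ".tsv")

  report <- list(
    name = design$name,
    scaffold_id = design$scaffold_id,
    checksum = checksum,
    n_substitutions = nrow(s),
    substitutions = s,
    substitution_ids = substitution_ids(design),
    provenance = design$provenance,
    score = if (!is.null(design$score)) unclass(design$score),
    mismatch_warnings = attr(mutant, "mismatch_warnings"))
  if (!is.null(rung_map)) {
    report$validation <- validate_design(design, scaffold_seq, rung_map)
    report$rung_offset <- rung_map$offset
  }
  if (!is.null(geometry)) {
    report$geometry <- list(rise = geometry$rise, twist = geometry$twist,
                            repeat_kind = geometry$repeat_kind,
                            rmsd = geometry$rmsd)
  }
  if (!is.null(exposure)) {
    pr <- exposure$residues
    hit <- match(s$position, pr$resno)
    report$site_exposure <- data.frame(
      position = s$position, relative = pr$relative[hit],
      class = pr$class[hit])
  }
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, dataframe = "rows", null = "null")

  wt_rec <- scaffold_seq
  wt_rec$id <- sprintf("%s|wildtype|subs=0|checksum=%s",
                       design$scaffold_id, checksum)
  mut_rec <- mutant
  mut_rec$id <- sprintf("%s|%s|subs=%d|checksum=%s", design$scaffold_id,
                        design$name, nrow(s), checksum)
  write_fasta(list(wt_rec, mut_rec), fasta_path)

  utils::write.table(s, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(json = json_path, fasta = fasta_path, tsv = tsv_path))
}

#' Read a design back from a rendered JSON report
#'
#' @param json_path path written by [render_report].
#' @return a `construct_design` equal to the rendered one.
#' @export
read_design_report <- function(json_path) {
  rep <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  score <- NULL
  if (!is.null(rep$score)) {
    score <- structure(lapply(rep$score, function(v)
      if (is.null(v)) NA else v), class = "graft_score")
  }
  prov <- rep$provenance
  new_construct_design(name = rep$name, scaffold_id = rep$scaffold_id,
                       substitutions = rep$substitutions,
                       provenance = prov, score = score)
}
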