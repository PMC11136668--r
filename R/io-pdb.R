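## PDB reading/writing. Parsing and serialization are delegated to bio3d;
## a light pre-scan of ATOM/HETATM records supplies line-numbered format
## diagnostics for malformed files. Only the first model of multi-model
## files is read.

## classify a bio3d atom row into a role
.assign_role <- function(type, resid, elety) {
  resid <- toupper(trimws(resid))
  role <- ifelse(type == "ATOM", "protein", "ligand")
  role[resid %in% .water_resnames] <- "water"
  role[type == "HETATM" & resid %in% .ion_resnames] <- "ion"
  role
}

.scan_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  for (i in sel) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop_ligdyn("format", "line %d: ATOM/HETATM record too short (%d chars)",
                  i, nchar(ln))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz))
      stop_ligdyn("format", "line %d: unparsable coordinates in '%s'",
                  i, substr(ln, 31, 54))
  }
  invisible(length(sel))
}

#' Read a protein-ligand complex from a PDB file
#'
#' Parses ATOM/HETATM records (first model only) into a [complex_record()].
#' Roles are assigned from the record type and residue name: `ATOM` atoms are
#' protein; `HETATM` atoms are water (HOH/WAT/...), monatomic ions, or
#' otherwise ligand. The B-factor column is captured; a blank column becomes
#' `NA` (absent), never 0.
#'
#' @param path PDB file.
#' @param entry_id key for the record; defaults to the file name stem.
#' @return a [complex_record()].
#' @export
read_complex_pdb <- function(path, entry_id = NULL) {
  if (!file.exists(path))
    stop_ligdyn("format", "PDB file not found: %s", path)
  .scan_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  if (nrow(at) == 0L)
    stop_ligdyn("format", "no ATOM/HETATM records in %s", path)
  ele <- at$elesy
  blank <- is.na(ele) | trimws(ele) == ""
  if (any(blank))
    ele[blank] <- bio3d::atom2ele(at$elety[blank])
  role <- .assign_role(at$type, at$resid, at$elety)
  atoms <- atom_table(element = ele, x = at$x, y = at$y, z = at$z,
                      atom_name = trimws(at$elety),
                      residue_index = at$resno,
                      residue_name = trimws(at$resid),
                      chain_id = ifelse(is.na(at$chain), "A", at$chain),
                      role = role,
                      b_factor = at$b)
  if (is.null(entry_id))
    entry_id <- sub("\\.[^.]*$", "", basename(path))
  complex_record(entry_id, atoms)
}

#' Write a complex to a PDB file
#'
#' Serializes a [complex_record()] back to PDB format (protein atoms as ATOM,
#' everything else as HETATM). Coordinates round-trip within the format's
#' 1e-3 Angstrom precision and atom order is preserved exactly. Absent B
#' factors are written as 0.00 (the fixed-column format has no empty
#' encoding).
#'
#' @param complex a [complex_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(complex, path) {
  at <- complex$atoms
  b <- at$b_factor
  b[is.na(b)] <- 0
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(at$role == "protein", "ATOM", "HETATM"),
    resno = at$residue_index,
    resid = at$residue_name,
    eleno = seq_len(nrow(at)),
    elety = at$atom_name,
    chain = at$chain_id,
    o = rep(1, nrow(at)),
    b = b,
    elesy = at$element
  )
  invisible(path)
}
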