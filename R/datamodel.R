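## Core domain types. All containers are plain S3 built on data.frames and
## arrays: atoms are rows of a data.frame, coordinates are n x 3 matrices,
## trajectories are [n_frames x n_atoms x 3] arrays. Indices are 1-based
## throughout; PDB serial numbers are carried only as labels.

.ligdyn_roles <- c("protein", "ligand", "ion", "water")

## residue names treated as water / monatomic ions during role assignment
.water_resnames <- c("HOH", "WAT", "H2O", "DOD", "TIP3")
.ion_resnames <- c("NA", "CL", "K", "MG", "ZN", "CA", "MN", "FE", "NI",
                   "CU", "CO", "CD", "BR", "IOD", "F")

#' Build an atom table
#'
#' Constructs the atom `data.frame` used inside a [complex_record()]. Each row
#' is one atom with its element, labels, role and Cartesian coordinates in
#' Angstrom. Masses default from the element table; B factors are optional
#' (`NA` means absent, which is distinct from a legal value of 0).
#'
#' @param element element symbols.
#' @param x,y,z coordinates, Angstrom.
#' @param atom_name atom labels (e.g. `"CA"`); defaults to the element.
#' @param residue_index integer residue numbers.
#' @param residue_name 3-letter residue code or ligand code.
#' @param chain_id chain labels.
#' @param role one of `"protein"`, `"ligand"`, `"ion"`, `"water"` per atom.
#' @param b_factor optional B factors, Angstrom^2 (`NA` = absent).
#' @param mass optional masses, Da; defaulted from the element when `NA`.
#' @return a `data.frame` with one row per atom.
#' @export
atom_table <- function(element, x, y, z,
                       atom_name = element,
                       residue_index = 1L,
                       residue_name = "LIG",
                       chain_id = "A",
                       role = "ligand",
                       b_factor = NA_real_,
                       mass = NA_real_) {
  n <- length(element)
  element <- .norm_element(element)
  df <- data.frame(
    element = element,
    atom_name = rep_len(as.character(atom_name), n),
    residue_index = rep_len(as.integer(residue_index), n),
    residue_name = rep_len(as.character(residue_name), n),
    chain_id = rep_len(as.character(chain_id), n),
    role = rep_len(as.character(role), n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    b_factor = rep_len(as.numeric(b_factor), n),
    mass = rep_len(as.numeric(mass), n),
    stringsAsFactors = FALSE
  )
  bad_role <- setdiff(unique(df$role), .ligdyn_roles)
  if (length(bad_role))
    stop_ligdyn("validation", "unknown atom role(s): %s",
                paste(bad_role, collapse = ", "))
  if (!all(is.finite(df$x) & is.finite(df$y) & is.finite(df$z)))
    stop_ligdyn("validation", "non-finite atom coordinates")
  need <- is.na(df$mass)
  df$mass[need] <- element_property(df$element[need], "mass")
  if (any(df$mass <= 0, na.rm = TRUE))
    stop_ligdyn("validation", "atom masses must be positive")
  df
}

#' Protein-ligand complex record
#'
#' One binary protein-ligand complex: an ordered atom table plus the derived
#' protein/ligand index partitions. Waters and monatomic ions are retained in
#' the atom table but excluded from both partitions (and thereby from all
#' downstream metrics and featurization).
#'
#' @param entry_id 4-character PDB-ID-like key.
#' @param atoms atom `data.frame` from [atom_table()].
#' @return object of class `complex_record` with elements `entry_id`, `atoms`,
#'   `protein_indices`, `ligand_indices`.
#' @export
complex_record <- function(entry_id, atoms) {
  stopifnot(is.data.frame(atoms))
  entry_id <- as.character(entry_id)[1]
  prot <- which(atoms$role == "protein")
  lig <- which(atoms$role == "ligand")
  if (length(prot) == 0L)
    stop_ligdyn("validation", "complex '%s' has no protein atoms", entry_id)
  if (length(lig) == 0L)
    stop_ligdyn("validation", "complex '%s' has no ligand atoms", entry_id)
  structure(list(entry_id = entry_id, atoms = atoms,
                 protein_indices = prot, ligand_indices = lig),
            class = "complex_record")
}

#' @export
print.complex_record <- function(x, ...) {
  cat(sprintf("<complex_record %s: %d atoms (%d protein, %d ligand, %d other)>\n",
              x$entry_id, nrow(x$atoms), length(x$protein_indices),
              length(x$ligand_indices),
              nrow(x$atoms) - length(x$protein_indices) - length(x$ligand_indices)))
  invisible(x)
}

#' Coordinates of a complex
#'
#' @param complex a [complex_record()].
#' @return n x 3 numeric matrix, Angstrom.
#' @export
coords <- function(complex) {
  as.matrix(complex$atoms[, c("x", "y", "z")])
}

## heavy-atom indicator
.is_heavy <- function(atoms) atoms$element != "H"

#' Trajectory record
#'
#' Frame-stacked coordinates plus per-frame and per-trajectory scalar
#' properties for one complex. Frame times are in nanoseconds and must be
#' strictly increasing.
#'
#' @param entry_id key matching the associated complex.
#' @param coordinates numeric array `[n_frames, n_atoms, 3]`, Angstrom.
#' @param frame_times numeric vector `[n_frames]`, ns. Defaults to an even
#'   spacing over 8 ns (the stored production window per complex).
#' @param frame_properties named list of length-`n_frames` numeric vectors
#'   (e.g. `ligand_rmsd`, `com_distance`, `buried_sasa`).
#' @param trajectory_properties named list of scalars.
#' @return object of class `trajectory_record`.
#' @export
trajectory_record <- function(entry_id, coordinates, frame_times = NULL,
                              frame_properties = list(),
                              trajectory_properties = list()) {
  d <- dim(coordinates)
  if (length(d) != 3L || d[3] != 3L)
    stop_ligdyn("validation", "coordinates must be an [n_frames x n_atoms x 3] array")
  if (d[1] < 1L) stop_ligdyn("validation", "trajectory needs >= 1 frame")
  if (is.null(frame_times))
    frame_times <- seq(0, 8, length.out = d[1])
  if (length(frame_times) != d[1] ||
      (d[1] > 1L && any(diff(frame_times) <= 0)))
    stop_ligdyn("validation", "frame_times must be strictly increasing, length n_frames")
  for (nm in names(frame_properties))
    if (length(frame_properties[[nm]]) != d[1])
      stop_ligdyn("validation", "frame property '%s' has wrong length", nm)
  structure(list(entry_id = as.character(entry_id)[1],
                 coordinates = coordinates,
                 frame_times = as.numeric(frame_times),
                 frame_properties = frame_properties,
                 trajectory_properties = trajectory_properties),
            class = "trajectory_record")
}

#' @export
print.trajectory_record <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf("<trajectory_record %s: %d frames x %d atoms, %.3g-%.3g ns>\n",
              x$entry_id, d[1], d[2], min(x$frame_times), max(x$frame_times)))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coordinates)[1]

## frame f as an n x 3 matrix
frame_coords <- function(traj, f) {
  d <- dim(traj$coordinates)
  if (f < 1L || f > d[1])
    stop_ligdyn("validation", "frame index %d out of range 1..%d", f, d[1])
  matrix(traj$coordinates[f, , ], ncol = 3)
}

#' Quantum-property record for one ligand
#'
#' Per-molecule scalar descriptors (eV unless noted) and per-atom property
#' tables for one ligand, as produced by semi-empirical quantum chemistry.
#' These values are consumed by the toolkit, never computed by it.
#'
#' @param entry_id key.
#' @param molecular named list/vector of scalars (e.g. `electron_affinity`,
#'   `chemical_hardness`, `electronegativity`, `ionization_potential`,
#'   `log_p`, `polarizability`, `homo_lumo_gap`, `electron_count`).
#' @param atomic named list of per-atom vectors (partial charges by scheme,
#'   atomic polarizabilities, hybridizations, ...). All must share one length.
#' @param n_ligand_atoms expected ligand atom count; checked against the
#'   atomic arrays when given.
#' @return object of class `qm_record`.
#' @export
qm_record <- function(entry_id, molecular = list(), atomic = list(),
                      n_ligand_atoms = NULL) {
  lens <- vapply(atomic, length, integer(1))
  if (length(lens) && length(unique(lens)) != 1L)
    stop_ligdyn("validation", "atomic property arrays differ in length")
  if (!is.null(n_ligand_atoms) && length(lens) &&
      lens[1] != n_ligand_atoms)
    stop_ligdyn("validation",
                "atomic arrays have length %d, ligand has %d atoms",
                lens[1], n_ligand_atoms)
  structure(list(entry_id = as.character(entry_id)[1],
                 molecular = as.list(molecular), atomic = atomic),
            class = "qm_record")
}

.ligdyn_affinity_types <- c("Ki", "Kd", "IC50")

#' Affinity metadata table
#'
#' Validated table of experimental binding-affinity records: one row per
#' complex with the affinity in nM, its measurement type, and the provenance
#' labels (protein group, publication) used for clustering and benchmark
#' construction.
#'
#' @param entry_id complex keys.
#' @param affinity_value affinities, nM (> 0).
#' @param affinity_type `"Ki"`, `"Kd"` or `"IC50"` (case-insensitive).
#' @param protein_group UniProt-like protein identifiers.
#' @param publication_id source-publication labels.
#' @param has_site_cofactor_or_metal logical flag: cofactor or metal at the
#'   binding site.
#' @return `data.frame` of class `affinity_table`.
#' @export
affinity_table <- function(entry_id, affinity_value, affinity_type,
                           protein_group, publication_id = NA_character_,
                           has_site_cofactor_or_metal = FALSE) {
  n <- length(entry_id)
  affinity_value <- as.numeric(affinity_value)
  if (any(!is.finite(affinity_value)) || any(affinity_value <= 0))
    stop_ligdyn("validation", "affinity values must be positive and finite (nM)")
  ty <- as.character(affinity_type)
  norm <- .ligdyn_affinity_types[match(toupper(ty), toupper(.ligdyn_affinity_types))]
  if (anyNA(norm))
    stop_ligdyn("validation", "unknown affinity type(s): %s (expected Ki, Kd or IC50)",
                paste(unique(ty[is.na(norm)]), collapse = ", "))
  df <- data.frame(entry_id = as.character(entry_id),
                   affinity_value = affinity_value,
                   affinity_type = rep_len(norm, n),
                   protein_group = rep_len(as.character(protein_group), n),
                   publication_id = rep_len(as.character(publication_id), n),
                   has_site_cofactor_or_metal =
                     rep_len(as.logical(has_site_cofactor_or_metal), n),
                   stringsAsFactors = FALSE)
  class(df) <- c("affinity_table", "data.frame")
  df
}
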