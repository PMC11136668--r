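## Trajectory-derived flexibility and interaction descriptors. Every metric
## first removes global rigid-body motion by superposing each frame onto a
## reference frame over an alignment selection (protein heavy atoms by
## default, matching the ligand-RMSD convention of aligning on the protein).

## default alignment selection: protein heavy atoms
.default_align <- function(complex) {
  at <- complex$atoms
  intersect(complex$protein_indices, which(.is_heavy(at)))
}

## superpose every frame onto frame `reference_frame` over `align_selection`;
## returns [n_frames x n_atoms x 3]
.aligned_coordinates <- function(traj, reference_frame = 1L,
                                 align_selection = NULL) {
  nf <- n_frames(traj)
  if (reference_frame < 1L || reference_frame > nf)
    stop_ligdyn("validation", "reference frame %d out of range 1..%d",
                reference_frame, nf)
  ref <- frame_coords(traj, reference_frame)
  if (is.null(align_selection)) align_selection <- seq_len(nrow(ref))
  out <- traj$coordinates
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    fit <- superpose(fr, ref, align_selection)
    out[f, , ] <- apply_superposition(fr, fit)
  }
  out
}

#' Per-atom adaptability of an aligned trajectory
#'
#' Adaptability gamma_x measures the conformational plasticity of each atom:
#' after superposing every frame onto the reference frame, it is the mean
#' Euclidean distance of atom x from its reference position over all frames,
#'
#'   gamma_x = (1 / N_frames) * sum_i | r_ref,x - r_i,x |.
#'
#' The reference frame itself contributes a zero term and is included in the
#' average by default (the divisor is N_frames, not N_frames - 1); set
#' `include_reference = FALSE` to average over the other frames only.
#' Hydrogens are dropped by default.
#'
#' @param traj a [trajectory_record()].
#' @param complex the matching [complex_record()] (used for the default
#'   alignment selection and hydrogen dropping); optional when both
#'   `align_selection` and `drop_hydrogens = FALSE` are given.
#' @param reference_frame 1-based frame index of the reference (default 1).
#' @param align_selection atom indices used for the superposition; defaults
#'   to protein heavy atoms.
#' @param drop_hydrogens exclude hydrogens from the profile (default `TRUE`).
#' @param include_reference include the reference frame's zero term in the
#'   average (default `TRUE`).
#' @return object of class `adaptability_profile`: list with `entry_id`,
#'   `gamma` (named per-atom vector, Angstrom), `atom_indices` (indices of
#'   retained atoms in the complex) and `reference_frame`.
#' @export
adaptability <- function(traj, complex = NULL, reference_frame = 1L,
                         align_selection = NULL, drop_hydrogens = TRUE,
                         include_reference = TRUE) {
  na <- dim(traj$coordinates)[2]
  if (!is.null(complex) && nrow(complex$atoms) != na)
    stop_ligdyn("validation", "trajectory has %d atoms, complex has %d",
                na, nrow(complex$atoms))
  if (is.null(align_selection))
    align_selection <- if (is.null(complex)) seq_len(na) else .default_align(complex)
  ac <- .aligned_coordinates(traj, reference_frame, align_selection)
  keep <- seq_len(na)
  if (drop_hydrogens && !is.null(complex))
    keep <- which(.is_heavy(complex$atoms))
  ref <- matrix(ac[reference_frame, keep, ], ncol = 3)
  nf <- n_frames(traj)
  frames <- seq_len(nf)
  if (!include_reference) frames <- setdiff(frames, reference_frame)
  acc <- numeric(length(keep))
  for (f in frames) {
    d <- matrix(ac[f, keep, ], ncol = 3) - ref
    acc <- acc + sqrt(rowSums(d * d))
  }
  gamma <- acc / length(frames)
  structure(list(entry_id = traj$entry_id, gamma = gamma,
                 atom_indices = keep, reference_frame = reference_frame),
            class = "adaptability_profile")
}

#' @export
print.adaptability_profile <- function(x, ...) {
  cat(sprintf("<adaptability_profile %s: %d atoms, mean gamma %.3g A>\n",
              x$entry_id, length(x$gamma), mean(x$gamma)))
  invisible(x)
}

#' Root-mean-square fluctuation per atom
#'
#' RMSF of each atom about its time-mean position after superposing every
#' frame onto the first (or chosen) frame.
#'
#' @inheritParams adaptability
#' @return per-atom numeric vector, Angstrom (all atoms; subset with the
#'   complex's heavy-atom indices if needed).
#' @export
rmsf <- function(traj, complex = NULL, align_selection = NULL,
                 reference_frame = 1L) {
  if (n_frames(traj) < 2L)
    stop_ligdyn("validation", "RMSF undefined for a single frame")
  na <- dim(traj$coordinates)[2]
  if (is.null(align_selection))
    align_selection <- if (is.null(complex)) seq_len(na) else .default_align(complex)
  ac <- .aligned_coordinates(traj, reference_frame, align_selection)
  nf <- dim(ac)[1]
  mean_pos <- apply(ac, c(2, 3), mean)               # n_atoms x 3
  acc <- numeric(na)
  for (f in seq_len(nf)) {
    d <- matrix(ac[f, , ], ncol = 3) - mean_pos
    acc <- acc + rowSums(d * d)
  }
  sqrt(acc / nf)
}

#' Ligand RMSD per frame after protein alignment
#'
#' For each frame, the protein atoms are superposed onto the reference frame
#' and the RMSD of the ligand atoms against their reference positions is
#' reported without any ligand re-fitting, so genuine ligand motion relative
#' to the protein frame is retained.
#'
#' @param traj a [trajectory_record()].
#' @param complex the matching [complex_record()].
#' @param reference_frame 1-based reference frame (default 1).
#' @param heavy_only restrict alignment and RMSD to heavy atoms (default
#'   `TRUE`).
#' @return per-frame numeric vector, Angstrom.
#' @export
ligand_rmsd <- function(traj, complex, reference_frame = 1L,
                        heavy_only = TRUE) {
  lig <- complex$ligand_indices
  prot <- complex$protein_indices
  if (heavy_only) {
    heavy <- which(.is_heavy(complex$atoms))
    lig <- intersect(lig, heavy); prot <- intersect(prot, heavy)
  }
  if (length(lig) == 0L)
    stop_ligdyn("validation", "complex '%s' has no (heavy) ligand atoms",
                complex$entry_id)
  ref <- frame_coords(traj, reference_frame)
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)
    fit <- superpose(fr, ref, prot)
    moved <- apply_superposition(fr, fit)
    d <- moved[lig, , drop = FALSE] - ref[lig, , drop = FALSE]
    sqrt(mean(rowSums(d * d)))
  }, numeric(1))
}

#' Protein-ligand centre-of-mass distance per frame
#'
#' @param traj a [trajectory_record()].
#' @param complex the matching [complex_record()].
#' @param mass_weighted use atomic masses (default); `FALSE` gives the
#'   geometric centroid.
#' @return per-frame numeric vector, Angstrom.
#' @export
com_distance <- function(traj, complex, mass_weighted = TRUE) {
  prot <- complex$protein_indices; lig <- complex$ligand_indices
  w <- if (mass_weighted) complex$atoms$mass else rep(1, nrow(complex$atoms))
  if (mass_weighted && anyNA(w))
    stop_ligdyn("validation", "masses required for mass-weighted COM")
  com <- function(xyz, idx) colSums(xyz[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- frame_coords(traj, f)
    sqrt(sum((com(fr, prot) - com(fr, lig))^2))
  }, numeric(1))
}
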