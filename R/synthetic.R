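## Seeded generators for offline testing: toy complexes with idealized
## geometry, trajectories with known per-atom mobility (so the expected
## adaptability is analytic), quantum-property tables with planted outliers,
## and affinity clusters with a known ground-truth affinity function.
## Displacements are i.i.d. Gaussian rather than force-field dynamics on
## purpose: the ground truth for the adaptability of an atom with per-axis
## s.d. sigma is then exactly sigma * sqrt(8/pi) (the Maxwell mean).
## All generators are pure functions of (seed, parameters).

## idealized all-trans chain in the xy plane: reference single-bond lengths,
## tetrahedral angles throughout
.build_chain_atoms <- function(elements, residue_name = "LIG",
                               chain_id = "L", role = "ligand") {
  n <- length(elements)
  theta <- (180 - 109.47) / 2 * pi / 180
  dirs <- rbind(c(cos(theta), sin(theta), 0), c(cos(theta), -sin(theta), 0))
  pos <- matrix(0, n, 3)
  for (k in seq_len(n - 1L)) {
    len <- .ref_bond_length(elements[k], elements[k + 1L], 1)
    if (is.na(len)) len <- sum(element_property(c(elements[k], elements[k + 1L]),
                                                "r_cov"))
    pos[k + 1L, ] <- pos[k, ] + len * dirs[1 + (k %% 2), ]
  }
  atom_table(element = elements, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             atom_name = paste0(elements, seq_len(n)),
             residue_index = 1L, residue_name = residue_name,
             chain_id = chain_id, role = role)
}

## random proper rotation with angle <= max_deg (Rodrigues)
.random_rotation <- function(max_deg) {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, max_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Generate a synthetic protein-ligand complex
#'
#' Builds a pseudo-protein (4-atom N/CA/C/O residues on a helical backbone
#' trace with canonical local geometry) and an idealized ligand chain from
#' the internal reference-geometry table, placed so that at least one heavy
#' ligand atom lies within 4 Angstrom of the protein with no steric clash at
#' the default curation threshold. Deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_residues number of pseudo-residues (>= 3).
#' @param n_ligand_atoms ligand heavy atoms (>= 2).
#' @param entry_id key; default derived from the seed.
#' @param max_tries placement retries before failing.
#' @return a [complex_record()].
#' @export
generate_complex <- function(seed, n_residues = 20, n_ligand_atoms = 10,
                             entry_id = sprintf("S%03d", seed %% 1000),
                             max_tries = 60) {
  if (n_residues < 3L) stop_ligdyn("validation", "need >= 3 residues")
  if (n_ligand_atoms < 2L) stop_ligdyn("validation", "need >= 2 ligand atoms")
  set.seed(seed)
  ## helical CA trace, 3.8 A spacing
  i <- seq_len(n_residues)
  th <- i * 100 * pi / 180
  ca <- cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * i) +
    matrix(stats::rnorm(3 * n_residues, sd = 0.03), n_residues)
  tangent <- rbind(ca[2, ] - ca[1, ],
                   ca[pmin(i + 1, n_residues), ] - ca[pmax(i - 1, 1), ])[-1, , drop = FALSE]
  tangent <- rbind(tangent, ca[n_residues, ] - ca[n_residues - 1, ])[i, , drop = FALSE]
  tangent <- tangent / sqrt(rowSums(tangent^2))
  radial <- ca - cbind(0, 0, ca[, 3])
  radial <- radial / sqrt(rowSums(radial^2))
  atoms <- NULL
  for (r in i) {
    npos <- ca[r, ] - 1.46 * tangent[r, ] * 0.9 + 0.3 * radial[r, ]
    cpos <- ca[r, ] + 1.52 * tangent[r, ] * 0.9 + 0.3 * radial[r, ]
    opos <- cpos + 1.23 * radial[r, ]
    atoms <- rbind(atoms,
                   data.frame(element = c("N", "C", "C", "O"),
                              atom_name = c("N", "CA", "C", "O"),
                              residue_index = r,
                              x = c(npos[1], ca[r, 1], cpos[1], opos[1]),
                              y = c(npos[2], ca[r, 2], cpos[2], opos[2]),
                              z = c(npos[3], ca[r, 3], cpos[3], opos[3])))
  }
  prot <- atom_table(element = atoms$element, x = atoms$x, y = atoms$y,
                     z = atoms$z, atom_name = atoms$atom_name,
                     residue_index = atoms$residue_index,
                     residue_name = "ALA", chain_id = "A", role = "protein")
  ## ligand: idealized chain, interior C/N/O, placed at 3.2-4 A contact
  interior <- sample(c("C", "C", "C", "N", "O"), max(n_ligand_atoms - 2L, 0L),
                     replace = TRUE)
  ends <- sample(c("C", "C", "N", "O"), 2L, replace = TRUE)
  lig0 <- .build_chain_atoms(c(ends[1], interior, ends[2])[seq_len(n_ligand_atoms)])
  pxyz <- as.matrix(prot[, c("x", "y", "z")])
  centroid <- colMeans(pxyz)
  for (try in seq_len(max_tries)) {
    R <- .random_rotation(180)
    lxyz <- as.matrix(lig0[, c("x", "y", "z")]) %*% R
    anchor <- pxyz[sample.int(nrow(pxyz), 1), ]
    dir <- anchor - centroid; dir <- dir / sqrt(sum(dir^2))
    lxyz <- sweep(lxyz, 2, colMeans(lxyz))
    gap <- stats::runif(1, 3.3, 3.8)
    lxyz <- sweep(lxyz, 2, anchor + dir * (gap + 2), "+")
    dmin <- min(vapply(seq_len(nrow(lxyz)), function(a) {
      d <- sweep(pxyz, 2, lxyz[a, ]); min(sqrt(rowSums(d * d)))
    }, numeric(1)))
    if (dmin >= 3.0 && dmin <= 4.0) {
      lig <- lig0
      lig$x <- lxyz[, 1]; lig$y <- lxyz[, 2]; lig$z <- lxyz[, 3]
      return(complex_record(entry_id, rbind(prot, lig)))
    }
  }
  stop_ligdyn("internal", "ligand placement failed after %d tries", max_tries)
}

#' Per-atom mobility profile
#'
#' Ground-truth displacement scales for [generate_trajectory()]: per-atom
#' per-axis Gaussian s.d. in Angstrom, optionally smoothed along the residue
#' chain.
#'
#' @param sigma per-atom s.d. vector (>= 0), Angstrom.
#' @param correlation_length smoothness scale used when generated, residues.
#' @return object of class `mobility_profile`.
#' @export
mobility_profile <- function(sigma, correlation_length = 0) {
  if (any(sigma < 0)) stop_ligdyn("validation", "sigma must be >= 0")
  structure(list(sigma = as.numeric(sigma),
                 correlation_length = correlation_length),
            class = "mobility_profile")
}

#' Generate a smooth random mobility profile for a complex
#'
#' Draws per-residue mobilities and smooths them with a moving average of
#' width `correlation_length` residues, emulating the smooth variation of
#' flexibility along a chain.
#'
#' @param seed integer seed.
#' @param complex a [complex_record()].
#' @param mean_sigma average per-axis s.d., Angstrom.
#' @param correlation_length smoothing window, residues.
#' @return a [mobility_profile()] with one sigma per atom.
#' @export
generate_mobility <- function(seed, complex, mean_sigma = 0.3,
                              correlation_length = 3) {
  set.seed(seed)
  res <- paste(complex$atoms$chain_id, complex$atoms$residue_index)
  ures <- unique(res)
  raw <- stats::rlnorm(length(ures), log(mean_sigma), 0.5)
  if (correlation_length > 1) {
    w <- rep(1 / correlation_length, correlation_length)
    raw <- stats::filter(c(rep(raw[1], correlation_length), raw,
                           rep(raw[length(raw)], correlation_length)),
                         w, sides = 2)
    raw <- as.numeric(raw)[correlation_length + seq_along(ures)]
  }
  mobility_profile(raw[match(res, ures)], correlation_length)
}

#' Generate a synthetic trajectory with known per-atom mobility
#'
#' Frame 1 is the complex's own coordinates (the reference). Every later
#' frame adds i.i.d. per-atom isotropic Gaussian displacements (per-axis
#' s.d. from the profile) and then one shared random rigid motion per frame
#' (up to `rigid_deg` degrees and `rigid_trans` Angstrom) so alignment is
#' exercised but solvable. Frame times are evenly spaced over 8 ns.
#'
#' @param complex a [complex_record()].
#' @param profile a [mobility_profile()] (or numeric sigma vector), one
#'   entry per atom.
#' @param n_frames number of frames (default 100).
#' @param seed integer seed.
#' @param rigid_deg,rigid_trans amplitude of the shared per-frame rigid
#'   motion (defaults 10 degrees / 3 Angstrom; 0 disables).
#' @return a [trajectory_record()].
#' @export
generate_trajectory <- function(complex, profile, n_frames = 100, seed = 1L,
                                rigid_deg = 10, rigid_trans = 3) {
  sigma <- if (inherits(profile, "mobility_profile")) profile$sigma
           else as.numeric(profile)
  xyz <- coords(complex)
  n <- nrow(xyz)
  if (length(sigma) == 1L) sigma <- rep(sigma, n)
  if (length(sigma) != n)
    stop_ligdyn("validation", "profile length %d, complex has %d atoms",
                length(sigma), n)
  set.seed(seed)
  co <- array(0, c(n_frames, n, 3))
  co[1, , ] <- xyz
  for (f in seq_len(n_frames)[-1]) {
    fr <- xyz + matrix(stats::rnorm(3 * n), n, 3) * sigma
    if (rigid_deg > 0 || rigid_trans > 0) {
      R <- .random_rotation(rigid_deg)
      tr <- stats::runif(3, -rigid_trans, rigid_trans)
      fr <- sweep(fr %*% R, 2, tr, "+")
    }
    co[f, , ] <- fr
  }
  trajectory_record(complex$entry_id, co,
                    frame_times = seq(0, 8, length.out = n_frames))
}

#' Generate quantum-property tables with planted outliers
#'
#' Fabricates `n_molecules` idealized ligand molecules whose molecular
#' targets (electron affinity, chemical hardness, eV) are fixed linear
#' functions of the element counts plus small Gaussian noise - a task a
#' graph network can learn by construction - and per-atom
#' (partial charge, atomic polarizability) pairs lying on a per-element
#' noisy line, with a fraction of atoms displaced far off the line and
#' recorded as ground-truth outliers (wrong-atom-assignment emulation).
#'
#' @param seed integer seed.
#' @param n_molecules molecule count.
#' @param outlier_rate fraction of atoms planted off-line (0 <= rate < 0.5).
#' @param n_atoms_range molecule size range.
#' @param target_noise s.d. of the molecular target noise, eV.
#' @return list: `records` ([qm_record()] per molecule), `molecules` (atom
#'   tables), `targets` (matrix `electron_affinity`, `chemical_hardness`),
#'   `atom_table` (pooled per-atom data.frame: `molecule`, `atom`,
#'   `element`, `charge`, `polarizability`, `is_outlier`).
#' @export
generate_qm_table <- function(seed, n_molecules, outlier_rate = 0.05,
                              n_atoms_range = c(6, 14),
                              target_noise = 0.05) {
  if (outlier_rate < 0 || outlier_rate >= 0.5)
    stop_ligdyn("validation", "outlier_rate must be in [0, 0.5)")
  set.seed(seed)
  vocab <- c("C", "N", "O", "S", "F", "CL", "BR")
  ## fixed linear coefficients defining the ground-truth targets
  ea_coef <- c(C = 0.05, N = 0.22, O = 0.31, S = 0.18, F = 0.40,
               CL = 0.35, BR = 0.28)
  hard_coef <- c(C = 0.12, N = -0.08, O = 0.20, S = -0.15, F = 0.30,
                 CL = 0.10, BR = -0.05)
  charge_base <- c(C = -0.05, N = -0.35, O = -0.45, S = 0.05, F = -0.25,
                   CL = -0.15, BR = -0.10)
  pol_slope <- c(C = -2.0, N = -1.5, O = -1.2, S = -3.0, F = -0.8,
                 CL = -2.4, BR = -3.2)
  pol_base <- c(C = 1.8, N = 1.1, O = 0.8, S = 3.0, F = 0.5,
                CL = 2.2, BR = 3.1)
  res_sd <- 0.05
  records <- molecules <- vector("list", n_molecules)
  targets <- matrix(0, n_molecules, 2,
                    dimnames = list(NULL, c("electron_affinity",
                                            "chemical_hardness")))
  pooled <- list()
  for (m in seq_len(n_molecules)) {
    nat <- sample(n_atoms_range[1]:n_atoms_range[2], 1)
    interior <- sample(c("C", "C", "C", "N", "O", "S"), max(nat - 2L, 0L),
                       replace = TRUE)
    ends <- sample(vocab, 2L, replace = TRUE, prob = c(3, 1, 1, 1, 1, 1, 1))
    el <- c(ends[1], interior, ends[2])[seq_len(nat)]
    mol <- .build_chain_atoms(el)
    counts <- vapply(names(ea_coef), function(e) sum(el == e), numeric(1))
    targets[m, 1] <- 0.5 + sum(ea_coef * counts) + stats::rnorm(1, 0, target_noise)
    targets[m, 2] <- 4.0 + sum(hard_coef * counts) + stats::rnorm(1, 0, target_noise)
    q <- charge_base[el] + stats::rnorm(nat, 0, 0.08)
    pol <- pol_base[el] + pol_slope[el] * q + stats::rnorm(nat, 0, res_sd)
    is_out <- stats::runif(nat) < outlier_rate
    pol[is_out] <- pol[is_out] +
      sample(c(-1, 1), sum(is_out), replace = TRUE) * 10 * res_sd *
        stats::runif(sum(is_out), 1, 2)
    records[[m]] <- qm_record(
      sprintf("Q%03d", m),
      molecular = list(electron_affinity = targets[m, 1],
                       chemical_hardness = targets[m, 2],
                       homo_lumo_gap = stats::runif(1, 2, 6),
                       electron_count = 2L * sample(20:60, 1),
                       closed_shell = TRUE),
      atomic = list(partial_charge_gfn2_water = unname(q),
                    atomic_polarizability = unname(pol),
                    hybridization = rep("sp3", nat)),
      n_ligand_atoms = nat)
    molecules[[m]] <- mol
    pooled[[m]] <- data.frame(molecule = m, atom = seq_len(nat),
                              element = el, charge = unname(q),
                              polarizability = unname(pol),
                              is_outlier = is_out,
                              stringsAsFactors = FALSE)
  }
  list(records = records, molecules = molecules, targets = targets,
       atom_table = do.call(rbind, pooled))
}

#' Generate affinity clusters with known ground truth
#'
#' Per cluster, one synthetic protein receives a family of ligand variants
#' (same scaffold length, varying element composition); the true decimal log
#' affinity is a fixed linear function of the ligand's element counts plus
#' noise. Clusters can be planted to violate benchmark filters (too few
#' entries, low dynamic range, cofactor at the site), with the violation
#' recorded in the returned truth table.
#'
#' @param seed integer seed.
#' @param sizes integer vector: entries per cluster.
#' @param violations character vector per cluster: `"none"`, `"small_size"`
#'   (size is used as given - pass one below the benchmark minimum),
#'   `"low_range"` (log-affinities compressed to ~0.8 decade) or
#'   `"cofactor"` (members flagged).
#' @param n_ligand_atoms scaffold length.
#' @param noise_sd s.d. of the log10 affinity noise (decades).
#' @param with_complexes also generate the complexes (slower).
#' @return list: `records` ([affinity_table()]), `complexes` (named list,
#'   when requested), `truth` (per-cluster data.frame with the violation
#'   labels and the coefficient vector as an attribute).
#' @export
generate_affinity_clusters <- function(seed, sizes = rep(6, 4),
                                       violations = rep("none", length(sizes)),
                                       n_ligand_atoms = 10, noise_sd = 0.1,
                                       with_complexes = TRUE) {
  stopifnot(length(violations) == length(sizes), all(sizes >= 2))
  set.seed(seed)
  beta <- c(C = -0.15, N = -0.45, O = -0.30, S = 0.25)
  types <- .ligdyn_affinity_types
  rows <- list(); complexes <- list(); truth <- list()
  entry_no <- 0L
  for (cidx in seq_along(sizes)) {
    base_cx <- if (with_complexes)
      generate_complex(seed * 1000L + cidx, n_residues = 10,
                       n_ligand_atoms = n_ligand_atoms) else NULL
    ty <- types[1 + (cidx - 1L) %% 3L]
    logaff <- numeric(sizes[cidx])
    ids <- character(sizes[cidx])
    for (k in seq_len(sizes[cidx])) {
      entry_no <- entry_no + 1L
      ids[k] <- sprintf("A%03d", entry_no)
      el <- sample(names(beta), n_ligand_atoms, replace = TRUE,
                   prob = c(5, 2, 2, 1))
      counts <- vapply(names(beta), function(e) sum(el == e), numeric(1))
      logaff[k] <- 2.5 + sum(beta * counts) + stats::rnorm(1, 0, noise_sd)
      if (with_complexes) {
        cx <- base_cx
        lig <- .build_chain_atoms(el)
        ## graft the variant ligand onto the shared receptor placement
        old <- cx$atoms[cx$ligand_indices, , drop = FALSE]
        fit <- superpose(as.matrix(lig[, c("x", "y", "z")]),
                         as.matrix(old[, c("x", "y", "z")]))
        moved <- apply_superposition(as.matrix(lig[, c("x", "y", "z")]), fit)
        lig$x <- moved[, 1]; lig$y <- moved[, 2]; lig$z <- moved[, 3]
        cx$atoms <- rbind(cx$atoms[cx$protein_indices, , drop = FALSE], lig)
        cx <- complex_record(ids[k], cx$atoms)
        complexes[[ids[k]]] <- cx
      }
    }
    if (violations[cidx] == "low_range")
      logaff <- mean(logaff) + 0.8 * (logaff - mean(logaff)) /
        max(diff(range(logaff)), 1e-9)
    rows[[cidx]] <- data.frame(
      entry_id = ids, affinity_value = 10^logaff, affinity_type = ty,
      protein_group = sprintf("UP%04d", cidx),
      publication_id = sprintf("PUB%03d", cidx),
      has_site_cofactor_or_metal = violations[cidx] == "cofactor",
      stringsAsFactors = FALSE)
    truth[[cidx]] <- data.frame(cluster = cidx,
                                protein_group = sprintf("UP%04d", cidx),
                                publication_id = sprintf("PUB%03d", cidx),
                                affinity_type = ty, size = sizes[cidx],
                                violation = violations[cidx],
                                stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  records <- affinity_table(df$entry_id, df$affinity_value, df$affinity_type,
                            df$protein_group, df$publication_id,
                            df$has_site_cofactor_or_metal)
  tr <- do.call(rbind, truth)
  attr(tr, "beta") <- beta
  list(records = records, complexes = complexes, truth = tr)
}
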