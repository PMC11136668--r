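## Shrake-Rupley solvent-accessible surface area with a deterministic
## Fibonacci-lattice point set, and the buried-surface difference
## SASA(protein) + SASA(ligand) - SASA(complex).

## n approximately evenly distributed points on the unit sphere
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Samples `n_sphere_points` Fibonacci-lattice points on each atom's expanded
#' sphere (van der Waals radius + probe radius, Bondi radii) and counts the
#' points not buried inside any other atom's expanded sphere.
#'
#' @param xyz n x 3 coordinate matrix, Angstrom.
#' @param elements element symbols (length n), used to look up vdW radii.
#' @param probe_radius solvent probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points sample points per atom (default 960).
#' @param per_atom return the per-atom vector instead of the total.
#' @return total SASA in Angstrom^2 (or per-atom vector).
#' @export
sasa <- function(xyz, elements, probe_radius = 1.4, n_sphere_points = 960,
                 per_atom = FALSE) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  r <- element_property(elements, "r_vdw") + probe_radius
  if (anyNA(r))
    stop_ligdyn("validation", "element without van der Waals radius")
  pts <- .fibonacci_sphere(n_sphere_points)
  out <- numeric(n)
  ## neighbour prefilter: atoms can only occlude within r_i + r_j
  for (i in seq_len(n)) {
    di <- sweep(xyz, 2, xyz[i, ])
    d2 <- rowSums(di * di)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) == 0L) { out[i] <- 4 * pi * r[i]^2; next }
    sp <- pts * r[i]
    sp <- sweep(sp, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dj <- sweep(sp, 2, xyz[j, ])
      free <- free & rowSums(dj * dj) > r[j]^2
      if (!any(free)) break
    }
    out[i] <- 4 * pi * r[i]^2 * mean(free)
  }
  if (per_atom) out else sum(out)
}

#' Buried solvent-accessible surface area of a complex
#'
#' Interface area lost on binding:
#' `SASA(protein alone) + SASA(ligand alone) - SASA(complex)`, each term via
#' [sasa()]. Non-negative up to sampling noise; waters/ions are excluded,
#' hydrogens optionally.
#'
#' @param complex a [complex_record()].
#' @param xyz optional n x 3 coordinates overriding the complex's own (e.g. a
#'   trajectory frame; must cover all complex atoms).
#' @param probe_radius,n_sphere_points passed to [sasa()].
#' @param heavy_only drop hydrogens (default `TRUE`).
#' @return buried SASA, Angstrom^2.
#' @export
buried_sasa <- function(complex, xyz = NULL, probe_radius = 1.4,
                        n_sphere_points = 960, heavy_only = TRUE) {
  at <- complex$atoms
  if (is.null(xyz)) xyz <- coords(complex)
  prot <- complex$protein_indices; lig <- complex$ligand_indices
  if (heavy_only) {
    heavy <- which(.is_heavy(at))
    prot <- intersect(prot, heavy); lig <- intersect(lig, heavy)
  }
  s <- function(idx) sasa(xyz[idx, , drop = FALSE], at$element[idx],
                          probe_radius, n_sphere_points)
  both <- c(prot, lig)
  s(prot) + s(lig) - s(both)
}
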