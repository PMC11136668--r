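## Geometry-level curation heuristics. The source protocol's checks are
## quantum-chemical; here each is re-expressed on geometry and connectivity,
## and quantum-derived quantities (HOMO-LUMO gap, electron count, charges,
## polarizabilities) enter as *inputs*. Findings are rows of a data.frame
## with a list-column of atom indices; a report's verdict is clean iff no
## finding of severity warn or fail is present.

.qc_kinds <- c("clash", "bond_length_deviation", "angle_deviation",
               "planarity_deviation", "valence_violation",
               "local_charge_excess", "connectivity_change",
               "property_outlier", "convergence_proxy")

.finding <- function(kind, atoms, measured = NA_real_, reference = NA_real_,
                     units = "", severity = "warn", detail = "") {
  stopifnot(kind %in% .qc_kinds)
  data.frame(kind = kind,
             atom_indices = I(list(as.integer(atoms))),
             measured = measured, reference = reference, units = units,
             severity = severity, detail = detail,
             stringsAsFactors = FALSE)
}

.no_findings <- function() {
  data.frame(kind = character(), atom_indices = I(list()),
             measured = numeric(), reference = numeric(),
             units = character(), severity = character(),
             detail = character(), stringsAsFactors = FALSE)
}

.bind_findings <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0L) return(.no_findings())
  do.call(rbind, lst)
}

## ---------------------------------------------------------------- clashes

.all_pairs_clashes <- function(xyz, thr) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n - 1L)) {
    d <- sweep(xyz[(i + 1L):n, , drop = FALSE], 2, xyz[i, ])
    dist <- sqrt(rowSums(d * d))
    hits <- which(dist < thr[i, (i + 1L):n])
    if (length(hits))
      out <- rbind(out, cbind(i, i + hits, dist[hits]))
  }
  out
}

.grid_clashes <- function(xyz, thr) {
  n <- nrow(xyz)
  cell <- max(thr)
  ci <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  key <- paste(ci[, 1], ci[, 2], ci[, 3])
  cells <- split(seq_len(n), key)
  coord <- do.call(rbind, lapply(strsplit(names(cells), " "), as.integer))
  lookup <- new.env(hash = TRUE)
  for (k in seq_along(cells)) assign(names(cells)[k], cells[[k]], envir = lookup)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- NULL
  for (k in seq_along(cells)) {
    mine <- cells[[k]]
    nb <- integer(0)
    for (o in seq_len(nrow(off))) {
      kk <- paste(coord[k, 1] + off[o, 1], coord[k, 2] + off[o, 2],
                  coord[k, 3] + off[o, 3])
      if (!is.null(v <- lookup[[kk]])) nb <- c(nb, v)
    }
    for (i in mine) {
      cand <- nb[nb > i]
      if (!length(cand)) next
      d <- sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])
      dist <- sqrt(rowSums(d * d))
      hits <- which(dist < thr[i, cand])
      if (length(hits))
        out <- rbind(out, cbind(i, cand[hits], dist[hits]))
    }
  }
  out
}

#' Detect steric clashes
#'
#' Flags atom pairs whose distance falls below
#' `overlap_fraction * (r_cov(a) + r_cov(b))` - a strong covalent-radius
#' overlap, the opening check of the curation protocol. Pairs listed in
#' `bonds` are skipped. A spatial-grid search and the brute-force all-pairs
#' enumeration give identical results; the grid is the default.
#'
#' @param atoms atom `data.frame` (see [atom_table()]).
#' @param overlap_fraction clash threshold as a fraction of the summed
#'   covalent radii (default 0.5).
#' @param bonds optional [bond_table()] whose pairs are exempt.
#' @param method `"grid"` (cell list) or `"brute"` (all pairs).
#' @return findings data.frame (kind `clash`, severity `fail`), one row per
#'   clashing pair, sorted by first then second atom index.
#' @export
detect_clashes <- function(atoms, overlap_fraction = 0.5, bonds = NULL,
                           method = c("grid", "brute")) {
  method <- match.arg(method)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 2L) return(.no_findings())
  rc <- element_property(atoms$element, "r_cov")
  thr <- overlap_fraction * outer(rc, rc, "+")
  raw <- if (method == "grid") .grid_clashes(xyz, thr) else .all_pairs_clashes(xyz, thr)
  if (is.null(raw)) return(.no_findings())
  if (!is.null(bonds)) {
    bk <- paste(bonds$bonds$i, bonds$bonds$j)
    keep <- !(paste(raw[, 1], raw[, 2]) %in% bk)
    raw <- raw[keep, , drop = FALSE]
  }
  if (nrow(raw) == 0L) return(.no_findings())
  raw <- raw[order(raw[, 1], raw[, 2]), , drop = FALSE]
  .bind_findings(lapply(seq_len(nrow(raw)), function(k)
    .finding("clash", raw[k, 1:2], measured = raw[k, 3],
             reference = thr[raw[k, 1], raw[k, 2]], units = "A",
             severity = "fail",
             detail = sprintf("distance %.3f A below %.2f x covalent overlap",
                              raw[k, 3], overlap_fraction))))
}

## ------------------------------------------------------- bond perception

#' Bond table
#'
#' Connectivity container: unordered bonded pairs with bond orders, per-atom
#' hybridizations, and any embedded findings from perception (e.g. an atom
#' exceeding its element's maximum coordination).
#'
#' @param bonds data.frame with integer columns `i < j` and numeric `order`
#'   (1, 1.5, 2 or 3).
#' @param hybridization per-atom character vector (`sp`, `sp2`, `sp3`,
#'   `other`).
#' @param n_atoms atom count the table refers to.
#' @param findings embedded findings data.frame.
#' @return object of class `bond_table`.
#' @export
bond_table <- function(bonds, hybridization, n_atoms,
                       findings = .no_findings()) {
  if (nrow(bonds)) {
    stopifnot(all(bonds$i < bonds$j), all(bonds$j <= n_atoms))
    bonds <- bonds[order(bonds$i, bonds$j), , drop = FALSE]
    rownames(bonds) <- NULL
  }
  structure(list(bonds = bonds, hybridization = hybridization,
                 n_atoms = as.integer(n_atoms), findings = findings),
            class = "bond_table")
}

#' @export
print.bond_table <- function(x, ...) {
  cat(sprintf("<bond_table: %d atoms, %d bonds>\n", x$n_atoms, nrow(x$bonds)))
  invisible(x)
}

.angle_deg <- function(a, center, b) {
  u <- a - center; v <- b - center
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

## out-of-plane distance of `center` from the plane of its 3 neighbours
.oop_distance <- function(center, nb_xyz) {
  nrm <- .cross(nb_xyz[2, ] - nb_xyz[1, ], nb_xyz[3, ] - nb_xyz[1, ])
  len <- sqrt(sum(nrm * nrm))
  if (len < 1e-12) return(0)
  abs(sum((center - nb_xyz[1, ]) * nrm / len))
}

.cross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                           u[3] * v[1] - u[1] * v[3],
                           u[1] * v[2] - u[2] * v[1])

#' Distance-based bond and hybridization perception
#'
#' Bonds are assigned where the interatomic distance does not exceed the sum
#' of covalent radii plus `tolerance`; the order is upgraded to double or
#' triple when the distance falls below the midpoint between the reference
#' lengths of adjacent orders for that element pair. Hybridization follows
#' from the bonded-neighbour count and local geometry (planarity for
#' 3-coordinate centres, bond angle for 2-coordinate ones). An atom bonded
#' beyond its element's maximum coordination yields an embedded
#' `valence_violation` finding rather than an error.
#'
#' @param atoms atom `data.frame`.
#' @param tolerance additive slack on the covalent-radius sum, Angstrom
#'   (default 0.4).
#' @param planarity_tol out-of-plane distance below which a 3-coordinate
#'   centre counts as planar (sp2), Angstrom (default 0.25).
#' @return a [bond_table()].
#' @export
perceive_bonds <- function(atoms, tolerance = 0.4, planarity_tol = 0.25) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  n <- nrow(xyz)
  el <- atoms$element
  rc <- element_property(el, "r_cov")
  bonds <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      d <- sweep(xyz[(i + 1L):n, , drop = FALSE], 2, xyz[i, ])
      dist <- sqrt(rowSums(d * d))
      cut <- rc[i] + rc[(i + 1L):n] + tolerance
      hits <- which(dist <= cut)
      if (length(hits))
        bonds <- rbind(bonds, cbind(i, i + hits, dist[hits]))
    }
  }
  if (is.null(bonds)) {
    bdf <- data.frame(i = integer(), j = integer(), order = numeric(),
                      length = numeric())
  } else {
    ord <- vapply(seq_len(nrow(bonds)), function(k) {
      i <- bonds[k, 1]; j <- bonds[k, 2]; d <- bonds[k, 3]
      r1 <- .ref_bond_length(el[i], el[j], 1)
      r2 <- .ref_bond_length(el[i], el[j], 2)
      r3 <- .ref_bond_length(el[i], el[j], 3)
      o <- 1
      if (!is.na(r2) && !is.na(r1) && d < (r1 + r2) / 2) o <- 2
      if (!is.na(r3) && !is.na(r2) && d < (r2 + r3) / 2) o <- 3
      o
    }, numeric(1))
    bdf <- data.frame(i = as.integer(bonds[, 1]), j = as.integer(bonds[, 2]),
                      order = ord, length = bonds[, 3])
  }
  ## adjacency for hybridization
  nb_of <- function(a) c(bdf$j[bdf$i == a], bdf$i[bdf$j == a])
  hyb <- character(n)
  for (a in seq_len(n)) {
    nb <- nb_of(a)
    k <- length(nb)
    if (el[a] == "H" || k == 0L) { hyb[a] <- "other"; next }
    omax <- max(c(bdf$order[bdf$i == a | bdf$j == a], 1))
    hyb[a] <-
      if (k >= 4L) "sp3"
      else if (k == 3L) {
        if (.oop_distance(xyz[a, ], xyz[nb, , drop = FALSE]) <= planarity_tol)
          "sp2" else "sp3"
      } else if (k == 2L) {
        ang <- .angle_deg(xyz[nb[1], ], xyz[a, ], xyz[nb[2], ])
        if (ang >= 160) "sp" else if (omax >= 2) "sp2" else "sp3"
      } else {
        if (omax >= 3) "sp" else if (omax >= 2) "sp2" else "sp3"
      }
  }
  findings <- .bind_findings(lapply(seq_len(n), function(a) {
    k <- length(nb_of(a))
    mx <- element_property(el[a], "max_bonds")
    if (!is.na(mx) && k > mx)
      .finding("valence_violation", a, measured = k, reference = mx,
               units = "bonds", severity = "fail",
               detail = sprintf("%s bonded to %d atoms (max %d)", el[a], k, mx))
  }))
  bond_table(bdf, hyb, n, findings)
}

## ------------------------------------------------------- valence audit

#' Audit valences and local formal charges
#'
#' Flags atoms whose bond-order sum, corrected by the formal charge, exceeds
#' the element's allowed valence (C 4, N 3 - so a 4-coordinate neutral N is
#' flagged while N+ is not - O 2, S 6, ...), and atoms whose one-bond
#' neighbourhood (the atom plus its bonded neighbours) carries a summed
#' formal charge of +2 or more (`local_charge_excess`) - the signature of an
#' over-protonated group such as a guanidinium carrying +3 around its
#' central carbon.
#'
#' @param atoms atom `data.frame`.
#' @param bonds a [bond_table()].
#' @param formal_charges per-atom integer charges (default all 0).
#' @param charge_excess_threshold neighbourhood charge at or above which to
#'   flag (default +2).
#' @return findings data.frame.
#' @export
audit_valence <- function(atoms, bonds, formal_charges = NULL,
                          charge_excess_threshold = 2) {
  n <- nrow(atoms)
  if (is.null(formal_charges)) formal_charges <- rep(0L, n)
  if (length(formal_charges) != n)
    stop_ligdyn("validation", "formal_charges length %d, %d atoms",
                length(formal_charges), n)
  el <- atoms$element
  bdf <- bonds$bonds
  order_sum <- numeric(n); nb <- vector("list", n)
  for (k in seq_len(nrow(bdf))) {
    i <- bdf$i[k]; j <- bdf$j[k]; o <- bdf$order[k]
    order_sum[i] <- order_sum[i] + o
    order_sum[j] <- order_sum[j] + o
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  out <- list()
  for (a in seq_len(n)) {
    base <- .ligdyn_valence[el[a]]
    if (!is.na(base)) {
      eff <- order_sum[a] - formal_charges[a]
      if (eff > base)
        out[[length(out) + 1L]] <-
          .finding("valence_violation", a, measured = eff, reference = base,
                   units = "valence", severity = "fail",
                   detail = sprintf("%s: bond-order sum %.1f, charge %+d exceeds valence %d",
                                    el[a], order_sum[a], formal_charges[a], base))
    }
    qloc <- formal_charges[a] + sum(formal_charges[nb[[a]]])
    if (qloc >= charge_excess_threshold)
      out[[length(out) + 1L]] <-
        .finding("local_charge_excess", c(a, nb[[a]]), measured = qloc,
                 reference = charge_excess_threshold, units = "e",
                 severity = "warn",
                 detail = sprintf("formal charge %+d within one bond of atom %d",
                                  qloc, a))
  }
  .bind_findings(out)
}

## ------------------------------------------------------- geometry checks

#' Check bond lengths, angles and planarity against reference geometry
#'
#' Compares the observed geometry to the chemical graph supplied in `bonds`:
#' bonds deviating more than `length_tol` (fractional) from the reference
#' length for their element pair and order; angles deviating more than
#' `angle_tol` degrees from the ideal VSEPR value for the central atom's
#' hybridization; and 3-coordinate sp2 centres pyramidalized beyond
#' `planarity_tol` (out-of-plane distance from the neighbours' plane).
#' `bonds` carries the *intended* connectivity: a nitro N-O stretched 17%
#' is only detectable against its order-2 reference, since re-perceiving
#' the stretched bond would classify it as a clean single bond.
#'
#' @param atoms atom `data.frame`.
#' @param bonds a [bond_table()] (perceived or template).
#' @param length_tol fractional bond-length tolerance (default 0.10).
#' @param angle_tol angle tolerance, degrees (default 12).
#' @param planarity_tol out-of-plane tolerance, Angstrom (default 0.25).
#' @return findings data.frame; a bond whose element pair/order has no
#'   reference entry yields an info-level finding, not a failure.
#' @export
check_geometry <- function(atoms, bonds, length_tol = 0.10, angle_tol = 12,
                           planarity_tol = 0.25) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  el <- atoms$element
  bdf <- bonds$bonds
  out <- list()
  for (k in seq_len(nrow(bdf))) {
    i <- bdf$i[k]; j <- bdf$j[k]
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ref <- .ref_bond_length(el[i], el[j], bdf$order[k])
    if (is.na(ref)) {
      out[[length(out) + 1L]] <-
        .finding("bond_length_deviation", c(i, j), measured = d,
                 units = "A", severity = "info",
                 detail = sprintf("no reference length for %s-%s order %.1f",
                                  el[i], el[j], bdf$order[k]))
    } else if (abs(d - ref) / ref > length_tol) {
      out[[length(out) + 1L]] <-
        .finding("bond_length_deviation", c(i, j), measured = d,
                 reference = ref, units = "A", severity = "warn",
                 detail = sprintf("%s-%s bond %.3f A deviates %.0f%% from %.3f A",
                                  el[i], el[j], d, 100 * abs(d - ref) / ref, ref))
    }
  }
  nb <- vector("list", nrow(atoms))
  for (k in seq_len(nrow(bdf))) {
    nb[[bdf$i[k]]] <- c(nb[[bdf$i[k]]], bdf$j[k])
    nb[[bdf$j[k]]] <- c(nb[[bdf$j[k]]], bdf$i[k])
  }
  for (a in seq_len(nrow(atoms))) {
    hy <- bonds$hybridization[a]
    ideal <- .ligdyn_ideal_angles[hy]
    ns <- nb[[a]]
    if (!is.na(ideal) && length(ns) >= 2L) {
      prs <- utils::combn(ns, 2)
      for (c2 in seq_len(ncol(prs))) {
        ang <- .angle_deg(xyz[prs[1, c2], ], xyz[a, ], xyz[prs[2, c2], ])
        dev <- if (hy == "sp") 180 - ang else abs(ang - ideal)
        if (dev > angle_tol)
          out[[length(out) + 1L]] <-
            .finding("angle_deviation", c(prs[1, c2], a, prs[2, c2]),
                     measured = ang, reference = unname(ideal),
                     units = "deg", severity = "warn",
                     detail = sprintf("%s (%s) angle %.1f deg vs ideal %.1f",
                                      el[a], hy, ang, ideal))
      }
    }
    if (identical(hy, "sp2") && length(ns) == 3L) {
      oop <- .oop_distance(xyz[a, ], xyz[ns, , drop = FALSE])
      if (oop > planarity_tol)
        out[[length(out) + 1L]] <-
          .finding("planarity_deviation", c(a, ns), measured = oop,
                   reference = planarity_tol, units = "A", severity = "warn",
                   detail = sprintf("sp2 %s pyramidalized %.2f A out of plane",
                                    el[a], oop))
    }
  }
  .bind_findings(out)
}

## ----------------------------------------------- connectivity comparison

#' Compare two bond tables
#'
#' Reports the symmetric difference of the bond sets (bonds broken or formed,
#' e.g. after a geometry optimization) and, separately, common bonds whose
#' order changed.
#'
#' @param before,after [bond_table()] objects over the same atoms.
#' @return findings data.frame (kind `connectivity_change`).
#' @export
compare_connectivity <- function(before, after) {
  if (before$n_atoms != after$n_atoms)
    stop_ligdyn("validation", "atom counts differ: %d vs %d",
                before$n_atoms, after$n_atoms)
  kb <- paste(before$bonds$i, before$bonds$j)
  ka <- paste(after$bonds$i, after$bonds$j)
  out <- list()
  for (k in which(!(kb %in% ka)))
    out[[length(out) + 1L]] <-
      .finding("connectivity_change",
               c(before$bonds$i[k], before$bonds$j[k]),
               severity = "warn",
               detail = sprintf("bond %d-%d broken", before$bonds$i[k],
                                before$bonds$j[k]))
  for (k in which(!(ka %in% kb)))
    out[[length(out) + 1L]] <-
      .finding("connectivity_change",
               c(after$bonds$i[k], after$bonds$j[k]),
               severity = "warn",
               detail = sprintf("bond %d-%d formed", after$bonds$i[k],
                                after$bonds$j[k]))
  common <- intersect(kb, ka)
  ob <- before$bonds$order[match(common, kb)]
  oa <- after$bonds$order[match(common, ka)]
  for (k in which(ob != oa)) {
    ij <- as.integer(strsplit(common[k], " ")[[1]])
    out[[length(out) + 1L]] <-
      .finding("connectivity_change", ij, measured = oa[k], reference = ob[k],
               units = "order", severity = "warn",
               detail = sprintf("bond %d-%d order %.1f -> %.1f",
                                ij[1], ij[2], ob[k], oa[k]))
  }
  .bind_findings(out)
}

## ------------------------------------------------- property outliers

#' Flag bivariate property outliers within element groups
#'
#' Screens property pairs (canonically atomic polarizability against partial
#' charge) element by element for wrong atom assignments: within each group
#' with at least `min_group` points, a least-squares line of `y` on `x` is
#' fitted and points whose robust z-score of the residual (median/MAD)
#' exceeds `k_sd` are flagged. A group with (near-)constant `x` falls back
#' to a univariate screen on `y`; smaller groups are skipped with an
#' info-level finding.
#'
#' @param x,y per-atom numeric vectors (e.g. partial charge, polarizability).
#' @param group per-atom labels (e.g. element symbols).
#' @param k_sd robust z-score threshold (default 4).
#' @param min_group minimum points per analyzed group (default 8).
#' @return findings data.frame (kind `property_outlier`), indices into the
#'   input vectors.
#' @export
flag_property_outliers <- function(x, y, group, k_sd = 4, min_group = 8) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  out <- list()
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < min_group) {
      out[[length(out) + 1L]] <-
        .finding("property_outlier", idx, severity = "info",
                 detail = sprintf("group %s skipped: %d < %d points",
                                  g, length(idx), min_group))
      next
    }
    xi <- x[idx]; yi <- y[idx]
    res <- if (stats::sd(xi) < 1e-12) {
      yi - stats::median(yi)
    } else {
      stats::residuals(stats::lm(yi ~ xi))
    }
    sc <- stats::mad(res)
    if (sc < 1e-12) sc <- stats::sd(res)
    if (sc < 1e-12) next
    z <- (res - stats::median(res)) / sc
    for (k in which(abs(z) > k_sd))
      out[[length(out) + 1L]] <-
        .finding("property_outlier", idx[k], measured = abs(z[k]),
                 reference = k_sd, units = "z", severity = "warn",
                 detail = sprintf("group %s: residual z %.1f", g, z[k]))
  }
  .bind_findings(out)
}

## ------------------------------------------------- electronic-flag screen

#' Screen consumed electronic-structure flags
#'
#' Consumes quantum-derived scalars and flags convergence proxies: a
#' vanishing HOMO-LUMO gap (below `gap_threshold`) warns; an odd electron
#' count on a ligand declared closed-shell fails. Missing fields yield
#' info-level findings; nothing is computed here.
#'
#' @param qm a [qm_record()] with `molecular$homo_lumo_gap` (eV),
#'   `molecular$electron_count` and optionally `molecular$closed_shell`
#'   (assumed `TRUE` when absent).
#' @param gap_threshold eV (default 0.1).
#' @return findings data.frame (kind `convergence_proxy`).
#' @export
screen_electronic_flags <- function(qm, gap_threshold = 0.1) {
  out <- list()
  gap <- qm$molecular$homo_lumo_gap
  if (is.null(gap)) {
    out[[length(out) + 1L]] <-
      .finding("convergence_proxy", integer(0), severity = "info",
               detail = "homo_lumo_gap not supplied")
  } else if (gap < gap_threshold) {
    out[[length(out) + 1L]] <-
      .finding("convergence_proxy", integer(0), measured = gap,
               reference = gap_threshold, units = "eV", severity = "warn",
               detail = sprintf("vanishing HOMO-LUMO gap %.3g eV", gap))
  }
  ne <- qm$molecular$electron_count
  closed <- qm$molecular$closed_shell
  if (is.null(closed)) closed <- TRUE
  if (is.null(ne)) {
    out[[length(out) + 1L]] <-
      .finding("convergence_proxy", integer(0), severity = "info",
               detail = "electron_count not supplied")
  } else if (isTRUE(closed) && ne %% 2 == 1) {
    out[[length(out) + 1L]] <-
      .finding("convergence_proxy", integer(0), measured = ne,
               units = "electrons", severity = "fail",
               detail = sprintf("odd electron count %d for declared closed shell", ne))
  }
  .bind_findings(out)
}

## ----------------------------------------------------------- QC report

#' Run the curation checks on a complex
#'
#' Applies clash detection over the whole complex and, on the ligand (by
#' default), bond perception, the valence/charge audit and the
#' reference-geometry checks; quantum-derived flags are screened when a
#' [qm_record()] is supplied. Verdict: `clean` (no warn/fail findings),
#' `needs_review` (warnings only) or `reject` (any failure).
#'
#' @param complex a [complex_record()].
#' @param formal_charges per-ligand-atom formal charges (default 0).
#' @param qm optional [qm_record()] for [screen_electronic_flags()].
#' @param ligand_only restrict geometry/valence checks to the ligand
#'   (default `TRUE`; the clash search always covers the complex).
#' @param ... tolerances passed to the individual checks.
#' @return object of class `qc_report`: list with `entry_id`, `findings`
#'   (atom indices refer to the complex atom table) and `verdict`.
#' @export
qc_report <- function(complex, formal_charges = NULL, qm = NULL,
                      ligand_only = TRUE, ...) {
  at <- complex$atoms
  all_bonds <- perceive_bonds(at)
  sub <- if (ligand_only) complex$ligand_indices else seq_len(nrow(at))
  sat <- at[sub, , drop = FALSE]
  bt <- perceive_bonds(sat)
  remap <- function(f) {
    f$atom_indices <- I(lapply(f$atom_indices, function(ix) sub[ix]))
    f
  }
  findings <- .bind_findings(list(
    detect_clashes(at, bonds = all_bonds, ...),
    remap(bt$findings),
    remap(audit_valence(sat, bt, formal_charges)),
    remap(check_geometry(sat, bt, ...)),
    if (!is.null(qm)) screen_electronic_flags(qm)
  ))
  sev <- findings$severity
  verdict <- if (any(sev == "fail")) "reject"
             else if (any(sev == "warn")) "needs_review"
             else "clean"
  structure(list(entry_id = complex$entry_id, findings = findings,
                 verdict = verdict),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report %s: %s (%d findings)>\n", x$entry_id, x$verdict,
              nrow(x$findings)))
  if (nrow(x$findings))
    print(x$findings[, c("kind", "severity", "detail")])
  invisible(x)
}
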