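## Shared fixture builders. Everything is generated in code at test time.

## a minimal two-group complex: protein atoms + ligand atoms at given spots
make_point_complex <- function(protein_xyz, ligand_xyz,
                               protein_el = "C", ligand_el = "C",
                               entry_id = "TOYA") {
  np <- nrow(protein_xyz); nl <- nrow(ligand_xyz)
  at <- atom_table(
    element = c(rep_len(protein_el, np), rep_len(ligand_el, nl)),
    x = c(protein_xyz[, 1], ligand_xyz[, 1]),
    y = c(protein_xyz[, 2], ligand_xyz[, 2]),
    z = c(protein_xyz[, 3], ligand_xyz[, 3]),
    residue_index = c(seq_len(np), rep(np + 1L, nl)),
    residue_name = c(rep("GLY", np), rep("LIG", nl)),
    chain_id = c(rep("A", np), rep("L", nl)),
    role = c(rep("protein", np), rep("ligand", nl)))
  complex_record(entry_id, at)
}

## non-collinear static scaffold used as alignment anchor
anchor_points <- function() {
  rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4), c(4, 4, 4))
}

## random rotation matrix (uniform axis, bounded angle)
random_rotation <- function(max_deg = 180) {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_deg * pi / 180)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## trajectory array from a list of n x 3 frames
traj_from_frames <- function(frames, entry_id = "TRAJ") {
  co <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) co[f, , ] <- frames[[f]]
  trajectory_record(entry_id, co)
}

## naive per-atom / per-frame double-loop adaptability (independent oracle)
naive_adaptability <- function(co_aligned, ref_frame = 1L) {
  nf <- dim(co_aligned)[1]; na <- dim(co_aligned)[2]
  g <- numeric(na)
  for (a in seq_len(na)) {
    s <- 0
    for (f in seq_len(nf)) {
      d <- co_aligned[f, a, ] - co_aligned[ref_frame, a, ]
      s <- s + sqrt(sum(d^2))
    }
    g[a] <- s / nf
  }
  g
}

## brute-force two-pass RMSF (independent oracle)
naive_rmsf <- function(co_aligned) {
  nf <- dim(co_aligned)[1]; na <- dim(co_aligned)[2]
  out <- numeric(na)
  for (a in seq_len(na)) {
    m <- colMeans(co_aligned[, a, , drop = FALSE][, 1, ])
    s <- 0
    for (f in seq_len(nf)) s <- s + sum((co_aligned[f, a, ] - m)^2)
    out[a] <- sqrt(s / nf)
  }
  out
}

## value whose single-pass z-score (mean/sd computed with it included, as
## the wide-band filter does) equals z
plant_outlier <- function(v, z) {
  f <- function(x) (x - mean(c(v, x))) - z * sd(c(v, x))
  uniroot(f, c(mean(v), mean(v) + 10 * z * max(sd(v), 1e-6)))$root
}

## all-pairs radius edges (independent oracle for build_graph)
brute_edges <- function(xyz, cutoff) {
  n <- nrow(xyz); out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  out
}
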