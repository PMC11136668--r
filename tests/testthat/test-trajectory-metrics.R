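test_that("superposition recovers identity, translations and rotations", {
  set.seed(1)
  cloud <- matrix(rnorm(60), 20, 3)
  s <- superpose(cloud, cloud)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)
  expect_equal(s$rotation, diag(3), tolerance = 1e-10)

  shifted <- sweep(cloud, 2, c(5, 0, 0), "+")
  s2 <- superpose(shifted, cloud)
  expect_equal(s2$rmsd, 0, tolerance = 1e-10)
  expect_equal(s2$translation, c(-5, 0, 0), tolerance = 1e-10)

  th <- 30 * pi / 180
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- cloud %*% Rz
  s3 <- superpose(rot, cloud)
  expect_lt(s3$rmsd, 1e-8)
  expect_equal(s3$rotation, t(Rz), tolerance = 1e-8)
  expect_equal(det(s3$rotation), 1, tolerance = 1e-10)
})

test_that("superposition agrees with bio3d's independent fit", {
  set.seed(2)
  for (rep in 1:5) {
    ref <- matrix(rnorm(45), 15, 3)
    mob <- sweep(ref %*% random_rotation(), 2, rnorm(3, sd = 4), "+") +
      matrix(rnorm(45, sd = 0.1), 15, 3)
    fit <- superpose(mob, ref)
    moved <- apply_superposition(mob, fit)
    b3d <- bio3d::fit.xyz(fixed = as.numeric(t(ref)),
                          mobile = as.numeric(t(mob)),
                          fixed.inds = 1:45, mobile.inds = 1:45)
    expect_equal(as.numeric(t(moved)), as.numeric(b3d), tolerance = 1e-6)
  }
})

test_that("degenerate superposition selections are rejected", {
  ref <- matrix(rnorm(30), 10, 3)
  expect_error(superpose(ref, ref, selection = 1:2), ">= 3",
               class = "ligdyn_validation_error")
  line <- cbind(1:10, 0, 0)
  expect_error(superpose(line + 0.0, line), "collinear",
               class = "ligdyn_validation_error")
})

test_that("adaptability is zero for a static trajectory and matches the
           hand-computed two-frame case with and without the reference", {
  anchors <- anchor_points()
  pts <- rbind(anchors, c(2, 2, 0))
  tr <- traj_from_frames(list(pts, pts, pts))
  prof <- adaptability(tr, align_selection = 1:5, drop_hydrogens = FALSE)
  expect_equal(prof$gamma, rep(0, 6))

  moved <- pts; moved[6, ] <- moved[6, ] + c(1, 0, 0)
  tr2 <- traj_from_frames(list(pts, moved))
  g_inc <- adaptability(tr2, align_selection = 1:5, drop_hydrogens = FALSE)
  expect_equal(g_inc$gamma[6], 0.5, tolerance = 1e-10)
  g_exc <- adaptability(tr2, align_selection = 1:5, drop_hydrogens = FALSE,
                        include_reference = FALSE)
  expect_equal(g_exc$gamma[6], 1.0, tolerance = 1e-10)
})

test_that("rmsf matches closed forms and the two-pass loop oracle", {
  anchors <- anchor_points()
  ## atom alternating +/- d about its mean
  d <- 0.7
  frames <- lapply(1:40, function(f) {
    p <- rbind(anchors, c(2, 2, 2))
    p[6, 1] <- p[6, 1] + d * (-1)^f
    p
  })
  tr <- traj_from_frames(frames)
  r <- rmsf(tr, align_selection = 1:5)
  expect_equal(r[6], d, tolerance = 1e-10)
  expect_equal(r[1:5], rep(0, 5), tolerance = 1e-10)

  set.seed(3)
  co <- array(rnorm(50 * 30 * 3, sd = 0.5), c(50, 30, 3))
  co[, 1:5, ] <- co[rep(1, 50), 1:5, ]      # fixed alignment anchors
  for (a in 1:5) for (k in 1:3) co[, a, k] <- co[1, a, k]
  tr2 <- trajectory_record("RND", co)
  r2 <- rmsf(tr2, align_selection = 1:5)
  expect_equal(r2, naive_rmsf(ligdyn:::.aligned_coordinates(tr2, 1L, 1:5)),
               tolerance = 1e-10)
  expect_error(rmsf(traj_from_frames(list(anchors))), "single frame",
               class = "ligdyn_validation_error")
})

test_that("ligand RMSD reports rigid ligand shifts in the protein frame", {
  cx <- make_point_complex(anchor_points(), rbind(c(2, 2, 2), c(3, 2, 2)))
  p0 <- coords(cx)
  p1 <- p0; p1[6:7, ] <- sweep(p1[6:7, ], 2, c(0, 2, 0), "+")
  tr <- traj_from_frames(list(p0, p1))
  rr <- ligand_rmsd(tr, cx)
  expect_equal(rr[1], 0, tolerance = 1e-10)
  expect_equal(rr[2], 2.0, tolerance = 1e-10)

  ## random fixture vs the direct formula (no alignment needed: anchors fixed)
  set.seed(4)
  p2 <- p0; p2[6:7, ] <- p2[6:7, ] + matrix(rnorm(6), 2, 3)
  tr2 <- traj_from_frames(list(p0, p2))
  manual <- sqrt(mean(rowSums((p2[6:7, ] - p0[6:7, ])^2)))
  expect_equal(ligand_rmsd(tr2, cx)[2], manual, tolerance = 1e-10)
})

test_that("centre-of-mass distance matches the weighted-mean oracle", {
  one <- make_point_complex(matrix(c(0, 0, 0), 1), matrix(c(7, 0, 0), 1))
  tr <- traj_from_frames(list(coords(one)))
  expect_equal(com_distance(tr, one), 7)
  expect_equal(com_distance(tr, one, mass_weighted = FALSE), 7)

  set.seed(5)
  cx <- make_point_complex(matrix(rnorm(36), 12, 3),
                           matrix(rnorm(24, mean = 6), 8, 3),
                           protein_el = sample(c("C", "N", "O"), 12, TRUE),
                           ligand_el = sample(c("C", "S"), 8, TRUE))
  tr2 <- traj_from_frames(list(coords(cx)))
  m <- cx$atoms$mass
  comp <- colSums(coords(cx)[1:12, ] * m[1:12]) / sum(m[1:12])
  coml <- colSums(coords(cx)[13:20, ] * m[13:20]) / sum(m[13:20])
  expect_equal(com_distance(tr2, cx), sqrt(sum((comp - coml)^2)),
               tolerance = 1e-12)
})

test_that("adaptability and rmsf are invariant under global rigid motion", {
  cx <- generate_complex(9, 8, 6)
  tr <- generate_trajectory(cx, mobility_profile(rep(0.3, nrow(cx$atoms))),
                            n_frames = 15, seed = 6, rigid_deg = 0,
                            rigid_trans = 0)
  g0 <- adaptability(tr, cx)$gamma
  r0 <- rmsf(tr, cx)
  set.seed(7)
  R <- random_rotation(); tv <- rnorm(3, sd = 10)
  co <- tr$coordinates
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- sweep(matrix(co[f, , ], ncol = 3) %*% R, 2, tv, "+")
  tr2 <- trajectory_record(tr$entry_id, co, tr$frame_times)
  expect_lt(max(abs(adaptability(tr2, cx)$gamma - g0)), 1e-8)
  expect_lt(max(abs(rmsf(tr2, cx) - r0)), 1e-8)
})
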