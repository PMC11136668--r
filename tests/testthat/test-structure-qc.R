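test_that("clash detection flags only genuinely overlapping pairs", {
  far <- atom_table(c("C", "C"), x = c(0, 3), y = 0, z = 0)
  expect_equal(nrow(detect_clashes(far)), 0L)
  near <- atom_table(c("C", "C"), x = c(0, 0.3), y = 0, z = 0)
  f <- detect_clashes(near)
  expect_equal(nrow(f), 1L)
  expect_equal(f$kind, "clash")
  expect_equal(f$atom_indices[[1]], c(1L, 2L))
})

test_that("grid and brute-force clash searches agree on random instances", {
  set.seed(10)
  for (rep in 1:25) {
    n <- sample(50:150, 1)
    at <- atom_table(sample(c("C", "N", "O", "S", "P"), n, TRUE),
                     x = runif(n, 0, 12), y = runif(n, 0, 12),
                     z = runif(n, 0, 12))
    a <- detect_clashes(at, method = "grid")
    b <- detect_clashes(at, method = "brute")
    expect_identical(a$atom_indices, b$atom_indices)
    expect_equal(a$measured, b$measured)
  }
})

test_that("bond perception assigns orders and hybridizations from distance", {
  ## ethane-like C-C
  cc <- atom_table(c("C", "C"), x = c(0, 1.54), y = 0, z = 0)
  bt <- perceive_bonds(cc)
  expect_equal(nrow(bt$bonds), 1L)
  expect_equal(bt$bonds$order, 1)

  ## planar C=C with three neighbours each (ethylene heavy-atom skeleton,
  ## substituted by carbons at ideal sp2 positions)
  sp2pos <- function(center, partner) {
    ## two substituents at 120 degrees from the partner direction, in-plane
    u <- (partner - center) / sqrt(sum((partner - center)^2))
    v <- c(-u[2], u[1], 0)
    list(center + 1.5 * (-0.5 * u + sqrt(3) / 2 * v),
         center + 1.5 * (-0.5 * u - sqrt(3) / 2 * v))
  }
  c1 <- c(0, 0, 0); c2 <- c(1.34, 0, 0)
  s1 <- sp2pos(c1, c2); s2 <- sp2pos(c2, c1)
  at <- atom_table(rep("C", 6),
                   x = c(c1[1], c2[1], s1[[1]][1], s1[[2]][1], s2[[1]][1], s2[[2]][1]),
                   y = c(c1[2], c2[2], s1[[1]][2], s1[[2]][2], s2[[1]][2], s2[[2]][2]),
                   z = 0)
  bt2 <- perceive_bonds(at)
  db <- bt2$bonds[bt2$bonds$i == 1 & bt2$bonds$j == 2, ]
  expect_equal(db$order, 2)
  expect_equal(bt2$hybridization[1:2], c("sp2", "sp2"))

  ## far atoms stay unbonded
  expect_equal(nrow(perceive_bonds(
    atom_table(c("C", "C"), x = c(0, 10), y = 0, z = 0))$bonds), 0L)

  ## over-coordination is an embedded finding, not an exception
  crowd <- atom_table(c("O", rep("C", 4)),
                      x = c(0, 1.4, -1.4, 0, 0),
                      y = c(0, 0, 0, 1.4, -1.4), z = 0)
  bt3 <- perceive_bonds(crowd)
  expect_true(any(bt3$findings$kind == "valence_violation"))
})

test_that("valence audit flags hypervalent atoms and local charge excess", {
  ## methane-like connectivity is clean
  ch4 <- atom_table(c("C", rep("H", 4)),
                    x = c(0, 1.09, -1.09, 0, 0),
                    y = c(0, 0, 0, 1.09, -1.09), z = 0)
  bt <- bond_table(data.frame(i = rep(1L, 4), j = 2:5, order = rep(1, 4)),
                   rep("other", 5), 5)
  expect_equal(nrow(audit_valence(ch4, bt)), 0L)

  ## neutral 4-coordinate nitrogen violates; N+ does not
  n4 <- atom_table(c("N", rep("C", 4)),
                   x = c(0, 1.47, -1.47, 0, 0),
                   y = c(0, 0, 0, 1.47, -1.47), z = 0)
  bt4 <- bond_table(data.frame(i = rep(1L, 4), j = 2:5, order = rep(1, 4)),
                    rep("other", 5), 5)
  f0 <- audit_valence(n4, bt4)
  expect_true(any(f0$kind == "valence_violation" & f0$severity == "fail"))
  fplus <- audit_valence(n4, bt4, formal_charges = c(1L, 0L, 0L, 0L, 0L))
  expect_false(any(fplus$kind == "valence_violation"))

  ## over-protonated guanidinium: +3 within one bond of the central carbon
  r <- 1.33; ang <- c(90, 210, 330) * pi / 180
  gd <- atom_table(c("C", "N", "N", "N"),
                   x = c(0, r * cos(ang)), y = c(0, r * sin(ang)), z = 0)
  btg <- bond_table(data.frame(i = rep(1L, 3), j = 2:4, order = rep(1, 3)),
                    rep("sp2", 4), 4)
  fg <- audit_valence(gd, btg, formal_charges = c(0L, 1L, 1L, 1L))
  lce <- fg[fg$kind == "local_charge_excess", ]
  expect_gte(nrow(lce), 1L)
  expect_true(any(lce$measured == 3))
})

test_that("geometry checks flag the canonical pathologies and pass ideals", {
  ## ideal planar amide fragment: C(=O)N with reference lengths/angles
  at <- atom_table(c("C", "O", "N", "C"),
                   x = c(0, 1.22 * cos(2 * pi / 3), 1.29 * cos(-2 * pi / 3), -1.54),
                   y = c(0, 1.22 * sin(2 * pi / 3), 1.29 * sin(-2 * pi / 3), 0),
                   z = 0)
  ## place the methyl along +x so all angles are 120 at the carbonyl C
  at$x[4] <- 1.54; at$y[4] <- 0
  bt <- bond_table(data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                              order = c(2, 2, 1)),
                   c("sp2", "other", "other", "other"), 4)
  f <- check_geometry(at, bt)
  expect_false(any(f$severity %in% c("warn", "fail")))

  ## nitro group with both N-O bonds 17% over the order-2 reference
  d <- 1.21 * 1.17
  nitro <- atom_table(c("C", "N", "O", "O"),
                      x = c(-1.47, 0, d * cos(pi / 3), d * cos(pi / 3)),
                      y = c(0, 0, d * sin(pi / 3), -d * sin(pi / 3)), z = 0)
  btn <- bond_table(data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                               order = c(1, 2, 2)),
                    c("sp3", "sp2", "other", "other"), 4)
  fn <- check_geometry(nitro, btn)
  bl <- fn[fn$kind == "bond_length_deviation" & fn$severity == "warn", ]
  expect_equal(nrow(bl), 2L)

  ## ether angle opened by 20 degrees beyond tetrahedral
  ang <- (109.47 + 20) * pi / 180
  eth <- atom_table(c("C", "O", "C"),
                    x = c(1.43, 0, 1.43 * cos(ang)),
                    y = c(0, 0, 1.43 * sin(ang)), z = 0)
  bte <- bond_table(data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)),
                    c("sp3", "sp3", "sp3"), 3)
  fe <- check_geometry(eth, bte)
  expect_true(any(fe$kind == "angle_deviation"))

  ## sp2 centre pyramidalized 0.5 A out of its substituent plane
  r <- 1.33; angs <- c(90, 210, 330) * pi / 180
  pyr <- atom_table(c("C", "N", "N", "N"),
                    x = c(0, r * cos(angs)), y = c(0, r * sin(angs)),
                    z = c(0.5, 0, 0, 0))
  btp <- bond_table(data.frame(i = rep(1L, 3), j = 2:4, order = rep(1, 3)),
                    c("sp2", "sp2", "sp2", "sp2"), 4)
  fp <- check_geometry(pyr, btp)
  pd <- fp[fp$kind == "planarity_deviation", ]
  expect_equal(nrow(pd), 1L)
  expect_equal(pd$measured, 0.5, tolerance = 1e-10)
})

test_that("connectivity comparison reports exactly the edit script", {
  mk <- function(df) bond_table(df, rep("sp3", 10), 10)
  b0 <- data.frame(i = c(1, 2, 3, 4), j = c(2, 3, 4, 5),
                   order = c(1, 1, 2, 1))
  expect_equal(nrow(compare_connectivity(mk(b0), mk(b0))), 0L)

  broken <- mk(b0[-2, ])
  f <- compare_connectivity(mk(b0), broken)
  expect_equal(nrow(f), 1L)
  expect_equal(f$atom_indices[[1]], c(2L, 3L))

  set.seed(11)
  for (rep in 1:10) {
    k_break <- sample(0:2, 1); k_make <- sample(0:2, 1); k_order <- sample(0:2, 1)
    keep <- setdiff(seq_len(nrow(b0)), sample(seq_len(nrow(b0)), k_break))
    after <- b0[keep, , drop = FALSE]
    ord_idx <- utils::head(seq_len(nrow(after)), k_order)
    after$order[ord_idx] <- after$order[ord_idx] + 1
    new_pairs <- data.frame(i = c(5, 7), j = c(7, 9), order = 1)[seq_len(k_make), ,
                                                                 drop = FALSE]
    after <- rbind(after, new_pairs)
    f2 <- compare_connectivity(mk(b0), mk(after))
    expect_equal(nrow(f2), k_break + k_make + min(k_order, nrow(after) - k_make))
  }
  expect_error(compare_connectivity(mk(b0),
                                    bond_table(b0, rep("sp3", 9), 9)),
               "atom counts", class = "ligdyn_validation_error")
})

test_that("property-outlier screening recovers planted points only", {
  set.seed(12)
  x <- rnorm(50); y <- 2 + 0.5 * x
  expect_false(any(flag_property_outliers(x, y, rep("CL", 50))$severity == "warn"))

  res_sd <- 0.05
  y2 <- y + rnorm(50, 0, res_sd)
  y2[17] <- y2[17] + 10 * res_sd * 1.8
  f <- flag_property_outliers(x, y2, rep("BR", 50))
  hits <- unlist(f$atom_indices[f$severity == "warn"])
  expect_equal(hits, 17L)

  f3 <- flag_property_outliers(rnorm(3), rnorm(3), rep("I", 3))
  expect_equal(f3$severity, "info")

  ## degenerate constant x falls back to a univariate screen
  y4 <- rnorm(20, 0, 0.1); y4[5] <- 5
  f4 <- flag_property_outliers(rep(1, 20), y4, rep("F", 20))
  expect_true(5L %in% unlist(f4$atom_indices[f4$severity == "warn"]))
})

test_that("electronic flags warn on vanishing gaps and fail on odd counts", {
  ok <- qm_record("A", molecular = list(homo_lumo_gap = 3.2,
                                        electron_count = 42))
  expect_false(any(screen_electronic_flags(ok)$severity %in% c("warn", "fail")))
  tiny <- qm_record("B", molecular = list(homo_lumo_gap = 0.01,
                                          electron_count = 42))
  expect_true(any(screen_electronic_flags(tiny)$severity == "warn"))
  odd <- qm_record("C", molecular = list(homo_lumo_gap = 3.0,
                                         electron_count = 41,
                                         closed_shell = TRUE))
  expect_true(any(screen_electronic_flags(odd)$severity == "fail"))
  missing <- qm_record("D", molecular = list())
  expect_true(all(screen_electronic_flags(missing)$severity == "info"))
})

test_that("checks are permutation-covariant", {
  set.seed(13)
  n <- 30
  at <- atom_table(sample(c("C", "N", "O"), n, TRUE),
                   x = runif(n, 0, 8), y = runif(n, 0, 8), z = runif(n, 0, 8))
  perm <- sample(n)
  atp <- at[perm, ]; rownames(atp) <- NULL
  f1 <- detect_clashes(at)
  f2 <- detect_clashes(atp)
  map <- match(seq_len(n), perm)     # old index -> new index
  remapped <- lapply(f1$atom_indices, function(ix) sort(map[ix]))
  expect_setequal(vapply(remapped, paste, "", collapse = ","),
                  vapply(lapply(f2$atom_indices, sort), paste, "",
                         collapse = ","))
})

test_that("an idealized generated ligand passes QC with verdict clean", {
  cx <- generate_complex(19, 10, 8)
  rep <- qc_report(cx)
  expect_equal(rep$verdict, "clean")
})
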