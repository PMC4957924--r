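test_that("superposition onto itself is the identity with zero RMSD", {
  ref <- toy_reference()
  sup <- superpose_pose(generate_toy_pose(), ref)
  expect_equal(sup$rmsd, 0, tolerance = 1e-9)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sup$translation, rep(0, 3), tolerance = 1e-9)
})

test_that("a known rigid motion is inverted by superposition", {
  ref <- toy_reference()
  moved <- transform_pose(generate_toy_pose(), rot_z(90), c(5, -3, 12))
  sup <- superpose_pose(moved, ref)
  expect_equal(sup$rmsd, 0, tolerance = 1e-8)
  expect_equal(sup$rotation %*% rot_z(90), diag(3), tolerance = 1e-8)
  expect_equal(as.matrix(sup$pose$atoms[, c("x", "y", "z")]),
               as.matrix(generate_toy_pose()$atoms[, c("x", "y", "z")]),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Kabsch fit agrees with the quaternion oracle on noisy copies", {
  set.seed(31)
  for (i in 1:10) {
    n <- sample(5:20, 1)
    Q <- matrix(rnorm(3 * n, sd = 5), n, 3)
    R0 <- rot_z(runif(1, 0, 360))
    P <- sweep(Q %*% R0, 2, runif(3, -10, 10), `+`) +
      matrix(rnorm(3 * n, sd = 0.1), n, 3)
    fit <- ptpscreen:::kabsch(P, Q)
    oracle <- quaternion_superpose(P, Q)
    fitted <- sweep(P %*% t(fit$rotation), 2, fit$translation, `+`)
    rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
    expect_equal(rmsd, oracle$rmsd, tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition requires at least three shared CA atoms", {
  ref <- toy_reference()
  pose <- generate_toy_pose()
  keep <- !(pose$atoms$chain == "A" & pose$atoms$elety == "CA" &
              pose$atoms$resno > 48)
  pose$atoms <- pose$atoms[keep, ]
  expect_error(superpose_pose(pose, ref), "at least 3")
})

test_that("pocket insertion uses an inclusive distance cutoff", {
  ref <- toy_reference()
  pose <- generate_toy_pose()           # P is 1 A from the pocket centroid
  res <- check_py_in_site(pose, ref, cutoff = 7)
  expect_true(res$ok)
  expect_equal(res$distance, 1, tolerance = 1e-9)
  expect_true(check_py_in_site(pose, ref, cutoff = res$distance)$ok)
  expect_false(check_py_in_site(pose, ref,
                                cutoff = res$distance - 1e-6)$ok)
  far <- generate_toy_pose(py_in_site = FALSE)
  expect_false(check_py_in_site(far, ref, cutoff = 7)$ok)
})

test_that("orientation is strict at 90 degrees and flags reversed peptides", {
  ref <- toy_reference()
  same <- check_orientation(generate_toy_pose(), ref)
  expect_true(same$ok)
  expect_equal(same$angle, 0, tolerance = 1e-9)

  rev <- check_orientation(generate_toy_pose(orientation = FALSE), ref)
  expect_false(rev$ok)
  expect_equal(rev$angle, 180, tolerance = 1e-9)

  # rotate the peptide CA trace into the y direction: exactly 90 degrees
  perp <- generate_toy_pose()
  sel <- perp$atoms$chain == "B" & perp$atoms$elety == "CA"
  perp$atoms$y[sel] <- 5 + perp$atoms$x[sel]
  perp$atoms$x[sel] <- 0
  res <- check_orientation(perp, ref)
  expect_equal(res$angle, 90, tolerance = 1e-9)
  expect_false(res$ok)
})

test_that("hydrogen bonds use inclusive heavy-atom distances", {
  ref <- toy_reference()
  hb_all <- detect_hbonds(generate_toy_pose(), ref)
  expect_equal(hb_all$present, c(TRUE, TRUE, TRUE))
  expect_equal(hb_all$distance, rep(2.9, 3), tolerance = 1e-9)

  hb_none <- detect_hbonds(
    generate_toy_pose(hb1 = FALSE, hb2 = FALSE, hb3 = FALSE), ref)
  expect_equal(hb_none$present, c(FALSE, FALSE, FALSE))

  # exactly at the cutoff counts as bonded
  pose <- generate_toy_pose(hb1 = FALSE)
  sel <- pose$atoms$chain == "B" & pose$atoms$resno == 3 &
    pose$atoms$elety == "N"
  od1 <- pose$atoms[pose$atoms$elety == "OD1", c("x", "y", "z")]
  pose$atoms[sel, c("x", "y", "z")] <- od1 + c(0, 0, 3.5)
  expect_true(detect_hbonds(pose, ref, dmax = 3.5)$present[1])

  # a missing acceptor reports the bond absent with a reason, not an error
  broken <- generate_toy_pose()
  broken$atoms <- broken$atoms[!broken$atoms$elety %in% c("OD1", "OD2"), ]
  hb <- detect_hbonds(broken, ref)
  expect_equal(hb$present[1:2], c(FALSE, FALSE))
  expect_match(hb$reason[1], "missing atom")
  expect_true(hb$present[3])
})

test_that("acceptance needs pocket + orientation + two of three bonds", {
  ref <- toy_reference()
  two <- evaluate_pose(generate_toy_pose(hb2 = FALSE), ref)
  expect_true(two$accepted)             # bonds 1 and 3 suffice
  one <- evaluate_pose(generate_toy_pose(hb1 = FALSE, hb3 = FALSE), ref)
  expect_false(one$accepted)            # only bond 2
  no_site <- evaluate_pose(generate_toy_pose(py_in_site = FALSE), ref)
  expect_false(no_site$accepted)
  # the reference evaluated against itself satisfies everything
  self <- evaluate_pose(generate_toy_pose(), ref)
  expect_true(self$py_in_site && self$orientation_ok &&
                self$n_hbonds == 3 && self$accepted)
})

test_that("evaluation is invariant under global rigid motion of the pose", {
  ref <- toy_reference()
  pose <- generate_toy_pose(hb2 = FALSE)
  base <- evaluate_pose(pose, ref)
  moved <- transform_pose(pose, rot_z(137), c(-20, 4, 9))
  ev <- evaluate_pose(moved, ref)
  expect_equal(ev$py_distance, base$py_distance, tolerance = 1e-6)
  expect_equal(ev$orientation_angle, base$orientation_angle,
               tolerance = 1e-6)
  expect_equal(ev$hbonds$distance, base$hbonds$distance, tolerance = 1e-6)
  expect_equal(ev$accepted, base$accepted)
})

test_that("pose PDB files round-trip and directories are batch-evaluated", {
  dir <- withr::local_tempdir()
  ref <- toy_reference()
  poses <- list(good = generate_toy_pose(),
                flip = generate_toy_pose(orientation = FALSE),
                weak = generate_toy_pose(hb1 = FALSE, hb2 = FALSE))
  for (nm in names(poses)) {
    write_pose_pdb(poses[[nm]], file.path(dir, paste0(nm, ".pdb")))
  }
  back <- read_pose_pdb(file.path(dir, "good.pdb"))
  expect_equal(back$py_resno, 3L)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(poses$good$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  ev_file <- evaluate_pose(back, ref)
  expect_true(ev_file$accepted)

  writeLines("not a pdb", file.path(dir, "junk.pdb"))
  expect_warning(report <- evaluate_pose_files(dir, ref), "skipping")
  expect_equal(nrow(report), 3L)
  expect_equal(report$pose[report$accepted], "good.pdb")
  expect_true(!is.unsorted(rev(report$accepted)))  # accepted sorted first
})
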