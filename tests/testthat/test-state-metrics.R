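test_that("superposition recovers rigid transforms and known RMSDs", {
  set.seed(42)
  pts <- matrix(stats::rnorm(30, sd = 5), 10L, 3L)

  expect_equal(superpose_rmsd(pts, pts)$rmsd, 0, tolerance = 1e-10)
  expect_equal(superpose_rmsd(sweep(pts, 2L, c(5, 0, 0), "+"), pts)$rmsd, 0,
               tolerance = 1e-10)

  for (k in 1:5) {
    r <- random_rotation()
    shift <- stats::rnorm(3, sd = 8)
    moved <- sweep(pts %*% r, 2L, shift, "+")
    fit <- superpose_rmsd(moved, pts)
    expect_lt(fit$rmsd, 1e-8)
    # the recovered rotation must invert the applied one
    expect_lt(max(abs(fit$rotation %*% r - diag(3))), 1e-6)
  }

  expect_error(superpose_rmsd(pts[1:4, ], pts), "differ in size")
  line <- cbind(1:5, 0, 0)
  expect_error(superpose_rmsd(line, line + 1), "degenerate")
})

test_that("superposition never increases RMSD", {
  set.seed(7)
  for (k in 1:20) {
    a <- matrix(stats::rnorm(24, sd = 3), 8L, 3L)
    b <- matrix(stats::rnorm(24, sd = 3), 8L, 3L)
    expect_lte(superpose_rmsd(a, b)$rmsd,
               sqrt(mean(rowSums((a - b)^2))) + 1e-12)
  }
})

test_that("rmsd_series matches hand computations and shapes", {
  s <- make_peptide(4L)
  static <- new_trajectory(s, replicate(3L, s$xyz, simplify = FALSE))
  rs <- rmsd_series(static)
  expect_equal(nrow(rs), 3L)
  expect_equal(rs$rmsd, rep(0, 3L), tolerance = 1e-10)

  # one atom displaced 3 A in frame 2, single-atom selection, no fitting
  f2 <- s$xyz; f2[2L, 1L] <- f2[2L, 1L] + 3
  traj <- new_trajectory(s, list(s$xyz, f2))
  rs1 <- rmsd_series(traj, selection = structure(2L, class = "hs_selection"),
                     fit = FALSE)
  expect_equal(rs1$rmsd, c(0, 3))
})

test_that("state classification follows the strict-threshold window rule", {
  times <- seq(0, 100, by = 2)
  expect_equal(classify_state(rep(1.0, 51), times)$label, "closed")
  expect_equal(classify_state(rep(3.0, 51), times)$label, "open")
  expect_equal(classify_state(rep(2.5, 51), times)$label, "open")
  expect_error(classify_state(rep(1, 5), seq(0, 8, by = 2)), "shorter than")

  # lowering the threshold can only move labels closed -> open
  set.seed(11)
  for (k in 1:20) {
    series <- stats::runif(51, 0, 5)
    hi <- classify_state(series, times, threshold = 3.0)$label
    lo <- classify_state(series, times, threshold = 1.5)$label
    expect_false(hi == "open" && lo == "closed")
  }
})

test_that("torsion operator matches the arccos-of-normals oracle", {
  expect_equal(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0)),
               0, tolerance = 1e-10)
  expect_equal(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)),
               180, tolerance = 1e-10)
  set.seed(5)
  for (k in 1:100) {
    q <- lapply(1:4, function(i) stats::rnorm(3, sd = 2))
    got <- torsion_angle(q[[1]], q[[2]], q[[3]], q[[4]])
    want <- oracle_torsion(q[[1]], q[[2]], q[[3]], q[[4]])
    expect_equal(got, want, tolerance = 1e-6)
  }
  expect_error(torsion_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("pseudo-dihedrals respect residue-range preconditions", {
  s <- make_peptide(6L)
  prof <- pseudo_dihedral_profile(s)
  expect_equal(prof$residue_index, 2:4)  # first residue and last two undefined
  expect_equal(ca_pseudo_dihedral(s, 3L), prof$value[prof$residue_index == 3L])
  expect_error(ca_pseudo_dihedral(s, 1L), "undefined")
  expect_error(ca_pseudo_dihedral(s, 6L), "undefined")
})

test_that("structure-pair dihedral differences wrap and ignore rigid motion", {
  s <- make_peptide(6L)
  d0 <- delta_dihe_structures(s, s)
  expect_equal(d0$value, rep(0, nrow(d0)))

  # a 170 vs -170 degree torsion differs by 20, not 340
  a <- make_torsion_structure(170)
  b <- make_torsion_structure(-170)
  dd <- delta_dihe_structures(a, b)
  expect_equal(dd$value, 20, tolerance = 1e-8)

  set.seed(9)
  rot <- random_rotation()
  s_moved <- new_structure(s$atoms, sweep(s$xyz %*% rot, 2L, c(3, -8, 2), "+"))
  d_rot <- delta_dihe_structures(s, s_moved)
  expect_equal(d_rot$value, rep(0, nrow(d_rot)), tolerance = 1e-8)
})

test_that("RMSF is zero for static runs and exact for a pure oscillation", {
  s <- make_peptide(5L)
  static <- new_trajectory(s, replicate(4L, s$xyz, simplify = FALSE))
  expect_equal(rmsf_profile(static)$value, rep(0, 5L), tolerance = 1e-10)

  # residue 3 oscillates +/-1 A about its mean along x; no superposition
  frames <- lapply(1:4, function(f) {
    x <- s$xyz
    x[3L, 1L] <- x[3L, 1L] + c(1, -1)[(f %% 2L) + 1L]
    x
  })
  osc <- new_trajectory(s, frames)
  prof <- rmsf_profile(osc, fit = FALSE)
  expect_equal(prof$value[3L], 1.0, tolerance = 1e-12)
  expect_equal(prof$value[-3L], rep(0, 4L), tolerance = 1e-12)
})

test_that("RMSF is invariant to per-frame rigid-body motion when fitting", {
  set.seed(21)
  s <- make_peptide(6L)
  frames <- lapply(1:6, function(f) s$xyz + matrix(stats::rnorm(18, sd = 0.3), 6L, 3L))
  traj <- new_trajectory(s, frames)
  moved <- rigid_transform_trajectory(traj)
  expect_equal(rmsf_profile(moved)$value, rmsf_profile(traj)$value,
               tolerance = 1e-6)
})

test_that("ensemble differences combine states as means with angular wrapping", {
  p <- function(v) tibble::tibble(residue_index = 1L, value = v)

  same <- ensemble_delta(list(p(1.3)), list(p(1.3)), metric = "linear")
  expect_equal(same$value, 0)

  d <- ensemble_delta(list(p(2.0)), list(p(1.0), p(3.0)), metric = "linear")
  expect_equal(d$value, 0)

  ang <- ensemble_delta(list(p(179)), list(p(-179)), metric = "angular")
  expect_equal(ang$value, 2, tolerance = 1e-10)

  expect_error(ensemble_delta(list(), list(p(1))), "at least one")
})
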