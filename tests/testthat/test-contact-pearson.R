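test_that("pair minimum distances equal brute-force enumeration", {
  # two single-atom residues 4 A apart in every frame
  s <- make_ca_structure(rbind(c(0, 0, 0), c(4, 0, 0)), residue_index = c(1L, 5L))
  traj <- new_trajectory(s, replicate(3L, s$xyz, simplify = FALSE))
  expect_equal(pair_min_distance_series(traj, 1L, 5L, "calpha"), rep(4, 3L))
  expect_error(pair_min_distance_series(traj, 1L, 1L), "must differ")

  # two-atom residues: minimum over the four atom pairs, vs enumeration
  set.seed(31)
  s2 <- make_peptide(2L, with_cb = TRUE)
  frames <- lapply(1:4, function(f) s2$xyz + matrix(stats::rnorm(12), 4L, 3L))
  traj2 <- new_trajectory(s2, frames)
  got <- pair_min_distance_series(traj2, 1L, 2L, "heavy")
  want <- vapply(frames, function(x) {
    idx1 <- which(s2$atoms$residue_index == 1L)
    idx2 <- which(s2$atoms$residue_index == 2L)
    dists <- c()
    for (a in idx1) for (b in idx2) {
      dists <- c(dists, sqrt(sum((x[a, ] - x[b, ])^2)))
    }
    min(dists)
  }, numeric(1L))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("hysteresis contacts trace the two-threshold state machine", {
  expect_equal(as.logical(hysteresis_contact_series(c(4, 6, 7.9, 8.1, 6), 5, 8)),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(as.logical(hysteresis_contact_series(c(6, 4.9, 7, 9, 4.5), 5, 8)),
               c(FALSE, TRUE, TRUE, FALSE, TRUE))
  never <- hysteresis_contact_series(c(5.0, 6, 7, 9), 5, 8)
  expect_false(any(never))
  expect_false(attr(never, "ever_in_contact"))
  expect_error(hysteresis_contact_series(1:3, 8, 5), "r_start < r_end")
})

test_that("hysteresis contacts agree with the recurrence oracle on random series", {
  set.seed(101)
  for (k in 1:1000) {
    d <- stats::runif(sample(5:40, 1L), 3, 10)
    got <- as.logical(hysteresis_contact_series(d, 5, 8))
    expect_identical(got, oracle_hysteresis(d, 5, 8))
  }
})

test_that("time correlation follows the sign convention and the textbook formula", {
  t5 <- 0:4
  expect_equal(pearson_vs_time(1:5, t5), 1)
  expect_equal(pearson_vs_time(5:1, t5), -1)
  expect_equal(pearson_vs_time(rep(2, 5), t5), 0)
  expect_error(pearson_vs_time(1, 0), "at least 2")

  set.seed(17)
  for (k in 1:1000) {
    n <- sample(3:30, 1L)
    d <- stats::runif(n, 0, 12)
    times <- sort(stats::runif(n, 0, 100))
    got <- pearson_vs_time(d, times, r_end = 8)
    expect_equal(got, oracle_pearson(pmin(d, 8), times), tolerance = 1e-12)
  }
})

test_that("the indicator variant keeps the early-contact-positive convention", {
  # contact early, lost late -> positive pixel in both variants
  d <- c(4, 4.5, 6, 9, 10, 11)
  times <- 0:5
  expect_gt(pearson_vs_time(d, times, method = "indicator"), 0)
  expect_gt(pearson_vs_time(d, times, method = "distance"), 0)
  # forms late -> negative
  expect_lt(pearson_vs_time(rev(d), times, method = "indicator"), 0)
})

test_that("the contact-change matrix is symmetric, sparse and sign-correct", {
  fx <- quiet_hinge(noise = 0)
  m <- build_pearson_matrix(fx$trajectory, ca_config())
  expect_identical(unclass(m), t(unclass(m)))
  expect_true(all(abs(m) <= 1 + 1e-12))
  expect_true(all(diag(m) == 0))

  # static trajectory: zero variance everywhere -> all-zero matrix
  s <- fx$trajectory$topology
  static <- new_trajectory(s, replicate(3L, s$xyz, simplify = FALSE))
  expect_true(all(build_pearson_matrix(static, ca_config()) == 0))

  # designed pair moving monotonically apart from contact: +1 pixel, mirrored
  truth <- dplyr::filter(fx$truth$pairs, perfect, sign > 0)
  for (k in seq_len(nrow(truth))) {
    i <- as.character(truth$i[k]); j <- as.character(truth$j[k])
    expect_equal(m[i, j], 1, tolerance = 1e-12)
    expect_identical(m[i, j], m[j, i])
  }
})

test_that("the matrix is invariant to rigid-body motion of every frame", {
  set.seed(77)
  fx <- quiet_hinge(seed = 2L, noise = 0.1)
  m0 <- build_pearson_matrix(fx$trajectory, ca_config())
  m1 <- build_pearson_matrix(rigid_transform_trajectory(fx$trajectory),
                             ca_config())
  expect_equal(unclass(m0), unclass(m1), tolerance = 1e-8)
})

test_that("matrix averaging is pixel-wise with shape checks", {
  base <- matrix(0, 4, 4)
  m1 <- base; m1[1, 4] <- m1[4, 1] <- 1
  m2 <- base; m2[1, 4] <- m2[4, 1] <- -1
  m3 <- base; m3[1, 4] <- m3[4, 1] <- 0.9; m3[2, 4] <- m3[4, 2] <- 0.2

  expect_equal(unclass(mean_pearson_matrix(list(m1))), m1,
               ignore_attr = TRUE)
  expect_equal(mean_pearson_matrix(list(m1, m2))[1, 4], 0)
  expect_equal(mean_pearson_matrix(list(m1, m2, m3))[1, 4], 0.3)
  expect_error(mean_pearson_matrix(list()), "empty")
  expect_error(mean_pearson_matrix(list(m1, matrix(0, 3, 3))), "mismatch")
})

test_that("crystal-pair matrices take values in {-1, 0, +1}", {
  xyz_a <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(12, 0, 0))
  a <- make_ca_structure(xyz_a)
  expect_true(all(two_structure_matrix(a, a, ca_config()) == 0))

  # residues 1 and 4: 4 A apart in A (contact), 12 A apart in B
  xyz_b <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(0, 12, 0))
  xyz_a2 <- rbind(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0), c(0, 4, 0))
  m <- two_structure_matrix(make_ca_structure(xyz_a2),
                            make_ca_structure(xyz_b), ca_config())
  expect_equal(m["1", "4"], 1)
  expect_true(all(m %in% c(-1, 0, 1)))
})

test_that("matrix TSV round trip preserves values in both formats", {
  fx <- quiet_hinge(noise = 0)
  m <- build_pearson_matrix(fx$trajectory, ca_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pearson_matrix(m, path, format = "long")
  back <- read_pearson_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-9)
  expect_equal(attr(back, "residues"), attr(m, "residues"))
  dense <- withr::local_tempfile(fileext = ".tsv")
  write_pearson_matrix(m, dense, format = "dense")
  expect_equal(nrow(utils::read.delim(dense, skip = 1L)), nrow(m))
})
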