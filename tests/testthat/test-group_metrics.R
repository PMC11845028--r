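test_that("adjacent-distance variance is a population variance over the chain", {
  # equidistant chain -> 0
  chain <- cbind(seq(0, 80, by = 20), 0)
  expect_equal(adjacent_distance_variance(chain), 0)
  # distances 1, 1, 1, 5 -> population variance 3.0
  kp <- cbind(cumsum(c(0, 1, 1, 1, 5)), 0)
  expect_equal(adjacent_distance_variance(kp), 3.0)
  # missing chain point -> NA; too-short chain -> error
  kp[2, ] <- NA
  expect_true(is.na(adjacent_distance_variance(kp)))
  expect_error(adjacent_distance_variance(cbind(0:1, 0)), "at least 3")
})

test_that("IQR outlier fence uses type-7 quantiles and the upper fence only", {
  r <- iqr_outlier_count(matrix(1:100, ncol = 1), 1:100)
  q <- stats::quantile(1:100, c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(r$threshold, q[2] + 1.5 * (q[2] - q[1]))
  expect_equal(r$threshold, 149.5)
  expect_equal(unname(r$counts), 0)
  # constant pooled values: fence equals the constant, larger values count
  r2 <- iqr_outlier_count(cbind(c(5, 5, 9), c(5, 5, 5)), rep(5, 50))
  expect_equal(r2$threshold, 5)
  expect_equal(unname(r2$counts), c(1, 0))
  expect_error(iqr_outlier_count(1:3, NA_real_), "no observed values")
})

test_that("heading angles follow the atan2 convention and degrade to NA", {
  expect_equal(heading_angle(c(1, 0), c(0, 0)), 0)
  expect_equal(heading_angle(c(0, 1), c(0, 0)), pi / 2)
  expect_equal(heading_angle(c(-1, 0), c(0, 0)), pi)
  expect_true(is.na(heading_angle(c(NA, NA), c(0, 0))))
  expect_true(is.na(heading_angle(c(3, 3), c(3, 3))))
})

test_that("group cosine similarity is the mean over unordered pairs", {
  expect_equal(group_cos_sim(rep(1.2, 7)), 1)
  expect_equal(group_cos_sim(c(0, pi)), -1)
  expect_equal(group_cos_sim(c(0, pi / 2)), 0)
  expect_true(is.na(group_cos_sim(c(0.4, NA))))
  # one reversed individual in an n-school: closed form
  n <- 10
  h <- c(rep(0, n - 1), pi)
  expected <- (choose(n - 1, 2) - (n - 1)) / choose(n, 2)
  expect_equal(group_cos_sim(h), expected)
  # bounded on random inputs
  set.seed(55)
  for (k in 1:50) {
    v <- stats::runif(sample(2:10, 1), -pi, pi)
    cs <- group_cos_sim(v)
    expect_true(cs >= -1 && cs <= 1)
  }
})

test_that("heading flips wrap angular differences into [0, 180] degrees", {
  expect_equal(heading_flip_count(rep(0.3, 10)), 0)
  expect_equal(heading_flip_count(c(0, 179 * pi / 180)), 1)
  expect_equal(heading_flip_count(c(350, 10) * pi / 180), 0)  # wrapped 20 deg
  expect_equal(heading_flip_count(c(0, NA, pi)), 0)           # NA pairs skipped
  expect_equal(heading_flip_count(c(0, pi / 2 + 0.01, 0)), 2)
  # wrapped difference never exceeds 180 degrees
  set.seed(56)
  a <- stats::runif(200, -10, 10)
  d <- abs(atan2(sin(diff(a)), cos(diff(a)))) * 180 / pi
  expect_true(all(d <= 180))
})

test_that("standardized distance matrices are z-scored and geometry-invariant", {
  set.seed(57)
  kp <- matrix(stats::runif(12, 0, 100), ncol = 2)
  D <- standardized_distance_matrix(kp)
  up <- D[upper.tri(D)]
  expect_equal(mean(up), 0, tolerance = 1e-12)
  expect_equal(stats::sd(up), 1, tolerance = 1e-12)
  expect_true(isSymmetric(unname(D)))
  # rigid motion: rotation + translation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  kp_rot <- t(R %*% t(kp)) + matrix(rep(c(40, -13), each = 6), ncol = 2)
  expect_equal(standardized_distance_matrix(kp_rot), D, tolerance = 1e-9)
  # uniform scaling cancels under standardization
  expect_equal(standardized_distance_matrix(kp * 3.7), D, tolerance = 1e-9)
  # degenerate pose: all pairwise distances equal (equilateral triangle)
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_error(standardized_distance_matrix(tri), "degenerate")
  expect_error(standardized_distance_matrix(kp[1:2, ]), "at least 3")
})

test_that("pose RMSD is a pseudometric and handles constant offsets", {
  set.seed(58)
  A <- standardized_distance_matrix(matrix(stats::runif(10, 0, 50), ncol = 2))
  expect_equal(pose_rmsd(A, A), 0)
  B <- A + 1
  expect_equal(pose_rmsd(A, B), 1)
  # symmetry and triangle inequality on random triples
  for (k in 1:20) {
    m <- lapply(1:3, function(i)
      standardized_distance_matrix(matrix(stats::runif(10, 0, 50), ncol = 2)))
    expect_equal(pose_rmsd(m[[1]], m[[2]]), pose_rmsd(m[[2]], m[[1]]))
    expect_lte(pose_rmsd(m[[1]], m[[3]]),
               pose_rmsd(m[[1]], m[[2]]) + pose_rmsd(m[[2]], m[[3]]) + 1e-12)
  }
})

test_that("identical poses give zero frame-mean RMSD across all pairs", {
  base <- matrix(stats::runif(14, 0, 100), ncol = 2)
  co <- array(NA_real_, dim = c(1, 7, 7, 2))
  for (i in 1:7) co[1, i, , ] <- base + 30 * i   # translated copies
  tr <- pose_track(co, paste0("d", 1:7), paste0("kp", 1:7))
  r <- frame_mean_rmsd(tr, 1)
  expect_equal(nrow(r$pairs), choose(7, 2))
  expect_equal(r$mean_rmsd, 0, tolerance = 1e-9)
})

test_that("overlap frequency is a strict-threshold fraction over co-observed frames", {
  co <- array(NA_real_, dim = c(10, 2, 1, 2))
  co[, 1, 1, 1] <- 0; co[, 1, 1, 2] <- 0
  co[, 2, 1, 1] <- 50; co[, 2, 1, 2] <- 0
  tr <- pose_track(co, c("a", "b"), "kp1")
  expect_equal(overlap_frequency(tr, c("a", "b"), "kp1"), 0)
  tr$coords[, 2, 1, 1] <- 0   # identical everywhere
  expect_equal(overlap_frequency(tr, c(1, 2), "kp1"), 1)
  # boundary: exactly 10 px apart is NOT an overlap (strict less-than)
  tr$coords[, 2, 1, 1] <- 10
  expect_equal(overlap_frequency(tr, c(1, 2), "kp1"), 0)
  # missing frames drop out of numerator and denominator
  tr$coords[1:5, 2, 1, ] <- NA
  tr$coords[6:10, 2, 1, 1] <- 3
  expect_equal(overlap_frequency(tr, c(1, 2), "kp1"), 1)
  expect_error(overlap_frequency(tr, c(1, 2), "nose"), "config error")
})

test_that("stray keypoints collapsed onto a remaining animal overlap nearly always", {
  gt <- simulate_ground_truth(simulation_config(
    n_animals = 3, n_keypoints = 6, spacing = 25, arena = c(460, 460),
    n_frames = 40, seed = 71))
  # animal 3 "leaves the frame": its slot tracks animal 1's keypoints
  stray <- gt
  stray$coords[, 3, , ] <- gt$coords[, 1, , ]
  f <- mean(vapply(paste0("kp", 1:6), function(b)
    overlap_frequency(stray, c(1, 3), b), numeric(1)))
  expect_gt(f, 0.9)
})
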