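test_that("Procrustes distance is a similarity-invariant metric", {
  tri <- padded_triangle(9)
  expect_equal(procrustes_distance(tri, tri), 0)
  moved <- similarity_transform(tri, angle_deg = 37, scale = 2.4,
                                shift = c(12, -3))
  expect_lt(procrustes_distance(tri, moved), 1e-9)
  other <- padded_triangle(9, jitter_seed = 2)
  d12 <- procrustes_distance(tri, other)
  expect_gt(d12, 0)
  expect_equal(procrustes_distance(other, tri), d12, tolerance = 1e-12)
})

test_that("full Procrustes distance matches the rotation grid-search oracle", {
  for (s in 1:4) {
    x <- padded_triangle(9, jitter_seed = s)
    y <- padded_triangle(9, jitter_seed = s + 10)
    expect_equal(procrustes_distance(x, y), proc_dist_grid(x, y),
                 tolerance = 1e-8)
  }
})

test_that("GPA aligns to zero centroid, unit size, and a mean consensus", {
  d <- generate_dataset(study_design_model(seed = 51))
  g <- gpa(d)
  n <- dim(g$aligned)[1]
  for (i in c(1, 50, 149)) {
    expect_lt(max(abs(colMeans(g$aligned[i, , ]))), 1e-9)
    expect_equal(sum(g$aligned[i, , ]^2), 1, tolerance = 1e-9)
  }
  cons <- apply(g$aligned, c(2, 3), mean)
  expect_equal(unname(cons / sqrt(sum(cons^2))), g$consensus,
               tolerance = 1e-8)
  expect_equal(unname(g$centroid_sizes[1]),
               sqrt(sum(scale(d$coords[1, , ], scale = FALSE)^2)))
})

test_that("GPA distances are invariant to arbitrary similarity pre-transforms", {
  d <- generate_dataset(shape_model(group_sizes = c(6, 6), seed = 52))
  g1 <- gpa(d)
  set.seed(53)
  tr <- array(NA_real_, dim(d$coords))
  for (i in 1:12) {
    tr[i, , ] <- similarity_transform(d$coords[i, , ],
                                      angle_deg = runif(1, 0, 360),
                                      scale = runif(1, 0.5, 3),
                                      shift = rnorm(2, sd = 50))
  }
  g2 <- gpa(landmark_dataset(tr, d$ids, d$groups))
  expect_equal(procrustes_dist_matrix(g2), procrustes_dist_matrix(g1),
               tolerance = 1e-9)
})

test_that("the consensus minimizes summed squared distance to aligned shapes", {
  d <- generate_dataset(shape_model(group_sizes = c(5, 5), seed = 54))
  g <- gpa(d)
  n <- dim(g$aligned)[1]
  obj <- function(cons) {
    cons <- cons / sqrt(sum(cons^2))
    tot <- 0
    for (i in seq_len(n)) {
      tot <- tot + procrustes_distance(g$aligned[i, , ], cons,
                                       type = "partial")^2
    }
    tot
  }
  base <- obj(g$consensus)
  set.seed(55)
  for (r in 1:5) {
    pert <- g$consensus + matrix(rnorm(18, sd = 0.01), 9, 2)
    expect_gte(obj(pert), base - 1e-10)
  }
})

test_that("degenerate configurations are rejected by specimen name", {
  coords <- array(0, c(2, 9, 2))
  coords[1, , ] <- padded_triangle(9)
  coords[2, , ] <- 5  # all landmarks coincident
  d <- landmark_dataset(coords, c("ok", "flat"), c("a", "b"))
  expect_error(gpa(d), "flat")
})

test_that("Procrustes ANOVA: degenerate data is reported, signal is detected", {
  m0 <- shape_model(noise_sd = 0, size_range = c(400, 400 + 1e-9),
                    group_sizes = c(4, 4), seed = 56)
  g0 <- gpa(generate_dataset(m0))
  a0 <- suppressWarnings(procrustes_anova(g0, n_perm = 49, seed = 1))
  expect_true(a0$shape$degenerate)
  # one landmark offset by 5 within-landmark SDs -> decisive rejection
  m1 <- two_group_model(n = 20, d = 5 * 0.5 / 400, noise = 0.5, seed = 57)
  g1 <- gpa(generate_dataset(m1))
  a1 <- procrustes_anova(g1, n_perm = 999, seed = 2)
  expect_lte(a1$shape$p_perm, 0.005)
  expect_equal(a1$shape$dfB, (2 - 1) * 14)
  expect_equal(a1$shape$dfW, (40 - 2) * 14)
})

test_that("permutation p-values are reproducible bit-for-bit under a seed", {
  m <- two_group_model(n = 8, d = 0.005, noise = 0.5, seed = 58)
  g <- gpa(generate_dataset(m))
  a1 <- procrustes_anova(g, n_perm = 199, seed = 7)
  a2 <- procrustes_anova(g, n_perm = 199, seed = 7)
  expect_identical(a1$shape$p_perm, a2$shape$p_perm)
  t1 <- group_mean_tests(g, n_perm = 99, seed = 7)
  t2 <- group_mean_tests(g, n_perm = 99, seed = 7)
  expect_identical(t1$p_perm, t2$p_perm)
})

test_that("shape PCA obeys the 2k-4 rank bound and sums to 100%", {
  d <- generate_dataset(study_design_model(seed = 59))
  sp <- shape_pca(gpa(d))
  expect_equal(sum(sp$percent_variance), 100, tolerance = 1e-8)
  # GPA removes 4 similarity dof to first order; the unit-size constraint is
  # a sphere, so the 4 removed directions keep second-order thickness only
  expect_lt(max(sp$eigenvalues[15:18]), 1e-4 * sp$eigenvalues[1])
  expect_gt(sp$cumulative_percent[14], 99.99)
  expect_gt(sp$eigenvalues[14], 1e-4 * sp$eigenvalues[1])
  ell <- group_ellipse(sp, "Son")
  expect_equal(dim(ell), c(100, 2))
})

test_that("pairwise mean-shape tests: null split behaves, offsets recover", {
  # a single population split into two arbitrary labels: distance ~ 0
  m0 <- shape_model(group_sizes = c(30, 30), noise_sd = 0.01,
                    size_range = c(300, 500), seed = 60)
  g0 <- gpa(generate_dataset(m0))
  t0 <- group_mean_tests(g0, n_perm = 199, seed = 1)
  expect_lte(t0$proc_dist, 0.005)
  expect_gt(t0$p_perm, 0.05)
  # known one-landmark offset: the difference vector points at that landmark
  del <- 0.02
  m1 <- two_group_model(n = 100, d = del, landmark = 3, noise = 0.2,
                        seed = 61)
  g1 <- gpa(generate_dataset(m1))
  t1 <- group_mean_tests(g1, n_perm = 199, seed = 1)
  expect_lte(t1$p_perm, 0.01)
  expect_gt(t1$loo_cv, 0.9)
  dv <- attr(t1, "shape_difference")[[1]]
  mags <- sqrt(rowSums(dv^2))
  expect_equal(unname(which.max(mags)), 3L)
  truth <- known_truth(m1)$procrustes_distances[1, 2]
  expect_equal(t1$proc_dist, truth, tolerance = 0.15)
})

test_that("groups below the CV minimum are skipped with a warning", {
  m <- shape_model(group_sizes = c(2, 10), noise_sd = 0.3, seed = 62)
  g <- gpa(generate_dataset(m))
  expect_warning(t1 <- group_mean_tests(g, n_perm = 49, seed = 1),
                 "fewer than 3")
  expect_null(t1)
})
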