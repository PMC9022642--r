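test_that("TPS interpolates landmarks exactly and is affine-exact", {
  ref <- knifefish_template()
  w0 <- tps_fit(ref, ref)
  expect_lt(max(abs(predict(w0, ref) - ref)), 1e-9)
  expect_lt(w0$total_bending_energy, 1e-12)
  A <- matrix(c(1.3, 0.4, -0.2, 0.8), 2, 2)
  aff <- ref %*% A + matrix(c(5, -2), nrow(ref), 2, byrow = TRUE)
  wa <- tps_fit(ref, aff)
  expect_lt(wa$total_bending_energy, 1e-10)
  expect_lt(max(abs(wa$weights)), 1e-8)
  expect_lt(max(abs(predict(wa, ref) - aff)), 1e-8)
  tgt <- ref
  tgt[5, ] <- tgt[5, ] + c(0.03, -0.05)
  wn <- tps_fit(ref, tgt)
  expect_lt(max(abs(predict(wn, ref) - tgt)), 1e-9)
  expect_gt(wn$total_bending_energy, 0)
})

test_that("bending energy matches the kernel quadratic form and affine invariance", {
  ref <- knifefish_template()
  set.seed(71)
  tgt <- ref + matrix(rnorm(18, sd = 0.03), 9, 2)
  w <- tps_fit(ref, tgt)
  # independent route: energy = sum over dims of w' K w with kernel weights
  d2 <- as.matrix(dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2))
  e2 <- sum(diag(t(w$weights) %*% K %*% w$weights))
  expect_equal(w$total_bending_energy, e2, tolerance = 1e-8)
  # bending-energy matrix annihilates affine functions of the reference
  expect_lt(max(abs(w$bending_energy_matrix %*% cbind(1, ref))), 1e-9)
  # energy is blind to any added affine image of the reference and to
  # rigid motions of the target
  tgt2 <- tgt + ref %*% matrix(c(0.9, 0.2, -0.1, 1.1), 2, 2) + 3
  w2 <- tps_fit(ref, tgt2)
  expect_equal(w2$total_bending_energy, w$total_bending_energy,
               tolerance = 1e-8)
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  w3 <- tps_fit(ref, tgt %*% R + 2)
  expect_equal(w3$total_bending_energy, w$total_bending_energy,
               tolerance = 1e-8)
  expect_error(tps_fit(cbind(1:9, 2 * (1:9)), tgt), "collinear")
})

test_that("deformation grid tracks the warp", {
  ref <- knifefish_template()
  w <- tps_fit(ref, ref * 2)
  gr <- deformation_grid(w, n = 5)
  expect_equal(nrow(gr), 25)
  expect_equal(gr$x, 2 * gr$ref_x, tolerance = 1e-8)
})

test_that("relative warps at alpha 0 equal shape PCA, and reconstruct shapes", {
  d <- generate_dataset(study_design_model(seed = 72))
  g <- gpa(d)
  sp <- shape_pca(g)
  rw <- relative_warps(g, alpha = 0)
  expect_equal(abs(unname(rw$scores[, 1:10])), abs(unname(sp$scores[, 1:10])),
               tolerance = 1e-9)
  expect_equal(sum(rw$percent_variance), 100, tolerance = 1e-8)
  # score/loading round trip reproduces the stored aligned specimens
  rec <- sweep(rw$scores %*% t(rw$rotation), 2, -rw$center)
  flat <- matrix(g$aligned, nrow = 149)
  expect_lt(max(abs(rec - flat)), 1e-6)
  expect_error(relative_warps(g, alpha = 2), "alpha")
})

test_that("bending-energy weighting changes emphasis but keeps proper variance", {
  d <- generate_dataset(shape_model(group_sizes = c(10, 10), noise_sd = 0.4,
                                    seed = 73))
  g <- gpa(d)
  rw1 <- relative_warps(g, alpha = 1)
  expect_equal(sum(rw1$percent_variance), 100, tolerance = 1e-8)
  rw0 <- relative_warps(g, alpha = 0)
  expect_gt(max(abs(abs(rw1$rotation[, 1]) - abs(rw0$rotation[, 1]))), 1e-4)
})

test_that("PSR reproduces every published extreme-pair ratio", {
  w <- warp_extreme_pairs()
  expect_equal(nrow(w), 7)
  expect_equal(round(psr(w$pc1_max, w$pc1_min), 2), w$psr_pc1,
               tolerance = 0.011)
  expect_equal(round(psr(w$pc2_max, w$pc2_min), 2), w$psr_pc2,
               tolerance = 0.011)
  expect_equal(psr(3, 3), 1)
  expect_warning(p0 <- psr(2, 0), "infinite")
  expect_identical(p0, Inf)
})

test_that("warp score summaries track group extremes", {
  d <- generate_dataset(study_design_model(seed = 74))
  g <- gpa(d)
  rw <- relative_warps(g)
  ws <- warp_score_summary(rw, 1)
  expect_equal(ws$group, levels(droplevels(rw$groups)))
  expect_true(all(ws$min <= ws$mean & ws$mean <= ws$max))
  expect_true(all(ws$psr > 0))
  expect_equal(ws$psr, ws$max_magnitude / ws$min_magnitude)
})

test_that("warp density score: zero, linear, and single-specimen behaviour", {
  sc <- cbind(c(1, -2, 3, 0.5), c(0, 0, 0, 0))
  toy <- list(scores = sc, groups = factor(c("a", "a", "b", "c")),
              n_landmarks = 9, center = rep(0, 18),
              rotation = matrix(0, 18, 2), consensus = knifefish_template())
  w1 <- warp_density_score(toy, 1, weights = 1)
  expect_equal(as.vector(w1), c(-1, 3, 0.5), ignore_attr = TRUE)
  w2 <- warp_density_score(toy, 1, weights = c(2, 2, 2, 2))
  expect_equal(as.vector(w2), 2 * as.vector(w1))
  toy0 <- toy; toy0$scores <- sc * 0
  expect_equal(unname(as.vector(warp_density_score(toy0, 1, weights = 1))),
               c(0, 0, 0))
})

test_that("RV coefficient: identity, bounds, symmetry, rotation invariance", {
  set.seed(75)
  x <- matrix(rnorm(200), 50, 4)
  expect_equal(rv_coefficient(x, x), 1, tolerance = 1e-12)
  y <- matrix(rnorm(150), 50, 3)
  rv <- rv_coefficient(x, y)
  expect_gte(rv, 0)
  expect_lte(rv, 1)
  expect_equal(rv_coefficient(y, x), rv, tolerance = 1e-12)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xr <- cbind(x[, 1:2] %*% R, x[, 3:4])
  expect_equal(rv_coefficient(xr, y), rv, tolerance = 1e-10)
  # independent blocks at large n: RV near zero
  xa <- matrix(rnorm(500 * 4), 500, 4)
  xb <- matrix(rnorm(500 * 4), 500, 4)
  expect_lte(rv_coefficient(xa, xb), 0.1)
})

test_that("landmark-subset modularity compares against alternative partitions", {
  d <- generate_dataset(study_design_model(seed = 76))
  g <- gpa(d)
  m <- rv_modularity(g, c(1, 8, 9), n_perm = 99, seed = 1)
  expect_gte(m$rv, 0)
  expect_lte(m$rv, 1)
  expect_equal(m$complement, c(2, 3, 4, 5, 6, 7))
  expect_length(m$alternatives, m$n_contiguous + 99)
  m2 <- rv_modularity(g, c(1, 8, 9), n_perm = 99, seed = 1)
  expect_identical(m$alternatives, m2$alternatives)
  expect_error(rv_modularity(g, c(1:8)), "at least 2")
})
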