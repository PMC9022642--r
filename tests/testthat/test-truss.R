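test_that("truss distances: 3-4-5 triangle, full pair count, homogeneity", {
  tri <- rbind(c(0, 0), c(3, 0), c(0, 4))
  d <- make_dataset(list(tri, tri * 2))
  tt <- truss_distances(d)
  expect_equal(colnames(tt$values), c("1_2", "1_3", "2_3"))
  expect_equal(unname(tt$values[1, ]), c(3, 4, 5))
  expect_equal(unname(tt$values[2, ]), 2 * c(3, 4, 5))
  d9 <- generate_dataset(shape_model(group_sizes = c(3, 3), seed = 1))
  expect_equal(ncol(truss_distances(d9)$values), 36)
})

test_that("truss distances are invariant to specimen order and rigid motion", {
  d <- generate_dataset(shape_model(group_sizes = c(4, 4), seed = 2))
  tt <- truss_distances(d)
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  dp <- landmark_dataset(d$coords[perm, , ], d$ids[perm], d$groups[perm])
  expect_equal(truss_distances(dp)$values, tt$values[perm, ])
  rot <- array(NA_real_, dim(d$coords))
  for (i in 1:8) {
    rot[i, , ] <- similarity_transform(d$coords[i, , ], angle_deg = 63,
                                       shift = c(10, -4))
  }
  dr <- landmark_dataset(rot, d$ids, d$groups)
  expect_equal(truss_distances(dr)$values, tt$values, tolerance = 1e-9)
})

test_that("allometric slope: isometry gives b = 1, constants give b = 0", {
  L0 <- c(100, 150, 200, 280, 333)
  vals <- cbind("1_4" = L0, "1_2" = 0.5 * L0, "2_3" = rep(7, 5))
  tt <- truss_table(vals, paste0("s", 1:5), rep(c("a", "b"), length.out = 5))
  mod <- fit_allometry(tt)
  expect_equal(unname(mod$b[c("1_4", "1_2")]), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(mod$b["2_3"]), 0, tolerance = 1e-12)
  expect_equal(mod$Ls, mean(L0))
})

test_that("size adjustment follows M * (Ls/L0)^b and drops the SL variable", {
  vals <- cbind("1_4" = c(20, 10), "1_2" = c(10, 10), "2_3" = c(5, 4))
  tt <- truss_table(vals, c("s1", "s2"), c("a", "b"))
  mod <- structure(list(b = c("1_4" = 1, "1_2" = 1, "2_3" = 0), Ls = 10,
                        L0 = c(20, 10), ids = c("s1", "s2"),
                        pooled_within = FALSE),
                   class = "allometric_model")
  adj <- size_adjust(tt, mod)
  expect_equal(colnames(adj$values), c("1_2", "2_3"))
  expect_equal(unname(adj$values[, "1_2"]), c(5, 10))  # M=10,L0=20,Ls=10,b=1
  expect_equal(unname(adj$values[, "2_3"]), c(5, 4))   # b=0 leaves M alone
  expect_equal(adj$state, "size_adjusted")
})

test_that("adjustment on noiseless isometric data removes all size signal", {
  d <- generate_dataset(shape_model(noise_sd = 0, group_sizes = c(10, 10),
                                    seed = 5))
  tt <- truss_distances(d)
  mod <- fit_allometry(tt)
  adj <- size_adjust(tt, mod)
  expect_true(all(adj$values > 0))
  # every specimen collapses to the mean-size shape: zero residual variance,
  # hence no size signal (a correlation with L0 is undefined at sd = 0)
  expect_lt(max(apply(adj$values, 2, stats::sd) / colMeans(adj$values)), 1e-9)
  # with digitization noise the adjusted values decorrelate from size
  dn <- generate_dataset(shape_model(noise_sd = 0.5,
                                     group_sizes = c(40, 40), seed = 5))
  tn <- truss_distances(dn)
  mn <- fit_allometry(tn)
  rn <- cor(mn$L0, size_adjust(tn, mn)$values)
  expect_lt(max(abs(rn)), 0.3)
  expect_lt(mean(abs(rn)), 0.1)
})

test_that("log transform is base 10 and errors on nonpositive values", {
  tt <- truss_table(cbind("1_2" = c(1, 10, 100)), paste0("s", 1:3),
                    c("a", "a", "b"))
  lt <- log_transform(tt)
  expect_equal(unname(lt$values[, 1]), c(0, 1, 2))
  expect_equal(unname(10^lt$values[, 1]), c(1, 10, 100), tolerance = 1e-12)
  bad <- truss_table(cbind("1_2" = c(1, 0, 2)), paste0("s", 1:3),
                     c("a", "a", "b"))
  expect_error(log_transform(bad), "s2.*1_2")
})

test_that("ANOVA screen flags overwhelming effects and reports the N/P band", {
  set.seed(31)
  g <- rep(c("a", "b", "c"), each = 20)
  strong <- rnorm(60) + 10 * (g == "b")    # means 10 within-SDs apart
  weak <- rnorm(60)
  tt <- truss_table(cbind("1_2" = exp(strong), "1_3" = exp(weak)),
                    paste0("s", 1:60), g)
  sc <- anova_screen(tt, alpha = 0.01)
  expect_true(sc$screen$keep[sc$screen$variable == "1_2"])
  expect_equal(sc$np_ratio, 30)
  expect_false(sc$np_in_band)
  # the study design: 149 specimens over 35 analysis variables
  expect_equal(149 / 35, 4.257, tolerance = 1e-3)
  expect_true(149 / 35 >= 3.5 && 149 / 35 <= 8)
})

test_that("under the null the ANOVA F statistic has mean ~ 1", {
  set.seed(77)
  g <- rep(c("a", "b", "c", "d"), each = 12)
  vals <- matrix(exp(rnorm(48 * 400, sd = 0.1)), 48, 400)
  colnames(vals) <- paste0(rep(1:20, each = 20), "_", rep(21:40, times = 20))
  tt <- truss_table(vals, paste0("s", 1:48), g)
  sc <- anova_screen(tt, alpha = 0.01)
  expect_equal(mean(sc$screen$F), 1, tolerance = 0.1)
  expect_gt(ks.test(sc$screen$p, "punif")$p.value, 0.01)
})
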