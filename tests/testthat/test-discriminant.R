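adjusted_table <- function(seed = 33, separation = 0.004) {
  d <- generate_dataset(study_design_model(separation = separation,
                                           seed = seed))
  raw <- truss_distances(d)
  log_transform(size_adjust(raw, fit_allometry(raw)))
}

test_that("one informative variable puts all discriminant variance on function 1", {
  set.seed(41)
  g <- rep(c("a", "b"), each = 30)
  vals <- cbind("1_2" = exp(rnorm(60, mean = ifelse(g == "a", 0, 3))),
                "1_3" = exp(rnorm(60)), "2_3" = exp(rnorm(60)))
  fit <- cdfa(truss_table(vals, paste0("s", 1:60), g))
  expect_length(fit$eigenvalues, 1)     # min(p, g-1) = 1
  expect_equal(fit$percent_variance, 100)
  expect_gt(abs(fit$coefficients["1_2", 1]), abs(fit$coefficients["1_3", 1]))
})

test_that("Wilks lambda and canonical correlations follow the eigenvalues", {
  fit <- cdfa(adjusted_table())
  lam <- fit$eigenvalues
  expect_equal(fit$canonical_correlations, sqrt(lam / (1 + lam)))
  for (k in seq_along(lam)) {
    expect_equal(fit$wilks_lambda[k], prod(1 / (1 + lam[k:length(lam)])),
                 tolerance = 1e-12)
  }
  expect_equal(fit$df, (fit$p - seq_along(lam) + 1) *
                 (nlevels(fit$groups) - seq_along(lam)))
  # lambda = {1, 1} arithmetic of the same formulas
  expect_equal(prod(1 / (1 + c(1, 1))), 0.25)
  expect_equal(sqrt(1 / (1 + 1)), 0.7071, tolerance = 1e-4)
})

test_that("membership probabilities are proper and match MASS::lda ordering", {
  tt <- adjusted_table(seed = 34)
  fit <- dapc(tt, n_pcs = 6)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 149), tolerance = 1e-10)
  skip_if_not_installed("MASS")
  sc <- fit$pca$scores[, 1:6]
  ld <- MASS::lda(sc, grouping = tt$groups)
  pr <- predict(ld)
  agree <- mean(as.character(pr$class) == as.character(fit$assignment))
  expect_gt(agree, 0.98)
  expect_equal(unname(pr$posterior[1:10, levels(tt$groups)]),
               unname(fit$posterior[1:10, ]), tolerance = 1e-6)
})

test_that("DAPC at full rank matches CDFA assignment; functions respect rank bounds", {
  tt <- adjusted_table(seed = 35)
  full <- sum(truss_pca(tt)$eigenvalues > 1e-10)
  da <- dapc(tt, n_pcs = full)
  cd <- cdfa(tt)
  expect_identical(as.character(da$assignment), as.character(cd$assignment))
  expect_equal(da$eigenvalues, cd$eigenvalues, tolerance = 1e-6)
  da6 <- dapc(tt, n_pcs = 6)
  expect_lte(length(da6$eigenvalues), 6)
  expect_equal(length(da6$eigenvalues), min(6, nlevels(tt$groups) - 1))
  expect_error(dapc(tt, n_pcs = 100), "rank")
})

test_that("well-separated groups get near-certain own-group posteriors", {
  tt <- adjusted_table(seed = 36, separation = 0.03)
  fit <- dapc(tt, n_pcs = 6)
  own <- fit$posterior[cbind(seq_len(149), as.integer(tt$groups))]
  expect_true(all(own > 0.999))
})

test_that("singular within-group covariance yields an instructive error", {
  set.seed(42)
  g <- rep(c("a", "b"), each = 4)
  base <- exp(matrix(rnorm(8 * 3), 8, 3))
  vals <- cbind(base, base[, 1] * 2)   # exact collinearity
  colnames(vals) <- c("1_2", "1_3", "2_3", "1_4")
  expect_error(cdfa(truss_table(vals, paste0("s", 1:8), g)), "DAPC")
})

test_that("AUC: pair-counting identity, oracle equivalence, bands, ties", {
  expect_equal(roc_auc(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0.75)
  sep <- roc_auc(c(5, 6, 7, 1, 2), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)
  expect_equal(sep$band, "outstanding")
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_equal(roc_auc(c(3, 1, 2, 2), c(TRUE, FALSE, TRUE, FALSE))$band,
               "excellent")
  set.seed(7)
  for (r in 1:20) {
    n <- sample(10:200, 1)
    sc <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lb) || all(lb)) next
    expect_identical(roc_auc(sc, lb)$auc, auc_brute(sc, lb))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "nonempty")
})

test_that("ROC curves are proper step curves and agree with pROC", {
  set.seed(8)
  sc <- rnorm(80) + rep(c(0, 1.5), 40)
  lb <- rep(c(FALSE, TRUE), 40)
  r <- roc_auc(sc, lb)
  expect_equal(unlist(r$curve[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  skip_if_not_installed("pROC")
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
})

test_that("null separation gives chance-level mean AUC", {
  set.seed(9)
  aucs <- replicate(50, {
    sc <- runif(149)
    lb <- rep(FALSE, 149)
    lb[sample(149, 20)] <- TRUE
    roc_auc(sc, lb)$auc
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.05)
})

test_that("score densities normalize, locate groups, and separate when disjoint", {
  tt <- adjusted_table(seed = 37)
  fit <- dapc(tt, n_pcs = 6)
  sd1 <- score_density(fit, 1)
  dx <- diff(sd1$grid[1:2])
  mass <- colSums(sd1$density) * dx
  expect_true(all(abs(mass - 1) < 0.01))
  expect_equal(unname(sd1$means[levels(tt$groups)[1]]),
               mean(fit$scores[tt$groups == levels(tt$groups)[1], 1]))
  # disjoint score ranges -> zero overlap of min-density
  toy <- list(scores = cbind(c(rnorm(30, -50, 0.5), rnorm(30, 50, 0.5))),
              groups = factor(rep(c("lo", "hi"), each = 30)))
  sd2 <- score_density(toy, 1)
  overlap <- sum(pmin(sd2$density[, 1], sd2$density[, 2])) * diff(sd2$grid[1:2])
  expect_lt(overlap, 1e-6)
})
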