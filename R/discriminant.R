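#' Canonical discriminant function analysis
#'
#' Solves the generalized eigenproblem of the between-group SSCP against the
#' pooled within-group SSCP, yielding `min(p, g - 1)` ordered canonical
#' discriminant functions. For each function k it reports the eigenvalue, the
#' share of discriminant variance, the canonical correlation
#' `sqrt(lambda / (1 + lambda))`, Wilks' lambda for the test of functions
#' k..K (`prod 1 / (1 + lambda_j)`), and Bartlett's chi-square approximation
#' `-(n - 1 - (p + g) / 2) * log(Lambda)` with `(p - k + 1)(g - k)` degrees of
#' freedom. Unstandardized coefficients are scaled so the pooled within-group
#' variance of every function's scores is 1, and each function's sign is fixed
#' so its largest-magnitude coefficient is positive.
#'
#' Membership probabilities are Gaussian class posteriors in the discriminant
#' space (where the pooled within-group covariance is the identity), with
#' priors proportional to group size by default.
#'
#' @param x A [truss_table()], or a numeric specimens x variables matrix.
#' @param groups Group labels; taken from the table when `x` is one.
#' @param priors `"proportional"` (default) or `"uniform"` class priors for
#'   the posteriors.
#' @param loo If `TRUE`, also compute leave-one-out assignments by refitting
#'   without each specimen in turn.
#' @return An object of class `cdfa` with fields `eigenvalues`,
#'   `percent_variance`, `cumulative_percent`, `canonical_correlations`,
#'   `wilks_lambda`, `chi_square`, `df`, `p_value`, `coefficients`
#'   (variables x functions), `constants`, `centroids`
#'   (groups x functions), `scores`, `posterior`
#'   (specimens x groups), `assignment`, `loo_assignment` (or `NULL`),
#'   `groups`, `priors`.
#' @examples
#' tt <- truss_distances(generate_dataset(study_design_model(seed = 3)))
#' fit <- cdfa(tt)
#' fit
#' @export
cdfa <- function(x, groups = NULL, priors = c("proportional", "uniform"),
                 loo = FALSE) {
  priors <- match.arg(priors)
  if (inherits(x, "truss_table")) {
    groups <- x$groups
    ids <- x$ids
    x <- x$values
  } else {
    x <- as.matrix(x)
    ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  }
  groups <- droplevels(factor(groups))
  fit <- cda_core(x, groups, priors)
  fit$ids <- ids
  if (loo) {
    fit$loo_assignment <- cda_loo(x, groups, priors)
  } else {
    fit$loo_assignment <- NULL
  }
  class(fit) <- "cdfa"
  fit
}

# core canonical discriminant computation on a plain matrix
cda_core <- function(x, groups, priors) {
  n <- nrow(x)
  p <- ncol(x)
  g <- nlevels(groups)
  if (g < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 specimens")
  vars <- colnames(x) %||% paste0("V", seq_len(p))
  mu <- colMeans(x)
  M <- rowsum(x, groups) / as.vector(table(groups))
  xw <- x - M[groups, , drop = FALSE]
  W <- crossprod(xw)                          # within-group SSCP
  B <- crossprod(sweep(M, 2, mu), sweep(M, 2, mu) * as.vector(table(groups)))
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < max(ew$values) * 1e-13) {
    stopf(paste("pooled within-group covariance is (near-)singular;",
                "reduce the variables first, e.g. run the discriminant",
                "analysis on retained principal components (DAPC) or drop",
                "collinear variables"))
  }
  Wih <- ew$vectors %*% diag(1 / sqrt(ew$values), p) %*% t(ew$vectors)
  C <- Wih %*% B %*% Wih
  C <- (C + t(C)) / 2
  ec <- eigen(C, symmetric = TRUE)
  K <- min(p, g - 1)
  lambda <- pmax(ec$values[seq_len(K)], 0)
  V <- Wih %*% ec$vectors[, seq_len(K), drop = FALSE]
  # normalize: pooled within-group variance of scores = 1 (SPSS convention)
  V <- V * sqrt(n - g)
  for (j in seq_len(K)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  dimnames(V) <- list(vars, paste0("DF", seq_len(K)))
  constants <- -as.vector(mu %*% V)
  scores <- sweep(x %*% V, 2, -constants)
  colnames(scores) <- colnames(V)
  centroids <- rowsum(scores, groups) / as.vector(table(groups))
  pct <- if (sum(lambda) > 0) 100 * lambda / sum(lambda) else rep(0, K)
  wilks <- rev(cumprod(rev(1 / (1 + lambda))))
  chi <- -(n - 1 - (p + g) / 2) * log(wilks)
  df <- (p - seq_len(K) + 1) * (g - seq_len(K))
  pv <- stats::pchisq(chi, df, lower.tail = FALSE)
  prior <- if (priors == "proportional") {
    as.vector(table(groups)) / n
  } else {
    rep(1 / g, g)
  }
  names(prior) <- levels(groups)
  post <- posterior_from_scores(scores, centroids, prior)
  assignment <- factor(levels(groups)[max.col(post)], levels = levels(groups))
  list(eigenvalues = lambda, percent_variance = pct,
       cumulative_percent = cumsum(pct),
       canonical_correlations = sqrt(lambda / (1 + lambda)),
       wilks_lambda = wilks, chi_square = chi, df = df, p_value = pv,
       coefficients = V, constants = constants, scores = scores,
       centroids = centroids, posterior = post, assignment = assignment,
       groups = groups, priors = prior, n = n, p = p)
}

# Gaussian posteriors in whitened discriminant space (within-cov = identity)
posterior_from_scores <- function(scores, centroids, prior) {
  d2 <- vapply(seq_len(nrow(centroids)), function(gi) {
    rowSums(sweep(scores, 2, centroids[gi, ])^2)
  }, numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  lp <- sweep(-0.5 * d2, 2, log(prior), `+`)
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp)
  post <- post / rowSums(post)
  colnames(post) <- rownames(centroids)
  rownames(post) <- rownames(scores)
  post
}

cda_loo <- function(x, groups, priors) {
  n <- nrow(x)
  out <- character(n)
  for (i in seq_len(n)) {
    gi <- droplevels(groups[-i])
    fit <- cda_core(x[-i, , drop = FALSE], gi, priors)
    sc <- sweep(x[i, , drop = FALSE] %*% fit$coefficients, 2, -fit$constants)
    post <- posterior_from_scores(sc, fit$centroids, fit$priors)
    out[i] <- colnames(post)[which.max(post)]
  }
  factor(out, levels = levels(groups))
}

#' @export
print.cdfa <- function(x, ...) {
  K <- length(x$eigenvalues)
  cat(sprintf("Canonical discriminant analysis: %d variables, %d groups, %d functions\n",
              x$p, nlevels(x$groups), K))
  df <- data.frame(eigenvalue = round(x$eigenvalues, 4),
                   pct_variance = round(x$percent_variance, 2),
                   cumulative = round(x$cumulative_percent, 2),
                   canon_corr = round(x$canonical_correlations, 3),
                   wilks = round(x$wilks_lambda, 4),
                   chi_sq = round(x$chi_square, 2), df = x$df,
                   p = signif(x$p_value, 3))
  print(df)
  acc <- mean(x$assignment == x$groups)
  cat(sprintf("Resubstitution accuracy: %.1f%%\n", 100 * acc))
  if (!is.null(x$loo_assignment)) {
    cat(sprintf("Leave-one-out accuracy: %.1f%%\n",
                100 * mean(x$loo_assignment == x$groups)))
  }
  invisible(x)
}

#' @export
plot.cdfa <- function(x, functions = c(1, 2), ...) {
  s <- x$scores[, functions, drop = FALSE]
  graphics::plot(s, col = as.integer(x$groups), pch = 19,
                 xlab = sprintf("Function %d (%.1f%%)", functions[1],
                                x$percent_variance[functions[1]]),
                 ylab = sprintf("Function %d (%.1f%%)", functions[2],
                                x$percent_variance[functions[2]]), ...)
  ctr <- x$centroids[, functions, drop = FALSE]
  graphics::points(ctr, pch = 8, cex = 1.6)
  graphics::legend("topright", legend = levels(x$groups), pch = 19,
                   col = seq_len(nlevels(x$groups)), cex = 0.8)
  invisible(x)
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Runs correlation-matrix PCA on the truss table, retains the first `n_pcs`
#' components (default 6) and feeds their scores to the canonical discriminant
#' analysis of [cdfa()]. Function coefficients are back-projected to the
#' original (standardized) truss variables — the coefficient of a variable is
#' the dot product of its PCA eigenvector row with the discriminant
#' coefficient vector — so a per-variable coefficient table is reported
#' alongside the PC-space fit.
#'
#' @param table A [truss_table()].
#' @param n_pcs Number of retained principal components (default 6).
#' @param priors,loo Passed to [cdfa()].
#' @return An object of class `dapc` (also inheriting from `cdfa`) with the
#'   extra fields `pca` (the [truss_pca()] fit), `n_pcs`, and
#'   `variable_coefficients` (truss variables x functions).
#' @examples
#' tt <- truss_distances(generate_dataset(study_design_model(seed = 3)))
#' fit <- dapc(tt, n_pcs = 6)
#' head(fit$variable_coefficients)
#' @export
dapc <- function(table, n_pcs = 6L, priors = c("proportional", "uniform"),
                 loo = FALSE) {
  stopifnot(inherits(table, "truss_table"))
  priors <- match.arg(priors)
  pca <- truss_pca(table)
  r <- sum(pca$eigenvalues > 1e-10)
  if (n_pcs < 1 || n_pcs > r) {
    stopf("n_pcs must be between 1 and the available rank (%d)", r)
  }
  sc <- pca$scores[, seq_len(n_pcs), drop = FALSE]
  fit <- cdfa(sc, table$groups, priors = priors, loo = loo)
  fit$pca <- pca
  fit$n_pcs <- as.integer(n_pcs)
  fit$variable_coefficients <-
    pca$rotation[, seq_len(n_pcs), drop = FALSE] %*% fit$coefficients
  rownames(fit$variable_coefficients) <- rownames(pca$loadings)
  fit$ids <- table$ids
  class(fit) <- c("dapc", "cdfa")
  fit
}

#' @export
print.dapc <- function(x, ...) {
  cat(sprintf("DAPC: %d retained PCs of %d variables\n",
              x$n_pcs, nrow(x$variable_coefficients)))
  NextMethod()
}

#' One-vs-rest ROC curve and AUC
#'
#' Computes the ROC curve of sensitivity against (1 - specificity) for a
#' numeric score separating one group from the rest, with AUC by the
#' Mann-Whitney pair-counting identity (ties count 1/2). The AUC is graded
#' with the conventional performance bands: 0.9-1.0 "outstanding",
#' 0.8-0.9 "excellent", below "lower".
#'
#' @param scores Numeric vector (e.g. a group's membership probability).
#' @param labels Logical vector, `TRUE` for the in-group (positive) class.
#' @return An object of class `roc_result` with `auc`, `band` and `curve`
#'   (data frame with columns `fpr` = 1 - specificity and `tpr` =
#'   sensitivity, from (0, 0) to (1, 1), monotone nondecreasing).
#' @examples
#' roc_auc(c(2, 4, 1, 3), c(TRUE, TRUE, FALSE, FALSE))$auc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stopf("both classes must be nonempty")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), 0)
  curve <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  band <- if (auc >= 0.9) "outstanding" else if (auc >= 0.8) "excellent" else "lower"
  structure(list(auc = auc, band = band, curve = curve,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%s), %d positive vs %d negative\n",
              x$auc, x$band, x$n_pos, x$n_neg))
  invisible(x)
}

#' Per-group ROC analysis of a discriminant fit
#'
#' One-vs-rest ROC for every group, scoring each specimen by its membership
#' probability for that group.
#'
#' @param fit A [cdfa()] or [dapc()] result.
#' @return A list of [roc_auc()] results, one per group, plus an `auc` summary
#'   vector; the score used is recorded in the `score` attribute.
#' @export
roc_analysis <- function(fit) {
  stopifnot(inherits(fit, "cdfa"))
  out <- lapply(levels(fit$groups), function(gl) {
    roc_auc(fit$posterior[, gl], fit$groups == gl)
  })
  names(out) <- levels(fit$groups)
  attr(out, "auc") <- vapply(out, function(r) r$auc, 0)
  attr(out, "score") <- "group membership probability"
  out
}

#' Per-group score density curves
#'
#' Kernel density estimates of one discriminant function's (or principal
#' component's) scores per group, on a shared evaluation grid, with the group
#' mean positions on that axis.
#'
#' @param fit A [cdfa()], [dapc()] or [truss_pca()] result.
#' @param function_index Which function / component axis to use.
#' @param n_grid Grid resolution.
#' @return An object of class `score_density`: list with `grid`, `density`
#'   (grid x groups matrix, each column integrating to ~1), `means`.
#' @export
score_density <- function(fit, function_index = 1L, n_grid = 512L) {
  scores <- fit$scores[, function_index]
  groups <- droplevels(fit$groups)
  if (any(table(groups) < 1)) stopf("empty group")
  rng <- range(scores)
  pad <- 0.35 * diff(rng) + 1e-8
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
  dens <- vapply(levels(groups), function(gl) {
    s <- scores[groups == gl]
    bw <- tryCatch(stats::bw.nrd0(s), error = function(e) NULL)
    if (is.null(bw) || !is.finite(bw) || bw <= 0) {
      bw <- max(stats::sd(s), 1e-3 * (diff(rng) + 1e-8), 1e-8)
    }
    d <- stats::density(s, bw = bw, from = min(grid), to = max(grid),
                        n = n_grid)
    d$y
  }, numeric(n_grid))
  means <- tapply(scores, groups, mean)
  structure(list(grid = grid, density = dens, means = means,
                 function_index = function_index),
            class = "score_density")
}

#' @export
print.score_density <- function(x, ...) {
  cat(sprintf("Score densities on axis %d for %d groups; group means:\n",
              x$function_index, ncol(x$density)))
  print(round(x$means, 3))
  invisible(x)
}

#' @export
plot.score_density <- function(x, ...) {
  graphics::matplot(x$grid, x$density, type = "l", lty = 1,
                    xlab = sprintf("Axis %d score", x$function_index),
                    ylab = "Density", ...)
  graphics::legend("topright", legend = colnames(x$density), lty = 1,
                   col = seq_len(ncol(x$density)), cex = 0.8)
  invisible(x)
}
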