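# Generalized Procrustes analysis and shape-space statistics.

# center a k x 2 configuration and return it with its centroid size
center_config <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  list(conf = m, cs = cs)
}

# optimal rotation (no reflection) aligning Y onto X, both centered.
# For 2D the maximal rotation trace has the closed form
# sqrt((A11+A22)^2 + (A21-A12)^2) with A = t(Y) %*% X.
opa_rotation <- function(X, Y) {
  A <- crossprod(Y, X)
  h <- sqrt((A[1, 1] + A[2, 2])^2 + (A[2, 1] - A[1, 2])^2)
  if (h == 0) {
    return(list(R = diag(2), trace = 0))
  }
  cth <- (A[1, 1] + A[2, 2]) / h
  sth <- (A[2, 1] - A[1, 2]) / h
  list(R = matrix(c(cth, sth, -sth, cth), 2, 2), trace = h)
}

#' Procrustes distance between two configurations
#'
#' Distance between two landmark configurations after translation, scaling to
#' unit centroid size and rotation (reflections disallowed). The full
#' Procrustes distance additionally optimizes a relative scale between the
#' superimposed unit-size shapes (`sqrt(1 - T^2)` with `T` the maximal
#' rotation trace); the partial distance keeps both at unit size
#' (`sqrt(2 - 2T)`).
#'
#' @param x,y `k x 2` landmark matrices.
#' @param type `"full"` (default, used for all group-mean comparisons) or
#'   `"partial"`.
#' @return Nonnegative scalar; 0 iff the shapes are similar (identical up to
#'   translation, rotation and scale).
#' @examples
#' tri <- cbind(c(0, 3, 0), c(0, 0, 4))
#' procrustes_distance(tri, tri * 2)  # 0
#' @export
procrustes_distance <- function(x, y, type = c("full", "partial")) {
  type <- match.arg(type)
  cx <- center_config(as.matrix(x))
  cy <- center_config(as.matrix(y))
  if (cx$cs == 0 || cy$cs == 0) stopf("degenerate (zero-size) configuration")
  X <- cx$conf / cx$cs
  Y <- cy$conf / cy$cs
  r <- opa_rotation(X, Y)
  T <- min(r$trace, 1)
  # residuals computed elementwise (not via 1 - T^2) to keep full precision
  # for near-identical shapes
  M <- Y %*% r$R
  if (type == "full") sqrt(sum((X - T * M)^2)) else sqrt(sum((X - M)^2))
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of all configurations: translate to zero
#' centroid, scale to unit centroid size, rotate each onto the current
#' consensus (closed-form optimal 2D rotation, reflections disallowed),
#' recompute the consensus, rescale it to unit size, and repeat until the
#' consensus moves less than `tol` (root-sum-square) or `max_iter` iterations.
#'
#' @param data A [landmark_dataset()], or an `n x k x 2` array.
#' @param tol Convergence tolerance on the consensus update (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @return An object of class `gpa` with `aligned` (`n x k x 2`, unit
#'   centroid size, zero centroid), `consensus` (`k x 2`, unit size),
#'   `centroid_sizes` (original units, mm for calibrated data), `groups`,
#'   `ids`, `iterations`, `delta`.
#' @examples
#' d <- generate_dataset(shape_model(group_sizes = c(5, 5), seed = 1))
#' g <- gpa(d)
#' g
#' @export
gpa <- function(data, tol = 1e-10, max_iter = 100L) {
  if (inherits(data, "landmark_dataset")) {
    coords <- data$coords
    ids <- data$ids
    groups <- data$groups
  } else {
    coords <- data
    ids <- dimnames(coords)[[1]] %||% as.character(seq_len(dim(coords)[1]))
    groups <- factor(rep("all", dim(coords)[1]))
  }
  n <- dim(coords)[1]
  k <- dim(coords)[2]
  if (n < 2) stopf("need at least 2 specimens")
  cs <- numeric(n)
  aligned <- array(NA_real_, dim(coords))
  for (i in seq_len(n)) {
    ci <- center_config(coords[i, , ])
    if (ci$cs == 0) stopf("specimen %s has zero centroid size", ids[i])
    cs[i] <- ci$cs
    aligned[i, , ] <- ci$conf / ci$cs
  }
  consensus <- aligned[1, , ]
  delta <- Inf
  iter <- 0L
  while (delta > tol && iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      R <- opa_rotation(consensus, aligned[i, , ])$R
      aligned[i, , ] <- aligned[i, , ] %*% R
    }
    new_cons <- apply(aligned, c(2, 3), mean)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
  }
  dimnames(aligned) <- list(ids, paste0("lm", seq_len(k)), c("x", "y"))
  structure(list(aligned = aligned, consensus = consensus,
                 centroid_sizes = stats::setNames(cs, ids), groups = groups,
                 ids = ids, iterations = iter, delta = delta),
            class = "gpa")
}

#' @export
print.gpa <- function(x, ...) {
  cat(sprintf("GPA: %d specimens, %d landmarks; converged in %d iteration(s) (delta %.2e)\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$iterations, x$delta))
  cat(sprintf("Centroid size: %.1f to %.1f\n",
              min(x$centroid_sizes), max(x$centroid_sizes)))
  invisible(x)
}

#' @export
plot.gpa <- function(x, ...) {
  flat <- matrix(aperm(x$aligned, c(2, 1, 3)), ncol = 2)
  graphics::plot(flat, pch = ".", col = "grey50", asp = 1,
                 xlab = "x", ylab = "y", ...)
  graphics::points(x$consensus, pch = 19)
  graphics::text(x$consensus, labels = seq_len(nrow(x$consensus)), pos = 3)
  invisible(x)
}

#' Pairwise Procrustes distances
#'
#' Full (or partial) Procrustes distance matrix between all specimens of a
#' GPA fit, or between group mean shapes.
#'
#' @param x A [gpa()] result.
#' @param by `"specimen"` or `"group"` (mean shapes).
#' @param type Passed to [procrustes_distance()].
#' @return Symmetric distance matrix.
#' @export
procrustes_dist_matrix <- function(x, by = c("specimen", "group"),
                                   type = "full") {
  stopifnot(inherits(x, "gpa"))
  by <- match.arg(by)
  shapes <- if (by == "specimen") {
    lapply(seq_len(dim(x$aligned)[1]), function(i) x$aligned[i, , ])
  } else {
    lapply(levels(x$groups), function(gl) {
      apply(x$aligned[x$groups == gl, , , drop = FALSE], c(2, 3), mean)
    })
  }
  nm <- if (by == "specimen") x$ids else levels(x$groups)
  m <- length(shapes)
  d <- matrix(0, m, m, dimnames = list(nm, nm))
  for (a in seq_len(m - 1)) {
    for (b in (a + 1):m) {
      d[a, b] <- d[b, a] <- procrustes_distance(shapes[[a]], shapes[[b]],
                                                type = type)
    }
  }
  d
}

#' Procrustes ANOVA for centroid size and shape
#'
#' Centroid size: classical one-way ANOVA on log centroid size. Shape: a
#' Goodall-style decomposition of the summed squared Procrustes residuals of
#' the aligned coordinates into between- and within-group parts, with the
#' shape dimensions pooled (`2k - 4` degrees of freedom per specimen
#' dimension) and the F ratio tested by permutation of group labels.
#'
#' @param x A [gpa()] result with at least 2 groups.
#' @param n_perm Number of label permutations for the shape test.
#' @param seed Integer seed for the permutations (reproducible bit-for-bit).
#' @return An object of class `procrustes_anova` with `size` (ANOVA table)
#'   and `shape` (list with `SSB`, `SSW`, `dfB`, `dfW`, `F`, `p_perm`,
#'   `n_perm`, `degenerate`).
#' @export
procrustes_anova <- function(x, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(x, "gpa"))
  groups <- droplevels(x$groups)
  g <- nlevels(groups)
  if (g < 2) stopf("need at least 2 groups")
  if (any(table(groups) < 2)) stopf("every group needs at least 2 specimens")
  n <- dim(x$aligned)[1]
  k <- dim(x$aligned)[2]
  m <- 2 * k - 4
  size_tab <- stats::anova(stats::lm(log(x$centroid_sizes) ~ groups))
  flat <- matrix(x$aligned, nrow = n)
  mu <- colMeans(flat)
  sst <- sum(sweep(flat, 2, mu)^2)
  ssb_for <- function(gr) {
    M <- rowsum(flat, gr) / as.vector(table(gr))
    sum(sweep(M, 2, mu)^2 * as.vector(table(gr)))
  }
  ssb <- ssb_for(groups)
  ssw <- sst - ssb
  if (sst < 1e-24) {
    shape <- list(SSB = 0, SSW = 0, dfB = (g - 1) * m, dfW = (n - g) * m,
                  F = NA_real_, p_perm = NA_real_, n_perm = n_perm,
                  degenerate = TRUE)
  } else {
    dfB <- (g - 1) * m
    dfW <- (n - g) * m
    Fobs <- (ssb / dfB) / (ssw / dfW)
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(r) {
        gr <- sample(groups)
        sb <- ssb_for(gr)
        (sb / dfB) / ((sst - sb) / dfW)
      }, 0)
    })
    p <- (1 + sum(perm >= Fobs)) / (n_perm + 1)
    shape <- list(SSB = ssb, SSW = ssw, dfB = dfB, dfW = dfW, F = Fobs,
                  p_perm = p, n_perm = n_perm, degenerate = FALSE)
  }
  structure(list(size = size_tab, shape = shape, seed = seed),
            class = "procrustes_anova")
}

#' @export
print.procrustes_anova <- function(x, ...) {
  cat("Procrustes ANOVA\n-- centroid size (log), one-way ANOVA:\n")
  print(x$size)
  s <- x$shape
  if (s$degenerate) {
    cat("-- shape: degenerate (no variation among aligned shapes)\n")
  } else {
    cat(sprintf("-- shape (Goodall-style): F(%d, %d) = %.3f, permutation p = %.4g (%d permutations)\n",
                s$dfB, s$dfW, s$F, s$p_perm, s$n_perm))
  }
  invisible(x)
}

#' PCA of Procrustes-aligned shapes
#'
#' Covariance-matrix PCA of the aligned coordinates (Procrustes residuals
#' from the consensus). GPA removes 4 similarity degrees of freedom, so at
#' most `2k - 4` eigenvalues are nonzero.
#'
#' @param x A [gpa()] result.
#' @return An object of class `shape_pca` with `eigenvalues`,
#'   `percent_variance`, `cumulative_percent`, `rotation`
#'   (`2k x` components; rows ordered x1..xk then y1..yk), `scores`,
#'   `center` (flattened consensus of the data), `groups`, `ids`.
#' @export
shape_pca <- function(x) {
  stopifnot(inherits(x, "gpa"))
  n <- dim(x$aligned)[1]
  k <- dim(x$aligned)[2]
  flat <- matrix(x$aligned, nrow = n)
  colnames(flat) <- c(paste0("x", 1:k), paste0("y", 1:k))
  p <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  pct <- 100 * ev / sum(ev)
  scores <- p$x
  structure(list(eigenvalues = ev, percent_variance = pct,
                 cumulative_percent = cumsum(pct), rotation = p$rotation,
                 scores = scores, center = p$center, groups = x$groups,
                 ids = x$ids, n_landmarks = k),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  m <- 2 * x$n_landmarks - 4
  cat(sprintf("Shape PCA: %d shape dimensions (2k - 4 = %d nonzero)\n",
              length(x$eigenvalues), m))
  df <- data.frame(eigenvalue = signif(x$eigenvalues[1:min(7, m)], 3),
                   pct = round(x$percent_variance[1:min(7, m)], 2),
                   cumulative = round(x$cumulative_percent[1:min(7, m)], 2))
  print(df)
  invisible(x)
}

#' 95% confidence ellipse of group scores
#'
#' Ellipse path from the group score covariance on a component pair,
#' chi-square quantile radius.
#'
#' @param x A [shape_pca()] (or any object with `scores` and `groups`).
#' @param group Group label.
#' @param components Length-2 component indices.
#' @param level Coverage level (default 0.95).
#' @param n_points Path resolution.
#' @return A `n_points x 2` matrix tracing the ellipse.
#' @export
group_ellipse <- function(x, group, components = c(1, 2), level = 0.95,
                          n_points = 100L) {
  s <- x$scores[x$groups == group, components, drop = FALSE]
  if (nrow(s) < 3) stopf("need at least 3 specimens for an ellipse")
  ctr <- colMeans(s)
  S <- stats::cov(s)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta)) * r
  es <- eigen(S, symmetric = TRUE)
  path <- circ %*% diag(sqrt(pmax(es$values, 0))) %*% t(es$vectors)
  sweep(path, 2, -ctr)
}

#' Pairwise group mean-shape tests
#'
#' For every pair of groups: the Procrustes distance between the group mean
#' shapes with a permutation p-value (group labels shuffled within the pair),
#' the Mahalanobis distance between the means in a shape-PCA score space
#' (components covering at least `var_cover` of variance, capped so the
#' pooled covariance stays invertible), leave-one-out cross-validated
#' assignment accuracy of the two-group discriminant, and the per-landmark
#' mean-difference ("lollipop") vectors.
#'
#' @param x A [gpa()] result.
#' @param n_perm Permutations per pair (default 999).
#' @param seed Integer seed.
#' @param var_cover Fraction of shape variance the score space must cover
#'   (default 0.95).
#' @param type Procrustes distance type (default `"full"`).
#' @return A data frame of class `group_shape_tests` with one row per pair
#'   (`group1`, `group2`, `n1`, `n2`, `proc_dist`, `mahalanobis`, `p_perm`,
#'   `loo_cv`, `n_perm`, `seed`) and the per-pair landmark difference vectors
#'   in `attr(, "shape_difference")` (list of `k x 2` matrices,
#'   mean(group2) - mean(group1)).
#' @export
group_mean_tests <- function(x, n_perm = 999L, seed = 1L, var_cover = 0.95,
                             type = "full") {
  stopifnot(inherits(x, "gpa"))
  groups <- droplevels(x$groups)
  lev <- levels(groups)
  if (length(lev) < 2) stopf("need at least 2 groups")
  sp <- shape_pca(x)
  n <- dim(x$aligned)[1]
  flat <- matrix(x$aligned, nrow = n)
  k <- dim(x$aligned)[2]
  rows <- list()
  diffs <- list()
  for (a in seq_along(lev)[-length(lev)]) {
    for (b in (a + 1):length(lev)) {
      g1 <- lev[a]; g2 <- lev[b]
      i1 <- which(groups == g1); i2 <- which(groups == g2)
      if (length(i1) < 3 || length(i2) < 3) {
        warnf("skipping pair %s-%s: fewer than 3 specimens in a group", g1, g2)
        next
      }
      m1 <- apply(x$aligned[i1, , , drop = FALSE], c(2, 3), mean)
      m2 <- apply(x$aligned[i2, , , drop = FALSE], c(2, 3), mean)
      pd <- procrustes_distance(m1, m2, type = type)
      # permutation: shuffle the two labels over the pair's specimens
      idx <- c(i1, i2)
      n1 <- length(i1)
      perm <- with_seed(seed + a * 1000L + b, {
        vapply(seq_len(n_perm), function(r) {
          sh <- sample(idx)
          mm1 <- matrix(colMeans(flat[sh[seq_len(n1)], , drop = FALSE]), k, 2)
          mm2 <- matrix(colMeans(flat[sh[-seq_len(n1)], , drop = FALSE]), k, 2)
          procrustes_distance(mm1, mm2, type = type)
        }, 0)
      })
      pval <- (1 + sum(perm >= pd)) / (n_perm + 1)
      # discriminant score space: >= var_cover of variance, capped for a
      # stable pooled covariance within the pair
      ncomp <- which(sp$cumulative_percent >= 100 * var_cover)[1]
      ncomp <- min(ncomp, length(idx) - 3, sum(sp$eigenvalues > 1e-12))
      ncomp <- max(ncomp, 1L)
      s1 <- sp$scores[i1, seq_len(ncomp), drop = FALSE]
      s2 <- sp$scores[i2, seq_len(ncomp), drop = FALSE]
      Sp <- ((nrow(s1) - 1) * stats::cov(s1) + (nrow(s2) - 1) * stats::cov(s2)) /
        (length(idx) - 2)
      dm <- colMeans(s1) - colMeans(s2)
      mah <- sqrt(drop(dm %*% solve(Sp, dm)))
      sub <- rbind(s1, s2)
      subg <- factor(rep(c(g1, g2), c(nrow(s1), nrow(s2))))
      loo <- cda_loo(sub, subg, "proportional")
      acc <- mean(loo == subg)
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = g1, group2 = g2, n1 = length(i1), n2 = length(i2),
        proc_dist = pd, mahalanobis = mah, p_perm = pval, loo_cv = acc,
        n_comp = ncomp, n_perm = n_perm, seed = seed,
        stringsAsFactors = FALSE)
      diffs[[paste(g1, g2, sep = "-")]] <- m2 - m1
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  attr(out, "shape_difference") <- diffs
  attr(out, "distance_type") <- type
  class(out) <- c("group_shape_tests", "data.frame")
  out
}

#' @export
print.group_shape_tests <- function(x, ...) {
  cat(sprintf("Pairwise group mean-shape tests (%s Procrustes distance):\n",
              attr(x, "distance_type")))
  df <- as.data.frame(x)
  df$proc_dist <- signif(df$proc_dist, 5)
  df$mahalanobis <- round(df$mahalanobis, 3)
  df$loo_cv <- round(df$loo_cv, 3)
  print(df)
  invisible(x)
}

#' Lollipop plot of a pairwise shape difference
#'
#' Consensus landmarks with segments to the displaced positions of one group
#' mean relative to another, magnified for visibility.
#'
#' @param x A [gpa()] result.
#' @param tests A [group_mean_tests()] result.
#' @param pair Pair name `"group1-group2"` as in the tests table.
#' @param magnify Vector display magnification (default 5).
#' @return The displacement matrix, invisibly.
#' @export
plot_shape_difference <- function(x, tests, pair, magnify = 5) {
  d <- attr(tests, "shape_difference")[[pair]]
  if (is.null(d)) stopf("unknown pair '%s'", pair)
  graphics::plot(x$consensus, asp = 1, pch = 19, xlab = "x", ylab = "y",
                 main = pair)
  graphics::segments(x$consensus[, 1], x$consensus[, 2],
                     x$consensus[, 1] + magnify * d[, 1],
                     x$consensus[, 2] + magnify * d[, 2])
  invisible(d)
}
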