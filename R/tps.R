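# Thin-plate-spline warps, relative warps and landmark-subset modularity.

tps_kernel <- function(r2) ifelse(r2 == 0, 0, r2 * log(r2))

# bending-energy matrix of a reference configuration: upper-left k x k block
# of the inverse of the bordered TPS system. Annihilates affine functions.
bending_energy_matrix <- function(reference) {
  k <- nrow(reference)
  d2 <- as.matrix(stats::dist(reference))^2
  K <- tps_kernel(d2)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- tryCatch(solve(L), error = function(e) {
    stopf("singular TPS system: reference landmarks are collinear or coincident")
  })
  B <- Li[seq_len(k), seq_len(k), drop = FALSE]
  (B + t(B)) / 2
}

#' Thin-plate-spline warp between two configurations
#'
#' Fits the standard 2D thin-plate spline (kernel `U(r) = r^2 log r^2`)
#' mapping every reference landmark exactly onto its target landmark, split
#' into an affine part and non-affine (principal-warp) kernel weights. The
#' total bending energy is the quadratic form of the reference's
#' bending-energy matrix applied to the target coordinates; it is zero iff
#' the target is an affine image of the reference.
#'
#' @param reference,target `k x 2` landmark matrices, `k >= 4`, reference not
#'   collinear.
#' @return An object of class `tps_warp` with `reference`, `target`,
#'   `weights` (`k x 2` non-affine coefficients), `affine` (`3 x 2`:
#'   intercept, x, y rows), `bending_energy_matrix` (`k x k`), and
#'   `total_bending_energy`.
#' @examples
#' ref <- knifefish_template()
#' w <- tps_fit(ref, ref * 2)       # pure scaling is affine
#' w$total_bending_energy           # ~ 0
#' @export
tps_fit <- function(reference, target) {
  reference <- as.matrix(reference)
  target <- as.matrix(target)
  k <- nrow(reference)
  if (k < 4) stopf("need at least 4 landmarks")
  if (!identical(dim(reference), dim(target))) {
    stopf("reference and target must have the same landmark count")
  }
  d2 <- as.matrix(stats::dist(reference))^2
  K <- tps_kernel(d2)
  Q <- cbind(1, reference)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  rhs <- rbind(target, matrix(0, 3, 2))
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    stopf("singular TPS system: reference landmarks are collinear or coincident")
  })
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:3, , drop = FALSE]
  B <- bending_energy_matrix(reference)
  be <- sum(diag(t(target) %*% B %*% target))
  structure(list(reference = reference, target = target, weights = W,
                 affine = A, bending_energy_matrix = B,
                 total_bending_energy = max(be, 0)),
            class = "tps_warp")
}

#' @export
print.tps_warp <- function(x, ...) {
  cat(sprintf("TPS warp: %d landmarks, total bending energy %.4g\n",
              nrow(x$reference), x$total_bending_energy))
  invisible(x)
}

#' Evaluate a TPS warp at arbitrary points
#'
#' @param object A [tps_fit()] result.
#' @param points `m x 2` matrix of locations in the reference plane.
#' @param ... Unused.
#' @return `m x 2` matrix of warped locations.
#' @export
predict.tps_warp <- function(object, points, ...) {
  pts <- as.matrix(points)
  d2 <- outer(rowSums(pts^2), rowSums(object$reference^2), `+`) -
    2 * pts %*% t(object$reference)
  d2 <- pmax(d2, 0)
  U <- tps_kernel(d2)
  cbind(1, pts) %*% object$affine + U %*% object$weights
}

#' Deformation grid of a TPS warp
#'
#' Regular lattice over the reference's bounding box (10% padding) warped
#' through the spline; purely presentational.
#'
#' @param warp A [tps_fit()] result.
#' @param n Lattice resolution per axis (default 25).
#' @param pad Bounding-box padding fraction (default 0.1).
#' @return Data frame with `ref_x`, `ref_y`, `x`, `y` (warped), `row`, `col`.
#' @export
deformation_grid <- function(warp, n = 25L, pad = 0.1) {
  rx <- range(warp$reference[, 1])
  ry <- range(warp$reference[, 2])
  rx <- rx + c(-1, 1) * pad * diff(rx)
  ry <- ry + c(-1, 1) * pad * diff(ry)
  gx <- seq(rx[1], rx[2], length.out = n)
  gy <- seq(ry[1], ry[2], length.out = n)
  pts <- as.matrix(expand.grid(ref_x = gx, ref_y = gy))
  wp <- predict(warp, pts)
  data.frame(ref_x = pts[, 1], ref_y = pts[, 2], x = wp[, 1], y = wp[, 2],
             row = rep(seq_len(n), each = n), col = rep(seq_len(n), n))
}

#' Relative warps of a GPA fit
#'
#' Principal components of the aligned shape residuals, optionally weighted
#' by the consensus bending-energy eigenstructure: each non-affine
#' eigendirection is scaled by `lambda^(-alpha/2)`, so `alpha = 0` (the
#' default) reproduces [shape_pca()] exactly, `alpha > 0` emphasizes
#' small-scale (high bending energy) deformation and `alpha < 0` large-scale
#' deformation. The affine subspace always passes with unit weight.
#'
#' @param x A [gpa()] result.
#' @param alpha Bending-energy weight exponent, `|alpha| <= 1`.
#' @return An object of class `relative_warps` with the [shape_pca()] fields
#'   plus `alpha` and `consensus`.
#' @export
relative_warps <- function(x, alpha = 0) {
  stopifnot(inherits(x, "gpa"))
  if (abs(alpha) > 1) stopf("'alpha' must be in [-1, 1]")
  n <- dim(x$aligned)[1]
  k <- dim(x$aligned)[2]
  flat <- matrix(x$aligned, nrow = n)
  colnames(flat) <- c(paste0("x", 1:k), paste0("y", 1:k))
  if (alpha == 0) {
    Gam <- diag(k)
  } else {
    B <- bending_energy_matrix(x$consensus)
    eb <- eigen(B, symmetric = TRUE)
    tol <- max(eb$values) * 1e-9
    nz <- eb$values > tol
    Enz <- eb$vectors[, nz, drop = FALSE]
    Ez <- eb$vectors[, !nz, drop = FALSE]   # nullspace = affine functions
    Gam <- Enz %*% diag(eb$values[nz]^(-alpha / 2), sum(nz)) %*% t(Enz) +
      Ez %*% t(Ez)
  }
  ctr <- colMeans(flat)
  res <- sweep(flat, 2, ctr)
  wres <- cbind(res[, 1:k] %*% t(Gam), res[, k + 1:k] %*% t(Gam))
  p <- stats::prcomp(wres, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  pct <- 100 * ev / sum(ev)
  structure(list(eigenvalues = ev, percent_variance = pct,
                 cumulative_percent = cumsum(pct), rotation = p$rotation,
                 scores = p$x, center = ctr, alpha = alpha,
                 consensus = x$consensus, groups = x$groups, ids = x$ids,
                 n_landmarks = k),
            class = c("relative_warps", "shape_pca"))
}

#' @export
print.relative_warps <- function(x, ...) {
  cat(sprintf("Relative warps (alpha = %g)\n", x$alpha))
  NextMethod()
}

#' Principal score ratio
#'
#' The group-level ratio of the tabulated extreme warp-deformation pair on a
#' shape principal component: the maximum-score extreme's magnitude divided
#' by the minimum-score extreme's magnitude, exactly as the pair is printed
#' (the "max" entry may be the smaller of the two, giving PSR below 1).
#'
#' @param max_magnitude,min_magnitude Extreme deformation magnitudes (may be
#'   vectors).
#' @return `max_magnitude / min_magnitude`; `Inf` with a warning when the
#'   minimum magnitude is zero.
#' @examples
#' psr(5.42, 1.96)  # 2.765...
#' @export
psr <- function(max_magnitude, min_magnitude) {
  if (any(min_magnitude == 0)) warnf("zero minimum magnitude: PSR is infinite")
  max_magnitude / min_magnitude
}

#' Per-group warp score summary
#'
#' For each group on one relative-warp axis: mean, SD, min and max of the raw
#' scores; the extreme deformation magnitude pair, defined as the square-root
#' bending energy of the thin-plate-spline warp from the consensus to the
#' shape reconstructed at the group's maximum (respectively minimum) score
#' along that axis; and the principal score ratio of the pair.
#'
#' @param x A [relative_warps()] (or [shape_pca()] with a consensus) result.
#' @param component Axis index (default 1).
#' @return Data frame with one row per group: `group`, `n`, `mean`, `sd`,
#'   `min`, `max`, `max_magnitude`, `min_magnitude`, `psr`.
#' @export
warp_score_summary <- function(x, component = 1L) {
  scores <- x$scores[, component]
  groups <- droplevels(x$groups)
  cons <- x$consensus
  if (is.null(cons)) stopf("need a relative_warps fit with a consensus shape")
  k <- x$n_landmarks
  load <- x$rotation[, component]
  B <- bending_energy_matrix(cons)
  deform <- function(s) {
    v <- matrix(x$center + s * load, k, 2)
    sqrt(max(0, sum(diag(t(v) %*% B %*% v))))
  }
  out <- do.call(rbind, lapply(levels(groups), function(gl) {
    s <- scores[groups == gl]
    mx <- deform(max(s))
    mn <- deform(min(s))
    data.frame(group = gl, n = length(s), mean = mean(s), sd = stats::sd(s),
               min = min(s), max = max(s), max_magnitude = mx,
               min_magnitude = mn, psr = psr(mx, mn),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Warp density score per group
#'
#' A group-level aggregate of warp scores on one axis: the sum over the
#' group's specimens of weight times score. Default weights are each
#' specimen's total bending energy (warp from the consensus to its aligned
#' shape), normalized to mean 1 so the score keeps the axis scale; pass
#' `weights = 1` for the unweighted sum. The aggregation formula is the
#' package's own choice and is recorded in the result's attributes.
#'
#' @param x A [relative_warps()] result.
#' @param component Axis index (default 1).
#' @param weights Per-specimen weights; `NULL` (default) for bending-energy
#'   weights, or a scalar/vector recycled over specimens.
#' @return Named numeric vector of per-group scores, with attributes
#'   `formula` and `weights`.
#' @export
warp_density_score <- function(x, component = 1L, weights = NULL) {
  scores <- x$scores[, component]
  groups <- droplevels(x$groups)
  n <- length(scores)
  k <- x$n_landmarks
  if (is.null(weights)) {
    B <- bending_energy_matrix(x$consensus)
    w <- vapply(seq_len(n), function(i) {
      v <- matrix(x$center + tcrossprod(x$scores[i, ], x$rotation)[1, ], k, 2)
      max(0, sum(diag(t(v) %*% B %*% v)))
    }, 0)
    if (mean(w) > 0) w <- w / mean(w)
    weights <- w
  } else {
    weights <- rep_len(weights, n)
  }
  out <- tapply(weights * scores, groups, sum)
  attr(out, "formula") <- "sum over group specimens of weight * score"
  attr(out, "weights") <- weights
  out
}

#' Escoufier RV coefficient between two coordinate blocks
#'
#' `RV = tr(S12 S21) / sqrt(tr(S11^2) tr(S22^2))` on the column-centered
#' blocks; always in `[0, 1]`, 1 for a block against itself.
#'
#' @param x,y Numeric matrices with the same number of rows.
#' @return Scalar RV.
#' @export
rv_coefficient <- function(x, y) {
  x <- scale(as.matrix(x), center = TRUE, scale = FALSE)
  y <- scale(as.matrix(y), center = TRUE, scale = FALSE)
  s12 <- crossprod(x, y)
  s11 <- crossprod(x)
  s22 <- crossprod(y)
  den <- sqrt(sum(s11^2) * sum(s22^2))
  if (den == 0) stopf("zero variance in a block")
  sum(s12^2) / den
}

#' Landmark-subset modularity via the RV coefficient
#'
#' Splits the aligned coordinates into the columns of `subset` and its
#' complement, computes the Escoufier RV between the blocks, and compares it
#' against alternative partitions of the same sizes: every contiguous
#' (cyclically consecutive) landmark window, plus `n_perm` random subsets.
#' The reported proportion is the fraction of alternatives with RV less than
#' or equal to the observed value (low proportions support modularity of the
#' hypothesized partition).
#'
#' @param x A [gpa()] result.
#' @param subset Landmark indices of the hypothesized module (e.g. the hump
#'   `c(1, 8, 9)` or the fin block `c(4, 5, 6)`).
#' @param n_perm Number of random alternative partitions (default 999).
#' @param seed Integer seed.
#' @return An object of class `rv_modularity` with `rv`, `subset`,
#'   `complement`, `alternatives` (RV values), `proportion_leq`.
#' @export
rv_modularity <- function(x, subset, n_perm = 999L, seed = 1L) {
  stopifnot(inherits(x, "gpa"))
  k <- dim(x$aligned)[2]
  subset <- sort(unique(as.integer(subset)))
  if (any(subset < 1 | subset > k)) stopf("subset indices out of range")
  comp <- setdiff(seq_len(k), subset)
  if (length(subset) < 2 || length(comp) < 2) {
    stopf("both blocks need at least 2 landmarks")
  }
  n <- dim(x$aligned)[1]
  flat <- matrix(x$aligned, nrow = n)   # x1..xk then y1..yk
  block <- function(idx) flat[, c(idx, k + idx), drop = FALSE]
  rv_of <- function(idx) rv_coefficient(block(idx), block(setdiff(seq_len(k), idx)))
  rv <- rv_of(subset)
  a <- length(subset)
  contiguous <- lapply(seq_len(k), function(s) sort((s + 0:(a - 1) - 1) %% k + 1))
  contiguous <- unique(contiguous)
  contiguous <- Filter(function(idx) !identical(idx, subset), contiguous)
  rand <- with_seed(seed, {
    replicate(n_perm, sort(sample(k, a)), simplify = FALSE)
  })
  alts <- vapply(c(contiguous, rand), rv_of, 0)
  structure(list(rv = rv, subset = subset, complement = comp,
                 alternatives = alts,
                 proportion_leq = mean(alts <= rv),
                 n_contiguous = length(contiguous), n_perm = n_perm,
                 seed = seed),
            class = "rv_modularity")
}

#' @export
print.rv_modularity <- function(x, ...) {
  cat(sprintf("RV modularity: subset {%s} vs {%s}\n",
              paste(x$subset, collapse = ","),
              paste(x$complement, collapse = ",")))
  cat(sprintf("RV = %.4f; %.1f%% of %d alternative partitions have RV <= observed\n",
              x$rv, 100 * x$proportion_leq,
              length(x$alternatives)))
  invisible(x)
}
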