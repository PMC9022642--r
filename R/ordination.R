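#' Principal component analysis of a truss table
#'
#' PCA of the correlation matrix (all variables standardized), with Kaiser
#' retention: components whose eigenvalue exceeds 1 are flagged as retained.
#' Loadings are reported as variable-component correlations
#' (eigenvector times sqrt(eigenvalue)), and each component's sign is fixed so
#' its largest-magnitude loading is positive, making tables reproducible.
#'
#' @param table A [truss_table()].
#' @param loading_threshold Absolute loading above which a loading is flagged
#'   as significant in the summary (reported, never filtered on).
#' @return An object of class `truss_pca` with `eigenvalues`,
#'   `percent_variance`, `cumulative_percent`, `loadings`
#'   (variables x components), `scores` (specimens x components, standardized
#'   variables), `n_retained`, `groups`.
#' @examples
#' tt <- truss_distances(generate_dataset(shape_model(group_sizes = c(8, 8))))
#' p <- truss_pca(tt)
#' p$n_retained
#' @export
truss_pca <- function(table, loading_threshold = 0.13) {
  stopifnot(inherits(table, "truss_table"))
  x <- table$values
  if (ncol(x) < 2) stopf("need at least 2 variables")
  if (nrow(x) < 3) stopf("need at least 3 specimens")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("constant variable(s): %s",
          paste(colnames(x)[sds == 0], collapse = ", "))
  }
  z <- scale(x)
  e <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  vec <- e$vectors
  # sign convention: largest-|loading| entry positive per component
  for (j in seq_len(ncol(vec))) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  loadings <- vec %*% diag(sqrt(ev), length(ev))
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_along(ev)))
  scores <- z %*% vec
  colnames(scores) <- colnames(loadings)
  pct <- 100 * ev / sum(ev)
  structure(
    list(eigenvalues = ev, percent_variance = pct,
         cumulative_percent = cumsum(pct), loadings = loadings,
         rotation = vec, scores = scores, sds = sds,
         n_retained = sum(ev > 1), loading_threshold = loading_threshold,
         groups = table$groups, ids = table$ids),
    class = "truss_pca"
  )
}

#' @export
print.truss_pca <- function(x, ...) {
  cat(sprintf("Correlation-matrix PCA: %d variables, %d components retained (eigenvalue > 1)\n",
              nrow(x$loadings), x$n_retained))
  df <- data.frame(eigenvalue = round(x$eigenvalues, 2),
                   pct_variance = round(x$percent_variance, 2),
                   cumulative = round(x$cumulative_percent, 2))
  print(utils::head(df, max(x$n_retained, 6L)))
  invisible(x)
}

#' @export
summary.truss_pca <- function(object, ...) {
  thr <- object$loading_threshold
  sig <- abs(object$loadings) > thr
  cat(sprintf("Retained components: %d; cumulative variance %.2f%%\n",
              object$n_retained,
              object$cumulative_percent[object$n_retained]))
  cat(sprintf("Loadings flagged significant at |loading| > %g per retained component:\n", thr))
  for (j in seq_len(object$n_retained)) {
    vars <- rownames(object$loadings)[sig[, j]]
    cat(sprintf("  PC%d: %s\n", j, paste(vars, collapse = " ")))
  }
  invisible(object)
}

#' @export
plot.truss_pca <- function(x, components = c(1, 2), ...) {
  s <- x$scores[, components, drop = FALSE]
  graphics::plot(s, col = as.integer(x$groups), pch = 19,
                 xlab = sprintf("PC%d (%.1f%%)", components[1],
                                x$percent_variance[components[1]]),
                 ylab = sprintf("PC%d (%.1f%%)", components[2],
                                x$percent_variance[components[2]]), ...)
  graphics::legend("topright", legend = levels(x$groups), pch = 19,
                   col = seq_len(nlevels(x$groups)), cex = 0.8)
  invisible(x)
}
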