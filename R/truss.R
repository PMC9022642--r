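#' Truss distance table
#'
#' Container for the full truss network: every unordered inter-landmark
#' Euclidean distance, named `"i_j"` with `i < j` landmark indices. For the
#' 9-landmark schema this is 36 variables, of which `1_4` (snout to vertebral
#' end) is the standard length (SL); the allometric adjustment removes it,
#' leaving the 35 analysis variables.
#'
#' @param values Numeric specimens x variables matrix with `"i_j"` column
#'   names.
#' @param ids,groups Specimen identifiers and group labels.
#' @param state One of `"raw"`, `"log"`, `"size_adjusted"`.
#' @param sl_var Name of the standard-length variable (default `"1_4"`).
#' @return An object of class `truss_table`.
#' @export
truss_table <- function(values, ids, groups, state = "raw", sl_var = "1_4") {
  values <- as.matrix(values)
  state <- match.arg(state, c("raw", "log", "size_adjusted"))
  if (is.null(colnames(values)) ||
      !all(grepl("^[0-9]+_[0-9]+$", colnames(values)))) {
    stopf("truss variables must be named 'i_j' with landmark indices")
  }
  ids <- as.character(ids)
  if (length(ids) != nrow(values)) stopf("'ids' must match rows of 'values'")
  if (anyDuplicated(ids)) stopf("duplicated specimen ids")
  groups <- factor(groups)
  if (length(groups) != nrow(values)) stopf("'groups' must match rows")
  if (state == "raw" && any(values < 0)) stopf("raw distances must be >= 0")
  rownames(values) <- ids
  structure(list(values = values, ids = ids, groups = groups, state = state,
                 sl_var = sl_var),
            class = "truss_table")
}

#' @export
print.truss_table <- function(x, ...) {
  cat(sprintf("Truss table: %d specimens x %d variables (%s)\n",
              nrow(x$values), ncol(x$values), x$state))
  cat(sprintf("Groups: %s\n",
              paste(sprintf("%s (%d)", levels(x$groups), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.truss_table <- function(x, ...) {
  data.frame(id = x$ids, group = as.character(x$groups), x$values,
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Build the truss network from landmarks
#'
#' Computes the Euclidean distance between every unordered pair of landmarks
#' (the fully interconnected truss): `n(n-1)/2` variables, 36 for the
#' 9-landmark schema. Distances are invariant to specimen ordering and to
#' global rotation/translation of the configurations.
#'
#' @param data A [landmark_dataset()].
#' @return A raw-state [truss_table()].
#' @examples
#' d <- generate_dataset(shape_model(group_sizes = c(5, 5), seed = 1))
#' tt <- truss_distances(d)
#' ncol(tt$values)  # 36
#' @export
truss_distances <- function(data) {
  stopifnot(inherits(data, "landmark_dataset"))
  k <- n_landmarks(data)
  if (k < 3) stopf("need at least 3 landmarks")
  pr <- all_pairs(k)
  vals <- vapply(seq_len(nrow(pr)), function(r) {
    dx <- data$coords[, pr[r, 1], 1] - data$coords[, pr[r, 2], 1]
    dy <- data$coords[, pr[r, 1], 2] - data$coords[, pr[r, 2], 2]
    sqrt(dx^2 + dy^2)
  }, numeric(n_specimens(data)))
  vals <- matrix(vals, nrow = n_specimens(data))
  colnames(vals) <- pair_name(pr[, 1], pr[, 2])
  if (any(vals == 0)) {
    warnf("coincident landmarks: %d zero distance(s) in the truss table",
          sum(vals == 0))
  }
  truss_table(vals, data$ids, data$groups, "raw")
}

#' Base-10 log transform of a truss table
#'
#' @param table A [truss_table()] with strictly positive values.
#' @return The table with `log10` values and state `"log"`.
#' @export
log_transform <- function(table) {
  stopifnot(inherits(table, "truss_table"))
  bad <- which(table$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("nonpositive value for specimen %s, variable %s",
          table$ids[bad[1, 1]], colnames(table$values)[bad[1, 2]])
  }
  truss_table(log10(table$values), table$ids, table$groups, "log",
              table$sl_var)
}

#' Fit the allometric growth model (Elliott)
#'
#' For each truss variable M, estimates the growth exponent b as the slope of
#' the pooled ordinary least-squares regression of `log10(M)` on
#' `log10(L0)`, where `L0` is each specimen's standard length (variable
#' `1_4`). Also records `Ls`, the overall mean standard length used as the
#' common size all measurements are adjusted to.
#'
#' @param table A raw-state [truss_table()] containing the SL variable.
#' @param pooled_within If `TRUE`, estimate a common within-group slope
#'   (group-centred regression) instead of the pooled slope; provided for
#'   sensitivity analysis.
#' @return An object of class `allometric_model` with `b` (named per
#'   variable), `Ls`, `L0` (per specimen) and `ids`.
#' @export
fit_allometry <- function(table, pooled_within = FALSE) {
  stopifnot(inherits(table, "truss_table"))
  if (table$state != "raw") stopf("allometry is fitted on the raw table")
  if (!table$sl_var %in% colnames(table$values)) {
    stopf("standard-length variable %s not present", table$sl_var)
  }
  L0 <- table$values[, table$sl_var]
  if (any(L0 <= 0)) {
    stopf("nonpositive standard length for specimen %s",
          table$ids[which(L0 <= 0)[1]])
  }
  if (stats::var(L0) == 0) stopf("standard length has zero variance; cannot fit b")
  bad <- which(table$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("nonpositive measurement for specimen %s, variable %s",
          table$ids[bad[1, 1]], colnames(table$values)[bad[1, 2]])
  }
  x <- log10(L0)
  y <- log10(table$values)
  if (pooled_within) {
    g <- table$groups
    x <- x - ave(x, g)
    y <- y - apply(y, 2, function(col) ave(col, g))
  }
  xc <- x - mean(x)
  b <- as.vector(crossprod(xc, sweep(y, 2, colMeans(y))) / sum(xc^2))
  names(b) <- colnames(table$values)
  structure(list(b = b, Ls = mean(L0), L0 = L0, ids = table$ids,
                 pooled_within = pooled_within),
            class = "allometric_model")
}

#' @export
print.allometric_model <- function(x, ...) {
  cat(sprintf("Allometric model (%s slopes): %d variables, Ls = %.2f mm\n",
              if (x$pooled_within) "pooled-within" else "pooled",
              length(x$b), x$Ls))
  cat(sprintf("b range: %.3f to %.3f\n", min(x$b), max(x$b)))
  invisible(x)
}

#' Allometric size adjustment (M-trans)
#'
#' Rescales every measurement to the common size `Ls` via
#' `M_adj = M * (Ls / L0)^b` with that variable's fitted exponent, then drops
#' the standard-length variable itself (it is constant `Ls` after adjustment),
#' leaving 35 analysis variables in the 9-landmark schema.
#'
#' @param table A raw-state [truss_table()].
#' @param model The matching [fit_allometry()] result.
#' @return A [truss_table()] with state `"size_adjusted"`.
#' @export
size_adjust <- function(table, model) {
  stopifnot(inherits(table, "truss_table"), inherits(model, "allometric_model"))
  if (table$state != "raw") stopf("size adjustment applies to the raw table")
  if (!identical(model$ids, table$ids)) {
    stopf("allometric model was fitted on different specimens")
  }
  fac <- model$Ls / model$L0
  vars <- colnames(table$values)
  adj <- table$values * outer(fac, model$b[vars], `^`)
  adj <- adj[, setdiff(vars, table$sl_var), drop = FALSE]
  truss_table(adj, table$ids, table$groups, "size_adjusted", table$sl_var)
}

#' One-way ANOVA screen across groups
#'
#' Classical fixed-effects one-way ANOVA per truss variable, flagging the
#' variables whose group differences are significant at `alpha`. Also reports
#' the N/P ratio (specimens per retained variable) against the 3.5-8 band
#' recommended for stable multivariate analysis.
#'
#' @param table A [truss_table()] (any state).
#' @param alpha Significance level for the keep flag (default 0.01).
#' @param drop_nonsig If `TRUE`, also return the table reduced to the
#'   significant variables; by default all variables are retained and the
#'   screen is purely a report.
#' @return An object of class `anova_screen` with a per-variable data frame
#'   (`F`, `p`, `keep`), `n_kept`, `np_ratio`, `np_in_band`, and (optionally)
#'   `reduced` table.
#' @export
anova_screen <- function(table, alpha = 0.01, drop_nonsig = FALSE) {
  stopifnot(inherits(table, "truss_table"))
  g <- droplevels(table$groups)
  if (nlevels(g) < 2) stopf("need at least 2 groups")
  if (any(table(g) < 2)) {
    stopf("group(s) with fewer than 2 specimens: %s",
          paste(names(which(table(g) < 2)), collapse = ", "))
  }
  res <- t(apply(table$values, 2, function(v) {
    a <- stats::anova(stats::lm(v ~ g))
    c(F = a[1, "F value"], p = a[1, "Pr(>F)"])
  }))
  screen <- data.frame(variable = rownames(res), F = res[, "F"], p = res[, "p"],
                       keep = res[, "p"] < alpha, row.names = NULL)
  n_kept <- sum(screen$keep)
  ratio <- nrow(table$values) / ncol(table$values)
  out <- list(screen = screen, alpha = alpha, n_kept = n_kept,
              np_ratio = ratio, np_in_band = ratio >= 3.5 && ratio <= 8)
  if (drop_nonsig) {
    keep_vars <- screen$variable[screen$keep]
    out$reduced <- truss_table(table$values[, keep_vars, drop = FALSE],
                               table$ids, table$groups, table$state,
                               table$sl_var)
  }
  class(out) <- "anova_screen"
  out
}

#' @export
print.anova_screen <- function(x, ...) {
  cat(sprintf("One-way ANOVA screen: %d/%d variables significant at alpha = %g\n",
              x$n_kept, nrow(x$screen), x$alpha))
  cat(sprintf("N/P ratio = %.2f (%s the recommended 3.5-8 band)\n",
              x$np_ratio, if (x$np_in_band) "inside" else "outside"))
  invisible(x)
}
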