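#' Landmark dataset container
#'
#' Bundles a set of digitized 2D landmark configurations with specimen ids,
#' group (sampling location) labels and the mm-per-unit scale calibration that
#' was applied. Coordinates are stored calibrated, in mm, as an
#' `n x k x 2` array (specimens x landmarks x (x, y)).
#'
#' @param coords Numeric array `n x k x 2`, or a list of `k x 2` matrices.
#' @param ids Character vector of unique specimen identifiers.
#' @param groups Character vector (or factor) of group labels, one per specimen.
#' @param scale Numeric vector of mm-per-unit calibration factors used to
#'   produce `coords` (recorded for provenance; coordinates are already in mm).
#'   Recycled if length 1.
#' @param require_k Integer; if non-`NULL`, enforce this landmark count.
#'
#' @return An object of class `landmark_dataset` with elements `coords`,
#'   `ids`, `groups` (factor) and `scale`.
#' @examples
#' m <- shape_model(group_sizes = c(5, 5), noise_sd = 0.2, seed = 1)
#' d <- generate_dataset(m)
#' d
#' @export
landmark_dataset <- function(coords, ids, groups, scale = 1, require_k = NULL) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (length(dim(coords)) != 3L || dim(coords)[3] != 2L) {
    stopf("'coords' must be an n x k x 2 array of 2D landmarks")
  }
  n <- dim(coords)[1]
  k <- dim(coords)[2]
  if (!is.null(require_k) && k != require_k) {
    stopf("expected %d landmarks per specimen, found %d", require_k, k)
  }
  ids <- as.character(ids)
  if (length(ids) != n) stopf("'ids' must have one entry per specimen")
  if (anyDuplicated(ids)) {
    stopf("duplicated specimen id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  groups <- factor(groups)
  if (length(groups) != n) stopf("'groups' must have one entry per specimen")
  scale <- rep_len(as.numeric(scale), n)
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stopf("'scale' must be positive and finite")
  }
  if (anyNA(coords) || any(!is.finite(coords))) {
    stopf("landmark coordinates must be finite")
  }
  dimnames(coords) <- list(ids, paste0("lm", seq_len(k)), c("x", "y"))
  structure(
    list(coords = coords, ids = ids, groups = groups, scale = scale),
    class = "landmark_dataset"
  )
}

#' @export
print.landmark_dataset <- function(x, ...) {
  k <- dim(x$coords)[2]
  cat(sprintf("Landmark dataset: %d specimens, %d landmarks (2D)\n",
              length(x$ids), k))
  tab <- table(x$groups)
  cat("Groups:\n")
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.landmark_dataset <- function(x, ...) {
  k <- dim(x$coords)[2]
  flat <- matrix(aperm(x$coords, c(1, 3, 2)), nrow = length(x$ids))
  # columns interleaved x1, y1, x2, y2, ...
  colnames(flat) <- as.vector(rbind(paste0("x", seq_len(k)),
                                    paste0("y", seq_len(k))))
  data.frame(id = x$ids, group = as.character(x$groups), flat,
             scale = x$scale, stringsAsFactors = FALSE)
}

#' Number of specimens / landmarks
#' @param x A `landmark_dataset`.
#' @return `n_specimens`: integer count of specimens; `n_landmarks`: integer
#'   count of landmarks per specimen.
#' @export
n_specimens <- function(x) length(x$ids)

#' @rdname n_specimens
#' @export
n_landmarks <- function(x) dim(x$coords)[2]

# subset specimens, keeping invariants
subset_dataset <- function(x, keep) {
  landmark_dataset(x$coords[keep, , , drop = FALSE], x$ids[keep],
                   droplevels(x$groups[keep]), x$scale[keep])
}
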