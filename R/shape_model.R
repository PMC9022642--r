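#' Stylized knifefish landmark template
#'
#' A hard-coded 9-landmark planar configuration with the landmark roles used
#' throughout the package: 1 snout tip, 2 nape (posterior neurocranium),
#' 3 dorsal-fin origin, 4 posterior end of the vertebral column, 5 point on the
#' anal fin perpendicular to the dorsal-fin origin, 6 anal-fin origin,
#' 7 pectoral-fin insertion, 8 posterior end of the maxilla, 9 point
#' perpendicular to the maxilla end. The template is expressed in units of
#' standard length (distance from landmark 1 to landmark 4 equals 1), y up,
#' mouth facing left-to-right along +x.
#'
#' @return A `9 x 2` numeric matrix with row names naming the landmark roles.
#' @examples
#' plot(knifefish_template(), asp = 1, type = "n")
#' text(knifefish_template(), labels = 1:9)
#' @export
knifefish_template <- function() {
  m <- matrix(c(
    0.00, 0.300,  # 1 snout tip
    0.26, 0.480,  # 2 nape, start of the humped back
    0.55, 0.430,  # 3 dorsal-fin origin
    1.00, 0.300,  # 4 posterior end of vertebral column
    0.55, 0.050,  # 5 on anal fin, perpendicular below dorsal-fin origin
    0.38, 0.020,  # 6 anal-fin origin
    0.21, 0.130,  # 7 pectoral-fin insertion
    0.12, 0.230,  # 8 posterior end of maxilla
    0.12, 0.020   # 9 perpendicular below maxilla end
  ), ncol = 2, byrow = TRUE)
  rownames(m) <- c("snout", "nape", "dorsal_origin", "vertebral_end",
                   "perp_dorsal", "anal_origin", "pectoral", "maxilla_end",
                   "perp_maxilla")
  colnames(m) <- c("x", "y")
  m
}

#' Generative model for multi-group landmark data
#'
#' Describes the simulator used for all in-package testing: each group has a
#' mean shape equal to a common template plus a group-specific per-landmark
#' offset; each specimen gets a standard length drawn uniformly from
#' `size_range`, the mean shape scaled to that size (with optional
#' non-isometric growth at one landmark), and isotropic Gaussian digitization
#' noise added to every coordinate.
#'
#' @param base_shape `k x 2` template in standard-length units (distance
#'   between landmarks 1 and 4 should be 1 so the size factor is the standard
#'   length in mm). Default [knifefish_template()].
#' @param group_offsets List (one per group) of `k x 2` matrices of mean-shape
#'   displacements in template units, applied before scaling. Default: zero
#'   offsets for every group.
#' @param allometry_b Growth exponent for the designated allometric landmark;
#'   1 = isometric growth (default).
#' @param allometry_landmark Index of the landmark whose displacement from the
#'   body centroid grows as `size^allometry_b`; only used when
#'   `allometry_b != 1`.
#' @param size_range Length-2 numeric, min < max standard length in mm.
#' @param noise_sd Digitization noise SD in mm (per coordinate, isotropic).
#' @param group_sizes Integer vector of specimens per group, all `>= 2`.
#' @param group_names Optional character vector of group labels.
#' @param seed Integer seed making [generate_dataset()] deterministic.
#'
#' @return An object of class `shape_model`.
#' @seealso [generate_dataset()], [known_truth()], [study_design_model()]
#' @export
shape_model <- function(base_shape = knifefish_template(),
                        group_offsets = NULL,
                        allometry_b = 1,
                        allometry_landmark = 3L,
                        size_range = c(250, 600),
                        noise_sd = 0.5,
                        group_sizes = c(10, 10),
                        group_names = NULL,
                        seed = 1L) {
  base_shape <- as.matrix(base_shape)
  if (ncol(base_shape) != 2L) stopf("'base_shape' must be a k x 2 matrix")
  k <- nrow(base_shape)
  g <- length(group_sizes)
  if (g < 1L || sum(group_sizes) == 0) stopf("'group_sizes' must be nonempty")
  if (any(group_sizes < 2)) stopf("every group needs at least 2 specimens")
  if (is.null(group_offsets)) {
    group_offsets <- replicate(g, matrix(0, k, 2), simplify = FALSE)
  }
  if (length(group_offsets) != g) {
    stopf("'group_offsets' must have one k x 2 matrix per group")
  }
  group_offsets <- lapply(group_offsets, function(o) {
    o <- as.matrix(o)
    if (!identical(dim(o), dim(base_shape))) {
      stopf("each group offset must match the %d x 2 template", k)
    }
    o
  })
  if (length(size_range) != 2L || size_range[1] >= size_range[2] ||
      any(size_range <= 0)) {
    stopf("'size_range' must be (min, max) with 0 < min < max")
  }
  if (noise_sd < 0) stopf("'noise_sd' must be >= 0")
  if (is.null(group_names)) group_names <- paste0("G", seq_len(g))
  structure(
    list(base_shape = base_shape, group_offsets = group_offsets,
         allometry_b = allometry_b,
         allometry_landmark = as.integer(allometry_landmark),
         size_range = as.numeric(size_range), noise_sd = noise_sd,
         group_sizes = as.integer(group_sizes),
         group_names = as.character(group_names), seed = as.integer(seed)),
    class = "shape_model"
  )
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf(
    "Shape model: %d landmarks, %d groups (n = %s), SL %g-%g mm, noise sd %g mm, b = %g\n",
    nrow(x$base_shape), length(x$group_sizes),
    paste(x$group_sizes, collapse = "/"),
    x$size_range[1], x$size_range[2], x$noise_sd, x$allometry_b))
  invisible(x)
}

# mean configuration of group g at standard length s (no noise)
model_mean_config <- function(model, g, s) {
  shp <- model$base_shape + model$group_offsets[[g]]
  out <- s * shp
  b <- model$allometry_b
  if (b != 1) {
    ctr <- colMeans(shp)
    al <- model$allometry_landmark
    # displacement of the allometric landmark from the body centroid grows
    # as s^b instead of s; s is in mm so b != 1 bends the size trajectory
    out[al, ] <- s * ctr + (shp[al, ] - ctr) * s^b
  }
  out
}

#' Simulate a landmark dataset from a shape model
#'
#' Deterministic for a fixed `model$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param model A [shape_model()].
#' @return A [landmark_dataset()] with specimens labelled
#'   `<group>_<number>`, coordinates in mm and `scale = 1` (already
#'   calibrated).
#' @examples
#' d <- generate_dataset(shape_model(group_sizes = c(5, 5), seed = 7))
#' table(d$groups)
#' @export
generate_dataset <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  n <- sum(model$group_sizes)
  k <- nrow(model$base_shape)
  g <- length(model$group_sizes)
  with_seed(model$seed, {
    sizes <- stats::runif(n, model$size_range[1], model$size_range[2])
    noise <- array(stats::rnorm(n * k * 2, sd = model$noise_sd), c(n, k, 2))
    coords <- array(NA_real_, c(n, k, 2))
    grp <- rep(seq_len(g), model$group_sizes)
    for (i in seq_len(n)) {
      coords[i, , ] <- model_mean_config(model, grp[i], sizes[i]) +
        noise[i, , ]
    }
    ids <- unlist(lapply(seq_len(g), function(j) {
      sprintf("%s_%02d", model$group_names[j], seq_len(model$group_sizes[j]))
    }))
    landmark_dataset(coords, ids, model$group_names[grp], scale = 1)
  })
}

#' Ground truth implied by a shape model
#'
#' Returns the exact (noise-free) group mean shapes and the pairwise full
#' Procrustes distances between them, for parameter-recovery tests. The truth
#' depends only on the template and offsets, never on the seed.
#'
#' @param model A [shape_model()].
#' @return A list with `mean_shapes` (list of `k x 2` matrices, one per group,
#'   at unit size) and `procrustes_distances` (symmetric `g x g` matrix of
#'   full Procrustes distances between group mean shapes).
#' @export
known_truth <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  g <- length(model$group_sizes)
  shapes <- lapply(seq_len(g), function(j) {
    model$base_shape + model$group_offsets[[j]]
  })
  names(shapes) <- model$group_names
  d <- matrix(0, g, g, dimnames = list(model$group_names, model$group_names))
  if (g > 1) {
    for (a in seq_len(g - 1)) {
      for (b in (a + 1):g) {
        d[a, b] <- d[b, a] <- procrustes_distance(shapes[[a]], shapes[[b]])
      }
    }
  }
  list(mean_shapes = shapes, procrustes_distances = d)
}

#' The study's sampling design as a shape model
#'
#' Convenience constructor reproducing the sampling structure the package's
#' tests emulate: seven river populations of unequal size
#' (43, 16, 31, 16, 13, 20, 10 specimens; 149 in total), nine landmarks,
#' group-specific mean-shape offsets concentrated on the hump and fin
#' landmarks, standard lengths 250-600 mm and 0.5 mm digitization noise.
#'
#' @param separation Scale factor (template units) applied to the built-in
#'   group offset directions; 0 gives identical group mean shapes.
#' @param noise_sd Digitization noise SD in mm.
#' @param seed Integer seed.
#' @return A [shape_model()].
#' @export
study_design_model <- function(separation = 0.004, noise_sd = 0.5, seed = 42L) {
  k <- 9L
  groups <- c("Son", "Tons", "Ken", "Brahmaputra", "Ganga", "Gomti", "Gandak")
  sizes <- c(43L, 16L, 31L, 16L, 13L, 20L, 10L)
  # one displacement direction per group, touching the hump (2, 3), the fin
  # landmarks (5, 6, 7) and the head (1, 8, 9) so both landmark-subset modules
  # carry signal
  dirs <- list(
    Son         = list(c(3,  0,  1), c(5,  1,  0)),
    Tons        = list(c(2,  0,  1), c(6, -1,  0)),
    Ken         = list(c(5,  0, -1), c(8,  1,  0)),
    Brahmaputra = list(c(7, -1,  0), c(2,  0, -1)),
    Ganga       = list(c(9,  0,  1), c(3, -1,  0)),
    Gomti       = list(c(6,  0, -1), c(1,  0,  1)),
    Gandak      = list(c(4,  0,  1), c(5, -1, -1))
  )
  offsets <- lapply(dirs, function(dd) {
    o <- matrix(0, k, 2)
    for (d in dd) o[d[1], ] <- o[d[1], ] + separation * d[2:3]
    o
  })
  shape_model(group_offsets = unname(offsets), size_range = c(250, 600),
              noise_sd = noise_sd, group_sizes = sizes, group_names = groups,
              seed = seed)
}
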