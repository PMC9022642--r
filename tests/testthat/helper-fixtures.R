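# Fixtures built in code; no stored data.

make_dataset <- function(coord_list, groups = NULL) {
  n <- length(coord_list)
  if (is.null(groups)) groups <- rep(c("a", "b"), length.out = n)
  landmark_dataset(coord_list, paste0("s", seq_len(n)), groups)
}

# right 3-4-5 triangle padded with extra landmarks up to k points
padded_triangle <- function(k = 9, jitter_seed = NULL) {
  base <- rbind(c(0, 0), c(3, 0), c(0, 4))
  extra <- cbind(seq(0.5, 2.5, length.out = k - 3),
                 seq(3, 0.5, length.out = k - 3))
  m <- rbind(base, extra)
  if (!is.null(jitter_seed)) {
    set.seed(jitter_seed)
    m <- m + matrix(rnorm(2 * k, sd = 0.3), k, 2)
  }
  m
}

# apply a similarity transform (rotation deg, scale, translation)
similarity_transform <- function(m, angle_deg = 0, scale = 1, shift = c(0, 0)) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(scale * m %*% R, 2, -shift)
}

# tiny two-group dataset with a known single-landmark offset (template units)
two_group_model <- function(n = 10, d = 0.02, landmark = 3, noise = 0,
                            seed = 1) {
  off <- matrix(0, 9, 2)
  off[landmark, 2] <- d
  shape_model(group_offsets = list(matrix(0, 9, 2), off),
              noise_sd = noise, group_sizes = c(n, n),
              size_range = c(300, 500), seed = seed)
}

# brute-force AUC by pair counting (ties count 1/2)
auc_brute <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# full Procrustes distance by grid search over the rotation angle
proc_dist_grid <- function(x, y, step = 1e-5) {
  cx <- sweep(x, 2, colMeans(x)); cx <- cx / sqrt(sum(cx^2))
  cy <- sweep(y, 2, colMeans(y)); cy <- cy / sqrt(sum(cy^2))
  A <- crossprod(cy, cx)
  th <- seq(0, 2 * pi, by = step)
  tr <- cos(th) * (A[1, 1] + A[2, 2]) + sin(th) * (A[2, 1] - A[1, 2])
  T <- min(max(tr), 1)
  sqrt(max(0, 1 - T^2))
}
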