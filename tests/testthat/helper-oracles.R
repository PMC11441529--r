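# Independent brute-force oracles used to verify the package's
# implementations.  These deliberately use different algorithms from the
# code under test.

# Minimum-image distance by explicit enumeration of all 27 periodic
# images.
oracle_min_image <- function(a, b, box) {
  shifts <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  min(sqrt(colSums((t(shifts * rep(box, each = 27)) + (b - a))^2)))
}

# Superposition RMSD via the quaternion (Theobald key-matrix) method.
oracle_quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- t(A) %*% B
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)))
}

# Maximal true runs by a plain which()-based boundary scan.
oracle_true_runs <- function(states) {
  idx <- which(states)
  if (!length(idx)) return(data.frame(formed_frame = integer(0),
                                      broken_frame = integer(0)))
  brk <- which(diff(idx) > 1)
  data.frame(formed_frame = idx[c(1, brk + 1)],
             broken_frame = idx[c(brk, length(idx))])
}

# Permeation counting by collapsing the label sequence to a
# below/inside/above string and counting "BIA"/"AIB" patterns.
oracle_permeation_counts <- function(labels) {
  cls <- ifelse(labels == "below", "B", ifelse(labels == "above", "A", "I"))
  s <- paste(rle(cls)$values, collapse = "")
  up <- length(gregexpr("BIA", s, fixed = TRUE)[[1]])
  if (!grepl("BIA", s, fixed = TRUE)) up <- 0L
  down <- length(gregexpr("AIB", s, fixed = TRUE)[[1]])
  if (!grepl("AIB", s, fixed = TRUE)) down <- 0L
  c(up = as.integer(up), down = as.integer(down))
}

# Monte-Carlo Shrake-Rupley for one atom: random test points instead of
# the deterministic spiral.
oracle_mc_sasa <- function(center, radius, nb_centers, nb_radii, n_mc) {
  p <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
  p <- p / sqrt(rowSums(p * p)) * radius
  p <- sweep(p, 2, center, "+")
  acc <- rep(TRUE, n_mc)
  if (length(nb_radii)) for (j in seq_along(nb_radii)) {
    d2 <- rowSums(sweep(p, 2, nb_centers[j, ])^2)
    acc <- acc & d2 >= nb_radii[j]^2
  }
  4 * pi * radius^2 * mean(acc)
}

# Pore radius in a slice by exhaustive grid search.
oracle_grid_pore_radius <- function(z, coords, vdw, center, half_width = 6,
                                    spacing = 0.1) {
  g <- seq(-half_width, half_width, by = spacing)
  pts <- as.matrix(expand.grid(x = center[1] + g, y = center[2] + g))
  best <- -Inf
  chunk <- 4000
  for (s in seq(1, nrow(pts), by = chunk)) {
    p <- pts[s:min(nrow(pts), s + chunk - 1), , drop = FALSE]
    dx <- outer(p[, 1], coords[, 1], "-")
    dy <- outer(p[, 2], coords[, 2], "-")
    dz2 <- (z - coords[, 3])^2
    d <- sqrt(dx * dx + dy * dy + rep(dz2, each = nrow(p))) -
      rep(vdw, each = nrow(p))
    dim(d) <- dim(dx)
    best <- max(best, max(apply(d, 1, min)))
  }
  best
}

# Adjusted-for-chance-free Rand index of two partitions.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
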