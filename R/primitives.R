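# Geometric primitives: minimum-image distances and least-squares
# superposition (Kabsch).

#' Minimum-image distance under an orthorhombic box
#'
#' Accepts single 3-vectors or n x 3 matrices (row-wise pairing, with
#' recycling of a single row); `box` is a length-3 vector or an n x 3
#' matrix.  Symmetric in its two arguments and never exceeds half the box
#' diagonal.
#'
#' @param a,b Coordinates in Angstrom.
#' @param box Orthorhombic box lengths (Lx, Ly, Lz) in Angstrom.
#' @return Numeric vector of distances in Angstrom.
#' @export
#' @examples
#' min_image_distance(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10))  # 1
min_image_distance <- function(a, b, box) {
  d <- min_image_displacement(a, b, box)
  unname(sqrt(rowSums(d * d)))
}

# Row-wise minimum-image displacement vectors b -> a.
min_image_displacement <- function(a, b, box) {
  a <- rbind(a); b <- rbind(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1) a <- a[rep(1, n), , drop = FALSE]
  if (nrow(b) == 1) b <- b[rep(1, n), , drop = FALSE]
  if (is.null(dim(box))) box <- matrix(box, n, 3, byrow = TRUE)
  if (any(box <= 0)) stopf("box lengths must be positive")
  d <- a - b
  d - box * round(d / box)
}

# Wrap coordinates into [0, L) per axis.
wrap_coords <- function(xyz, box) {
  xyz - box * floor(xyz / box)
}

#' Least-squares superposition and RMSD
#'
#' With `fit = TRUE`, finds the proper rotation (Kabsch, via SVD) and
#' translation minimising the RMSD of `mobile` onto `reference`, then
#' reports that minimal RMSD.  With `fit = FALSE`, reports the raw RMSD
#' of the coordinates as given.
#'
#' @param mobile,reference n x 3 coordinate matrices, equal row counts.
#' @param fit Superpose before measuring?
#' @return List with `rmsd` (Angstrom), `rotation` (3 x 3, determinant
#'   +1), and `translation` (length 3); the fitted mobile coordinates are
#'   `mobile %*% rotation + translation` (row-wise).
#' @export
superpose_rmsd <- function(mobile, reference, fit = TRUE) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  if (nrow(mobile) != nrow(reference))
    stopf("point counts differ: %d vs %d", nrow(mobile), nrow(reference))
  if (!fit) {
    d <- mobile - reference
    return(list(rmsd = sqrt(mean(rowSums(d * d))),
                rotation = diag(3), translation = c(0, 0, 0)))
  }
  if (nrow(mobile) < 3)
    stopf("superposition requires at least 3 points")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  m <- sweep(mobile, 2, mc); r <- sweep(reference, 2, rc)
  s <- svd(crossprod(m, r))       # H = t(m) %*% r = U D t(V)
  dsign <- sign(det(s$u) * det(s$v))
  if (dsign == 0) dsign <- 1
  rot <- s$u %*% diag(c(1, 1, dsign)) %*% t(s$v)
  fitted <- m %*% rot
  d <- fitted - r
  list(rmsd = sqrt(mean(rowSums(d * d))), rotation = rot,
       translation = rc - as.vector(mc %*% rot))
}
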