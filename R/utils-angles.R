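## Angular helpers shared across the package.  All user-facing angles are in
## degrees on (-180, 180], 0 deg = cis, following the IUPAC convention.

#' Wrap angles to the interval (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped to `(-180, 180]`.
#' @examples
#' wrap_angle(c(190, -180, 360, 181))
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # the representative of the half-open interval: -180 maps to +180
  w[w == -180] <- 180
  w
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Smallest absolute circular difference a - b in degrees, signed.
angle_diff <- function(a, b) wrap_angle(a - b)

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(a) sqrt(sum(a * a))

#' Measure a proper dihedral angle
#'
#' Computes the torsion angle defined by four points using the
#' `atan2(|b2| b1 . (b2 x b3), (b1 x b2) . (b2 x b3))` formulation.  The
#' value is independent of the atom order direction (quadruple and reversed
#' quadruple give the same angle) and changes sign when the coordinates are
#' mirrored.
#'
#' @param coords numeric matrix with one row per atom and columns x, y, z.
#' @param quad integer vector of four (1-based) row indices.
#' @return the dihedral angle in degrees on `(-180, 180]`; 0 is cis.
#' @examples
#' sq <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
#' dihedral_angle(sq, 1:4)   # planar cis: 0
#' @export
dihedral_angle <- function(coords, quad) {
  stopifnot(length(quad) == 4)
  p <- coords[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]
  b2 <- p[3, ] - p[2, ]
  b3 <- p[4, ] - p[3, ]
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) {
    stop("collinear atoms in dihedral quadruple [",
         paste(quad, collapse = ", "), "]")
  }
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * b2) / vnorm(b2)
  wrap_angle(rad2deg(atan2(y, x)))
}

## Vectorised form over a matrix of quadruples (rows).
dihedral_angles <- function(coords, quads) {
  apply(quads, 1L, function(q) dihedral_angle(coords, q))
}

## Bond angle i-j-k in degrees.
bond_angle <- function(coords, triple) {
  u <- coords[triple[1], ] - coords[triple[2], ]
  v <- coords[triple[3], ] - coords[triple[2], ]
  cosang <- sum(u * v) / (vnorm(u) * vnorm(v))
  rad2deg(acos(pmin(1, pmax(-1, cosang))))
}
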