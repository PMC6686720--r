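## Idealized Cartesian geometry construction from the internal-coordinate
## BUILD records of a model_peptide.  Bond lengths and angles are fixed at
## their idealized values; only torsion variables move.  This is the
## torsion-only parametrization used by the synthetic reference-data
## generator: it isolates the dihedral degrees of freedom, so a fitted
## parameter set has an exact self-consistent fixed point.

#' Build Cartesian coordinates from torsion variables
#'
#' Places atoms sequentially with the natural-extension reference frame
#' (NeRF) construction: each atom is positioned at its idealized bond length
#' and bond angle from three previously placed reference atoms, with the
#' torsion taken either from a fixed value (e.g. trans amides) or from a
#' named torsion variable, optionally shifted (methyl hydrogens at
#' +/-120 degrees).
#'
#' @param peptide a `model_peptide`.
#' @param vars named numeric vector of torsion variable values in degrees;
#'   defaults from the topology are used for variables not supplied.
#' @return coordinate matrix (atoms x 3, Angstrom), rows in atom order.
#' @examples
#' pep <- build_diamide("beta0")
#' xyz <- build_coordinates(pep, c(phi = -140, theta = 60, psi = -135))
#' round(measure_dihedrals(pep, xyz))
#' @export
build_coordinates <- function(peptide, vars = numeric()) {
  v <- peptide$vars
  if (length(vars)) {
    unknown <- setdiff(names(vars), names(v))
    if (length(unknown)) {
      stop("unknown torsion variable(s): ", paste(unknown, collapse = ", "))
    }
    v[names(vars)] <- vars
  }
  ba <- peptide$build_arrays
  if (is.null(ba)) ba <- make_build_arrays(peptide)
  xyz <- cpp_build_coords(nrow(peptide$atoms), ba$atom, ba$ref1, ba$ref2,
                          ba$ref3, ba$bond, ba$angle, ba$tvar, ba$tfixed,
                          ba$toffset, as.numeric(v))
  rownames(xyz) <- peptide$atoms$name
  xyz
}

## flat integer/numeric arrays for the C++ NeRF builder; torsion variables
## are referenced by their position in peptide$vars.
make_build_arrays <- function(peptide) {
  b <- peptide$build
  zero_na <- function(x) {
    x[is.na(x)] <- 0L
    as.integer(x)
  }
  list(atom = as.integer(b$atom),
       ref1 = zero_na(b$ref1), ref2 = zero_na(b$ref2),
       ref3 = zero_na(b$ref3),
       bond = b$bond, angle = b$angle,
       tvar = zero_na(match(b$tvar, names(peptide$vars))),
       tfixed = ifelse(is.na(b$torsion), 0, b$torsion),
       toffset = b$toffset)
}

## Place atom D bonded to A with angle D-A-B and dihedral D-A-B-C.
nerf_place <- function(a, b, c_, bond, angle, torsion) {
  th <- deg2rad(angle)              # polar angle from the A->B direction
  ph <- -deg2rad(torsion)           # sign matches dihedral_angle()
  ab <- b - a
  bhat <- ab / vnorm(ab)
  nrm <- vcross(b - c_, bhat)
  nlen <- vnorm(nrm)
  if (nlen < 1e-10) stop("collinear BUILD reference atoms")
  nhat <- nrm / nlen
  mhat <- vcross(nhat, bhat)
  d2 <- bond * c(cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  a + d2[1L] * bhat + d2[2L] * mhat + d2[3L] * nhat
}
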