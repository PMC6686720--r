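## Minimization backends for the MEP workflow.  A backend bundles a model
## peptide with an energy model and provides restrained minimization,
## plain energy evaluation and backbone torsion measurement.  Two kinds are
## provided: the Cartesian backend (steepest descent on all coordinates)
## and the torsion-space backend, which keeps the idealized internal
## coordinates fixed and relaxes only the torsion variables -- the
## parametrization used by the synthetic reference-data generator.

#' Cartesian minimization backend
#'
#' @param peptide a `model_peptide`.
#' @param model the `ff_model` for that peptide.
#' @param max_steps,tol passed to [minimize_restrained].
#' @return an object of classes `cartesian_backend`, `mep_backend`.
#' @export
cartesian_backend <- function(peptide, model, max_steps = 4000L,
                              tol = 0.24) {
  structure(list(peptide = peptide, model = model,
                 max_steps = max_steps, tol = tol),
            class = c("cartesian_backend", "mep_backend"))
}

#' Torsion-space minimization backend
#'
#' Geometries are parametrized by the topology's torsion variables
#' (backbone torsions plus the free rotors, e.g. the capping methyls); bond
#' lengths and angles stay at their idealized values.  Restrained
#' minimization runs in this low-dimensional torsion space with `optim`
#' (BFGS); restraint targets are matched to torsion variables through the
#' corresponding atom quadruples.
#'
#' @param peptide a `model_peptide`.
#' @param model the `ff_model`.
#' @param reltol relative convergence tolerance for the optimizer.
#' @return an object of classes `torsion_backend`, `mep_backend`.
#' @export
torsion_backend <- function(peptide, model, reltol = 1e-10) {
  ## quadruple defining each torsion variable: first BUILD row that uses
  ## the variable with zero offset
  b <- peptide$build
  vq <- lapply(names(peptide$vars), function(v) {
    r <- which(!is.na(b$tvar) & b$tvar == v & b$toffset == 0)[1L]
    if (is.na(r)) stop("torsion variable ", v, " has no defining BUILD row")
    c(b$atom[r], b$ref1[r], b$ref2[r], b$ref3[r])
  })
  names(vq) <- names(peptide$vars)
  structure(list(peptide = peptide, model = model, var_quads = vq,
                 reltol = reltol),
            class = c("torsion_backend", "mep_backend"))
}

#' Restrained minimization through a backend
#'
#' @param backend an `mep_backend`.
#' @param coords starting coordinates (atoms x 3).
#' @param restraints a `restraint_set` (or `NULL`).
#' @return list with `coords`, `energy` (restraint-free potential energy),
#'   `converged`.
#' @export
backend_minimize <- function(backend, coords, restraints = NULL) {
  UseMethod("backend_minimize")
}

#' @export
backend_minimize.cartesian_backend <- function(backend, coords,
                                               restraints = NULL) {
  res <- minimize_restrained(backend$model, coords, restraints,
                             max_steps = backend$max_steps,
                             tol = backend$tol)
  list(coords = res$coords,
       energy = potential_energy(backend$model, res$coords)$total,
       converged = res$converged)
}

#' @export
backend_minimize.torsion_backend <- function(backend, coords,
                                             restraints = NULL) {
  pep <- backend$peptide
  vq <- backend$var_quads
  vars0 <- vapply(vq, function(q) dihedral_angle(coords, q), 0)

  ## map restraint quadruples to torsion variables
  rest_var <- integer(); rest_target <- numeric(); rest_k <- numeric()
  if (!is.null(restraints)) {
    for (r in seq_len(nrow(restraints$quads))) {
      q <- restraints$quads[r, ]
      hit <- which(vapply(vq, function(v) {
        all(v == q) || all(v == rev(q))
      }, TRUE))
      if (!length(hit)) {
        stop("restrained quadruple [", paste(q, collapse = ", "),
             "] is not a torsion variable of this backend")
      }
      rest_var <- c(rest_var, hit[1L])
      rest_target <- c(rest_target, restraints$targets[r])
      rest_k <- c(rest_k, restraints$k[r])      # kcal/mol/rad^2
    }
    vars0[rest_var] <- rest_target              # start on target
  }

  ba <- pep$build_arrays
  nat <- nrow(pep$atoms)
  obj <- function(v) {
    xyz <- cpp_build_coords(nat, ba$atom, ba$ref1, ba$ref2, ba$ref3,
                            ba$bond, ba$angle, ba$tvar, ba$tfixed,
                            ba$toffset, v)
    e <- cpp_call(backend$model, xyz)
    if (e$overlap) return(1e8)
    pen <- 0
    if (length(rest_var)) {
      dev <- deg2rad(angle_diff(v[rest_var], rest_target))
      pen <- sum(rest_k * dev^2)
    }
    e$total + pen
  }
  opt <- stats::optim(vars0, obj, method = "BFGS",
                      control = list(reltol = backend$reltol,
                                     maxit = 500L))
  vfin <- stats::setNames(opt$par, names(vq))
  xyz <- build_coordinates(pep, vfin)
  list(coords = xyz,
       energy = potential_energy(backend$model, xyz)$total,
       converged = opt$convergence == 0L)
}

#' Restraint-free potential energy through a backend
#'
#' @param backend an `mep_backend`.
#' @param coords coordinates.
#' @return total energy, kcal/mol.
#' @export
backend_energy <- function(backend, coords) {
  potential_energy(backend$model, coords)$total
}

#' Replace the independent barrier-height parameters of a backend's model
#'
#' @param backend an `mep_backend`.
#' @param k_values parameter vector (one per constraint group).
#' @return the updated backend.
#' @export
backend_set_params <- function(backend, k_values) {
  backend$model <- set_parameters(backend$model, k_values)
  backend
}

#' Default starting geometry of a backend's peptide
#'
#' @param backend an `mep_backend`.
#' @return coordinate matrix built from the topology's default torsions.
#' @export
backend_start_coords <- function(backend) {
  build_coordinates(backend$peptide)
}
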