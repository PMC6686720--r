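## Energy evaluation and restrained steepest-descent minimization.
## Internal units: kcal/mol and Angstrom (CHARMM convention); dihedral
## restraint constants are supplied in kJ/mol/rad^2, as customary for the
## MEP-matching protocol, and converted on input.

KJ_PER_KCAL <- 4.184

empty4 <- function() matrix(integer(), ncol = 4L)

#' Harmonic dihedral restraints
#'
#' @param quads matrix (or vector) of atom index quadruples, one row per
#'   restrained torsion.
#' @param targets target angles in degrees.
#' @param k force constant in kJ/mol/rad^2 (default `1e5`, stiff enough to
#'   pin a torsion to well under 0.1 degree against typical barriers).
#' @return a `restraint_set` object.
#' @export
dihedral_restraints <- function(quads, targets, k = 1e5) {
  quads <- matrix(as.integer(quads), ncol = 4L)
  stopifnot(nrow(quads) == length(targets), all(k >= 0))
  structure(list(quads = quads, targets = as.numeric(targets),
                 k = rep(as.numeric(k) / KJ_PER_KCAL,
                         length.out = nrow(quads))),
            class = "restraint_set")
}

cpp_call <- function(model, coords, restraints = NULL, want_grad = FALSE,
                     r_floor = 0.2) {
  r <- restraints
  rq <- if (is.null(r)) empty4() else r$quads
  rk <- if (is.null(r)) numeric() else r$k
  rt <- if (is.null(r)) numeric() else r$targets
  cpp_energy(coords,
             model$bonds, model$bond_kb, model$bond_b0,
             model$angles, model$ang_k, model$ang_th0,
             model$ubs, model$ub_k, model$ub_s0,
             model$dih_idx,
             model$dih$K, as.integer(model$dih$n), model$dih$chi0,
             model$imps, model$imp_k, model$imp_chi0,
             model$pairs, model$nb_eps, model$nb_rmin, model$nb_qq,
             rq, rk, rt,
             want_grad, r_floor)
}

#' Potential energy of a conformation
#'
#' Evaluates the CHARMM-form potential: `Kb (b - b0)^2` bonds (no 1/2
#' factor), harmonic angles and Urey-Bradley terms, periodic proper
#' dihedrals `K (1 + cos(n chi - chi0))`, harmonic impropers,
#' Lennard-Jones in the `eps [(Rmin/r)^12 - 2 (Rmin/r)^6]` form and vacuum
#' Coulomb over the non-excluded pair list (1-2 and 1-3 excluded, 1-4 with
#' special LJ parameters and full Coulomb).  No cutoffs or periodicity:
#' the model compounds are small gas-phase molecules.
#'
#' @param model an `ff_model`.
#' @param coords coordinate matrix (atoms x 3, Angstrom).
#' @param restraints optional `restraint_set`.
#' @param r_floor smallest allowed nonbonded distance (Angstrom); closer
#'   contacts are rejected to avoid the LJ/Coulomb singularity.
#' @return a list with `total` (kcal/mol) and the per-term `breakdown`.
#' @export
potential_energy <- function(model, coords, restraints = NULL,
                             r_floor = 0.2) {
  stopifnot(inherits(model, "ff_model"), nrow(coords) == model$n_atoms)
  out <- cpp_call(model, coords, restraints, want_grad = FALSE,
                  r_floor = r_floor)
  if (out$overlap) {
    stop("overlapping atoms: nonbonded distance below ", r_floor,
         " Angstrom")
  }
  out[c("total", "breakdown")]
}

#' Analytic gradient of the potential
#'
#' @inheritParams potential_energy
#' @return gradient matrix (atoms x 3, kcal/mol/Angstrom).
#' @export
ff_gradient <- function(model, coords, restraints = NULL, r_floor = 0.2) {
  out <- cpp_call(model, coords, restraints, want_grad = TRUE,
                  r_floor = r_floor)
  if (out$overlap) {
    stop("overlapping atoms: nonbonded distance below ", r_floor,
         " Angstrom")
  }
  out$gradient
}

#' Restrained steepest-descent minimization
#'
#' Minimizes the potential energy (plus harmonic dihedral restraints) by
#' steepest descent with a backtracking line search; steps are only
#' accepted when they lower the energy.  Convergence is declared when the
#' largest gradient component falls below `tol`.
#'
#' @param model an `ff_model`.
#' @param coords starting coordinates.
#' @param restraints optional `restraint_set` (e.g. the scanned torsion
#'   pinned at its grid value).
#' @param max_steps maximum number of accepted steps.
#' @param tol convergence threshold on the maximum gradient component,
#'   kcal/mol/Angstrom (default 0.24, i.e. 10 kJ/mol/nm).
#' @param step0 initial trial step length in Angstrom.
#' @return list with `coords`, `energy`, `converged`, `steps`.
#' @export
minimize_restrained <- function(model, coords, restraints = NULL,
                                max_steps = 5000L, tol = 0.24,
                                step0 = 0.02) {
  stopifnot(inherits(model, "ff_model"))
  out <- cpp_call(model, coords, restraints, want_grad = TRUE)
  if (out$overlap) stop("overlapping atoms in starting geometry")
  e <- out$total
  g <- out$gradient
  step <- step0
  nsteps <- 0L
  converged <- max(abs(g)) < tol
  while (!converged && nsteps < max_steps) {
    gmax <- max(abs(g))
    dir <- -g / gmax                       # largest component moves `step`
    accepted <- FALSE
    for (bt in 1:25) {
      trial <- coords + step * dir
      tout <- cpp_call(model, trial, restraints, want_grad = TRUE)
      if (!tout$overlap && tout$total < e) {
        coords <- trial
        e <- tout$total
        g <- tout$gradient
        step <- step * 1.2
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    nsteps <- nsteps + 1L
    if (!accepted) break                   # line search exhausted
    converged <- max(abs(g)) < tol
  }
  list(coords = coords, energy = e, converged = converged, steps = nsteps)
}

#' Per-parameter torsional energy basis
#'
#' Evaluates, for each independent barrier-height parameter of the model's
#' constraint system, the sum over its member term instances of
#' `sign * (1 + cos(n chi - chi0))` at the given geometry.  The fitted part
#' of the dihedral energy is then exactly the dot product of the parameter
#' vector with this basis, which is what makes the barrier-height fit a
#' linear least-squares problem.
#'
#' @param model an `ff_model` built with a constraint system.
#' @param coords coordinate matrix.
#' @param n_groups total number of independent parameters (defaults to the
#'   model's own group count; pass the global count when several molecules
#'   share one parameter vector).
#' @return numeric vector of basis values, one per parameter.
#' @export
torsional_energy_vector <- function(model, coords,
                                    n_groups = model$n_groups) {
  d <- model$dih
  fit <- model$fit_rows
  basis <- numeric(n_groups)
  if (!length(fit)) return(basis)
  chi <- cpp_dihedral_angles(coords, model$fit_quads)
  contrib <- d$sign[fit] * (1 + cos(deg2rad(d$n[fit] * chi - d$chi0[fit])))
  basis_sum <- rowsum(contrib, d$group[fit])
  basis[as.integer(rownames(basis_sum))] <- basis_sum[, 1L]
  basis
}

## Dihedral energy of the non-fitted terms plus everything else: total
## energy with all fitted K set to zero.  Used as the fixed offset in the
## fit design.
nonfitted_energy <- function(model, coords) {
  m0 <- model
  m0$dih$K[!is.na(m0$dih$group)] <- 0
  potential_energy(m0, coords)$total
}
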