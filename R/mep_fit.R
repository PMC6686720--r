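## Relaxed torsion scans, global minimum-energy-path extraction, the linear
## least-squares barrier-height fit, and the self-consistent optimization
## loop that alternates restrained MM minimization with refitting until the
## parameters and MEP energies stop changing.

MEP_GRID <- seq(-175, 180, by = 5)   # 72 angles, 5 degree spacing

new_mep <- function(torsion, angles, energies, geoms, source, converged,
                    origin, backbone = NULL) {
  stopifnot(length(angles) == length(energies),
            length(angles) == length(geoms))
  structure(list(torsion = torsion, angles = angles, energies = energies,
                 geoms = geoms, source = source, converged = converged,
                 origin = origin, backbone = backbone),
            class = "mep")
}

#' @export
print.mep <- function(x, ...) {
  cat("MEP for torsion '", x$torsion, "' (", x$origin, "): ",
      length(x$angles), " points, energy span ",
      round(diff(range(x$energies)), 3), " kcal/mol",
      if (!all(x$converged)) paste0(", ", sum(!x$converged),
                                    " unconverged"), "\n", sep = "")
  invisible(x)
}

#' Run a relaxed scan of one backbone torsion
#'
#' Drives the chosen torsion in 5-degree steps over full turns, restraining
#' only the scanned torsion at each step and relaxing everything else, with
#' each minimization seeded from the previous step's geometry (so hysteresis
#' between scan directions is representable).  The default protocol is two
#' complete turns; combining clockwise and anticlockwise scans and taking
#' per-angle minima yields the global MEP.
#'
#' @param backend an `mep_backend`.
#' @param start starting coordinates (default: the topology's idealized
#'   geometry).
#' @param torsion torsion label (`"phi"`, `"theta"`, `"psi"`).
#' @param direction +1 (anticlockwise) or -1.
#' @param turns number of full turns (default 2).
#' @param step_deg grid spacing in degrees (default 5).
#' @param k restraint force constant, kJ/mol/rad^2.
#' @return an object of class `torsion_scan`: grid targets, wrapped angles,
#'   energies, geometries and convergence flags, in scan order.
#' @export
run_relaxed_scan <- function(backend, start = NULL, torsion = "phi",
                             direction = 1, turns = 2, step_deg = 5,
                             k = 1e5) {
  stopifnot(direction %in% c(-1, 1), inherits(backend, "mep_backend"))
  pep <- backend$peptide
  quad <- pep$tors[[torsion]]
  if (is.null(quad)) stop("unknown torsion label '", torsion, "'")
  coords <- if (is.null(start)) backend_start_coords(backend) else start
  n_steps <- as.integer(round(360 / step_deg) * turns)
  a0 <- round(dihedral_angle(coords, quad) / step_deg) * step_deg
  targets <- a0 + direction * step_deg * seq_len(n_steps)

  angles <- numeric(n_steps); energies <- numeric(n_steps)
  geoms <- vector("list", n_steps); conv <- logical(n_steps)
  for (i in seq_len(n_steps)) {
    rs <- dihedral_restraints(quad, wrap_angle(targets[i]), k)
    res <- backend_minimize(backend, coords, rs)
    coords <- res$coords
    angles[i] <- wrap_angle(targets[i])
    energies[i] <- res$energy
    geoms[[i]] <- res$coords
    conv[i] <- res$converged
  }
  structure(list(torsion = torsion, targets = targets,
                 angles = angles, energies = energies, geoms = geoms,
                 converged = conv, direction = direction,
                 step_deg = step_deg),
            class = "torsion_scan")
}

#' Extract the global minimum energy path from scans
#'
#' For each grid angle, selects the lowest-energy conformation over all
#' supplied scans of the same torsion.  Because the minimum is taken
#' pointwise, the resulting path may contain nonadjacent geometries.
#'
#' @param scans list of `torsion_scan` objects (e.g. two turns in each
#'   direction).
#' @param peptide optional `model_peptide`; when given, the backbone
#'   torsions of each selected geometry are recorded (needed to recompute
#'   the MEP under a force field, where all backbone torsions are
#'   restrained at their MEP values).
#' @param grid angle grid (default 72 points at 5-degree spacing).
#' @return an object of class `mep` with one entry per grid angle.
#' @export
extract_global_mep <- function(scans, peptide = NULL, grid = MEP_GRID) {
  if (inherits(scans, "torsion_scan")) scans <- list(scans)
  torsion <- scans[[1L]]$torsion
  angles <- numeric(0); energies <- numeric(0)
  geoms <- list(); source <- integer(0); conv <- logical(0)
  for (s in seq_along(scans)) {
    sc <- scans[[s]]
    if (sc$torsion != torsion) stop("scans refer to different torsions")
    angles <- c(angles, sc$angles)
    energies <- c(energies, sc$energies)
    geoms <- c(geoms, sc$geoms)
    source <- c(source, rep(s, length(sc$angles)))
    conv <- c(conv, sc$converged)
  }
  pick <- integer(length(grid))
  for (gi in seq_along(grid)) {
    cand <- which(abs(angle_diff(angles, grid[gi])) < 1e-6)
    if (!length(cand)) {
      stop("no scan point covers grid angle ", grid[gi], " degrees")
    }
    ok <- cand[conv[cand]]
    use <- if (length(ok)) ok else cand
    pick[gi] <- use[which.min(energies[use])]
  }
  bb <- NULL
  if (!is.null(peptide)) {
    bb <- t(vapply(pick, function(p) measure_dihedrals(peptide, geoms[[p]]),
                   numeric(length(peptide$tors))))
    colnames(bb) <- names(peptide$tors)
  }
  new_mep(torsion = torsion, angles = grid, energies = energies[pick],
          geoms = geoms[pick], source = source[pick],
          converged = conv[pick], origin = "scan", backbone = bb)
}

#' Recompute a MEP under a force-field model
#'
#' For every point of a reference MEP, minimizes the backend's model with
#' all backbone torsions simultaneously restrained at that point's
#' reference values (stiff harmonic restraints, default 1e5 kJ/mol/rad^2)
#' while all other degrees of freedom relax.  Starting geometries default
#' to the reference geometries; across self-consistent iterations the
#' previous MM geometries are passed instead.
#'
#' @param backend an `mep_backend`.
#' @param qm_mep the reference `mep` (must carry `backbone` values).
#' @param start_geoms optional list of starting geometries, one per point.
#' @param k restraint force constant, kJ/mol/rad^2.
#' @return an `mep` with origin `"mm"`.
#' @export
compute_mm_mep <- function(backend, qm_mep, start_geoms = NULL, k = 1e5) {
  stopifnot(inherits(qm_mep, "mep"))
  if (is.null(qm_mep$backbone)) {
    stop("reference MEP carries no backbone torsion values")
  }
  pep <- backend$peptide
  quads <- do.call(rbind, pep$tors)
  np <- length(qm_mep$angles)
  if (is.null(start_geoms)) start_geoms <- qm_mep$geoms
  energies <- numeric(np); geoms <- vector("list", np)
  conv <- logical(np)
  for (i in seq_len(np)) {
    rs <- dihedral_restraints(quads, qm_mep$backbone[i, ], k)
    res <- backend_minimize(backend, start_geoms[[i]], rs)
    energies[i] <- res$energy
    geoms[[i]] <- res$coords
    conv[i] <- res$converged && qm_mep$converged[i]
  }
  bb <- t(vapply(geoms, function(g) measure_dihedrals(pep, g),
                 numeric(length(pep$tors))))
  colnames(bb) <- names(pep$tors)
  new_mep(torsion = qm_mep$torsion, angles = qm_mep$angles,
          energies = energies, geoms = geoms, source = qm_mep$source,
          converged = conv, origin = "mm", backbone = bb)
}

#' Least-squares fit of barrier heights to reference MEP energies
#'
#' Matches the model energies along the MM MEPs to the reference energies
#' as a linear least-squares problem: the reference energy at each matched
#' point is modelled as the non-fitted part of the MM energy (evaluated at
#' the MM MEP geometry) plus the dot product of the independent barrier
#' heights with the torsional basis, plus one free additive offset per MEP
#' (the reference and MM energy zeroes are unrelated).  All matched points
#' are weighted uniformly; unconverged points are excluded.
#'
#' @param qm_meps list of reference `mep` objects.
#' @param mm_meps list of MM `mep` objects, parallel to `qm_meps`.
#' @param backends list of `mep_backend`s, parallel to the MEPs (the same
#'   backend may appear several times when one molecule contributes several
#'   torsions).
#' @param system the `constraint_system` shared by the backends' models.
#' @return an object of class `fit_result`: `K` (full parameter vector;
#'   parameters without support in the supplied MEPs keep their input
#'   value), `active` (which parameters were fitted), `offsets`, `se`
#'   (standard errors), `correlation` (over active parameters), `rms`
#'   (overall RMS deviation, kcal/mol), `n_points`, and rank diagnostics
#'   (`rank_deficient`, `null_space`).
#' @export
fit_barrier_heights <- function(qm_meps, mm_meps, backends, system) {
  stopifnot(length(qm_meps) == length(mm_meps),
            length(qm_meps) == length(backends))
  ng <- nrow(system$groups)
  rows <- list(); y <- numeric(0); mep_id <- integer(0)
  for (m in seq_along(qm_meps)) {
    qm <- qm_meps[[m]]; mm <- mm_meps[[m]]
    mod <- backends[[m]]$model
    use <- which(qm$converged & mm$converged)
    for (i in use) {
      g <- mm$geoms[[i]]
      rows[[length(rows) + 1L]] <-
        torsional_energy_vector(mod, g, n_groups = ng)
      y <- c(y, qm$energies[i] - nonfitted_energy(mod, g))
      mep_id <- c(mep_id, m)
    }
  }
  A <- do.call(rbind, rows)
  nm <- length(qm_meps)
  D <- matrix(0, nrow(A), nm)
  D[cbind(seq_len(nrow(A)), mep_id)] <- 1
  active <- colSums(abs(A)) > 1e-12
  X <- cbind(A[, active, drop = FALSE], D)
  qrx <- qr(X)
  rank_deficient <- qrx$rank < ncol(X)
  null_space <- NULL
  if (rank_deficient) {
    sv <- svd(X)
    null_space <- sv$v[, seq.int(qrx$rank + 1L, ncol(X)), drop = FALSE]
  }
  beta <- qr.coef(qrx, y)
  beta[is.na(beta)] <- 0
  resid <- y - X %*% beta
  rms <- sqrt(mean(resid^2))
  dof <- max(nrow(X) - qrx$rank, 1L)
  sigma2 <- sum(resid^2) / dof
  xtx_inv <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
  na <- sum(active)
  se_full <- rep(NA_real_, ng)
  correlation <- NULL
  if (!is.null(xtx_inv)) {
    kinv <- xtx_inv[seq_len(na), seq_len(na), drop = FALSE]
    se_full[active] <- sqrt(pmax(sigma2 * diag(kinv), 0))
    ## parameter correlations do not depend on the residual scale
    correlation <- stats::cov2cor(kinv)
    dimnames(correlation) <- list(system$groups$label[active],
                                  system$groups$label[active])
  }
  K <- system$groups$K
  K[active] <- beta[seq_len(na)]
  structure(list(K = K, active = active,
                 offsets = beta[seq.int(na + 1L, length(beta))],
                 se = se_full, correlation = correlation, rms = rms,
                 n_points = nrow(X), rank_deficient = rank_deficient,
                 null_space = null_space),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Barrier-height fit: ", sum(x$active), " parameters from ",
      x$n_points, " matched points, overall RMS ",
      round(x$rms, 4), " kcal/mol",
      if (x$rank_deficient) " [RANK DEFICIENT]", "\n", sep = "")
  invisible(x)
}

#' Self-consistent barrier-height optimization
#'
#' Alternates (1) recomputing the MM MEPs with all backbone torsions
#' restrained at the reference values, starting from the previous
#' iteration's MM geometries, and (2) refitting the barrier heights to the
#' reference energies, until both the parameters and the MM MEP energies
#' stop changing.  At convergence the parameters and the MEPs are
#' self-consistent: rerunning the loop from a converged state is a no-op.
#'
#' @param backends list of `mep_backend`s, parallel to `qm_meps`.
#' @param qm_meps list of reference `mep` objects.
#' @param system the shared `constraint_system`.
#' @param initial_params starting parameter vector (default: the system's
#'   current group values, i.e. parameters carried over from analogous atom
#'   types).
#' @param tol_K convergence threshold on max parameter change, kcal/mol.
#' @param tol_E convergence threshold on max MM MEP energy change,
#'   kcal/mol.
#' @param max_iter maximum iterations.
#' @param k restraint force constant, kJ/mol/rad^2.
#' @return list with the final `fit` (`fit_result`), `mm_meps`, `params`,
#'   `converged`, `iterations`, and a per-iteration `trace` data frame
#'   (RMS, max parameter change, max energy change).  If the loop fails to
#'   converge the best-RMS iterate is returned, flagged.
#' @export
self_consistent_optimize <- function(backends, qm_meps, system,
                                     initial_params = NULL,
                                     tol_K = 1e-3, tol_E = 1e-2,
                                     max_iter = 50L, k = 1e5) {
  params <- if (is.null(initial_params)) system$groups$K else initial_params
  stopifnot(length(params) == nrow(system$groups))
  starts <- lapply(qm_meps, function(m) m$geoms)
  prev_E <- NULL
  trace <- data.frame(iter = integer(), rms = numeric(),
                      max_dK = numeric(), max_dE = numeric())
  best <- NULL
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    backends <- lapply(backends, backend_set_params, k_values = params)
    mm_meps <- vector("list", length(qm_meps))
    for (m in seq_along(qm_meps)) {
      mm_meps[[m]] <- compute_mm_mep(backends[[m]], qm_meps[[m]],
                                     start_geoms = starts[[m]], k = k)
    }
    fit <- fit_barrier_heights(qm_meps, mm_meps, backends, system)
    dK <- max(abs(fit$K[fit$active] - params[fit$active]))
    E_now <- unlist(lapply(mm_meps, `[[`, "energies"))
    dE <- if (is.null(prev_E)) Inf else max(abs(E_now - prev_E))
    trace <- rbind(trace, data.frame(iter = it, rms = fit$rms,
                                     max_dK = dK, max_dE = dE))
    state <- list(fit = fit, mm_meps = mm_meps, params = fit$K,
                  iterations = it)
    if (is.null(best) || fit$rms < best$fit$rms) best <- state
    params <- fit$K
    prev_E <- E_now
    starts <- lapply(mm_meps, `[[`, "geoms")
    if (dK < tol_K && dE < tol_E) {
      converged <- TRUE
      best <- state
      break
    }
  }
  c(best, list(converged = converged, trace = trace))
}
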