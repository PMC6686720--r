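## Synthetic reference data with known ground truth: "QM-like" MEPs
## generated by the forward model at a known parameter set (so the fit and
## the self-consistent loop have exact expected answers), and toy
## trajectories with prescribed state populations, interproton distances,
## torsion distributions and hydrogen-bond geometries for the validation
## estimators.

#' Define a synthetic reference-data scenario
#'
#' The scenario fixes the ground-truth independent barrier heights, the
#' background energy model (the shipped generic parameter set), the
#' Gaussian energy noise and the random seed; a scenario fully determines
#' the generated data.
#'
#' @param truth_K ground-truth parameter vector, one value per constraint
#'   group (default: the published barrier heights shipped with the
#'   package).
#' @param noise_sd standard deviation of Gaussian noise added to the
#'   reference energies, kcal/mol (default 0).
#' @param seed integer random seed.
#' @param molecule which model diamide the scenario scans.
#' @return an object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(truth_K = NULL, noise_sd = 0, seed = 1L,
                               molecule = "beta0") {
  stopifnot(noise_sd >= 0)
  structure(list(truth_K = truth_K, noise_sd = noise_sd,
                 seed = as.integer(seed), molecule = molecule),
            class = "synthetic_scenario")
}

#' Generate synthetic reference MEPs from a known parameter set
#'
#' Builds the scenario's diamide with the torsion-space backend at the
#' ground-truth parameters, runs a relaxed scan of each backbone torsion
#' over the 72-point grid (5-degree steps), extracts the per-angle-minimum
#' path and records its energies (plus optional Gaussian noise) as the
#' reference.  Because the geometries come from the same forward model, the
#' ground-truth parameters are an exact fixed point of the self-consistent
#' loop, and with zero noise the linear fit recovers them to machine
#' precision.
#'
#' @param scenario a `synthetic_scenario`.
#' @param system the `constraint_system` whose independent parameters are
#'   being exercised.
#' @param peptide optional `model_peptide` (default: the scenario's
#'   molecule).
#' @param params base parameter set (default: the shipped generic set).
#' @param torsions which backbone torsions to scan (default all three).
#' @param turns scan turns per torsion (default 1 for the generator; the
#'   scan is seeded from the idealized geometry).
#' @return list with `meps` (list of reference `mep` objects, with
#'   geometries and backbone torsion values), `backend` (at ground truth),
#'   `truth_K`, and `scenario`.
#' @export
synth_qm_meps <- function(scenario, system, peptide = NULL,
                          params = default_parameters(),
                          torsions = c("phi", "theta", "psi"), turns = 1) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  if (is.null(peptide)) peptide <- build_diamide(scenario$molecule)
  truth <- scenario$truth_K
  if (is.null(truth)) truth <- system$groups$K
  stopifnot(length(truth) == nrow(system$groups))
  set.seed(scenario$seed)

  model <- build_ff_model(peptide, params, system)
  model <- set_parameters(model, truth)
  backend <- torsion_backend(peptide, model)

  meps <- lapply(torsions, function(tor) {
    sc <- run_relaxed_scan(backend, torsion = tor, direction = 1,
                           turns = turns)
    mep <- extract_global_mep(list(sc), peptide = peptide)
    mep$origin <- "synthetic-reference"
    if (scenario$noise_sd > 0) {
      mep$energies <- mep$energies +
        stats::rnorm(length(mep$energies), sd = scenario$noise_sd)
    }
    mep
  })
  names(meps) <- torsions
  list(meps = meps, backend = backend, truth_K = truth,
       scenario = scenario)
}

## von Mises sampler (Best & Fisher 1979 rejection scheme)
rvonmises <- function(n, mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2L] > 0 || log(c_ / u[2L]) + 1 - c_ >= 0) {
      th <- sign(u[3L] - 0.5) * acos(f)
      out[i] <- th
      i <- i + 1L
    }
  }
  wrap_angle(mu_deg + rad2deg(out))
}

## place a 4-atom chain with a prescribed dihedral
chain4 <- function(torsion_deg, origin = c(0, 0, 0)) {
  a <- origin
  b <- origin + c(1.5, 0, 0)
  c_ <- b + 1.5 * c(cos(deg2rad(70)), sin(deg2rad(70)), 0)
  d <- nerf_place(c_, b, a, 1.5, 110, torsion_deg)
  rbind(a, b, c_, d)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Generate a toy trajectory with known ground truth
#'
#' Emits frames with prescribed properties so the validation estimators
#' have exact expected answers:
#' \describe{
#'   \item{`two_state`}{each frame is folded with probability `p_folded`;
#'     the folded and unfolded states differ in a probe torsion (von Mises
#'     scatter around state means), an interproton distance, and a
#'     donor-hydrogen-acceptor geometry (folded: near-linear and short;
#'     unfolded: bent and long).  Atoms 1-4 are the torsion probe, 5-6 the
#'     proton pair, 7-9 donor/hydrogen/acceptor.}
#'   \item{`helix`}{a single-state version of `two_state` (all frames
#'     folded): torsions scatter around one mean, as in a stable helix.}
#'   \item{`bundles`}{frames jitter tightly around `n_centers` well
#'     separated random 8-atom templates; the generating assignment is the
#'     expected cluster partition.}
#' }
#' Every frame is given a random rigid rotation and translation unless
#' `rigid_motion = FALSE`.
#'
#' @param kind `"two_state"`, `"helix"` or `"bundles"`.
#' @param n_frames number of frames.
#' @param seed integer random seed (fully determines the output).
#' @param p_folded folded-state probability (two_state).
#' @param torsion_means folded/unfolded probe torsion means, degrees.
#' @param torsion_kappa von Mises concentration of the probe torsion.
#' @param pair_dist folded/unfolded interproton distances, Angstrom.
#' @param n_centers number of bundles (bundles kind).
#' @param jitter_sd Cartesian jitter within a bundle, Angstrom.
#' @param rigid_motion apply a random rigid motion to every frame.
#' @return list with `traj` (a `trajectory`) and `truth` (state labels and
#'   the generating parameters; for `two_state`/`helix` also the probe
#'   atom indices: `torsion_quad`, `pair`, `dha`).
#' @export
synth_trajectory <- function(kind = c("two_state", "helix", "bundles"),
                             n_frames = 100L, seed = 1L, p_folded = 0.5,
                             torsion_means = c(folded = -60,
                                               unfolded = 180),
                             torsion_kappa = 50,
                             pair_dist = c(folded = 2.2, unfolded = 4.5),
                             n_centers = 2L, jitter_sd = 0.05,
                             rigid_motion = TRUE) {
  kind <- match.arg(kind)
  stopifnot(n_frames >= 1L)
  set.seed(seed)

  if (kind == "bundles") {
    centers <- lapply(seq_len(n_centers), function(i) {
      matrix(stats::rnorm(24, sd = 4), 8L, 3L)
    })
    labels <- sample.int(n_centers, n_frames, replace = TRUE)
    frames <- lapply(labels, function(l) {
      fr <- centers[[l]] + matrix(stats::rnorm(24, sd = jitter_sd), 8L, 3L)
      if (rigid_motion) fr <- sweep(fr %*% random_rotation(), 2L,
                                    stats::rnorm(3, sd = 10), `+`)
      fr
    })
    return(list(traj = trajectory(frames),
                truth = list(labels = labels, n_centers = n_centers,
                             jitter_sd = jitter_sd)))
  }

  folded <- if (kind == "helix") rep(TRUE, n_frames) else
    stats::runif(n_frames) < p_folded
  state <- ifelse(folded, "folded", "unfolded")
  tors <- ifelse(folded,
                 rvonmises(n_frames, torsion_means[["folded"]],
                           torsion_kappa),
                 rvonmises(n_frames, torsion_means[["unfolded"]],
                           torsion_kappa))
  ## recompute per-frame to keep the RNG stream deterministic by frame
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    quad <- chain4(tors[i])
    r <- pair_dist[[if (folded[i]) "folded" else "unfolded"]]
    pair <- rbind(c(8, 0, 0), c(8 + r, 0, 0))
    if (folded[i]) {
      dha <- rbind(c(0, 8, 0), c(1.0, 8, 0), c(1.0 + 1.9, 8, 0.1))
    } else {
      dha <- rbind(c(0, 8, 0), c(1.0, 8, 0),
                   c(1.0 + 3.5 * cos(deg2rad(80)),
                     8 + 3.5 * sin(deg2rad(80)), 0))
    }
    fr <- rbind(quad, pair, dha)
    if (rigid_motion) {
      fr <- sweep(fr %*% random_rotation(), 2L, stats::rnorm(3, sd = 10),
                  `+`)
    }
    frames[[i]] <- fr
  }
  list(traj = trajectory(frames),
       truth = list(state = state, p_folded = p_folded,
                    torsions = tors, torsion_means = torsion_means,
                    torsion_kappa = torsion_kappa, pair_dist = pair_dist,
                    torsion_quad = 1:4, pair = 5:6, dha = 7:9))
}
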