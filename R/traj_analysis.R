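## Validation statistics computed from trajectories: backbone RMSD,
## conformational clustering, folding free energy, NOE violations, Karplus
## couplings, hydrogen-bond measures and circular kernel density estimates.

KB_KCAL <- 0.0019872   # Boltzmann constant, kcal/mol/K

#' Trajectory container
#'
#' @param frames list of coordinate matrices (atoms x 3), constant atom
#'   count across frames.
#' @param atoms optional atom metadata data frame.
#' @param dt frame interval (arbitrary time unit), stored as metadata.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(frames, atoms = NULL, dt = 1) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  n <- nrow(frames[[1L]])
  if (!all(vapply(frames, nrow, 0L) == n)) {
    stop("all frames must have the same atom count")
  }
  structure(list(frames = frames, atoms = atoms, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$frames), "frames,",
      nrow(x$frames[[1L]]), "atoms\n")
  invisible(x)
}

as_frames <- function(traj) {
  if (inherits(traj, "trajectory")) traj$frames
  else if (is.list(traj)) traj
  else list(traj)
}

## Kabsch superposition of `mob` onto `ref` (both m x 3, same atom order);
## returns the rotated+translated mobile coordinates.
kabsch_fit <- function(mob, ref) {
  cm <- colMeans(mob); cr <- colMeans(ref)
  a <- sweep(mob, 2L, cm)
  b <- sweep(ref, 2L, cr)
  s <- svd(crossprod(a, b))
  d <- sign(det(s$u %*% t(s$v)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sweep(a %*% rot, 2L, cr, `+`)
}

rmsd_pair <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' Backbone RMSD per trajectory frame
#'
#' Optimal-superposition (Kabsch) root-mean-square deviation of the selected
#' atoms of each frame from a reference conformation.  The superposition is
#' unweighted.
#'
#' @param traj a `trajectory` (or list of coordinate matrices).
#' @param reference reference coordinate matrix (full atom set).
#' @param sel integer vector of atom indices to superpose and measure
#'   (default: all atoms).
#' @return numeric vector of per-frame RMSD values in Angstrom.
#' @export
backbone_rmsd <- function(traj, reference, sel = NULL) {
  frames <- as_frames(traj)
  if (is.null(sel)) sel <- seq_len(nrow(reference))
  if (!length(sel)) stop("empty atom selection")
  if (max(sel) > nrow(reference) || max(sel) > nrow(frames[[1L]])) {
    stop("selection indices exceed atom count")
  }
  ref <- reference[sel, , drop = FALSE]
  vapply(frames, function(fr) {
    rmsd_pair(kabsch_fit(fr[sel, , drop = FALSE], ref), ref)
  }, 0)
}

#' Conformational clustering by the greedy neighbour-count algorithm
#'
#' Clusters frames by pairwise RMSD: the frame with the most neighbours
#' within the cutoff forms a cluster together with those neighbours, the
#' cluster is removed, and the procedure repeats on the remainder (the
#' algorithm of Daura and co-workers).  Ties in neighbour count are broken
#' toward the lowest frame index.  Each cluster's central representative is
#' the member minimizing the summed RMSD to the other members.
#'
#' @param traj a `trajectory` or list of coordinate matrices.
#' @param cutoff RMSD cutoff in Angstrom (the reference protocol uses 1).
#' @param sel atom selection used for the pairwise RMSD (default all).
#' @return list of clusters, ordered as extracted (decreasing neighbour
#'   count); each is a list with `members` (frame indices) and
#'   `representative` (frame index).
#' @export
daura_cluster <- function(traj, cutoff = 1, sel = NULL) {
  frames <- as_frames(traj)
  nf <- length(frames)
  if (!nf) return(list())
  d <- pairwise_rmsd(frames, sel)
  remaining <- seq_len(nf)
  clusters <- list()
  while (length(remaining)) {
    sub <- d[remaining, remaining, drop = FALSE]
    counts <- rowSums(sub <= cutoff)      # includes self
    centre <- remaining[which.max(counts)]
    members <- remaining[sub[which.max(counts), ] <= cutoff]
    reps <- if (length(members) == 1L) members else {
      ms <- d[members, members, drop = FALSE]
      members[which.min(rowSums(ms))]
    }
    clusters[[length(clusters) + 1L]] <-
      list(members = members, representative = reps)
    remaining <- setdiff(remaining, members)
  }
  clusters
}

#' Pairwise superposition RMSD matrix
#'
#' @param frames list of coordinate matrices.
#' @param sel optional atom selection.
#' @return symmetric matrix of pairwise RMSD values.
#' @export
pairwise_rmsd <- function(frames, sel = NULL) {
  frames <- as_frames(frames)
  nf <- length(frames)
  if (is.null(sel)) sel <- seq_len(nrow(frames[[1L]]))
  d <- matrix(0, nf, nf)
  for (i in seq_len(nf)) {
    a <- frames[[i]][sel, , drop = FALSE]
    j <- i + 1L
    while (j <= nf) {
      b <- frames[[j]][sel, , drop = FALSE]
      d[i, j] <- d[j, i] <- rmsd_pair(kabsch_fit(a, b), b)
      j <- j + 1L
    }
  }
  d
}

#' Number of clusters needed to cover a fraction of the trajectory
#'
#' @param clusters list of clusters ([daura_cluster]) or an integer vector
#'   of cluster sizes, ordered by decreasing size.
#' @param coverage fraction of frames to cover, in (0, 1].
#' @return smallest number of top clusters whose combined size reaches the
#'   requested coverage.
#' @export
count_clusters_for_coverage <- function(clusters, coverage = 0.95) {
  if (!is.numeric(coverage) || coverage <= 0 || coverage > 1) {
    stop("coverage must lie in (0, 1]")
  }
  sizes <- if (is.numeric(clusters)) clusters else
    vapply(clusters, function(cl) length(cl$members), 0L)
  total <- sum(sizes)
  cum <- cumsum(sizes)
  which(cum >= coverage * total)[1L]
}

#' Gibbs free energy of folding from a folded-state population
#'
#' `Delta G = -kB T ln(p / (1 - p))` with `kB = 0.0019872` kcal/mol/K; the
#' folded population is typically the fraction of frames within an RMSD
#' threshold of the reference fold.
#'
#' @param p_folded folded-state probability, strictly between 0 and 1.
#' @param temperature temperature in Kelvin (default 300).
#' @return free energy of folding in kcal/mol (negative = folding favoured).
#' @examples
#' folding_free_energy(0.5)      # 0
#' @export
folding_free_energy <- function(p_folded, temperature = 300) {
  if (any(p_folded <= 0 | p_folded >= 1)) {
    stop("p_folded must lie strictly between 0 and 1")
  }
  -KB_KCAL * temperature * log(p_folded / (1 - p_folded))
}

#' NOE distance violation with r^-6 time averaging
#'
#' Computes `<r^-6>^(-1/6) - r0` for a proton pair over the trajectory.  NOE
#' bounds are upper bounds, so only positive values constitute violations.
#'
#' @param traj a `trajectory` or list of coordinate matrices.
#' @param pair integer vector of the two proton indices.
#' @param r0 experimental upper-bound distance in Angstrom.
#' @return the (signed) violation in Angstrom.
#' @export
noe_violation <- function(traj, pair, r0) {
  stopifnot(length(pair) == 2L, r0 > 0)
  frames <- as_frames(traj)
  r <- vapply(frames, function(fr) {
    sqrt(sum((fr[pair[1L], ] - fr[pair[2L], ])^2))
  }, 0)
  if (any(r < 1e-8)) stop("zero interproton distance in trajectory")
  mean(r^-6)^(-1 / 6) - r0
}

#' Three-bond scalar coupling via the Karplus relation
#'
#' `3J = <a cos^2 theta + b cos theta + c>`, averaged over frames.  The
#' conventional coefficient sets are `c(6.4, -1.4, 1.9)` Hz for couplings
#' between an amide and an aliphatic proton and `c(9.5, -1.6, 1.8)` Hz for
#' aliphatic-aliphatic couplings.
#'
#' @param traj a `trajectory` or list of coordinate matrices.
#' @param quad four atom indices defining the torsion theta.
#' @param coeffs numeric vector `c(a, b, c)` in Hz.
#' @return the averaged coupling constant in Hz.
#' @export
karplus_j <- function(traj, quad, coeffs = c(6.4, -1.4, 1.9)) {
  stopifnot(length(coeffs) == 3L)
  frames <- as_frames(traj)
  th <- deg2rad(vapply(frames, function(fr) dihedral_angle(fr, quad), 0))
  mean(coeffs[1L] * cos(th)^2 + coeffs[2L] * cos(th) + coeffs[3L])
}

#' Geometric hydrogen-bond population
#'
#' Fraction of frames in which the donor-hydrogen-acceptor angle is strictly
#' greater than the angle cutoff and the hydrogen-acceptor distance strictly
#' smaller than the distance cutoff.
#'
#' @param traj a `trajectory` or list of coordinate matrices.
#' @param donor,hydrogen,acceptor atom indices.
#' @param angle_cutoff minimum D-H-A angle in degrees (default 125).
#' @param dist_cutoff maximum H..A distance in Angstrom (default 2.4).
#' @return fraction of frames in `[0, 1]`.
#' @export
hbond_population <- function(traj, donor, hydrogen, acceptor,
                             angle_cutoff = 125, dist_cutoff = 2.4) {
  frames <- as_frames(traj)
  hits <- vapply(frames, function(fr) {
    dist <- sqrt(sum((fr[hydrogen, ] - fr[acceptor, ])^2))
    ang <- bond_angle(fr, c(donor, hydrogen, acceptor))
    ## ties break toward "not bonded": strict inequalities with a tiny
    ## guard so boundary geometries are excluded despite rounding
    ang > angle_cutoff + 1e-9 && dist < dist_cutoff - 1e-9
  }, TRUE)
  mean(hits)
}

#' Switching-function hydrogen-bond count
#'
#' Smooth per-frame count over hydrogen-acceptor pairs using the rational
#' switching function `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with the
#' removable singularity at `r0` evaluated as `n/m` (the convention of
#' the PLUMED implementation, default `r0 = 2` Angstrom, `n = 6`, `m = 10`).
#'
#' @param traj a `trajectory` or list of coordinate matrices.
#' @param pairs two-column matrix of hydrogen/acceptor index pairs.
#' @param r0,n,m switching-function parameters.
#' @return numeric vector: the real-valued count per frame.
#' @export
hbond_switching_count <- function(traj, pairs, r0 = 2, n = 6, m = 10) {
  frames <- as_frames(traj)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  vapply(frames, function(fr) {
    r <- sqrt(rowSums((fr[pairs[, 1L], , drop = FALSE] -
                         fr[pairs[, 2L], , drop = FALSE])^2))
    sum(switching_value(r, r0, n, m))
  }, 0)
}

#' @rdname hbond_switching_count
#' @param r distance(s) in Angstrom.
#' @export
switching_value <- function(r, r0 = 2, n = 6, m = 10) {
  x <- r / r0
  out <- (1 - x^n) / (1 - x^m)
  at_r0 <- abs(x - 1) < 1e-9
  out[at_r0] <- n / m
  out
}

#' Circular kernel density estimate for torsion angles
#'
#' Kernel density estimation on the circle using a von Mises (cyclic
#' Gaussian) kernel whose concentration corresponds to the requested
#' bandwidth, or an ordinary Gaussian KDE on the line for non-periodic
#' quantities.  The von Mises density integrates to one over a full period.
#'
#' @param samples angles in degrees (von Mises) or arbitrary values
#'   (gaussian).
#' @param bandwidth kernel bandwidth; degrees for the von Mises kernel.
#' @param kernel `"von_mises"` (default) or `"gaussian"`.
#' @param n number of grid points.
#' @return list with `x` (grid), `y` (density per degree or per unit), and
#'   `bandwidth`.
#' @export
circular_kde <- function(samples, bandwidth = 5,
                         kernel = c("von_mises", "gaussian"), n = 512L) {
  if (!length(samples)) stop("no samples supplied")
  if (bandwidth <= 0) stop("bandwidth must be positive")
  kernel <- match.arg(kernel)
  if (kernel == "gaussian") {
    d <- stats::density(samples, bw = bandwidth, n = n)
    return(list(x = d$x, y = d$y, bandwidth = bandwidth))
  }
  kappa <- 1 / deg2rad(bandwidth)^2
  grid <- seq(-180, 180, length.out = n + 1L)[-1L]
  th <- deg2rad(grid)
  s <- deg2rad(wrap_angle(samples))
  ## log-I0 via scaled Bessel keeps large concentrations finite
  log_norm <- log(2 * pi) + log(besselI(kappa, 0, expon.scaled = TRUE)) +
    kappa
  y <- vapply(th, function(t) {
    mean(exp(kappa * cos(t - s) - log_norm))
  }, 0)
  ## density per degree so that the integral over (-180, 180] is one
  list(x = grid, y = y * pi / 180, bandwidth = bandwidth)
}

#' Scott's-rule bandwidth
#'
#' `sigma-hat * N^(-1/5)` with the plain sample standard deviation.
#'
#' @param samples numeric samples.
#' @return the bandwidth on the scale of the samples.
#' @export
scott_bandwidth <- function(samples) {
  stats::sd(samples) * length(samples)^(-1 / 5)
}
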