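test_that("backbone RMSD removes rigid motion and matches a Kabsch oracle", {
  set.seed(31)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(backbone_rmsd(list(ref), ref), 0, tolerance = 1e-10)

  ## rigidly moved copy superposes to zero
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3)
  moved <- sweep(ref %*% rot, 2, c(3, -2, 8), `+`)
  expect_equal(backbone_rmsd(list(moved), ref), 0, tolerance = 1e-10)

  ## two tabulated 4-point toys against an independent superposition
  ## (closed-form via eigendecomposition of the quaternion matrix)
  a <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  b <- a + matrix(rnorm(12, sd = 0.2), 4, 3)
  oracle <- function(mob, refm) {
    mc <- sweep(mob, 2, colMeans(mob))
    rc <- sweep(refm, 2, colMeans(refm))
    best <- Inf
    ## brute force over a fine rotation grid is impractical; use the
    ## quaternion eigenvalue method as the independent route
    M <- crossprod(mc, rc)
    Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
    Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
    Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
    K <- matrix(c(
      Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
      Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
      Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
      Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
    lam <- max(eigen(K, symmetric = TRUE)$values)
    sqrt(max(0, (sum(mc^2) + sum(rc^2) - 2 * lam)) / nrow(mob))
  }
  expect_equal(backbone_rmsd(list(b), a), oracle(b, a),
               tolerance = 1e-8)

  expect_error(backbone_rmsd(list(ref), ref, sel = integer()), "empty")
})

test_that("neighbour-count clustering matches the exhaustive oracle", {
  ## two well-separated tight bundles are recovered exactly
  sb <- synth_trajectory("bundles", n_frames = 40, seed = 5,
                         n_centers = 2)
  cl <- daura_cluster(sb$traj, cutoff = 1)
  expect_identical(length(cl), 2L)
  got <- lapply(cl, function(x) sort(x$members))
  want <- split(seq_along(sb$truth$labels), sb$truth$labels)
  expect_true(all(vapply(got, function(g) {
    any(vapply(want, function(w) identical(g, unname(w)), TRUE))
  }, TRUE)))

  ## random instances of <= 20 frames against the brute-force oracle
  for (seed in 1:8) {
    set.seed(seed)
    nf <- sample(3:20, 1)
    frames <- replicate(nf, matrix(rnorm(15, sd = sample(c(0.3, 1.5), 1)),
                                   5, 3), simplify = FALSE)
    cutoff <- runif(1, 0.5, 2)
    d <- pairwise_rmsd(frames)
    got <- lapply(daura_cluster(frames, cutoff),
                  function(x) sort(x$members))
    want <- oracle_daura(d, cutoff)
    expect_identical(got, want)
  }

  ## representative minimizes the summed RMSD to the other members
  cl1 <- cl[[1]]
  d <- pairwise_rmsd(sb$traj$frames)
  sums <- rowSums(d[cl1$members, cl1$members, drop = FALSE])
  expect_identical(cl1$representative,
                   cl1$members[which.min(sums)])

  expect_identical(daura_cluster(list(), 1), list())
})

test_that("cluster coverage counts follow the cumulative rule", {
  expect_identical(count_clusters_for_coverage(c(100), 0.95), 1L)
  expect_identical(count_clusters_for_coverage(c(50, 30, 20), 0.95), 3L)
  expect_identical(count_clusters_for_coverage(c(96, 4), 0.95), 1L)
  expect_error(count_clusters_for_coverage(c(10, 5), 1.2), "coverage")
})

test_that("folding free energy matches the two-state formula", {
  expect_equal(folding_free_energy(0.5), 0)
  ## invert the formula at a representative helix stability of
  ## -1.91 kcal/mol at 300 K: p = 1 / (1 + exp(dG / kBT))
  kbt <- 0.0019872 * 300
  p <- 1 / (1 + exp(-1.91 / kbt))
  expect_equal(folding_free_energy(p, 300), -1.91, tolerance = 1e-10)
  ## antisymmetry
  for (p in c(0.1, 0.37, 0.8)) {
    expect_equal(folding_free_energy(p), -folding_free_energy(1 - p),
                 tolerance = 1e-12)
  }
  expect_error(folding_free_energy(1), "between")
})

test_that("NOE violations use r^-6 time averaging", {
  frame_at <- function(r) rbind(c(0, 0, 0), c(r, 0, 0))
  ## constant distance at the bound: zero violation
  expect_equal(noe_violation(list(frame_at(2), frame_at(2)), 1:2, 2), 0,
               tolerance = 1e-12)
  ## frames at 2 and 4 Angstrom with a 2 Angstrom bound
  expect_equal(noe_violation(list(frame_at(2), frame_at(4)), 1:2, 2),
               ((2^-6 + 4^-6) / 2)^(-1 / 6) - 2, tolerance = 1e-12)
  ## the r^-6 average never exceeds the arithmetic mean (power mean)
  set.seed(41)
  for (k in 1:5) {
    r <- runif(20, 1.5, 6)
    frames <- lapply(r, frame_at)
    v <- noe_violation(frames, 1:2, 2)    # violation = <r^-6>^(-1/6) - 2
    expect_lte(v + 2, mean(r))
  }
})

test_that("Karplus couplings average the torsion-dependent form", {
  quad_at <- function(th) {
    rbind(c(0, 1.5, 0), c(0, 0, 0), c(1.5, 0, 0),
          betamep:::nerf_place(c(1.5, 0, 0), c(0, 0, 0), c(0, 1.5, 0),
                               1.5, 110, th))
  }
  ## cos(90 deg) = 0: only the constant c survives
  expect_equal(karplus_j(list(quad_at(90)), 4:1), 1.9, tolerance = 1e-9)
  ## anti-periplanar with the amide-aliphatic set: a + (-b) + c = 9.7 Hz
  expect_equal(karplus_j(list(quad_at(180)), 4:1), 6.4 + 1.4 + 1.9,
               tolerance = 1e-9)
  ## the aliphatic-aliphatic set
  expect_equal(karplus_j(list(quad_at(180)), 4:1, c(9.5, -1.6, 1.8)),
               9.5 + 1.6 + 1.8, tolerance = 1e-9)
  ## averaging linearity over concatenated trajectories
  f1 <- lapply(c(40, 80, 120), quad_at)
  f2 <- lapply(c(-30, 170), quad_at)
  j12 <- karplus_j(c(f1, f2), 4:1)
  expect_equal(j12, (3 * karplus_j(f1, 4:1) + 2 * karplus_j(f2, 4:1)) / 5,
               tolerance = 1e-12)
})

test_that("hydrogen-bond criteria use strict thresholds", {
  dha <- function(angle, dist) {
    h <- c(0, 0, 0)
    d <- c(-1, 0, 0)
    a <- h + dist * c(cos(deg2rad(180 - angle)),
                      sin(deg2rad(180 - angle)), 0)
    rbind(d, h, a)
  }
  expect_equal(hbond_population(list(dha(180, 1.9)), 1, 2, 3), 1)
  expect_equal(hbond_population(list(dha(120, 1.9)), 1, 2, 3), 0)
  expect_equal(hbond_population(list(dha(170, 2.8)), 1, 2, 3), 0)
  ## exactly at the angle threshold: not bonded (strict inequality)
  expect_equal(hbond_population(list(dha(125, 1.9)), 1, 2, 3), 0)
  ## loosening the criteria never lowers the population
  frames <- lapply(seq(100, 180, by = 10), function(a) dha(a, 2.2))
  p_tight <- hbond_population(frames, 1, 2, 3, 140, 2.0)
  p_loose <- hbond_population(frames, 1, 2, 3, 125, 2.4)
  expect_gte(p_loose, p_tight)
})

test_that("the switching function obeys its limits and monotonicity", {
  expect_equal(switching_value(1e-9), 1, tolerance = 1e-9)
  ## removable singularity at r0: n/m
  expect_equal(switching_value(2), 0.6, tolerance = 1e-12)
  ## strictly decreasing on a fine sweep
  r <- seq(0.05, 8, by = 0.05)
  s <- switching_value(r)
  expect_true(all(diff(s) < 0))
  ## per-frame counts sum over pairs
  fr <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0))
  cnt <- hbond_switching_count(list(fr), rbind(c(1, 2), c(1, 3)))
  expect_equal(cnt, switching_value(2) + switching_value(4),
               tolerance = 1e-12)
})

test_that("the circular KDE is normalized and wraps correctly", {
  ## integral over one period equals one (trapezoid quadrature)
  set.seed(51)
  samples <- runif(200, -180, 180)
  kde <- circular_kde(samples, bandwidth = 5)
  dx <- diff(kde$x[1:2])
  expect_equal(sum(kde$y) * dx, 1, tolerance = 1e-6)

  ## a single sample puts the mode at the sample
  one <- circular_kde(37.3, bandwidth = 5, n = 3600)
  expect_lt(abs(wrap_angle(one$x[which.max(one$y)] - 37.3)), 0.2)

  ## samples at +179 and -179 give a single mode near 180 (wrapping)
  two <- circular_kde(c(179, -179), bandwidth = 5, n = 720)
  mode <- two$x[which.max(two$y)]
  expect_lt(abs(wrap_angle(mode - 180)), 1.5)

  expect_error(circular_kde(10, bandwidth = 0), "bandwidth")

  ## Scott's rule
  x <- rnorm(1000, sd = 2)
  expect_equal(scott_bandwidth(x), sd(x) * 1000^(-1 / 5),
               tolerance = 1e-12)
})

test_that("trajectory statistics are invariant under rigid motion", {
  st <- synth_trajectory("two_state", n_frames = 30, seed = 3,
                         rigid_motion = FALSE)
  moved <- synth_trajectory("two_state", n_frames = 30, seed = 3,
                            rigid_motion = TRUE)
  tq <- st$truth$torsion_quad
  pr <- st$truth$pair
  dha <- st$truth$dha
  expect_equal(karplus_j(moved$traj, tq), karplus_j(st$traj, tq),
               tolerance = 1e-8)
  expect_equal(noe_violation(moved$traj, pr, 2.5),
               noe_violation(st$traj, pr, 2.5), tolerance = 1e-8)
  expect_equal(hbond_population(moved$traj, dha[1], dha[2], dha[3]),
               hbond_population(st$traj, dha[1], dha[2], dha[3]))
  expect_equal(hbond_switching_count(moved$traj, t(pr)),
               hbond_switching_count(st$traj, t(pr)), tolerance = 1e-8)
})
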